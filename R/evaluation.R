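#' Per-cell-type Pearson correlation between estimated and true proportions
#'
#' Correlates estimates and truth across mixtures, one coefficient per cell
#' type. A type with zero variance in the truth has no defined correlation
#' and is reported as `NA` (not coerced to 0), so summary means must skip it
#' explicitly.
#'
#' @param est a `proportion_estimates` or mixture x cell-type matrix.
#' @param truth mixture x cell-type matrix (same dimensions and order).
#' @return named numeric vector of correlations in `[-1, 1]` (or `NA`).
#' @export
accuracy_correlation <- function(est, truth) {
  E <- if (inherits(est, "proportion_estimates")) est$values else as.matrix(est)
  truth <- as.matrix(truth)
  if (!all(dim(E) == dim(truth))) stop("estimate and truth dimensions differ")
  if (nrow(E) < 3) stop("need >= 3 mixtures for a correlation")
  out <- vapply(seq_len(ncol(E)), function(j) {
    if (sd(truth[, j]) == 0 || sd(E[, j]) == 0) return(NA_real_)
    cor(E[, j], truth[, j])
  }, numeric(1))
  setNames(out, colnames(truth))
}

#' Normalised mean absolute error of proportion estimates
#'
#' For each cell type, the mean over mixtures of the absolute difference
#' between estimate and truth, divided by the mean true proportion. 0 means
#' perfect recovery; an estimator stuck at zero scores exactly 1. A type
#' with zero mean truth has no defined nmae and is reported as `NA`.
#'
#' @inheritParams accuracy_correlation
#' @return named numeric vector of non-negative values (or `NA`).
#' @export
nmae <- function(est, truth) {
  E <- if (inherits(est, "proportion_estimates")) est$values else as.matrix(est)
  truth <- as.matrix(truth)
  if (!all(dim(E) == dim(truth))) stop("estimate and truth dimensions differ")
  out <- vapply(seq_len(ncol(E)), function(j) {
    mt <- mean(truth[, j])
    if (mt == 0) return(NA_real_)
    mean(abs(E[, j] - truth[, j])) / mt
  }, numeric(1))
  setNames(out, colnames(truth))
}

#' Reconstruction goodness-of-fit for samples without ground truth
#'
#' When true composition is unknown (real bulk tissue), accuracy is proxied
#' by how well the estimated composition reconstructs the observed
#' expression: each sample is reconstructed as the signature-weighted sum
#' `sum_j s_j p_j` and correlated (Pearson) with the observed profile on the
#' log2(x + 0.5) scale. Observed and signature columns are quantile
#' normalised beforehand — jointly by default (one column pool), or
#' per-matrix with `qn = "separate"`, or not at all with `qn = "none"`.
#'
#' @param mixtures a [mixture_set] or gene x sample matrix.
#' @param signature a [signature_matrix()].
#' @param est a `proportion_estimates` or mixture x cell-type matrix whose
#'   rows correspond to the mixture columns.
#' @param qn quantile-normalisation mode: `"joint"` (default),
#'   `"separate"`, or `"none"`.
#' @return named per-sample vector of correlations.
#' @export
goodness_of_fit <- function(mixtures, signature, est, qn = c("joint", "separate", "none")) {
  qn <- match.arg(qn)
  al <- align_features(mixtures, signature)
  E <- if (inherits(est, "proportion_estimates")) est$values else as.matrix(est)
  if (nrow(E) != ncol(al$mixtures)) stop("one estimate row per mixture required")
  X <- al$mixtures
  S <- al$signature[, colnames(E), drop = FALSE]
  if (qn == "joint") {
    pool <- quantile_normalize(cbind(X, S))
    X <- pool[, seq_len(ncol(X)), drop = FALSE]
    S <- pool[, ncol(X) + seq_len(ncol(S)), drop = FALSE]
  } else if (qn == "separate") {
    X <- quantile_normalize(X)
    S <- quantile_normalize(S)
  }
  recon <- S %*% t(E)
  out <- vapply(seq_len(ncol(X)), function(i) {
    cor(log2p5(X[, i]), log2p5(recon[, i]))
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Collinearity and abundance diagnostics for a signature
#'
#' Cell types whose signature columns are highly rank-correlated are hard to
#' separate, and types below ~2% abundance are estimated poorly; both are
#' failure modes worth flagging before deconvolution. Correlations are
#' computed between signature columns on log2(x + 0.5); Spearman by default
#' since rank agreement is what degrades separability.
#'
#' @param signature a [signature_matrix()].
#' @param truth optional mixture x cell-type truth matrix used for the
#'   low-abundance flag.
#' @param rho_threshold collinearity flag threshold (default 0.95).
#' @param abundance_threshold low-abundance flag threshold on the mean true
#'   proportion (default 0.02).
#' @param method correlation type, `"spearman"` (default) or `"pearson"`.
#' @return list: `rho` (cell-type pairwise correlation matrix) and `flags`
#'   (data frame with `collinear` and, when truth is given, `low_abundance`
#'   per type).
#' @export
collinearity_diagnostics <- function(signature, truth = NULL, rho_threshold = 0.95,
                                     abundance_threshold = 0.02,
                                     method = c("spearman", "pearson")) {
  stopifnot(inherits(signature, "signature_matrix"))
  method <- match.arg(method)
  lg <- log2p5(signature$values)
  rho <- cor(lg, method = method)
  off <- rho; diag(off) <- NA
  flags <- data.frame(
    cell_type = colnames(rho),
    max_rho = apply(off, 1, max, na.rm = TRUE),
    collinear = apply(off, 1, max, na.rm = TRUE) > rho_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(truth)) {
    mt <- colMeans(as.matrix(truth))[flags$cell_type]
    flags$mean_abundance <- as.numeric(mt)
    flags$low_abundance <- as.numeric(mt) < abundance_threshold
  }
  list(rho = rho, flags = flags)
}

#' Effect of omitting one cell type from the signature
#'
#' Runs the random-mixture benchmark twice — once with the full signature
#' and once with `drop_type`'s column removed — and reports the per-type
#' change in correlation and nmae. Since estimates are renormalised to the
#' simplex, RNA from the missing type is redistributed over the remaining
#' types, degrading them in proportion to the missing type's abundance.
#'
#' @param dataset an `sc_dataset` (split internally into signature and
#'   mixture halves).
#' @param drop_type cell type to omit.
#' @param n_mixtures,cells_per_mixture passed to
#'   [simulate_random_mixtures()].
#' @param seed integer seed.
#' @return list with `full` and `dropped` evaluation tables (per-type r and
#'   nmae against pRNA) and `delta` (dropped minus full, for the retained
#'   types).
#' @export
missing_type_experiment <- function(dataset, drop_type, n_mixtures = 50,
                                    cells_per_mixture = 200, seed = 1L) {
  stopifnot(inherits(dataset, "sc_dataset"))
  if (!drop_type %in% levels(dataset$cell_type)) stop("unknown cell type: ", drop_type)
  halves <- split_dataset(dataset, 0.5, seed)
  sig <- build_signature(halves$signature_half, "CPM")
  mix <- simulate_random_mixtures(halves$mixture_half, n_mixtures, cells_per_mixture, seed)
  sig_drop <- sig
  sig_drop$values <- sig$values[, setdiff(colnames(sig$values), drop_type), drop = FALSE]
  eval_one <- function(s) {
    est <- deconvolve_nnls(mix, s)
    keep <- colnames(est$values)
    data.frame(cell_type = keep,
               r = accuracy_correlation(est, mix$truth_pRNA[, keep, drop = FALSE]),
               nmae = nmae(est, mix$truth_pRNA[, keep, drop = FALSE]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  full <- eval_one(sig)
  dropped <- eval_one(sig_drop)
  common <- intersect(full$cell_type, dropped$cell_type)
  delta <- data.frame(
    cell_type = common,
    delta_r = dropped$r[match(common, dropped$cell_type)] -
      full$r[match(common, full$cell_type)],
    delta_nmae = dropped$nmae[match(common, dropped$cell_type)] -
      full$nmae[match(common, full$cell_type)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(full = full, dropped = dropped, delta = delta, drop_type = drop_type)
}

#' Summarise a deconvolution run as an evaluation report
#'
#' Bundles per-type correlation and nmae, per-sample goodness-of-fit, and
#' the signature diagnostics into one object, and serialises it as JSON
#' plus a flat per-cell-type TSV.
#'
#' @param est a `proportion_estimates`.
#' @param truth mixture x cell-type truth matrix (pRNA by default in this
#'   package's benchmarks).
#' @param mixtures,signature optional; when both are given, per-sample
#'   goodness-of-fit and collinearity diagnostics are included.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(est, truth, mixtures = NULL, signature = NULL) {
  rep <- list(
    method = est$method,
    per_type = data.frame(
      cell_type = colnames(truth),
      r = accuracy_correlation(est, truth),
      nmae = nmae(est, truth),
      stringsAsFactors = FALSE, row.names = NULL
    )
  )
  if (!is.null(mixtures) && !is.null(signature)) {
    rep$per_sample_gof <- goodness_of_fit(mixtures, signature, est)
    diag <- collinearity_diagnostics(signature, truth)
    rep$flags <- diag$flags
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report [", x$method, "]\n")
  print(x$per_type, digits = 3)
  if (!is.null(x$per_sample_gof)) {
    cat("median goodness-of-fit:", round(median(x$per_sample_gof), 3), "\n")
  }
  invisible(x)
}

#' @rdname evaluation_report
#' @param report an `evaluation_report`.
#' @param path_json,path_tsv output paths (either may be `NULL`).
#' @export
write_evaluation_report <- function(report, path_json = NULL, path_tsv = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, na = "null")
  }
  if (!is.null(path_tsv)) {
    write.table(report$per_type, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
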