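#' Two-group differential expression by per-gene ordinary least squares
#'
#' Fits, for every gene, an ordinary least-squares model of
#' log2(expression + 0.5) on a group indicator plus optional composition
#' covariate terms, and tests the group coefficient with a two-sided t test;
#' p-values are Benjamini-Hochberg adjusted across all tested genes. The
#' covariate (typically the target cell type's proportion) can enter as a
#' linear term, with an added quadratic term, or as a cubic B-spline basis
#' with interior knots at its 25th/50th/75th percentiles.
#'
#' All genes share one design matrix, so the fit is a single QR
#' decomposition applied to every gene at once.
#'
#' @param expr gene x sample matrix of linear-scale normalised expression
#'   (e.g. CPM); log2(x + 0.5) is taken internally.
#' @param group factor/character/logical of length `ncol(expr)` with exactly
#'   two levels, each with >= 3 samples. The reported log2 fold-change is
#'   second level vs first.
#' @param covariate optional numeric vector of length `ncol(expr)`.
#' @param covariate_form `"none"`, `"linear"`, `"quadratic"`, or
#'   `"spline"`.
#' @return `de_result`: data frame with `gene`, `log2fc`, `t`, `p`, `fdr`,
#'   plus the model descriptor in attributes.
#' @export
differential_expression <- function(expr, group, covariate = NULL,
                                    covariate_form = c("none", "linear",
                                                       "quadratic", "spline")) {
  covariate_form <- match.arg(covariate_form)
  expr <- as.matrix(expr)
  assert_genes_rows(expr, "expression matrix")
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 3)) stop("each group needs >= 3 samples")
  if (length(group) != ncol(expr)) stop("group length must equal sample count")
  X <- cbind(intercept = 1, group = as.numeric(group == levels(group)[2]))
  if (covariate_form != "none") {
    if (is.null(covariate)) stop("covariate_form '", covariate_form,
                                 "' requires a covariate")
    if (length(covariate) != ncol(expr)) stop("covariate length must equal sample count")
    Z <- switch(covariate_form,
      linear = cbind(cov = covariate),
      quadratic = cbind(cov = covariate, cov2 = covariate^2),
      spline = {
        kn <- quantile(covariate, c(0.25, 0.5, 0.75))
        b <- splines::bs(covariate, degree = 3, knots = kn)
        colnames(b) <- paste0("bs", seq_len(ncol(b)))
        b
      })
    X <- cbind(X, Z)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient: the covariate ('", covariate_form,
         "') is collinear with the intercept + group design")
  }
  Y <- t(log2p5(expr))                       # samples x genes
  coef <- qr.coef(qrX, Y)                    # p x genes
  resid <- qr.resid(qrX, Y)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtXinv_gg <- chol2inv(qr.R(qrX))[2, 2]     # variance factor of the group coefficient
  se <- sqrt(sigma2 * XtXinv_gg)
  tstat <- coef["group", ] / se
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  p[se == 0] <- 1                            # constant gene: no evidence either way
  out <- data.frame(gene = rownames(expr),
                    log2fc = as.numeric(coef["group", ]),
                    t = as.numeric(tstat),
                    p = as.numeric(p),
                    fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "model") <- list(covariate_form = covariate_form,
                             group_sizes = as.integer(table(group)),
                             df_residual = df)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Count false-positive discoveries
#'
#' Discoveries at the FDR threshold that are not in the set of truly
#' perturbed genes. With no perturbation every discovery is a false
#' positive.
#'
#' @param de a `de_result`.
#' @param truth_perturbed character vector of truly perturbed genes (may be
#'   empty).
#' @param fdr significance threshold (default 0.05).
#' @return integer count.
#' @export
count_false_positives <- function(de, truth_perturbed = character(), fdr = 0.05) {
  disc <- de$gene[de$fdr < fdr]
  length(setdiff(disc, truth_perturbed))
}

#' Cell-type marker enrichment among false-positive genes
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) of the overlap
#' between the false-positive gene set and each cell type's markers, over a
#' stated background. Composition-driven false positives are expected to be
#' strongly enriched for markers of the shifted cell type. To ensure
#' adequate power the test is gated: when the false-positive set has 100 or
#' fewer genes, `NA` is returned for every type.
#'
#' @param fp_genes character vector of false-positive genes.
#' @param markers a `marker_map`.
#' @param background character vector of all tested genes.
#' @param min_fp gate: enrichment is only computed when
#'   `length(fp_genes) > min_fp` (default 100).
#' @return named per-type vector of one-sided p-values (or `NA` when
#'   gated).
#' @export
marker_enrichment <- function(fp_genes, markers, background, min_fp = 100) {
  stopifnot(inherits(markers, "marker_map"))
  if (length(fp_genes) <= min_fp) {
    return(setNames(rep(NA_real_, length(markers)), names(markers)))
  }
  fp <- intersect(fp_genes, background)
  vapply(markers, function(m) {
    mk <- intersect(m$gene, background)
    q <- length(intersect(fp, mk))
    phyper(q - 1, length(mk), length(background) - length(mk), length(fp),
           lower.tail = FALSE)
  }, numeric(1))
}

#' Discriminatory power of a differential-expression ranking
#'
#' The fraction of the truly perturbed genes found among the top-n most
#' significant genes, where n is the number of perturbed genes. Ties in p
#' are broken by descending |log2FC|, then by gene id, so the ranking is
#' deterministic.
#'
#' @param de a `de_result`.
#' @param perturbed character vector of truly perturbed genes.
#' @return fraction in `[0, 1]`.
#' @export
discriminatory_power <- function(de, perturbed) {
  n <- length(perturbed)
  if (n == 0) stop("empty perturbed set")
  ord <- order(de$p, -abs(de$log2fc), de$gene)
  top <- de$gene[ord][seq_len(min(n, nrow(de)))]
  length(intersect(top, perturbed)) / n
}

#' Smallest composition shift at which discriminatory power degrades
#'
#' A correction strategy is robust up to the composition difference at
#' which its discriminatory power first drops below its expected value,
#' defined as 0.95 times the power of an uncorrected model in a simulation
#' with no composition confound.
#'
#' @param power_by_shift named numeric vector: tested shift (proportion
#'   units, names coercible to numeric) -> power.
#' @param baseline_power power of the uncorrected model at zero shift.
#' @return the smallest shift whose power is below `0.95 * baseline_power`;
#'   if none, the largest tested shift with attribute `not_reached = TRUE`.
#' @export
robustness_threshold <- function(power_by_shift, baseline_power) {
  shifts <- as.numeric(names(power_by_shift))
  if (anyNA(shifts)) stop("power_by_shift must be named by numeric shifts")
  o <- order(shifts)
  shifts <- shifts[o]
  pw <- as.numeric(power_by_shift)[o]
  below <- which(pw < 0.95 * baseline_power)
  if (!length(below)) {
    return(structure(max(shifts), not_reached = TRUE))
  }
  structure(shifts[below[1]], not_reached = FALSE)
}

#' Run the composition-confound differential-expression experiment
#'
#' For each tested shift k: simulates two 50-sample groups whose
#' `target_type` proportion differs by about k/cells (pCt), optionally
#' perturbs marker/non-marker gene sets by `fold` in group A, runs the OLS
#' differential expression with each requested covariate form (covariate =
#' true target-type pRNA, or an NNLS estimate with
#' `covariate_source = "estimate"`), and collects false-positive counts,
#' discriminatory power, and per-type marker enrichment.
#'
#' @param dataset an `sc_dataset`.
#' @param target_type cell type whose proportion is shifted.
#' @param shifts integer vector of range shifts k (cells; pCt shift is
#'   k/cells).
#' @param fold perturbation fold; `NULL` or 1 for no planted expression
#'   change.
#' @param n_marker_genes,n_nonmarker_genes perturbation set sizes (default
#'   100 each), passed to [perturb_expression()].
#' @param covariate_forms subset of `c("none","linear","quadratic",
#'   "spline")`.
#' @param markers a `marker_map` (built from the dataset if `NULL`).
#' @param covariate_source `"truth"` (true target-type pRNA; default) or
#'   `"estimate"` (NNLS estimate from a signature built on a held-out
#'   half).
#' @param n_per_group,cells,n_range passed to
#'   [simulate_confounded_groups()].
#' @param fdr discovery threshold.
#' @param min_expr expression filter: only genes with mean CPM above this
#'   value across all samples are tested (default 1); the enrichment
#'   background is the filtered gene set.
#' @param seed integer seed.
#' @return `confound_report`: data frame with one row per (shift,
#'   covariate_form): `shift`, `pct_shift`, `covariate_form`, `fp_count`,
#'   `power`, and `enrich_<type>` columns; the robustness threshold per
#'   covariate form is attached as attribute `robustness` when a
#'   perturbation was planted.
#' @export
run_confound_experiment <- function(dataset, target_type, shifts = c(0, 50, 100),
                                    fold = NULL,
                                    n_marker_genes = 100, n_nonmarker_genes = 100,
                                    covariate_forms = c("none", "linear"),
                                    markers = NULL,
                                    covariate_source = c("truth", "estimate"),
                                    n_per_group = 50, cells = 500,
                                    n_range = c(200, 300), fdr = 0.05,
                                    min_expr = 1, seed = 1L) {
  stopifnot(inherits(dataset, "sc_dataset"))
  covariate_source <- match.arg(covariate_source)
  covariate_forms <- match.arg(covariate_forms,
                               c("none", "linear", "quadratic", "spline"),
                               several.ok = TRUE)
  if (is.null(markers)) {
    markers <- select_markers(build_signature(dataset, "CPM"), top = 100)
  }
  sig <- if (covariate_source == "estimate") build_signature(dataset, "CPM") else NULL
  rows <- list()
  for (k in shifts) {
    sk <- substream_seed(seed, paste0("confound_k", k))
    grp <- simulate_confounded_groups(dataset, target_type, k_shift = k,
                                      direction = "up", n_per_group = n_per_group,
                                      cells = cells, n_range = n_range, seed = sk)
    perturbed <- character()
    if (!is.null(fold) && fold != 1) {
      grp$groupA <- perturb_expression(grp$groupA, fold, markers, target_type,
                                       target_mixtures = seq_len(n_per_group),
                                       n_marker_genes = n_marker_genes,
                                       n_nonmarker_genes = n_nonmarker_genes,
                                       seed = sk)
      perturbed <- grp$groupA$perturbation$genes
    }
    expr <- cbind(grp$groupA$expression, grp$groupB$expression)
    colnames(expr) <- sprintf("S%03d", seq_len(ncol(expr)))
    expr <- expr[rowMeans(expr) > min_expr, , drop = FALSE]
    group <- rep(c("A", "B"), each = n_per_group)
    covariate <- if (covariate_source == "truth") {
      c(grp$groupA$truth_pRNA[, target_type], grp$groupB$truth_pRNA[, target_type])
    } else {
      est <- deconvolve_nnls(expr, sig)
      est$values[, target_type]
    }
    for (form in covariate_forms) {
      de <- differential_expression(expr, group,
                                    covariate = if (form == "none") NULL else covariate,
                                    covariate_form = form)
      fp_genes <- setdiff(de$gene[de$fdr < fdr], perturbed)
      enrich <- marker_enrichment(fp_genes, markers, background = de$gene)
      row <- data.frame(shift = k, pct_shift = k / cells, covariate_form = form,
                        fp_count = length(fp_genes),
                        power = if (length(perturbed)) {
                          discriminatory_power(de, perturbed)
                        } else NA_real_,
                        stringsAsFactors = FALSE)
      for (tp in names(enrich)) row[[paste0("enrich_", tp)]] <- enrich[[tp]]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("confound_report", "data.frame")
  if (!is.null(fold) && fold != 1) {
    base <- out$power[out$shift == min(shifts) & out$covariate_form == "none"]
    if (length(base) == 1 && min(shifts) == 0) {
      rob <- lapply(split(out, out$covariate_form), function(d) {
        robustness_threshold(setNames(d$power, d$pct_shift), base)
      })
      attr(out, "robustness") <- rob
      attr(out, "baseline_power") <- base
    }
  }
  out
}

#' Serialise a confound report as JSON and tidy TSV
#'
#' @param report a `confound_report`.
#' @param path_json,path_tsv output paths (either may be `NULL`).
#' @return the report, invisibly.
#' @export
write_confound_report <- function(report, path_json = NULL, path_tsv = NULL) {
  stopifnot(inherits(report, "confound_report"))
  if (!is.null(path_json)) {
    payload <- list(table = as.data.frame(report))
    if (!is.null(attr(report, "robustness"))) {
      payload$robustness <- lapply(attr(report, "robustness"), as.numeric)
      payload$baseline_power <- attr(report, "baseline_power")
    }
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  if (!is.null(path_tsv)) {
    write.table(as.data.frame(report), path_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(report)
}
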