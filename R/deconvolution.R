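#' Restrict mixtures and signature to their common gene space
#'
#' All solvers require mixtures and signature on the same genes; this takes
#' the (sorted) gene-ID intersection and returns both matrices restricted to
#' it in identical order, recording how many genes were dropped from each
#' side.
#'
#' @param mixtures a [mixture_set] or a gene x sample matrix with rownames.
#' @param signature a [signature_matrix()].
#' @return list with `mixtures` (matrix), `signature` (matrix), and
#'   `dropped` (named counts).
#' @export
align_features <- function(mixtures, signature) {
  stopifnot(inherits(signature, "signature_matrix"))
  X <- if (inherits(mixtures, "mixture_set")) mixtures$expression else as.matrix(mixtures)
  assert_genes_rows(X, "mixture matrix")
  common <- sort(intersect(rownames(X), rownames(signature$values)))
  if (!length(common)) stop("empty gene intersection between mixtures and signature")
  list(mixtures = X[common, , drop = FALSE],
       signature = signature$values[common, , drop = FALSE],
       dropped = c(mixtures = nrow(X) - length(common),
                   signature = nrow(signature$values) - length(common)))
}

.proportions <- function(values, method, genes_used, diagnostics) {
  values[values < 0] <- 0
  rs <- rowSums(values)
  rs[rs == 0] <- 1
  structure(list(values = values / rs, method = method, genes_used = genes_used,
                 diagnostics = diagnostics),
            class = "proportion_estimates")
}

#' @export
print.proportion_estimates <- function(x, ...) {
  cat("proportion_estimates [", x$method, "]:", nrow(x$values), "mixtures x",
      ncol(x$values), "cell types;", length(x$genes_used), "genes used\n")
  invisible(x)
}

#' Estimate proportions by non-negative least squares
#'
#' Per mixture solves `min || S p - x ||_2` subject to `p >= 0`
#' (Lawson-Hanson active set via [pracma::lsqnonneg()]) and renormalises the
#' solution to the simplex. Expects linear-scale normalised expression
#' (CPM/RPKM) in both inputs.
#'
#' @param mixtures a [mixture_set] or gene x sample matrix.
#' @param signature a [signature_matrix()].
#' @return a `proportion_estimates` (mixture x cell-type, rows sum to 1)
#'   with per-mixture residual RMSE in `diagnostics`.
#' @export
deconvolve_nnls <- function(mixtures, signature) {
  al <- align_features(mixtures, signature)
  S <- al$signature
  if (any(colSums(S) == 0)) {
    stop("signature has an all-zero column (unidentifiable cell type): ",
         paste(colnames(S)[colSums(S) == 0], collapse = ", "))
  }
  n <- ncol(al$mixtures)
  est <- matrix(0, n, ncol(S), dimnames = list(colnames(al$mixtures), colnames(S)))
  rmse <- numeric(n)
  for (i in seq_len(n)) {
    fit <- pracma::lsqnonneg(S, al$mixtures[, i])
    est[i, ] <- fit$x
    rmse[i] <- sqrt(mean((S %*% fit$x - al$mixtures[, i])^2))
  }
  .proportions(est, "nnls", rownames(S),
               list(rmse = setNames(rmse, rownames(est))))
}

#' Estimate proportions by linear nu-support-vector regression
#'
#' The SVR approach regresses each (standardised) mixture on the
#' standardised signature columns with a linear-kernel nu-SVR, trying each
#' value in `nu_grid` and keeping the fit whose reconstruction has the
#' smallest root-mean-square error against the standardised mixture;
#' coefficients are mapped back to the signature's original column scales
#' (undoing the per-column standardisation), negative ones are clipped to
#' zero and the rest renormalised to the simplex. The epsilon-insensitive loss makes the estimator robust to
#' genes that deviate from the linear mixing model, at the cost of small
#' bias on clean data.
#'
#' SVR tools conventionally operate on compact signatures of a few hundred
#' to ~1000 discriminative genes; when the aligned gene space is larger
#' than `max_genes`, the genes with the largest log-scale spread across
#' cell types are kept (deterministic, ties by gene id).
#'
#' @inheritParams deconvolve_nnls
#' @param nu_grid candidate nu values (default 0.25, 0.5, 0.75).
#' @param max_genes cap on the genes used by the support-vector fit
#'   (default 1000).
#' @return a `proportion_estimates` with the chosen nu and reconstruction
#'   RMSE per mixture; mixtures where every coefficient was non-positive
#'   get uniform proportions and are listed in `diagnostics$degenerate`.
#' @export
deconvolve_svr <- function(mixtures, signature, nu_grid = c(0.25, 0.5, 0.75),
                           max_genes = 1000) {
  al <- align_features(mixtures, signature)
  if (nrow(al$signature) > max_genes) {
    lg <- log2p5(al$signature)
    spread <- apply(lg, 1, max) - apply(lg, 1, min)
    keep <- rownames(al$signature)[order(-spread, rownames(al$signature))][seq_len(max_genes)]
    keep <- sort(keep)
    al$signature <- al$signature[keep, , drop = FALSE]
    al$mixtures <- al$mixtures[keep, , drop = FALSE]
  }
  S <- scale(al$signature)
  col_sd <- attr(S, "scaled:scale")
  n <- ncol(al$mixtures)
  k <- ncol(S)
  est <- matrix(0, n, k, dimnames = list(colnames(al$mixtures), colnames(S)))
  rmse <- numeric(n)
  nu_sel <- numeric(n)
  degenerate <- character()
  for (i in seq_len(n)) {
    y <- as.numeric(scale(al$mixtures[, i]))
    best <- NULL
    for (nu in nu_grid) {
      fit <- e1071::svm(x = S, y = y, type = "nu-regression", kernel = "linear",
                        nu = nu, scale = FALSE)
      r <- sqrt(mean((predict(fit, S) - y)^2))
      if (is.null(best) || r < best$rmse) {
        w <- as.numeric(t(fit$coefs) %*% fit$SV)
        best <- list(rmse = r, w = w, nu = nu)
      }
    }
    w <- best$w / col_sd           # back to the original column scale
    if (all(w <= 0)) {
      w <- rep(1, k)
      degenerate <- c(degenerate, rownames(est)[i])
    }
    est[i, ] <- w
    rmse[i] <- best$rmse
    nu_sel[i] <- best$nu
  }
  .proportions(est, "svr", rownames(S),
               list(rmse = setNames(rmse, rownames(est)),
                    nu = setNames(nu_sel, rownames(est)),
                    degenerate = degenerate))
}

#' Estimate proportions by the marker-offset linear mixing model
#'
#' For each cell type j the average offset between the mixture and the
#' signature is computed over j's marker genes on the log2(x + 0.5) scale;
#' proportions are the renormalised antilogs of these offsets. Because only
#' each type's own markers enter its estimate, the method tolerates genes
#' that violate the mixing model elsewhere, in the style of linear-mixing
#' marker methods.
#'
#' @inheritParams deconvolve_nnls
#' @param markers a `marker_map` with at least one marker per cell type.
#' @return a `proportion_estimates`.
#' @export
deconvolve_dtangle <- function(mixtures, signature, markers) {
  stopifnot(inherits(markers, "marker_map"))
  al <- align_features(mixtures, signature)
  types <- colnames(al$signature)
  mk <- lapply(types, function(j) intersect(markers[[j]]$gene, rownames(al$signature)))
  names(mk) <- types
  empty <- types[vapply(mk, length, integer(1)) == 0]
  if (length(empty)) stop("no markers for type(s): ", paste(empty, collapse = ", "))
  lx <- log2p5(al$mixtures)
  ls <- log2p5(al$signature)
  n <- ncol(lx)
  est <- matrix(0, n, length(types), dimnames = list(colnames(lx), types))
  for (j in seq_along(types)) {
    idx <- match(mk[[j]], rownames(ls))
    est[, j] <- 2^colMeans(lx[idx, , drop = FALSE] - ls[idx, j])
  }
  .proportions(est, "dtangle", rownames(al$signature),
               list(markers_used = vapply(mk, length, integer(1))))
}

#' Estimate proportions by subject-weighted non-negative least squares
#'
#' Genes whose cell-type-specific expression varies across subjects are
#' unreliable for deconvolution. Starting from a plain NNLS fit, gene
#' weights are set to the reciprocal of (cross-subject variance of the
#' gene's reconstruction under the current proportions + the current
#' residual variance), and a weighted NNLS is refit until the proportion
#' change falls below `tol` or `max_iter` iterations.
#'
#' @param mixtures a [mixture_set] or gene x sample matrix (linear scale).
#' @param dataset source `sc_dataset` with subject labels (>= 2 subjects);
#'   per-subject, per-type mean CPM profiles are built from it.
#' @param tol convergence tolerance on the proportion vector (default 1e-6).
#' @param max_iter iteration cap (default 50).
#' @return a `proportion_estimates` with per-mixture iteration counts; with
#'   a single subject the function warns and falls back to
#'   [deconvolve_nnls()].
#' @export
deconvolve_wnnls <- function(mixtures, dataset, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(dataset, "sc_dataset"))
  subs <- levels(droplevels(dataset$subject))
  sig <- build_signature(dataset, "CPM")
  if (length(subs) < 2) {
    warning("single subject: falling back to unweighted NNLS", call. = FALSE)
    return(deconvolve_nnls(mixtures, sig))
  }
  types <- levels(dataset$cell_type)
  # per-subject signatures (subjects lacking a type contribute NA there)
  expr <- cpm(dataset$counts)
  sub_sigs <- lapply(subs, function(s) {
    vapply(types, function(j) {
      cells <- dataset$subject == s & dataset$cell_type == j
      if (!any(cells)) return(rep(NA_real_, nrow(expr)))
      rowMeans(expr[, cells, drop = FALSE])
    }, numeric(nrow(expr)))
  })
  al <- align_features(mixtures, sig)
  S <- al$signature
  gidx <- match(rownames(S), rownames(expr))
  sub_sigs <- lapply(sub_sigs, function(m) m[gidx, , drop = FALSE])
  n <- ncol(al$mixtures)
  est <- matrix(0, n, ncol(S), dimnames = list(colnames(al$mixtures), colnames(S)))
  iters <- integer(n)
  for (i in seq_len(n)) {
    x <- al$mixtures[, i]
    q <- pracma::lsqnonneg(S, x)$x          # unnormalised coefficients
    p <- q / max(sum(q), .Machine$double.eps)
    for (it in seq_len(max_iter)) {
      recon <- vapply(sub_sigs, function(m) as.numeric(m %*% p), numeric(nrow(S)))
      cross_var <- apply(recon, 1, var, na.rm = TRUE)
      cross_var[!is.finite(cross_var)] <- 0
      resid_var <- mean((S %*% q - x)^2)
      w <- 1 / (cross_var + resid_var + .Machine$double.eps)
      sw <- sqrt(w / mean(w))
      q <- pracma::lsqnonneg(S * sw, x * sw)$x
      p_new <- q / max(sum(q), .Machine$double.eps)
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < tol) break
    }
    est[i, ] <- p
    iters[i] <- it
  }
  .proportions(est, "wnnls", rownames(S),
               list(iterations = setNames(iters, rownames(est))))
}
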