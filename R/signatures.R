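#' Construct a signature-matrix object
#'
#' A signature matrix holds the reference expression profile of each pure
#' cell type (genes in rows, cell types in columns); partial deconvolution
#' models a bulk sample X as S P with P the composition vector.
#'
#' @param values non-negative gene x cell-type matrix with dimnames.
#' @param normalization one of `"counts"`, `"CPM"`, `"RPKM"`, `"TPM"`.
#' @param provenance character vector of source identifiers.
#' @return object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, normalization = c("CPM", "counts", "RPKM", "TPM"),
                             provenance = character()) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  assert_genes_rows(values, "signature")
  if (is.null(colnames(values))) stop("signature must carry cell-type names as colnames")
  assert_unique(rownames(values), "gene ids")
  assert_unique(colnames(values), "cell-type names")
  if (any(values < 0)) stop("signature entries must be non-negative")
  structure(list(values = values, normalization = normalization,
                 provenance = provenance),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "cell types [", x$normalization, "]\n")
  if (length(x$provenance)) cat("provenance:", paste(x$provenance, collapse = ", "), "\n")
  invisible(x)
}

#' Quality-filter cells and under-represented cell types
#'
#' Removes cells with fewer than `min_counts` total counts or fewer than
#' `min_genes` expressed genes, cells above `max_mito` mitochondrial
#' fraction (skipped when the dataset carries none), cells whose total
#' counts exceed the dataset's `max_counts_quantile` quantile, and finally
#' whole cell types left with fewer than `min_cells_per_type` cells. All
#' count thresholds are strict ("fewer than"), so a cell at exactly the
#' minimum passes. Per-rule removal counts are attached as the
#' `"qc_log"` attribute.
#'
#' @param dataset an `sc_dataset`.
#' @param min_counts,min_genes,max_mito,max_counts_quantile,min_cells_per_type
#'   thresholds; defaults 1000 counts, 200 genes, 5% mitochondrial, 99.5th
#'   percentile, 200 cells per type.
#' @return filtered `sc_dataset`; errors (naming the offending rule) if a
#'   rule removes every cell.
#' @export
qc_filter_cells <- function(dataset, min_counts = 1000, min_genes = 200,
                            max_mito = 0.05, max_counts_quantile = 0.995,
                            min_cells_per_type = 200) {
  stopifnot(inherits(dataset, "sc_dataset"))
  tot <- Matrix::colSums(dataset$counts)
  ngene <- Matrix::colSums(dataset$counts > 0)
  keep <- rep(TRUE, length(tot))
  log <- c()
  apply_rule <- function(keep, pass, rule) {
    removed <- sum(keep & !pass)
    keep2 <- keep & pass
    if (!any(keep2)) stop("QC rule '", rule, "' removed all remaining cells", call. = FALSE)
    log[[rule]] <<- removed
    keep2
  }
  keep <- apply_rule(keep, tot >= min_counts, "min_counts")
  keep <- apply_rule(keep, ngene >= min_genes, "min_genes")
  if (!is.null(dataset$mito_fraction)) {
    keep <- apply_rule(keep, dataset$mito_fraction <= max_mito, "max_mito")
  }
  keep <- apply_rule(keep, tot <= quantile(tot, max_counts_quantile), "max_counts")

  type_n <- table(dataset$cell_type[keep])
  ok_types <- names(type_n)[type_n >= min_cells_per_type]
  keep <- apply_rule(keep, as.character(dataset$cell_type) %in% ok_types,
                     "min_cells_per_type")

  out <- subset_cells(dataset, which(keep))
  out$cell_types <- ok_types
  out$cell_type <- factor(out$cell_type, levels = ok_types)
  attr(out, "qc_log") <- unlist(log)
  out
}

# index-subset the cells of an sc_dataset, keeping truth slots intact
subset_cells <- function(dataset, idx) {
  out <- dataset
  out$counts <- dataset$counts[, idx, drop = FALSE]
  out$cell_type <- dataset$cell_type[idx]
  out$subject <- dataset$subject[idx]
  if (!is.null(dataset$mito_fraction)) out$mito_fraction <- dataset$mito_fraction[idx]
  out
}

#' Build a cell-type signature by averaging normalised single-cell profiles
#'
#' Column j is the mean of the normalised expression over all cells labelled
#' j. `"RPKM"` additionally divides by gene length in kilobases and requires
#' `gene_lengths`.
#'
#' @param dataset an `sc_dataset`.
#' @param normalization `"CPM"`, `"counts"`, or `"RPKM"`.
#' @param gene_lengths named numeric vector of gene lengths in bases
#'   (required for RPKM).
#' @return a [signature_matrix()].
#' @export
build_signature <- function(dataset, normalization = c("CPM", "counts", "RPKM"),
                            gene_lengths = NULL) {
  stopifnot(inherits(dataset, "sc_dataset"))
  normalization <- match.arg(normalization)
  if (ncol(dataset$counts) == 0) stop("dataset has no cells")
  expr <- switch(normalization,
    counts = as.matrix(dataset$counts),
    CPM = cpm(dataset$counts),
    RPKM = {
      if (is.null(gene_lengths)) stop("RPKM requested without gene lengths")
      len <- gene_lengths[rownames(dataset$counts)]
      if (anyNA(len)) stop("gene lengths missing for some genes")
      cpm(dataset$counts) / (len / 1000)
    })
  types <- levels(dataset$cell_type)
  vals <- vapply(types, function(j) {
    rowMeans(expr[, dataset$cell_type == j, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(vals) <- list(rownames(dataset$counts), types)
  signature_matrix(vals, normalization, provenance = "synthetic")
}

#' Drop genes below a minimum-expression threshold in every cell type
#'
#' Keeps genes whose value strictly exceeds `min_expr` in at least one cell
#' type. Idempotent.
#'
#' @param sig a [signature_matrix()].
#' @param min_expr threshold (default 1, i.e. > 1 CPM/RPKM in >= 1 type).
#' @return thresholded [signature_matrix()].
#' @export
threshold_signature <- function(sig, min_expr = 1.0) {
  stopifnot(inherits(sig, "signature_matrix"))
  keep <- apply(sig$values, 1, max) > min_expr
  if (!any(keep)) stop("no gene exceeds the threshold in any cell type")
  out <- sig
  out$values <- sig$values[keep, , drop = FALSE]
  out
}

#' Merge signatures by joint quantile normalisation and per-type averaging
#'
#' Composite signatures average out inter-individual and technical
#' differences between sources. All columns of all inputs are pooled on the
#' gene-ID intersection and quantile-normalised jointly to a common
#' reference distribution (the mean of the sorted columns), then each cell
#' type is averaged across sources. Output column order follows the first
#' signature's cell-type order.
#'
#' @param sigs list of >= 2 [signature_matrix()] objects sharing cell-type
#'   names (merging one signature with itself is allowed and yields its
#'   quantile-normalised form).
#' @return merged [signature_matrix()].
#' @export
merge_signatures <- function(sigs) {
  stopifnot(is.list(sigs), length(sigs) >= 2,
            all(vapply(sigs, inherits, logical(1), "signature_matrix")))
  types <- colnames(sigs[[1]]$values)
  for (s in sigs) {
    if (!setequal(colnames(s$values), types)) stop("signatures must share cell-type names")
  }
  genes <- Reduce(intersect, lapply(sigs, function(s) rownames(s$values)))
  if (!length(genes)) stop("empty gene intersection across signatures")
  pooled <- do.call(cbind, lapply(sigs, function(s) s$values[genes, types, drop = FALSE]))
  qn <- quantile_normalize(pooled)
  k <- length(types)
  vals <- vapply(seq_len(k), function(j) {
    rowMeans(qn[, seq(j, ncol(qn), by = k), drop = FALSE])
  }, numeric(length(genes)))
  dimnames(vals) <- list(genes, types)
  signature_matrix(vals, sigs[[1]]$normalization,
                   provenance = unlist(lapply(sigs, `[[`, "provenance")))
}

#' Select cell-type marker genes by the log-difference score
#'
#' For gene g and type j the "diff" score is the mean log2(expression + 0.5)
#' in j minus the maximum of that quantity over all other types; each gene
#' is assigned to the type maximising its score, and the top `top` genes
#' (count, or fraction of the type's assigned genes when `top < 1`) are kept
#' per type, sorted by descending score. Ties are broken by gene id so the
#' selection is deterministic.
#'
#' @param sig a [signature_matrix()].
#' @param top markers per type: a count (>= 1) or a fraction in (0, 1)
#'   (e.g. 0.01 keeps the top 1% of each type's assigned genes).
#' @return object of class `marker_map`: named list (per type) of data
#'   frames with columns `gene` and `score`.
#' @export
select_markers <- function(sig, top = 0.01) {
  stopifnot(inherits(sig, "signature_matrix"), top > 0)
  lg <- log2p5(sig$values)
  k <- ncol(lg)
  if (k < 2) stop("marker selection needs >= 2 cell types")
  best <- max.col(lg, ties.method = "first")
  score <- vapply(seq_len(nrow(lg)), function(i) {
    lg[i, best[i]] - max(lg[i, -best[i]])
  }, numeric(1))
  types <- colnames(lg)
  out <- lapply(seq_len(k), function(j) {
    idx <- which(best == j)
    df <- data.frame(gene = rownames(lg)[idx], score = score[idx],
                     stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$gene), , drop = FALSE]
    n_keep <- if (top < 1) max(1L, ceiling(top * nrow(df))) else as.integer(top)
    if (n_keep > nrow(df)) {
      warning("type '", types[j], "': only ", nrow(df), " assigned genes (",
              n_keep, " requested); returning all", call. = FALSE)
      n_keep <- nrow(df)
    }
    rownames(df) <- NULL
    df[seq_len(n_keep), , drop = FALSE]
  })
  names(out) <- types
  structure(out, class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat("marker_map:", paste(sprintf("%s (%d)", names(x),
                                   vapply(x, nrow, integer(1))), collapse = ", "), "\n")
  invisible(x)
}

#' Identify compartment-specific genes from paired nuclear and bulk profiles
#'
#' Genes enriched or depleted in nuclear RNA relative to total (whole-cell)
#' RNA distort deconvolution when single-nucleus signatures are applied to
#' bulk data. A per-gene two-group ordinary-least-squares test (equivalently
#' a pooled-variance t-test) is run on log2(x + 0.5); a gene is flagged iff
#' its linear-scale fold-change magnitude exceeds `fc_threshold` AND its
#' Benjamini-Hochberg FDR is below `fdr`.
#'
#' @param nuclear,bulk gene x sample matrices of normalised expression with
#'   matching gene ids, >= 2 samples per arm.
#' @param fc_threshold linear-scale fold-change gate (default 1.3; a gene
#'   with ratio in (1/1.3, 1.3) is never flagged regardless of p).
#' @param fdr BH-adjusted p-value gate (default 0.05).
#' @return list: `table` (per-gene data frame with fold-change on the
#'   linear scale, log2 fold-change, p, FDR, flag, direction),
#'   `flagged` (character vector), and `filter` — a closure that removes the
#'   flagged genes from any [signature_matrix()].
#' @export
filter_compartment_genes <- function(nuclear, bulk, fc_threshold = 1.3, fdr = 0.05) {
  nuclear <- as.matrix(nuclear); bulk <- as.matrix(bulk)
  if (!identical(rownames(nuclear), rownames(bulk))) {
    stop("nuclear and bulk matrices must share identical gene sets and order")
  }
  if (ncol(nuclear) < 2 || ncol(bulk) < 2) stop("need >= 2 samples per arm")
  ln <- log2p5(nuclear); lb <- log2p5(bulk)
  n1 <- ncol(ln); n2 <- ncol(lb)
  m1 <- rowMeans(ln); m2 <- rowMeans(lb)
  v1 <- apply(ln, 1, var); v2 <- apply(lb, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0 & m1 == m2] <- 1
  padj <- p.adjust(p, "BH")
  fc <- rowMeans(nuclear) / rowMeans(bulk)  # linear-scale ratio of arm means
  flag <- (fc > fc_threshold | fc < 1 / fc_threshold) & padj < fdr & is.finite(fc)
  tab <- data.frame(
    gene = rownames(nuclear), fold_change = fc, log2fc = m1 - m2,
    t = tstat, p = p, fdr = padj, flagged = flag,
    direction = ifelse(fc >= 1, "nuclear_enriched", "nuclear_depleted"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  flagged <- tab$gene[tab$flagged]
  list(
    table = tab,
    flagged = flagged,
    filter = function(sig) {
      stopifnot(inherits(sig, "signature_matrix"))
      keep <- !(rownames(sig$values) %in% flagged)
      out <- sig
      out$values <- sig$values[keep, , drop = FALSE]
      out
    }
  )
}

#' Write / read a signature matrix as TSV
#'
#' Rows are genes, columns cell types; the normalisation tag travels in a
#' leading `#` comment line.
#'
#' @param sig a [signature_matrix()].
#' @param path file path.
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns a [signature_matrix()].
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# normalization=", sig$normalization), con)
  df <- data.frame(gene = rownames(sig$values), sig$values, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  first <- readLines(path, n = 1)
  norm <- if (startsWith(first, "# normalization=")) sub("# normalization=", "", first) else "CPM"
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  signature_matrix(vals, norm, provenance = path)
}
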