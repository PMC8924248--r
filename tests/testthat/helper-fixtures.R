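# Shared fixtures, built lazily and cached for the whole test session.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# small brain-like dataset: 1500 genes, 5 types, ~1500 cells
fx_dataset <- function() fx_get("dataset", function() {
  generate_single_cell(synthetic_config(
    n_genes = 1500, cells_per_type = 300, markers_per_type = 50, seed = 101L))
})

fx_halves <- function() fx_get("halves", function() split_dataset(fx_dataset(), seed = 101L))

fx_signature <- function() fx_get("signature", function() {
  build_signature(fx_halves()$signature_half, "CPM")
})

fx_markers <- function() fx_get("markers", function() select_markers(fx_signature(), top = 50))

fx_mixtures <- function() fx_get("mixtures", function() {
  simulate_random_mixtures(fx_halves()$mixture_half, n_mixtures = 30,
                           cells_per_mixture = 300, seed = 101L)
})

# balanced dataset (equal weights and library sizes) for sampler comparisons
fx_balanced <- function() fx_get("balanced", function() {
  generate_single_cell(synthetic_config(
    n_genes = 1500, cell_types = setNames(rep(1, 5), c("A", "B", "C", "D", "E")),
    cells_per_type = 400, markers_per_type = 50,
    library_size = list(meanlog = log(2000), sdlog = 0.3), seed = 8L))
})

# full-scale dataset under the default study conditions (10k genes)
fx_big <- function() fx_get("big", function() {
  generate_single_cell(synthetic_config(seed = 424242L))
})

# moderate dataset for the confounded-group designs in unit tests
fx_confound_ds <- function() fx_get("confound_ds", function() {
  generate_single_cell(synthetic_config(
    n_genes = 1000, cells_per_type = 300, markers_per_type = 30, seed = 5L))
})

# null-calibration runs on the full-scale dataset, shared by several checks:
# 20 seeds of a zero-shift two-group design, false positives and KS uniformity
fx_nulls <- function() fx_get("nulls", function() {
  ds <- fx_big()
  res <- lapply(1:20, function(s) {
    grp <- simulate_confounded_groups(ds, "Excitatory", 0, "up", seed = 1000L + s)
    expr <- cbind(grp$groupA$expression, grp$groupB$expression)
    colnames(expr) <- sprintf("S%03d", seq_len(ncol(expr)))
    expr <- expr[rowMeans(expr) > 1, , drop = FALSE]
    de <- differential_expression(expr, rep(c("A", "B"), each = 50))
    list(fp = count_false_positives(de),
         ks = unname(suppressWarnings(stats::ks.test(de$p, "punif"))$statistic),
         n_genes = nrow(de))
  })
  list(fp = vapply(res, `[[`, numeric(1), "fp"),
       ks = vapply(res, `[[`, numeric(1), "ks"),
       n_genes = vapply(res, `[[`, numeric(1), "n_genes"))
})

rdirichlet <- function(n, k) {
  g <- matrix(rgamma(n * k, 1), n, k)
  g / rowSums(g)
}

# hand-build an sc_dataset from a dense count matrix
make_dataset <- function(counts, cell_type, subject = NULL, cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- unique(cell_type)
  if (is.null(subject)) subject <- rep("S1", ncol(counts))
  structure(list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cell_type = stats::setNames(factor(cell_type, levels = cell_types), colnames(counts)),
    subject = stats::setNames(factor(subject), colnames(counts)),
    mito_fraction = NULL, cell_types = cell_types, truth = NULL
  ), class = "sc_dataset")
}
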