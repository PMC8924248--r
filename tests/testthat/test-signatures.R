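test_that("QC keeps a fully passing dataset intact", {
  ds <- fx_dataset()
  out <- qc_filter_cells(ds, min_counts = 0, min_genes = 0, max_mito = 1,
                         max_counts_quantile = 1, min_cells_per_type = 1)
  expect_identical(as.matrix(out$counts), as.matrix(ds$counts))
  expect_identical(out$cell_type, ds$cell_type)
})

test_that("the count threshold is strict: a 999-count cell is removed, 1000 passes", {
  G <- 400
  counts <- matrix(5L, G, 4, dimnames = list(sprintf("g%03d", 1:G), paste0("c", 1:4)))
  counts[, 1] <- 0L; counts[1:333, 1] <- 3L  # cell 1: 999 counts
  counts[, 2] <- 0L; counts[1:200, 2] <- 5L  # cell 2: exactly 1000
  ds <- make_dataset(counts, rep("T1", 4))
  stopifnot(sum(ds$counts[, 1]) == 999, sum(ds$counts[, 2]) == 1000)
  out <- qc_filter_cells(ds, min_counts = 1000, min_genes = 100,
                         max_counts_quantile = 1, min_cells_per_type = 1)
  expect_identical(colnames(out$counts), c("c2", "c3", "c4"))
  expect_equal(unname(attr(out, "qc_log")["min_counts"]), 1)
})

test_that("a cell type left under the minimum size is dropped entirely", {
  counts <- matrix(10L, 50, 399,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:399)))
  ds <- make_dataset(counts, rep(c("Big", "Small"), c(200, 199)))
  out <- qc_filter_cells(ds, min_counts = 1, min_genes = 1,
                         max_counts_quantile = 1, min_cells_per_type = 200)
  expect_identical(out$cell_types, "Big")
  expect_equal(ncol(out$counts), 200)
  expect_error(
    qc_filter_cells(ds, min_counts = 1e6, min_genes = 1, min_cells_per_type = 1),
    "min_counts")
})

test_that("signature columns are per-type means of normalised profiles", {
  G <- 40
  a <- rpois(G, 20); b <- rpois(G, 20)
  counts <- cbind(a, b, rpois(G, 5))
  dimnames(counts) <- list(sprintf("g%02d", 1:G), c("c1", "c2", "c3"))
  ds <- make_dataset(counts, c("T1", "T1", "T2"))
  sig <- build_signature(ds, "CPM")
  manual <- (a / sum(a) + b / sum(b)) / 2 * 1e6
  expect_equal(unname(sig$values[, "T1"]), manual)
  # one cell per type: the signature is that cell's normalised profile
  sig2 <- build_signature(make_dataset(counts[, c(1, 3)], c("T1", "T2")), "CPM")
  expect_equal(unname(sig2$values[, "T1"]), a / sum(a) * 1e6)
  # permuting cells leaves the signature unchanged
  perm <- c(3, 1, 2)
  sig3 <- build_signature(make_dataset(counts[, perm], c("T2", "T1", "T1")), "CPM")
  expect_equal(sig3$values[, colnames(sig$values)], sig$values)
  expect_error(build_signature(ds, "RPKM"), "gene lengths")
})

test_that("expression thresholding is strict and idempotent", {
  vals <- rbind(atmax = c(1.0, 0.4), kept = c(1.01, 0), zero = c(0.2, 0.3),
                high = c(5, 8))
  colnames(vals) <- c("T1", "T2")
  sig <- signature_matrix(vals, "CPM")
  thr <- threshold_signature(sig, 1)
  expect_identical(rownames(thr$values), c("kept", "high"))
  expect_identical(threshold_signature(thr, 1)$values, thr$values)
  # min_expr = 0 on a positive matrix is the identity
  pos <- signature_matrix(vals + 0.1, "CPM")
  expect_identical(threshold_signature(pos, 0)$values, pos$values)
})

test_that("merging a signature with itself is joint quantile normalisation", {
  sig <- fx_signature()
  m <- merge_signatures(list(sig, sig))
  expect_equal(m$values, quantile_normalize(sig$values))
})

test_that("merge matches a brute-force quantile-normalisation oracle on rank-identical inputs", {
  set.seed(42)
  v <- matrix(rlnorm(200 * 3), 200, 3,
              dimnames = list(sprintf("g%03d", 1:200), c("T1", "T2", "T3")))
  s1 <- signature_matrix(v, "CPM")
  s2 <- signature_matrix(v * 7, "CPM")  # column-wise rank-identical, scaled
  m <- merge_signatures(list(s1, s2))
  # brute-force QN of the 6-column pool (no ties in continuous draws)
  pool <- cbind(v, v * 7)
  target <- rowMeans(apply(pool, 2, sort))
  qn <- apply(pool, 2, function(col) target[rank(col)])
  oracle <- (qn[, 1:3] + qn[, 4:6]) / 2
  dimnames(oracle) <- dimnames(v)
  expect_equal(m$values, oracle)
  # every merged column has the identical marginal: sorted columns coincide
  sorted <- apply(m$values, 2, sort)
  expect_equal(max(abs(sorted - sorted[, 1])), 0)
  # column order follows the first signature regardless of input column order
  s3 <- signature_matrix(v[, c(3, 1, 2)], "CPM")
  m2 <- merge_signatures(list(s1, s3))
  expect_identical(colnames(m2$values), colnames(v))
  expect_error(merge_signatures(list(s1, signature_matrix(
    matrix(1, 2, 3, dimnames = list(c("x1", "x2"), colnames(v))), "CPM"))),
    "empty gene intersection")
})

test_that("marker selection assigns exclusive genes to their type with positive scores", {
  v <- diag(c(10, 20, 30))
  dimnames(v) <- list(c("gA", "gB", "gC"), c("A", "B", "C"))
  mk <- select_markers(signature_matrix(v, "CPM"), top = 1)
  expect_identical(mk$A$gene, "gA")
  expect_identical(mk$B$gene, "gB")
  expect_identical(mk$C$gene, "gC")
  expect_true(all(vapply(mk, function(d) all(d$score > 0), logical(1))))
})

test_that("marker selection recovers planted markers and breaks ties deterministically", {
  mk <- fx_markers()
  truth <- fx_dataset()$truth$markers
  for (j in names(truth)) {
    expect_gte(mean(truth[[j]] %in% mk[[j]]$gene), 0.9)
  }
  # exact ties ordered by gene id
  v <- rbind(g2 = c(8, 1), g1 = c(8, 1), g3 = c(1, 8))
  colnames(v) <- c("A", "B")
  mkt <- suppressWarnings(select_markers(signature_matrix(v, "CPM"), top = 2))
  expect_identical(mkt$A$gene, c("g1", "g2"))
  # warns (per short type) when fewer assigned genes than requested
  w <- capture_warnings(select_markers(signature_matrix(v, "CPM"), top = 5))
  expect_true(any(grepl("only", w)))
})

test_that("marker sets are invariant to scaling all columns by one global factor", {
  sig <- fx_signature()
  scaled <- signature_matrix(sig$values * 10, sig$normalization)
  mk1 <- select_markers(sig, top = 20)
  mk2 <- select_markers(scaled, top = 20)
  for (j in names(mk1)) {
    expect_gte(length(intersect(mk1[[j]]$gene, mk2[[j]]$gene)) / 20, 0.95)
  }
})

test_that("the compartment filter gates on both fold-change and FDR", {
  set.seed(9)
  G <- 400
  mu <- rlnorm(G, 4, 0.5)
  noise <- function(n) matrix(exp(rnorm(G * n, 0, 0.01)), G, n)
  bulk <- mu * noise(5)
  nuc <- mu * noise(5)
  nuc[1, ] <- nuc[1, ] * 1.25      # tiny p but below the fold gate
  nuc[2, ] <- nuc[2, ] * 2         # clearly flagged
  dimnames(bulk) <- dimnames(nuc) <- list(sprintf("g%03d", 1:G), paste0("s", 1:5))
  fl <- filter_compartment_genes(nuc, bulk, fc_threshold = 1.3, fdr = 0.05)
  expect_lt(fl$table$fdr[1], 1e-6)
  expect_false(fl$table$flagged[1])            # fold 1.25 < 1.3: never flagged
  expect_true(fl$table$flagged[2])
  expect_identical(fl$table$direction[2], "nuclear_enriched")
  # the closure removes flagged genes from a signature
  sig <- signature_matrix(matrix(1, G, 2, dimnames = list(rownames(nuc), c("A", "B"))),
                          "CPM")
  expect_false(any(fl$flagged %in% rownames(fl$filter(sig)$values)))
  expect_error(filter_compartment_genes(nuc[-1, ], bulk), "share identical")
})

test_that("identical arms produce no flagged genes", {
  cfg <- synthetic_config(n_genes = 800, cells_per_type = 50, markers_per_type = 20,
                          seed = 15L)
  pc <- generate_paired_compartments(cfg, n_samples = 6)
  # two halves of the same (bulk) arm: a null contrast
  fl <- filter_compartment_genes(pc$bulk[, 1:3], pc$bulk[, 4:6])
  expect_lte(length(fl$flagged), 2)
})

test_that("signatures round-trip through TSV with their normalisation tag", {
  sig <- fx_signature()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$values, sig$values, tolerance = 1e-12)
  expect_identical(back$normalization, sig$normalization)
})
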