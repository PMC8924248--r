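test_that("splitting is stratified, disjoint, exhaustive, and reproducible", {
  ds <- fx_dataset()
  h1 <- split_dataset(ds, 0.5, seed = 7)
  h2 <- split_dataset(ds, 0.5, seed = 7)
  a <- colnames(h1$signature_half$counts)
  b <- colnames(h1$mixture_half$counts)
  expect_length(intersect(a, b), 0)
  expect_setequal(c(a, b), colnames(ds$counts))
  expect_identical(a, colnames(h2$signature_half$counts))
  # stratified: each type split in half
  for (j in levels(ds$cell_type)) {
    n <- sum(ds$cell_type == j)
    expect_equal(sum(h1$signature_half$cell_type == j), round(n / 2))
  }
})

test_that("random mixtures carry exact dual ground truth from the manifest", {
  # 2 types with 3x library-size difference: pCt and pRNA diverge predictably
  G <- 60
  counts <- cbind(matrix(rpois(G * 40, 25), G, 40),   # type A, ~1500 counts
                  matrix(rpois(G * 40, 75), G, 40))   # type B, ~4500 counts
  dimnames(counts) <- list(sprintf("g%02d", 1:G), sprintf("c%02d", 1:80))
  ds <- make_dataset(counts, rep(c("A", "B"), each = 40))
  mix <- simulate_random_mixtures(ds, n_mixtures = 20, cells_per_mixture = 40, seed = 2)
  # stored truth equals direct recomputation from the manifest
  for (i in seq_len(20)) {
    ids <- mix$manifest[[i]]
    expect_length(unique(ids), 40)  # without replacement
    ct <- ds$cell_type[ids]
    expect_equal(unname(mix$truth_pCt[i, "A"]), mean(ct == "A"))
    per_cell <- colSums(counts[, ids])
    expect_equal(unname(mix$truth_pRNA[i, "A"]),
                 sum(per_cell[ct == "A"]) / sum(per_cell))
  }
  expect_identical(recompute_pRNA(mix, ds), mix$truth_pRNA)
  # pRNA is pulled toward the RNA-rich type relative to pCt
  expect_lt(mean(mix$truth_pRNA[, "A"]), mean(mix$truth_pCt[, "A"]))
  # truth rows sum to one; CPM columns sum to 1e6
  expect_equal(unname(rowSums(mix$truth_pRNA)), rep(1, 20), tolerance = 1e-9)
  expect_equal(unname(rowSums(mix$truth_pCt)), rep(1, 20), tolerance = 1e-9)
  expect_equal(unname(colSums(mix$expression)), rep(1e6, 20), tolerance = 1e-6)
})

test_that("a single-type dataset yields unit truth and oversampling errors out", {
  G <- 30
  counts <- matrix(rpois(G * 20, 10), G, 20,
                   dimnames = list(sprintf("g%02d", 1:G), sprintf("c%02d", 1:20)))
  ds <- make_dataset(counts, rep("A", 20))
  mix <- simulate_random_mixtures(ds, 5, 10, seed = 1)
  expect_equal(unname(mix$truth_pRNA[, "A"]), rep(1, 5))
  expect_equal(unname(mix$truth_pCt[, "A"]), rep(1, 5))
  expect_error(simulate_random_mixtures(ds, 5, 21, seed = 1), "exceeds available")
})

test_that("achieved type shares track dataset frequencies under random sampling", {
  mix <- fx_mixtures()
  half <- fx_halves()$mixture_half
  freq <- as.numeric(table(half$cell_type) / ncol(half$counts))
  obs <- colMeans(mix$truth_pCt)
  # binomial bound on the mean of 30 mixtures x 300 cells
  se <- sqrt(freq * (1 - freq) / (300 * 30))
  expect_true(all(abs(obs - freq) < 5 * se + 1e-3))
})

test_that("wide-range caps follow the library-size formula", {
  expect_equal(unname(wide_range_caps(rep(3, 5), 500)), rep(100, 5))
  m <- 1e6
  expect_equal(unname(wide_range_caps(c(m, 2 * m, 2 * m, 2 * m, 2 * m), 500)),
               c(100, 50, 50, 50, 50))
  expect_warning(out <- wide_range_caps(c(1, 1000), 4), "clamped")
  expect_equal(unname(out), c(2, 1))
})

test_that("wide-range mixtures span a wider composition range than random ones", {
  ds <- fx_balanced()
  mr <- simulate_random_mixtures(ds, 60, 500, seed = 3)
  mw <- simulate_wide_range_mixtures(ds, 60, 500, seed = 3)
  expect_equal(unname(vapply(mw$manifest, length, integer(1))), rep(500L, 60))
  expect_true(all(vapply(mw$manifest, function(x) !anyDuplicated(x), logical(1))))
  dom <- names(which.max(colMeans(mr$truth_pCt)))
  expect_gt(var(mw$truth_pCt[, dom]) / var(mr$truth_pCt[, dom]), 2)
})

test_that("confounded groups realise the designed composition shift", {
  ds <- fx_confound_ds()
  # k = 0: both groups drawn from the same law
  g0 <- simulate_confounded_groups(ds, "Excitatory", 0, "up", seed = 1)
  expect_lt(abs(mean(g0$groupA$truth_pCt[, "Excitatory"]) -
                mean(g0$groupB$truth_pCt[, "Excitatory"])), 0.03)
  # k = 50 up: expected pCt difference 50/500 = 0.10
  g50 <- simulate_confounded_groups(ds, "Excitatory", 50, "up", seed = 1)
  d <- mean(g50$groupB$truth_pCt[, "Excitatory"]) -
    mean(g50$groupA$truth_pCt[, "Excitatory"])
  expect_lt(abs(d - 0.10), 0.02)
  # direction = down flips the sign
  gd <- simulate_confounded_groups(ds, "Excitatory", 50, "down", seed = 1)
  expect_lt(mean(gd$groupB$truth_pCt[, "Excitatory"]),
            mean(gd$groupA$truth_pCt[, "Excitatory"]))
  # k = 195: target counts stay within [395, 495], never above `cells`
  g195 <- simulate_confounded_groups(ds, "Excitatory", 195, "up",
                                     n_per_group = 10, seed = 1)
  nt <- g195$groupB$truth_pCt[, "Excitatory"] * 500
  expect_true(all(nt >= 395 & nt <= 495))
  # infeasible shift errors out
  expect_error(simulate_confounded_groups(ds, "Microglia", 100, "up", seed = 1),
               "available")
  expect_error(simulate_confounded_groups(ds, "Excitatory", 250, "up", seed = 1),
               "exceeds cells")
})

test_that("bulk-mode perturbation scales raw counts exactly before renormalisation", {
  mix <- fx_mixtures()
  mk <- fx_markers()
  pert <- perturb_expression(mix, fold = 2, markers = mk, marker_type = "Excitatory",
                             target_mixtures = 1:15, n_marker_genes = 20,
                             n_nonmarker_genes = 20, seed = 9)
  info <- pert$perturbation
  expect_length(info$genes, 40)
  expect_equal(sum(info$direction == "up"), 20)
  expect_length(intersect(info$marker_genes, info$nonmarker_genes), 0)
  up <- names(info$direction)[info$direction == "up"]
  down <- names(info$direction)[info$direction == "down"]
  expect_equal(pert$counts[up, 1:15], mix$counts[up, 1:15] * 2)
  expect_equal(pert$counts[down, 1:15], mix$counts[down, 1:15] / 2)
  # untouched mixtures and genes unchanged
  expect_equal(pert$counts[, 16:30], mix$counts[, 16:30])
  keep <- setdiff(rownames(mix$counts), info$genes)
  expect_equal(pert$counts[keep, ], mix$counts[keep, ])
  # fold = 1 is the identity
  id <- perturb_expression(mix, 1, mk, "Excitatory", 1:15,
                           n_marker_genes = 20, n_nonmarker_genes = 20, seed = 9)
  expect_equal(id$expression, mix$expression)
})

test_that("cell-type-mode perturbation only alters mixtures containing that type", {
  G <- 50
  counts <- matrix(rpois(G * 30, 20), G, 30,
                   dimnames = list(sprintf("g%02d", 1:G), sprintf("c%02d", 1:30)))
  # all cells are type A, but type B is declared: vacuous scaling
  ds <- make_dataset(counts, rep("A", 30), cell_types = c("A", "B"))
  mix <- simulate_random_mixtures(ds, 6, 10, seed = 4)
  mk <- structure(list(
    A = data.frame(gene = rownames(counts)[1:10], score = 1),
    B = data.frame(gene = rownames(counts)[11:20], score = 1)),
    class = "marker_map")
  pert <- perturb_expression(mix, 2, mk, "B", target_mixtures = 1:6,
                             n_marker_genes = 5, n_nonmarker_genes = 5,
                             cell_type = "B", dataset = ds, seed = 4)
  expect_equal(pert$counts, mix$counts)
  # whereas scaling type A changes every mixture's perturbed genes
  pert2 <- perturb_expression(mix, 2, mk, "B", target_mixtures = 1:6,
                              n_marker_genes = 5, n_nonmarker_genes = 5,
                              cell_type = "A", dataset = ds, seed = 4)
  up <- names(pert2$perturbation$direction)[pert2$perturbation$direction == "up"]
  expect_equal(pert2$counts[up, ], mix$counts[up, ] * 2)
})

test_that("pseudo-bulk sums are CPM-normalised and linear in the type decomposition", {
  ds <- fx_dataset()
  pb_all <- pseudo_bulk(ds)
  manual <- Matrix::rowSums(ds$counts)
  expect_equal(unname(pb_all[, 1]), unname(as.numeric(manual / sum(manual) * 1e6)))
  # recombining per-type pseudo-bulk by pRNA weights reproduces the total
  pb_type <- pseudo_bulk(ds, ds$cell_type)
  tot_per_type <- vapply(levels(ds$cell_type), function(j) {
    sum(ds$counts[, ds$cell_type == j])
  }, numeric(1))
  w <- tot_per_type / sum(tot_per_type)
  expect_equal(unname(as.numeric(pb_type %*% w)), unname(pb_all[, 1]),
               tolerance = 1e-8)
  expect_error(pseudo_bulk(ds, factor(rep("x", ncol(ds$counts)),
                                      levels = c("x", "empty"))), "empty group")
})

test_that("mixture sets round-trip through their on-disk representation", {
  mix <- fx_mixtures()
  dir <- withr::local_tempdir()
  write_mixture_set(mix, dir)
  back <- read_mixture_set(dir)
  expect_equal(back$expression, mix$expression, tolerance = 1e-12)
  expect_equal(back$truth_pRNA, mix$truth_pRNA, tolerance = 1e-12)
  expect_identical(back$manifest, mix$manifest)
  expect_identical(back$cell_types, mix$cell_types)
})
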