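#' Pseudo-bulk mixture sets with dual ground truth
#'
#' A `mixture_set` stores the CPM expression of each simulated mixture, the
#' raw summed counts it was normalised from, the sampling manifest (which
#' cells went into which mixture), and two ground-truth composition
#' matrices: `truth_pCt` — the share of sampled cells per type — and
#' `truth_pRNA` — the share of summed counts contributed by each type.
#' Because cell types differ in RNA content these differ, and deconvolution
#' estimates track pRNA, the share of sequenced RNA.
#'
#' @name mixture_set
NULL

# aggregate a list of per-mixture cell-index vectors into a mixture_set;
# `counts` may be a perturbed copy of dataset$counts (same dimnames)
.aggregate_manifest <- function(dataset, manifest, seed, counts = dataset$counts) {
  types <- levels(dataset$cell_type)
  G <- nrow(counts)
  n <- length(manifest)
  mix_ids <- sprintf("M%03d", seq_len(n))
  cm <- matrix(0, G, n, dimnames = list(rownames(counts), mix_ids))
  pct <- matrix(0, n, length(types), dimnames = list(mix_ids, types))
  prna <- matrix(0, n, length(types), dimnames = list(mix_ids, types))
  for (i in seq_len(n)) {
    idx <- manifest[[i]]
    sub <- counts[, idx, drop = FALSE]
    cm[, i] <- Matrix::rowSums(sub)
    ct <- dataset$cell_type[idx]
    pct[i, ] <- as.numeric(table(ct)[types]) / length(idx)
    pct[i, is.na(pct[i, ])] <- 0
    per_cell <- Matrix::colSums(sub)
    for (j in seq_along(types)) {
      prna[i, j] <- sum(per_cell[ct == types[j]])
    }
    prna[i, ] <- prna[i, ] / sum(per_cell)
  }
  structure(list(
    expression = cpm(cm),
    counts = cm,
    normalization = "CPM",
    truth_pCt = pct,
    truth_pRNA = prna,
    manifest = lapply(manifest, function(i) colnames(dataset$counts)[i]),
    cell_types = types,
    seed = seed
  ), class = "mixture_set")
}

#' @export
print.mixture_set <- function(x, ...) {
  cat("mixture_set:", nrow(x$expression), "genes x", ncol(x$expression),
      "mixtures;", length(x$cell_types), "cell types [", x$normalization, "]\n")
  invisible(x)
}

#' Recompute the pRNA ground truth from the sampling manifest
#'
#' The stored `truth_pRNA` is exactly recomputable from the manifest and the
#' source counts; this function performs that recomputation (used as an
#' integrity check).
#'
#' @param mixtures a `mixture_set`.
#' @param dataset the source `sc_dataset`.
#' @return mixture x cell-type matrix of read shares.
#' @export
recompute_pRNA <- function(mixtures, dataset) {
  idx <- lapply(mixtures$manifest, match, colnames(dataset$counts))
  .aggregate_manifest(dataset, idx, mixtures$seed)$truth_pRNA
}

#' Split a dataset into disjoint signature and mixture halves
#'
#' The split is stratified by cell type so both halves preserve the type
#' composition.
#'
#' @param dataset an `sc_dataset`.
#' @param fraction fraction assigned to the signature half (default 0.5).
#' @param seed integer seed.
#' @return list with `signature_half` and `mixture_half` (`sc_dataset`s with
#'   disjoint cells whose union is the input).
#' @export
split_dataset <- function(dataset, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(dataset, "sc_dataset"), fraction > 0, fraction < 1)
  with_seed(substream_seed(seed, "split_dataset"), {
    in_sig <- logical(ncol(dataset$counts))
    for (j in levels(dataset$cell_type)) {
      cells <- which(dataset$cell_type == j)
      take <- sample(cells, round(fraction * length(cells)))
      in_sig[take] <- TRUE
    }
    list(signature_half = subset_cells(dataset, which(in_sig)),
         mixture_half = subset_cells(dataset, which(!in_sig)))
  })
}

#' Simulate randomly sampled pseudo-bulk mixtures
#'
#' Each mixture is the column sum of `cells_per_mixture` cells sampled
#' without replacement (within a mixture) from the whole dataset, then
#' CPM-normalised. The achieved composition therefore fluctuates around the
#' dataset's type frequencies.
#'
#' @param dataset an `sc_dataset`.
#' @param n_mixtures number of mixtures (default 100).
#' @param cells_per_mixture cells summed per mixture (default 500; 100 is
#'   typical for small single-cell datasets).
#' @param seed integer seed.
#' @return a [mixture_set].
#' @export
simulate_random_mixtures <- function(dataset, n_mixtures = 100, cells_per_mixture = 500,
                                     seed = 1L) {
  stopifnot(inherits(dataset, "sc_dataset"))
  n_avail <- ncol(dataset$counts)
  if (cells_per_mixture > n_avail) {
    stop("cells_per_mixture (", cells_per_mixture, ") exceeds available cells (",
         n_avail, "); sampling is without replacement within a mixture")
  }
  with_seed(substream_seed(seed, "simulate_random_mixtures"), {
    manifest <- lapply(seq_len(n_mixtures), function(i) sample(n_avail, cells_per_mixture))
    .aggregate_manifest(dataset, manifest, seed)
  })
}

# per-type sampling caps for the wide-range design:
# n_j = (n/k) / (s_j / min(s)), s_j = total library size of type j
wide_range_caps <- function(s, n) {
  k <- length(s)
  nj <- round((n / k) / (s / min(s)))
  if (any(nj < 1)) {
    warning("n_j < 1 after rounding for ", sum(nj < 1), " type(s); clamped to 1",
            call. = FALSE)
    nj <- pmax(nj, 1)
  }
  nj
}

#' Simulate mixtures spanning a wide range of cell-type compositions
#'
#' Random sampling yields compositions tightly concentrated around the
#' dataset frequencies; this design instead draws, for each type j, a
#' uniform number of cells between 1 and n_j where
#' `n_j = (n/k) / (s_j / min(s))` (k = number of types, s_j = total library
#' size of type j), so rarer and RNA-poor types can dominate individual
#' mixtures. If more than `n` cells are drawn a random subset of `n` is
#' kept; if fewer, the mixture is topped up from any type (still without
#' replacement). Counts are summed and CPM-normalised.
#'
#' @inheritParams simulate_random_mixtures
#' @param n target cells per mixture (default 500).
#' @return a [mixture_set].
#' @export
simulate_wide_range_mixtures <- function(dataset, n_mixtures = 100, n = 500, seed = 1L) {
  stopifnot(inherits(dataset, "sc_dataset"))
  types <- levels(dataset$cell_type)
  s <- vapply(types, function(j) {
    sum(Matrix::colSums(dataset$counts[, dataset$cell_type == j, drop = FALSE]))
  }, numeric(1))
  nj <- wide_range_caps(s, n)
  avail <- split(seq_len(ncol(dataset$counts)), dataset$cell_type)[types]
  with_seed(substream_seed(seed, "simulate_wide_range_mixtures"), {
    manifest <- lapply(seq_len(n_mixtures), function(i) {
      picked <- unlist(lapply(seq_along(types), function(j) {
        m <- sample.int(min(nj[j], length(avail[[j]])), 1)
        sample(avail[[j]], m)
      }))
      if (length(picked) > n) {
        picked <- sample(picked, n)
      } else if (length(picked) < n) {
        pool <- setdiff(seq_len(ncol(dataset$counts)), picked)
        picked <- c(picked, sample(pool, n - length(picked)))
      }
      picked
    })
    .aggregate_manifest(dataset, manifest, seed)
  })
}

#' Simulate two sample groups differing in one cell type's proportion
#'
#' Each sample of the reference group A sums `n` cells of `target_type` and
#' `cells - n` cells of the other types, with `n` uniform on
#' `[n_range[1], n_range[2]]`; group B shifts that range by `k_shift` up or
#' down, producing an expected composition difference of about
#' `k_shift / cells` in pCt. This is the engine behind the
#' composition-confounded differential-expression experiments.
#'
#' @param dataset an `sc_dataset`.
#' @param target_type the cell type whose proportion differs.
#' @param k_shift integer shift of the sampling range (0-195 by 5 in the
#'   standard design).
#' @param direction `"up"` or `"down"`: whether group B has more or fewer
#'   target cells.
#' @param n_per_group samples per group (default 50).
#' @param cells cells per sample (default 500).
#' @param n_range base range of target-type cells per sample (default
#'   `c(200, 300)`, i.e. 40-60% target).
#' @param seed integer seed.
#' @return list with `groupA` and `groupB` [mixture_set]s.
#' @export
simulate_confounded_groups <- function(dataset, target_type, k_shift = 0,
                                       direction = c("up", "down"),
                                       n_per_group = 50, cells = 500,
                                       n_range = c(200, 300), seed = 1L) {
  stopifnot(inherits(dataset, "sc_dataset"))
  direction <- match.arg(direction)
  types <- levels(dataset$cell_type)
  if (!target_type %in% types) stop("unknown target_type: ", target_type)
  shift <- if (direction == "up") k_shift else -k_shift
  rangeB <- n_range + shift
  if (rangeB[1] < 0) stop("shifted range drops below 0 target cells")
  if (rangeB[2] > cells) stop("shifted range exceeds cells per sample")
  tgt <- which(dataset$cell_type == target_type)
  oth <- which(dataset$cell_type != target_type)
  need_tgt <- max(n_range[2], rangeB[2])
  need_oth <- cells - min(n_range[1], rangeB[1])
  if (length(tgt) < need_tgt) {
    stop("only ", length(tgt), " cells of ", target_type, " available; need ", need_tgt)
  }
  if (length(oth) < need_oth) {
    stop("only ", length(oth), " non-target cells available; need ", need_oth)
  }
  draw_group <- function(rng) {
    lapply(seq_len(n_per_group), function(i) {
      n_t <- sample(seq(rng[1], rng[2]), 1)
      c(sample(tgt, n_t), sample(oth, cells - n_t))
    })
  }
  with_seed(substream_seed(seed, "simulate_confounded_groups"), {
    mA <- draw_group(n_range)
    mB <- draw_group(rangeB)
    list(groupA = .aggregate_manifest(dataset, mA, seed),
         groupB = .aggregate_manifest(dataset, mB, seed))
  })
}

#' Perturb the expression of marker and non-marker genes
#'
#' Plants known expression changes to measure discriminatory power: a fixed
#' set of the target type's top markers plus an equal number of random
#' non-marker genes is perturbed by `fold`, half of each set up- and half
#' down-regulated. In bulk mode the summed counts of the target mixtures
#' are multiplied/divided before re-normalisation to CPM. In cell-type mode
#' (`cell_type` given, requires `dataset`) only counts of cells of that
#' type are scaled before re-aggregation, so mixtures without such cells
#' are unchanged.
#'
#' @param mixtures a [mixture_set].
#' @param fold fold-change > 0 (1 leaves the data untouched; 1.1, 1.3, 1.5,
#'   2 in the standard design).
#' @param markers a `marker_map` from [select_markers()].
#' @param marker_type the cell type whose markers are perturbed.
#' @param target_mixtures indices (or logical vector) of the mixtures to
#'   perturb; required — which arm of a two-group design carries the
#'   perturbation is an explicit experimental choice.
#' @param n_marker_genes,n_nonmarker_genes set sizes (default 100 each).
#' @param cell_type if non-`NULL`, perturb only cells of this type
#'   (cell-type mode); requires `dataset`.
#' @param dataset the source `sc_dataset` (cell-type mode only).
#' @param seed integer seed for the up/down assignment and non-marker draw.
#' @return a [mixture_set] with a `perturbation` field recording the gene
#'   sets, directions, fold, mode and perturbed mixtures.
#' @export
perturb_expression <- function(mixtures, fold, markers, marker_type,
                               target_mixtures,
                               n_marker_genes = 100, n_nonmarker_genes = 100,
                               cell_type = NULL, dataset = NULL, seed = 1L) {
  stopifnot(inherits(mixtures, "mixture_set"), inherits(markers, "marker_map"),
            fold > 0)
  if (is.logical(target_mixtures)) target_mixtures <- which(target_mixtures)
  genes <- rownames(mixtures$counts)
  mk <- markers[[marker_type]]
  if (is.null(mk)) stop("no markers for type: ", marker_type)
  mk_genes <- intersect(mk$gene, genes)
  if (length(mk_genes) < n_marker_genes) {
    stop("fewer than ", n_marker_genes, " markers of ", marker_type,
         " available (", length(mk_genes), ")")
  }
  mk_genes <- mk_genes[seq_len(n_marker_genes)]
  all_markers <- unlist(lapply(markers, `[[`, "gene"))
  with_seed(substream_seed(seed, "perturb_expression"), {
    nonmk <- sample(setdiff(genes, all_markers), n_nonmarker_genes)
    assign_dir <- function(g) {
      up <- sample(g, floor(length(g) / 2))
      setNames(ifelse(g %in% up, "up", "down"), g)
    }
    dirs <- c(assign_dir(mk_genes), assign_dir(nonmk))
  })
  pert_genes <- names(dirs)
  mult <- ifelse(dirs == "up", fold, 1 / fold)

  out <- mixtures
  if (is.null(cell_type)) {
    cm <- mixtures$counts
    cm[pert_genes, target_mixtures] <- cm[pert_genes, target_mixtures] * mult
    out$counts <- cm
    out$expression <- cpm(cm)
  } else {
    if (is.null(dataset)) stop("cell-type mode requires the source dataset")
    sc <- as.matrix(dataset$counts)
    cells_of_type <- colnames(sc)[dataset$cell_type == cell_type]
    sc[pert_genes, cells_of_type] <- sc[pert_genes, cells_of_type] * mult
    for (i in target_mixtures) {
      ids <- mixtures$manifest[[i]]
      out$counts[, i] <- rowSums(sc[, ids, drop = FALSE])
    }
    out$expression <- cpm(out$counts)
  }
  out$perturbation <- list(genes = pert_genes, direction = dirs, fold = fold,
                           marker_genes = mk_genes, nonmarker_genes = nonmk,
                           marker_type = marker_type,
                           mode = if (is.null(cell_type)) "bulk" else "cell_type",
                           cell_type = cell_type,
                           target_mixtures = target_mixtures)
  out
}

#' Aggregate single cells into pseudo-bulk profiles
#'
#' Sums counts per group and normalises each group to counts-per-million.
#'
#' @param dataset an `sc_dataset`.
#' @param grouping factor/character of length `ncol(counts)` (e.g. the
#'   subject labels), or `NULL` for one global pseudo-bulk column.
#' @return gene x group CPM matrix.
#' @export
pseudo_bulk <- function(dataset, grouping = NULL) {
  stopifnot(inherits(dataset, "sc_dataset"))
  if (is.null(grouping)) grouping <- rep("all", ncol(dataset$counts))
  grouping <- as.factor(grouping)
  if (length(grouping) != ncol(dataset$counts)) {
    stop("grouping length must equal the number of cells")
  }
  if (any(table(grouping) == 0)) {
    stop("empty group: ", paste(levels(grouping)[table(grouping) == 0], collapse = ", "))
  }
  sums <- vapply(levels(grouping), function(g) {
    Matrix::rowSums(dataset$counts[, grouping == g, drop = FALSE])
  }, numeric(nrow(dataset$counts)))
  dimnames(sums) <- list(rownames(dataset$counts), levels(grouping))
  cpm(sums)
}

#' Serialise / load a mixture set
#'
#' Writes the expression matrix, both truth tables and raw counts as TSV,
#' plus a JSON manifest carrying the seed and per-mixture cell ids.
#'
#' @param mixtures a [mixture_set].
#' @param dir output directory (created if needed).
#' @return `write_mixture_set` returns `dir` invisibly; `read_mixture_set`
#'   a [mixture_set].
#' @export
write_mixture_set <- function(mixtures, dir) {
  stopifnot(inherits(mixtures, "mixture_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(mixtures$expression, file.path(dir, "expression.tsv"))
  write_matrix(mixtures$counts, file.path(dir, "counts.tsv"))
  write_matrix(mixtures$truth_pRNA, file.path(dir, "truth_pRNA.tsv"))
  write_matrix(mixtures$truth_pCt, file.path(dir, "truth_pCt.tsv"))
  jsonlite::write_json(
    list(seed = mixtures$seed, cell_types = mixtures$cell_types,
         normalization = mixtures$normalization, manifest = mixtures$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_mixture_set
#' @export
read_mixture_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(list(
    expression = read_matrix(file.path(dir, "expression.tsv")),
    counts = read_matrix(file.path(dir, "counts.tsv")),
    normalization = man$normalization,
    truth_pCt = read_matrix(file.path(dir, "truth_pCt.tsv")),
    truth_pRNA = read_matrix(file.path(dir, "truth_pRNA.tsv")),
    manifest = lapply(man$manifest, function(x) unlist(x, use.names = FALSE)),
    cell_types = unlist(man$cell_types, use.names = FALSE),
    seed = man$seed
  ), class = "mixture_set")
}
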