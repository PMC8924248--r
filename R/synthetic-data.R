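#' Configuration for the synthetic single-cell generator
#'
#' Defines the generative model used throughout the package's simulation
#' suite: per-gene baseline means are drawn from a long-tailed log-normal
#' (reproducing the dynamic range of RNA-seq that expression-thresholding
#' rules assume), cell-type identity multiplies a set of planted marker genes
#' by `marker_fold`, per-subject multiplicative noise acts on gene means, and
#' counts are drawn negative-binomially around the cell's mean profile scaled
#' to a log-normal per-cell library size. `dispersion = 0` degenerates to
#' Poisson sampling, which small exact tests rely on.
#'
#' Per-cell-type library-size location is a first-class knob because the
#' distinction between the share of cells (pCt) and the share of sequenced
#' RNA (pRNA) in a mixture only manifests when cell types differ in RNA
#' content; the defaults give neurons roughly twice the RNA content of glia,
#' as observed in brain tissue.
#'
#' @param n_genes number of genes.
#' @param cell_types named numeric vector of relative abundance weights
#'   (> 0); names are the cell-type labels. Defaults to a five-type cortical
#'   composition (excitatory/inhibitory neurons, astrocytes,
#'   oligodendrocytes, microglia).
#' @param cells_per_type integer, cells simulated per type (recycled across
#'   types after scaling by the abundance weights, minimum 10).
#' @param markers_per_type number of marker genes planted per type (disjoint
#'   across types).
#' @param marker_fold fold-change (> 1) applied to a type's markers in that
#'   type's mean profile.
#' @param base_expression list(meanlog, sdlog) of the log-normal baseline
#'   gene means.
#' @param library_size list(meanlog, sdlog): per-type location (recycled) and
#'   common log-scale spread of counts per cell.
#' @param dispersion negative-binomial overdispersion (>= 0; variance
#'   `mu + dispersion * mu^2`). 0 means Poisson.
#' @param n_subjects number of subjects; cells are assigned uniformly.
#' @param subject_sd log-scale standard deviation of per-subject, per-gene
#'   multiplicative noise.
#' @param compartment list(n_enriched, n_depleted, fold): planted
#'   nuclear-enriched and nuclear-depleted gene sets (disjoint) and their
#'   fold (> 1), used by [generate_paired_compartments()].
#' @param bulk list(library, dispersion): sequencing depth and
#'   overdispersion for simulated paired bulk/nuclear profiles.
#' @param mito list(shape1, shape2) Beta parameters of the per-cell
#'   mitochondrial fraction, or `NULL` to omit it (QC then skips that rule).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 10000,
                             cell_types = c(Excitatory = 0.40, Inhibitory = 0.20,
                                            Astrocyte = 0.20, Oligodendrocyte = 0.15,
                                            Microglia = 0.05),
                             cells_per_type = 600,
                             markers_per_type = 100,
                             marker_fold = 8,
                             base_expression = list(meanlog = 1, sdlog = 1.5),
                             library_size = list(meanlog = log(c(4000, 4000, 2000, 2000, 2000)),
                                                 sdlog = 0.3),
                             dispersion = 0.3,
                             n_subjects = 4,
                             subject_sd = 0.1,
                             compartment = list(n_enriched = 100, n_depleted = 100, fold = 2),
                             bulk = list(library = 1e7, dispersion = 0.02),
                             mito = list(shape1 = 2, shape2 = 98),
                             seed = 1L) {
  if (is.null(names(cell_types)) || any(!nzchar(names(cell_types)))) {
    stop("cell_types must be a named vector of abundance weights")
  }
  assert_unique(names(cell_types), "cell-type names")
  if (any(!is.finite(cell_types)) || any(cell_types <= 0)) {
    stop("all abundance weights must be finite and > 0")
  }
  if (marker_fold <= 1) stop("marker_fold must be > 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  k <- length(cell_types)
  if (n_genes < markers_per_type * k) {
    stop("marker request exceeds gene count: ", markers_per_type, " markers x ",
         k, " types > ", n_genes, " genes")
  }
  if (!is.null(compartment)) {
    if (compartment$fold <= 1) stop("compartment fold must be > 1")
    if (compartment$n_enriched + compartment$n_depleted > n_genes) {
      stop("compartment gene request exceeds gene count")
    }
  }
  w <- cell_types / mean(cell_types)
  n_cells <- pmax(10L, as.integer(round(rep_len(cells_per_type, k) * w)))
  structure(list(
    n_genes = as.integer(n_genes),
    cell_types = cell_types,
    n_cells_per_type = setNames(n_cells, names(cell_types)),
    markers_per_type = as.integer(markers_per_type),
    marker_fold = marker_fold,
    base_expression = base_expression,
    library_size = list(meanlog = rep_len(library_size$meanlog, k),
                        sdlog = library_size$sdlog),
    dispersion = dispersion,
    n_subjects = as.integer(n_subjects),
    subject_sd = subject_sd,
    compartment = compartment,
    bulk = bulk,
    mito = mito,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# draw a gene x n count matrix around per-gene means `lam` (columns scaled
# individually); dispersion 0 -> Poisson
.draw_counts <- function(lam, dispersion) {
  n <- length(lam)
  if (dispersion == 0) rpois(n, lam) else rnbinom(n, size = 1 / dispersion, mu = lam)
}

#' Generate a labelled synthetic single-cell/nucleus dataset
#'
#' Draws counts under the model described in [synthetic_config()] and
#' records the planted ground truth (marker map, compartment gene sets,
#' per-type mean profiles) in the `truth` slot, so downstream selection and
#' filtering steps can be scored against it.
#'
#' @param config a [synthetic_config()].
#' @return object of class `sc_dataset` with fields `counts` (sparse gene x
#'   cell integer matrix), `cell_type` (factor per cell), `subject`,
#'   `mito_fraction` (or `NULL`), `cell_types` (declared labels), and
#'   `truth`.
#' @export
generate_single_cell <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(substream_seed(config$seed, "generate_single_cell"), {
    G <- config$n_genes
    types <- names(config$cell_types)
    k <- length(types)
    gene_ids <- sprintf("G%05d", seq_len(G))

    mu <- rlnorm(G, config$base_expression$meanlog, config$base_expression$sdlog)
    names(mu) <- gene_ids

    # disjoint marker sets, planted among genes above the lower expression
    # quartile so markers are detectable at realistic depth
    eligible <- which(mu >= quantile(mu, 0.25))
    picked <- sample(eligible, config$markers_per_type * k)
    markers <- split(gene_ids[picked], rep(types, each = config$markers_per_type))
    markers <- markers[types]

    profiles <- matrix(mu, G, k, dimnames = list(gene_ids, types))
    for (j in seq_len(k)) {
      idx <- match(markers[[j]], gene_ids)
      profiles[idx, j] <- profiles[idx, j] * config$marker_fold
    }

    # disjoint compartment gene sets (also detectable)
    comp <- NULL
    if (!is.null(config$compartment)) {
      pool <- setdiff(eligible, picked)
      cpick <- sample(pool, config$compartment$n_enriched + config$compartment$n_depleted)
      comp <- list(
        nuclear_enriched = gene_ids[cpick[seq_len(config$compartment$n_enriched)]],
        nuclear_depleted = gene_ids[cpick[config$compartment$n_enriched +
                                            seq_len(config$compartment$n_depleted)]],
        fold = config$compartment$fold
      )
    }

    subj_ids <- sprintf("S%02d", seq_len(config$n_subjects))
    subj_fx <- matrix(exp(rnorm(G * config$n_subjects, 0, config$subject_sd)),
                      G, config$n_subjects, dimnames = list(gene_ids, subj_ids))

    n_cells <- config$n_cells_per_type
    total <- sum(n_cells)
    cell_type <- factor(rep(types, n_cells), levels = types)
    subject <- factor(sample(subj_ids, total, replace = TRUE), levels = subj_ids)
    lib <- rlnorm(total, config$library_size$meanlog[as.integer(cell_type)],
                  config$library_size$sdlog)

    counts <- matrix(0, G, total)
    for (j in seq_len(k)) {
      for (s in seq_len(config$n_subjects)) {
        cells <- which(cell_type == types[j] & subject == subj_ids[s])
        if (!length(cells)) next
        prof <- profiles[, j] * subj_fx[, s]
        lam <- outer(prof / sum(prof), lib[cells])
        counts[, cells] <- .draw_counts(lam, config$dispersion)
      }
    }
    cell_ids <- sprintf("C%05d", seq_len(total))
    dimnames(counts) <- list(gene_ids, cell_ids)

    mito <- NULL
    if (!is.null(config$mito)) {
      mito <- rbeta(total, config$mito$shape1, config$mito$shape2)
      names(mito) <- cell_ids
    }

    structure(list(
      counts = as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      cell_type = setNames(cell_type, cell_ids),
      subject = setNames(subject, cell_ids),
      mito_fraction = mito,
      cell_types = types,
      truth = list(markers = markers, compartment = comp, profiles = profiles,
                   baseline = mu),
      config = config
    ), class = "sc_dataset")
  })
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("sc_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(x$cell_types), "cell types;",
      nlevels(x$subject), "subjects\n")
  print(table(x$cell_type))
  invisible(x)
}

#' Generate paired whole-cell and nuclear bulk expression profiles
#'
#' Emulates paired total-RNA and nuclear-RNA sequencing of the same tissue:
#' the whole-cell expectation is the abundance-weighted sum of the cell-type
#' profiles, and the nuclear expectation multiplies (enriched set) or divides
#' (depleted set) that expectation by the compartment fold before count-level
#' sampling noise is added. Used to exercise the compartment-specific gene
#' filter against planted truth.
#'
#' @param config a [synthetic_config()] with a non-`NULL` `compartment`
#'   block.
#' @param n_samples samples per arm (default 5, minimum 2).
#' @return list with `bulk` and `nuclear` gene x sample count matrices and
#'   `truth` (the planted compartment gene sets and fold).
#' @export
generate_paired_compartments <- function(config, n_samples = 5L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$compartment)) stop("config has no compartment block")
  if (n_samples < 2) stop("n_samples must be >= 2 per arm (a two-group test is impossible)")
  with_seed(substream_seed(config$seed, "generate_paired_compartments"), {
    G <- config$n_genes
    gene_ids <- sprintf("G%05d", seq_len(G))
    mu <- rlnorm(G, config$base_expression$meanlog, config$base_expression$sdlog)
    names(mu) <- gene_ids
    eligible <- which(mu >= quantile(mu, 0.25))
    cpick <- sample(eligible, config$compartment$n_enriched + config$compartment$n_depleted)
    enr <- gene_ids[cpick[seq_len(config$compartment$n_enriched)]]
    dep <- gene_ids[cpick[config$compartment$n_enriched +
                            seq_len(config$compartment$n_depleted)]]
    fold <- config$compartment$fold

    nuc_mu <- mu
    nuc_mu[enr] <- nuc_mu[enr] * fold
    nuc_mu[dep] <- nuc_mu[dep] / fold

    draw_arm <- function(m, prefix) {
      out <- vapply(seq_len(n_samples), function(i) {
        lam <- m / sum(m) * config$bulk$library
        .draw_counts(lam, config$bulk$dispersion)
      }, numeric(G))
      dimnames(out) <- list(gene_ids, sprintf("%s%02d", prefix, seq_len(n_samples)))
      out
    }
    list(bulk = draw_arm(mu, "BULK"),
         nuclear = draw_arm(nuc_mu, "NUC"),
         truth = list(nuclear_enriched = enr, nuclear_depleted = dep, fold = fold))
  })
}
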