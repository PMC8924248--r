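#' Write / read a matrix with ids
#'
#' Dense TSV: row ids in the first column (`id`), header row of column ids.
#' Matrix Market (`mtx_triplet`): standard 1-based coordinate format with
#' companion `<path>.rownames.tsv` / `<path>.colnames.tsv` id files.
#' Round-trips are lossless for integer counts.
#'
#' @param x matrix (dense or sparse) with full dimnames.
#' @param path output file.
#' @param kind `"dense_tsv"` (default) or `"mtx_triplet"`.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` the
#'   matrix (sparse for `mtx_triplet`).
#' @export
write_matrix <- function(x, path, kind = c("dense_tsv", "mtx_triplet")) {
  kind <- match.arg(kind)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix must carry full dimnames")
  }
  assert_unique(rownames(x), "row ids")
  assert_unique(colnames(x), "column ids")
  if (kind == "dense_tsv") {
    df <- data.frame(id = rownames(x), as.matrix(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"), path)
    writeLines(rownames(x), paste0(path, ".rownames.tsv"))
    writeLines(colnames(x), paste0(path, ".colnames.tsv"))
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, kind = c("dense_tsv", "mtx_triplet")) {
  kind <- match.arg(kind)
  if (kind == "dense_tsv") {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    ids <- df[[1]]
    assert_unique(ids, "row ids")
    vals <- df[, -1, drop = FALSE]
    m <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, names(vals)))
    if (anyNA(m) ) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("non-numeric cell at row '", ids[bad[1]], "', column '",
           colnames(m)[bad[2]], "'")
    }
    rownames(m) <- ids
    m
  } else {
    m <- as(Matrix::readMM(path), "CsparseMatrix")
    rn <- readLines(paste0(path, ".rownames.tsv"))
    cn <- readLines(paste0(path, ".colnames.tsv"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("companion id files do not match matrix dimensions")
    }
    assert_unique(rn, "row ids")
    assert_unique(cn, "column ids")
    dimnames(m) <- list(rn, cn)
    m
  }
}

#' Write / read a single-cell dataset as Matrix Market plus metadata TSVs
#'
#' Counts go to `counts.mtx`, gene ids to `genes.tsv`, and per-cell
#' metadata (columns `cell_id`, `cell_type`, `subject`, `mito_fraction`) to
#' `cells.tsv`.
#'
#' @param dataset an `sc_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_sc_dataset` returns `dir` invisibly; `read_sc_dataset`
#'   an `sc_dataset` (without the generator's truth slot, which is not
#'   serialised).
#' @export
write_sc_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dataset$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(dataset$counts), file.path(dir, "genes.tsv"))
  meta <- data.frame(cell_id = colnames(dataset$counts),
                     cell_type = as.character(dataset$cell_type),
                     subject = as.character(dataset$subject),
                     stringsAsFactors = FALSE)
  if (!is.null(dataset$mito_fraction)) meta$mito_fraction <- dataset$mito_fraction
  write.table(meta, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sc_dataset
#' @export
read_sc_dataset <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  if (length(genes) != nrow(m) || nrow(meta) != ncol(m)) {
    stop("metadata dimensions do not match the count matrix")
  }
  assert_unique(genes, "gene ids")
  assert_unique(meta$cell_id, "cell ids")
  dimnames(m) <- list(genes, meta$cell_id)
  types <- unique(meta$cell_type)
  structure(list(
    counts = m,
    cell_type = setNames(factor(meta$cell_type, levels = types), meta$cell_id),
    subject = setNames(factor(meta$subject), meta$cell_id),
    mito_fraction = if ("mito_fraction" %in% names(meta)) {
      setNames(meta$mito_fraction, meta$cell_id)
    } else NULL,
    cell_types = types,
    truth = NULL
  ), class = "sc_dataset")
}

# -- run configuration --------------------------------------------------------

.known_stages <- c("simulate", "signature", "mix", "deconvolve", "evaluate")

#' Validate a pipeline run configuration
#'
#' A run config is a list (typically parsed from JSON) with a global `seed`,
#' and a `stages` list whose elements have a `stage` name from
#' `simulate`, `signature`, `mix`, `deconvolve`, `evaluate` plus that
#' stage's parameters. Validation fails before any stage runs.
#'
#' @param config list.
#' @return the config, invisibly, or an error describing the violation.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  if (is.null(config$seed) || !is.finite(as.numeric(config$seed))) {
    stop("config$seed must be a finite integer")
  }
  if (is.null(config$stages) || !length(config$stages)) {
    stop("config$stages must be a non-empty list")
  }
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage) || !st$stage %in% .known_stages) {
      stop("stage ", i, ": unknown or missing stage name (expected one of: ",
           paste(.known_stages, collapse = ", "), ")")
    }
  }
  wants <- vapply(config$stages, `[[`, character(1), "stage")
  need <- c(signature = "simulate", mix = "simulate", deconvolve = "signature",
            evaluate = "deconvolve")
  for (s in names(need)) {
    if (s %in% wants && !need[[s]] %in% wants[seq_len(match(s, wants) - 1)]) {
      stop("stage '", s, "' requires an earlier '", need[[s]], "' stage")
    }
  }
  invisible(config)
}

.stage_manifest <- function(dir, stage, seed, params, inputs = character()) {
  checks <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(stage = stage, seed = seed, parameters = params,
         input_md5 = checks,
         package_version = as.character(utils::packageVersion("deconvbench"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
}

#' Run a configured end-to-end benchmark pipeline
#'
#' Executes the configured stages in order, writing each stage's outputs
#' and a manifest (parameters, substream seed, input checksums) into its
#' own subdirectory of `out_dir`. Stages never mutate earlier outputs, and
#' rerunning with an identical config reproduces identical files. On a
#' stage failure, completed outputs are retained and the run manifest marks
#' the failed stage.
#'
#' @param config run configuration (see [validate_run_config()]); may be a
#'   file path to a JSON config.
#' @param out_dir run directory (created; must not require overwriting
#'   earlier stages).
#' @return invisibly, a list with the per-stage objects and the run status.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  validate_run_config(config)
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  status <- list()
  for (st in config$stages) {
    name <- st$stage
    sdir <- file.path(out_dir, name)
    dir.create(sdir, showWarnings = FALSE)
    sseed <- substream_seed(seed, name)
    res <- try({
      state <- .run_stage(name, st, state, sdir, sseed)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      status[[name]] <- list(ok = FALSE, error = attr(res, "condition")$message)
      break
    }
    status[[name]] <- list(ok = TRUE)
  }
  jsonlite::write_json(list(seed = seed, stages = status),
                       file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(state = state, status = status))
}

.run_stage <- function(name, st, state, sdir, sseed) {
  params <- st[setdiff(names(st), "stage")]
  if (name == "simulate") {
    cfg_args <- params
    cfg_args$seed <- sseed
    if (!is.null(cfg_args$cell_types)) cfg_args$cell_types <- unlist(cfg_args$cell_types)
    cfg <- do.call(synthetic_config, cfg_args)
    state$dataset <- generate_single_cell(cfg)
    write_sc_dataset(state$dataset, sdir)
    .stage_manifest(sdir, name, sseed, params)
  } else if (name == "signature") {
    halves <- split_dataset(state$dataset, seed = sseed)
    state$signature_half <- halves$signature_half
    state$mixture_half <- halves$mixture_half
    state$signature <- build_signature(halves$signature_half,
                                       params$normalization %||% "CPM")
    state$markers <- select_markers(state$signature, params$top %||% 0.01)
    write_signature(state$signature, file.path(sdir, "signature.tsv"))
    .stage_manifest(sdir, name, sseed, params)
  } else if (name == "mix") {
    src <- state$mixture_half %||% state$dataset
    state$mixtures <- switch(params$design %||% "random",
      random = simulate_random_mixtures(src,
        params$n_mixtures %||% 100, params$cells_per_mixture %||% 500, seed = sseed),
      wide = simulate_wide_range_mixtures(src,
        params$n_mixtures %||% 100, params$n %||% 500, seed = sseed),
      stop("unknown mix design: ", params$design))
    write_mixture_set(state$mixtures, sdir)
    .stage_manifest(sdir, name, sseed, params)
  } else if (name == "deconvolve") {
    method <- params$method %||% "nnls"
    state$estimates <- switch(method,
      nnls = deconvolve_nnls(state$mixtures, state$signature),
      svr = deconvolve_svr(state$mixtures, state$signature),
      dtangle = deconvolve_dtangle(state$mixtures, state$signature, state$markers),
      wnnls = deconvolve_wnnls(state$mixtures, state$signature_half),
      stop("unknown deconvolution method: ", method))
    write_matrix(state$estimates$values, file.path(sdir, "estimates.tsv"))
    .stage_manifest(sdir, name, sseed, params)
  } else if (name == "evaluate") {
    truth <- switch(params$truth %||% "pRNA",
                    pRNA = state$mixtures$truth_pRNA,
                    pCt = state$mixtures$truth_pCt)
    rep <- evaluation_report(state$estimates, truth,
                             mixtures = state$mixtures, signature = state$signature)
    write_evaluation_report(rep, file.path(sdir, "report.json"),
                            file.path(sdir, "report.tsv"))
    state$report <- rep
    .stage_manifest(sdir, name, sseed, params)
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
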