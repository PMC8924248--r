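#' @importFrom stats rnbinom rpois rlnorm rnorm rbeta runif cor sd var
#'   quantile p.adjust pt phyper setNames complete.cases ks.test median
#' @importFrom utils head write.table read.delim
#' @importFrom methods as is
NULL

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a fixed seed yields byte-identical output and the
#' caller's RNG stream is left untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed from a global seed
#'
#' Hashes `(seed, name)` to an integer in `[0, 2^31 - 2]`. Substreams are
#' order-independent: inserting a new stage does not shift the randomness of
#' other stages.
#'
#' @param seed integer global seed.
#' @param name character stage name.
#' @return integer seed for the substream.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  h <- 0
  for (ch in utf8ToInt(paste0(name, collapse = ""))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 2654435761 + h * 40503 + 17) %% 2147483629)
}

#' Counts-per-million normalisation
#'
#' Scales each column (sample/cell) to sum to one million. Columns with zero
#' total are left at zero.
#'
#' @param counts gene x sample numeric or sparse matrix.
#' @return matrix of the same shape and dimnames.
#' @export
cpm <- function(counts) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  out <- sweep(as.matrix(counts), 2, tot, "/") * 1e6
  dimnames(out) <- dimnames(counts)
  out
}

# log2 with the +0.5 offset used throughout the package
log2p5 <- function(x) log2(x + 0.5)

#' Quantile-normalise the columns of a matrix
#'
#' Standard column quantile normalisation: the target distribution is the
#' mean of the sorted columns; ties are resolved by averaging ranks.
#'
#' @param x numeric matrix.
#' @return matrix with identical marginal distribution in every column.
#' @export
quantile_normalize <- function(x) {
  out <- limma::normalizeQuantiles(as.matrix(x), ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

# shared argument checks ------------------------------------------------------

assert_unique <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stop("duplicate ", what, ": ", paste(head(ids[duplicated(ids)], 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(ids)
}

assert_genes_rows <- function(x, what = "matrix") {
  if (is.null(rownames(x))) stop(what, " must carry gene ids as rownames", call. = FALSE)
  invisible(x)
}
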