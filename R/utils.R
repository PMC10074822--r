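#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All multi-stage simulations in this package draw their randomness from a
#' single integer seed; independent stages (community counts, taxonomy,
#' tree, GSMM content, ...) receive sub-seeds derived deterministically from
#' the master seed and a stage label, so adding a stage never perturbs the
#' random stream of another.
#'
#' @param seed master integer seed
#' @param key character label of the consuming stage
#' @return an integer in [0, 2^31 - 1]
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  # FNV-1a style mixing, kept inside 31 bits so set.seed() accepts it
  h <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(key)) {
    h <- (h * 16777619 + ch) %% 2147483647
  }
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# geometric mean of a strictly positive vector
gmean <- function(x) exp(mean(log(x)))

# rdirichlet via gamma draws; rows are draws
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

stop_if_not_count_matrix <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with sample row names and ASV column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at sample '%s', ASV '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at sample '%s', ASV '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  invisible(counts)
}

#' The seven taxonomic ranks used throughout the package
#' @export
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")
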