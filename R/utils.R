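#' Run code with a local, restorable random seed
#'
#' Sets the RNG to a reproducible state for the duration of `code` and
#' restores the caller's RNG state afterwards, so seeded generators are
#' pure functions of their arguments.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that every class is spread
#' as evenly as possible across folds. Assignment order within a class is
#' randomized (call inside [local_seed()] for reproducibility).
#'
#' @param y Factor or character vector of class labels.
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1:k`, aligned with `y`.
#' @keywords internal
#' @noRd
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
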