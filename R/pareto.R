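#' Fit interaction response surfaces for PC scores
#'
#' Models PC1 and PC2 scores of the per-run principal component analysis
#' as linear-with-interactions functions of the three coded factors,
#' using the same 8-term basis as [fit_ffd()].
#'
#' @param design A three-factor `design_table`.
#' @param pc_scores Matrix or data frame with columns `PC1` and `PC2`
#'   (one row per run, aligned with the design), or any two score
#'   columns.
#' @return Named list of two `surface_model` objects (one per column):
#'   each has `response_name`, `coefficients` (named 8-vector), `r2`.
#' @export
fit_pc_surfaces <- function(design, pc_scores) {
  S <- as.matrix(pc_scores)
  if (ncol(S) != 2L) stop("pc_scores must have exactly 2 columns", call. = FALSE)
  if (is.null(colnames(S))) colnames(S) <- c("PC1", "PC2")
  if (nrow(S) != nrow(design)) {
    stop("pc_scores rows (", nrow(S), ") do not align with design runs (",
         nrow(design), ")", call. = FALSE)
  }
  X <- ffd_model_matrix(design)
  out <- lapply(colnames(S), function(nm) {
    y <- S[, nm]
    beta <- qr.coef(qr(X), y)
    fitted <- drop(X %*% beta)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - sum((y - fitted)^2) / tss else 1
    structure(list(response_name = nm,
                   coefficients = stats::setNames(unname(beta), ffd_terms()),
                   r2 = r2),
              class = "surface_model")
  })
  stats::setNames(out, colnames(S))
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %s (R2 = %.3f)\n", x$response_name, x$r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Build a dense factor grid over the experimental ranges
#'
#' For every factor, `n_levels` equally spaced real values from low to
#' high inclusive; the grid is their full cartesian product. With 40
#' levels and 3 factors this is the 64,000-point grid used for the
#' Pareto search.
#'
#' @param factors List of `factor_spec` objects.
#' @param n_levels Number of levels per factor (>= 2).
#' @return An object of class `factor_grid`: list with `real` (data
#'   frame of factor settings), `coded` (matrix of coded equivalents),
#'   `levels` (per-factor level sequences), `n_points`.
#' @export
build_grid <- function(factors, n_levels = 40) {
  stopifnot(is.list(factors))
  lapply(factors, function(f) stopifnot(inherits(f, "factor_spec")))
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  nm <- vapply(factors, `[[`, character(1), "name")
  levels <- stats::setNames(
    lapply(factors, function(f) seq(f$low, f$high, length.out = n_levels)), nm)
  real <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  coded <- vapply(seq_along(factors),
                  function(j) real_to_coded(real[[j]], factors[[j]]),
                  numeric(nrow(real)))
  colnames(coded) <- nm
  structure(list(real = real, coded = coded, levels = levels,
                 n_points = nrow(real)),
            class = "factor_grid")
}

#' @export
print.factor_grid <- function(x, ...) {
  cat("<factor_grid>", x$n_points, "points (",
      paste(vapply(x$levels, length, integer(1)), collapse = " x "), ")\n")
  invisible(x)
}

#' Evaluate PC response surfaces on a factor grid
#'
#' @param grid A `factor_grid`.
#' @param surfaces List of two `surface_model` objects (see
#'   [fit_pc_surfaces()]).
#' @return Data frame: factor settings in real units followed by one
#'   column of predicted values per surface.
#' @export
evaluate_surfaces <- function(grid, surfaces) {
  stopifnot(inherits(grid, "factor_grid"))
  X <- ffd_model_matrix(grid$coded)
  out <- grid$real
  for (s in surfaces) {
    stopifnot(inherits(s, "surface_model"))
    out[[s$response_name]] <- drop(X %*% s$coefficients)
  }
  out
}

#' Non-dominated (Pareto) front of a two-objective point set
#'
#' Point p dominates q when p is at least as good as q in both oriented
#' objectives and strictly better in at least one. The front is the set
#' of points not dominated by any other; points tied on both
#' coordinates are all retained.
#'
#' @param points Matrix or data frame with two objective columns.
#' @param directions Character vector of length 2, each `"max"` or
#'   `"min"`.
#' @return Integer vector of row indices on the front, in ascending
#'   order.
#' @export
pareto_front <- function(points, directions = c("max", "max")) {
  P <- as.matrix(points)
  if (nrow(P) == 0L) stop("empty point set", call. = FALSE)
  if (ncol(P) != 2L) stop("exactly two objectives are supported", call. = FALSE)
  directions <- match.arg(directions, c("max", "min"), several.ok = TRUE)
  if (length(directions) != 2L) stop("directions must have length 2", call. = FALSE)
  # orient both objectives to maximize
  Z <- P
  for (j in 1:2) if (directions[j] == "min") Z[, j] <- -Z[, j]

  # sweep over objective-1 blocks in descending order. A point q is
  # dominated by an earlier block iff some earlier point (strictly larger
  # obj1) has obj2 >= q2, and within its own block iff some tied-obj1
  # point has obj2 > q2. So keep q iff q2 > best2_prev and q2 == blockmax2
  # (which retains every point tied on both coordinates).
  keep <- logical(nrow(Z))
  best2_prev <- -Inf
  for (v in sort(unique(Z[, 1]), decreasing = TRUE)) {
    block <- which(Z[, 1] == v)
    blockmax2 <- max(Z[block, 2])
    if (blockmax2 > best2_prev) {
      keep[block[Z[block, 2] == blockmax2]] <- TRUE
    }
    best2_prev <- max(best2_prev, blockmax2)
  }
  sort(which(keep))
}

#' Pick a compromise setting from a Pareto front
#'
#' Selects the front point closest (Euclidean distance) to the utopia
#' point — the infeasible combination of each objective's best value —
#' after min-max normalization of both objectives over the front, so the
#' choice is invariant to objective units. A single-point front is
#' returned directly.
#'
#' @param evaluated Data frame from [evaluate_surfaces()] (factor columns
#'   followed by the two objective columns).
#' @param front Integer indices from [pareto_front()].
#' @param objectives Names of the two objective columns (default: last
#'   two columns of `evaluated`).
#' @param directions Objective senses, as in [pareto_front()].
#' @return An object of class `pareto_compromise`: list with `setting`
#'   (one-row data frame of factor values and objective values), `index`
#'   (row in `evaluated`), `distance` (normalized distance to utopia),
#'   `rule`.
#' @export
select_compromise <- function(evaluated, front,
                              objectives = utils::tail(names(evaluated), 2),
                              directions = c("max", "max")) {
  if (length(front) == 0L) stop("empty front", call. = FALSE)
  Z <- as.matrix(evaluated[front, objectives, drop = FALSE])
  for (j in 1:2) if (directions[j] == "min") Z[, j] <- -Z[, j]
  if (length(front) == 1L) {
    idx <- front
    dist <- 0
  } else {
    rng <- apply(Z, 2, range)
    span <- rng[2, ] - rng[1, ]
    # a flat objective contributes nothing to the trade-off
    span[span == 0] <- 1
    N <- sweep(sweep(Z, 2, rng[1, ]), 2, span, "/")
    d <- sqrt(rowSums((1 - N)^2))  # utopia is (1, 1) after normalization
    best <- which.min(d)
    idx <- front[best]
    dist <- d[best]
  }
  structure(
    list(setting = evaluated[idx, , drop = FALSE], index = idx,
         distance = dist, rule = "nearest-to-utopia (min-max normalized)"),
    class = "pareto_compromise"
  )
}

#' @export
print.pareto_compromise <- function(x, ...) {
  cat("<pareto_compromise>", x$rule, sprintf("(distance %.4f)\n", x$distance))
  print(x$setting, row.names = FALSE)
  invisible(x)
}
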