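# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive results by the most naive route available.

# all 2^k sign combinations by recursive enumeration
recursive_corners <- function(k) {
  if (k == 1L) return(matrix(c(-1, 1), ncol = 1))
  sub <- recursive_corners(k - 1L)
  rbind(cbind(-1, sub), cbind(1, sub))
}

# normal-equation least squares: beta = (X'X)^-1 X'y
normal_eq_beta <- function(X, y) drop(solve(t(X) %*% X) %*% t(X) %*% y)

# naive O(n^3) UPGMA on squared Euclidean distances: recompute every
# between-cluster average from the raw point matrix at every merge
naive_upgma <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d2 <- function(i, j) sum((x[i, ] - x[j, ])^2)
  clusters <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  heights <- numeric(n - 1L)
  sizes <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        ca <- clusters[[active[a]]]; cb <- clusters[[active[b]]]
        h <- mean(outer(ca, cb, Vectorize(d2)))
        if (h < best_h) { best_h <- h; best <- c(active[b], active[a]) }
      }
    }
    heights[m] <- best_h
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    sizes[m] <- length(clusters[[best[1]]])
    active <- setdiff(active, best[2])
  }
  list(heights = heights, sizes = sizes)
}

# O(n^2) all-pairs dominance filter for a two-objective front
brute_pareto <- function(P, directions) {
  Z <- as.matrix(P)
  for (j in 1:2) if (directions[j] == "min") Z[, j] <- -Z[, j]
  n <- nrow(Z)
  keep <- rep(TRUE, n)
  for (q in seq_len(n)) {
    for (p in seq_len(n)) {
      if (p == q) next
      if (all(Z[p, ] >= Z[q, ]) && any(Z[p, ] > Z[q, ])) {
        keep[q] <- FALSE
        break
      }
    }
  }
  which(keep)
}

mae_design_11 <- function() build_full_factorial(mae_factors(), n_center = 3)
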