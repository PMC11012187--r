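#' NIPALS PLS2 regression on a one-hot class matrix
#'
#' Core fitting routine behind the PLS-DA diagnostics. X is
#' mean-centered (and optionally autoscaled); Y is the mean-centered
#' one-hot indicator matrix. Components are extracted by NIPALS with
#' sequential deflation of X and Y.
#'
#' @param X Numeric matrix, samples x variables.
#' @param y Factor (or coercible) of class labels.
#' @param ncomp Number of latent components.
#' @param scale Autoscale X columns (default TRUE).
#' @return An object of class `pls_model` used by [predict.pls_model()].
#' @keywords internal
#' @export
pls_fit <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.factor(y)
  classes <- levels(y)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- classes

  x_center <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1  # constant columns carry no information; leave centered at 0
    s
  } else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)

  max_rank <- qr(Xc)$rank
  ncomp <- min(ncomp, max_rank)
  if (ncomp < 1L) stop("X has rank 0 after centering", call. = FALSE)

  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (it in 1:500) {
      w <- drop(crossprod(Xd, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t_vec <- drop(Xd %*% w)
      cvec <- drop(crossprod(Yd, t_vec)) / sum(t_vec^2)
      u <- drop(Yd %*% cvec) / sum(cvec^2)
      if (sum((t_vec - t_old)^2) < 1e-12 * sum(t_vec^2)) break
      t_old <- t_vec
    }
    pvec <- drop(crossprod(Xd, t_vec)) / sum(t_vec^2)
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cvec; Tm[, a] <- t_vec
    Xd <- Xd - tcrossprod(t_vec, pvec)
    Yd <- Yd - tcrossprod(t_vec, cvec)
  }
  # regression coefficients on the centered/scaled scale
  B <- W %*% solve(crossprod(P, W), t(C))
  structure(
    list(B = B, W = W, P = P, C = C, scores = Tm,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         classes = classes, ncomp = ncomp),
    class = "pls_model"
  )
}

#' Predict class responses from a fitted PLS2 model
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix of new samples.
#' @param ... Unused.
#' @return List with `y_pred` (continuous predicted indicator matrix,
#'   one column per class) and `class` (arg-max assignment, factor with
#'   the training levels).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xn <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  Yp <- Xn %*% object$B
  Yp <- sweep(Yp, 2, object$y_center, "+")
  colnames(Yp) <- object$classes
  cls <- factor(object$classes[max.col(Yp, ties.method = "first")],
                levels = object$classes)
  list(y_pred = Yp, class = cls)
}

#' Cross-validated Q2 and discriminant Q2 for one class response
#'
#' `Q2 = 1 - PRESS/TSS` on held-out predictions of a 0/1 response. DQ2
#' applies the discriminant convention: residuals of predictions that
#' overshoot their label in the correct direction (prediction above 1
#' for class members, below 0 for non-members) are zeroed before
#' accumulating PRESS, so `DQ2 >= Q2` always.
#'
#' @param y_true 0/1 vector (class membership).
#' @param y_pred Continuous predicted responses.
#' @return Named numeric vector `c(Q2 = ..., DQ2 = ...)`.
#' @examples
#' compute_q2_dq2(c(1, 0), c(1.5, 0))  # DQ2 = 1 > Q2
#' @export
compute_q2_dq2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.numeric(y_true)
  if (!all(y_true %in% c(0, 1))) stop("y_true must be 0/1", call. = FALSE)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) stop("constant y_true: Q2 undefined", call. = FALSE)
  res <- y_true - y_pred
  press <- sum(res^2)
  res_d <- res
  res_d[y_true == 1 & y_pred > 1] <- 0
  res_d[y_true == 0 & y_pred < 0] <- 0
  c(Q2 = 1 - press / tss, DQ2 = 1 - sum(res_d^2) / tss)
}

# per-class diagnostics from accumulated held-out predictions
plsda_stats <- function(y, y_pred, class_pred) {
  classes <- levels(y)
  out <- lapply(classes, function(cl) {
    y01 <- as.numeric(y == cl)
    q <- compute_q2_dq2(y01, y_pred[, cl])
    tp <- sum(class_pred == cl & y == cl)
    fn <- sum(class_pred != cl & y == cl)
    fp <- sum(class_pred == cl & y != cl)
    tn <- sum(class_pred != cl & y != cl)
    c(RMSECV = sqrt(sum((y01 - y_pred[, cl])^2) / length(y01)),
      Q2 = unname(q["Q2"]), DQ2 = unname(q["DQ2"]),
      Accuracy = (tp + tn) / length(y01),
      Sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      Specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  stats_mat <- do.call(cbind, out)
  colnames(stats_mat) <- classes
  stats_mat
}

#' PLS-DA with double cross-validation
#'
#' Model quality assessment in a double (nested) cross-validation
#' schema: the outer loop holds out test folds never seen during
#' fitting; within each outer training set, an inner cross-validation
#' selects the number of latent components maximizing the mean
#' held-out Q2 across classes. Outer-fold predictions are accumulated
#' into per-class RMSECV, Q2, DQ2 and, after arg-max class assignment,
#' one-vs-rest accuracy, sensitivity and specificity.
#'
#' @param X Numeric matrix, samples x variables.
#' @param y Class labels (3 solvent groups in the screening workflow).
#' @param outer_folds,inner_folds Fold counts (defaults 6 and 5;
#'   stratified by class).
#' @param max_components Largest number of latent components tried.
#' @param scale Autoscale X within each training fold (default TRUE).
#' @param seed Integer seed for the fold shuffling.
#' @return An object of class `plsda_report`: list with `stats`
#'   (6 statistics x classes matrix), `mode = "double_cv"`,
#'   `n_components_chosen` (per outer fold), `classes`, `y_pred`
#'   (held-out continuous predictions), `class_pred`.
#' @export
plsda_double_cv <- function(X, y, outer_folds = 6, inner_folds = 5,
                            max_components = 5, scale = TRUE, seed = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (min(table(y)) < outer_folds) {
    stop("each class needs at least `outer_folds` samples for stratified folds",
         call. = FALSE)
  }
  local_seed(seed, {
    fold <- stratified_folds(y, outer_folds)
    y_pred <- matrix(NA_real_, nrow(X), nlevels(y),
                     dimnames = list(NULL, levels(y)))
    ncomp_chosen <- integer(outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- fold != f
      ncomp_chosen[f] <- select_ncomp_cv(X[tr, , drop = FALSE], y[tr],
                                         inner_folds, max_components, scale)
      m <- pls_fit(X[tr, , drop = FALSE], y[tr], ncomp_chosen[f], scale)
      y_pred[!tr, ] <- predict(m, X[!tr, , drop = FALSE])$y_pred
    }
    class_pred <- factor(levels(y)[max.col(y_pred, ties.method = "first")],
                         levels = levels(y))
    structure(
      list(stats = plsda_stats(y, y_pred, class_pred), mode = "double_cv",
           n_components_chosen = ncomp_chosen, classes = levels(y),
           y_pred = y_pred, class_pred = class_pred),
      class = "plsda_report"
    )
  })
}

# inner CV: mean Q2 across classes per candidate ncomp
select_ncomp_cv <- function(X, y, k, max_components, scale) {
  y <- droplevels(as.factor(y))
  k <- min(k, min(table(y)))
  fold <- stratified_folds(y, k)
  max_a <- min(max_components, qr(scale(X, scale = FALSE))$rank)
  q2 <- numeric(max_a)
  preds <- array(NA_real_, c(nrow(X), nlevels(y), max_a))
  for (f in seq_len(k)) {
    tr <- fold != f
    m_full <- pls_fit(X[tr, , drop = FALSE], y[tr],
                      min(max_a, sum(tr) - 1L), scale)
    for (a in seq_len(min(max_a, m_full$ncomp))) {
      # truncate to a components by re-deriving B from the first a vectors
      Ba <- m_full$W[, 1:a, drop = FALSE] %*%
        solve(crossprod(m_full$P[, 1:a, drop = FALSE],
                        m_full$W[, 1:a, drop = FALSE]),
              t(m_full$C[, 1:a, drop = FALSE]))
      Xn <- sweep(sweep(X[!tr, , drop = FALSE], 2, m_full$x_center), 2,
                  m_full$x_scale, "/")
      preds[!tr, , a] <- sweep(Xn %*% Ba, 2, m_full$y_center, "+")
    }
  }
  for (a in seq_len(max_a)) {
    if (anyNA(preds[, , a])) { q2[a] <- -Inf; next }
    q2[a] <- mean(vapply(seq_len(nlevels(y)), function(j) {
      compute_q2_dq2(as.numeric(y == levels(y)[j]), preds[, j, a])["Q2"]
    }, numeric(1)))
  }
  which.max(q2)
}

#' PLS-DA diagnostics by stratified bootstrap
#'
#' Fits the PLS-DA model on `B` stratified resamples drawn with
#' replacement and evaluates each on its out-of-bag samples; the six
#' diagnostic statistics are averaged over replicates. Replicates whose
#' out-of-bag set misses a class entirely are skipped (counted in
#' `n_skipped`).
#'
#' @param X,y As in [plsda_double_cv()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param ncomp Number of latent components; when `NULL` it is chosen
#'   once by stratified cross-validation on the full data.
#' @param scale Autoscale X (default TRUE).
#' @param seed Integer seed.
#' @return A `plsda_report` with `mode = "bootstrap"`, averaged `stats`,
#'   `n_components_chosen`, `n_used`, `n_skipped`.
#' @export
plsda_bootstrap <- function(X, y, B = 1000, ncomp = NULL, scale = TRUE,
                            seed = 1) {
  if (B < 100) stop("use at least 100 bootstrap replicates", call. = FALSE)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  local_seed(seed, {
    if (is.null(ncomp)) {
      ncomp <- select_ncomp_cv(X, y, 5, 5, scale)
    }
    acc <- NULL
    n_used <- 0L; n_skipped <- 0L
    for (b in seq_len(B)) {
      idx <- unlist(lapply(levels(y), function(cl) {
        i <- which(y == cl)
        sample(i, length(i), replace = TRUE)
      }), use.names = FALSE)
      oob <- setdiff(seq_along(y), unique(idx))
      if (length(oob) == 0L || nlevels(droplevels(y[oob])) < nlevels(y)) {
        n_skipped <- n_skipped + 1L
        next
      }
      m <- pls_fit(X[idx, , drop = FALSE], y[idx], ncomp, scale)
      pr <- predict(m, X[oob, , drop = FALSE])
      st <- plsda_stats(y[oob], pr$y_pred, pr$class)
      acc <- if (is.null(acc)) st else acc + st
      n_used <- n_used + 1L
    }
    if (n_used == 0L) stop("all bootstrap replicates skipped", call. = FALSE)
    structure(
      list(stats = acc / n_used, mode = "bootstrap",
           n_components_chosen = ncomp, classes = levels(y),
           n_used = n_used, n_skipped = n_skipped),
      class = "plsda_report"
    )
  })
}

#' @export
print.plsda_report <- function(x, ...) {
  cat("<plsda_report> mode:", x$mode, "| components:",
      paste(x$n_components_chosen, collapse = ","), "\n")
  print(round(x$stats, 3))
  invisible(x)
}
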