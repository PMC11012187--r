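#' Fit the 8-term factorial model to one response
#'
#' Ordinary least squares of a single response on the fixed basis
#' `(1, x1, x2, x3, x1:x2, x1:x3, x2:x3, x1:x2:x3)` in coded units.
#' Coefficient p-values come from two-sided t tests on the residual
#' degrees of freedom (`n - 8`); the model p-value from the overall F
#' test against the intercept-only model.
#'
#' With 11 runs (2^3 corners + 3 center replicates) the fit has 3
#' residual degrees of freedom; the residual variance is pooled over all
#' runs, not estimated from center replicates alone. A design with
#' exactly 8 runs is fitted in coefficient-only mode (`inference =
#' FALSE`): the saturated model leaves no residual degrees of freedom.
#'
#' A numerically exact fit (zero residuals, e.g. responses generated
#' noiselessly from a coefficient table) is detected and reported with
#' `r2 = r2_adj = 1`; coefficient p-values are then 0 for non-zero
#' coefficients and 1 for zero ones, since the data are consistent with
#' the model to machine precision.
#'
#' @param design A three-factor `design_table`.
#' @param response Numeric response vector aligned with the design rows.
#' @param response_name Label carried into reports.
#' @return An object of class `ffd_fit`: a list with `response_name`,
#'   `coefficients` (data frame term/value/std_error/t_stat/p_value/tier),
#'   `r2`, `r2_adj`, `f_stat`, `p_model`, `df_resid`, `fitted`,
#'   `residuals`, `inference`.
#' @examples
#' d <- build_full_factorial(mae_factors(), 3)
#' beta <- c(0.4, 0.3, 0, 0, 0, 0, 0, 0)
#' y <- drop(ffd_model_matrix(d) %*% beta)
#' fit <- fit_ffd(d, y)
#' coef(fit)[["b1"]]  # 0.3
#' @export
fit_ffd <- function(design, response, response_name = "response") {
  X <- ffd_model_matrix(design)
  y <- as.numeric(response)
  if (length(y) != nrow(X)) {
    stop("response length (", length(y), ") does not match design rows (",
         nrow(X), ")", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("response contains non-finite values", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: the 8-term model is not estimable", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (n < p) stop("need at least 8 runs to fit the 8-term model", call. = FALSE)
  df_resid <- n - p
  inference <- df_resid >= 1L

  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted

  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  # exact-fit detection relative to the response scale
  exact <- rss <= max(tss, sum(y^2), 1) * 1e-24

  r2 <- if (tss > 0) 1 - rss / tss else 1
  r2_adj <- if (inference && tss > 0) 1 - (1 - r2) * (n - 1) / df_resid else r2
  if (exact) { r2 <- 1; r2_adj <- 1 }

  if (inference) {
    sigma2 <- rss / df_resid
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
    if (exact) {
      tol <- max(abs(beta), 1) * 1e-10
      t_stat <- ifelse(abs(beta) > tol, Inf, 0)
      p_val <- ifelse(abs(beta) > tol, 0, 1)
      f_stat <- Inf
      p_model <- if (any(abs(beta[-1]) > tol)) 0 else 1
    } else {
      t_stat <- beta / se
      p_val <- 2 * stats::pt(abs(t_stat), df_resid, lower.tail = FALSE)
      f_stat <- ((tss - rss) / (p - 1)) / sigma2
      p_model <- stats::pf(f_stat, p - 1, df_resid, lower.tail = FALSE)
    }
  } else {
    se <- t_stat <- p_val <- rep(NA_real_, p)
    f_stat <- NA_real_; p_model <- NA_real_
  }

  tier <- rep("ns", p)
  tier[!is.na(p_val) & p_val < 0.05] <- "p05"
  tier[!is.na(p_val) & p_val < 0.01] <- "p01"

  structure(
    list(
      response_name = response_name,
      coefficients = data.frame(
        term = ffd_terms(), value = unname(beta), std_error = unname(se),
        t_stat = unname(t_stat), p_value = unname(p_val), tier = tier,
        stringsAsFactors = FALSE
      ),
      r2 = r2, r2_adj = r2_adj, f_stat = f_stat, p_model = p_model,
      df_resid = df_resid, fitted = fitted, residuals = resid,
      inference = inference
    ),
    class = "ffd_fit"
  )
}

#' @export
coef.ffd_fit <- function(object, ...) {
  stats::setNames(object$coefficients$value, object$coefficients$term)
}

#' @export
print.ffd_fit <- function(x, ...) {
  cat(sprintf("<ffd_fit> %s: R2adj = %.3f, model p = %.3g (df_resid = %d)\n",
              x$response_name, x$r2_adj, x$p_model, x$df_resid))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit the factorial model to every response column
#'
#' @param design A three-factor `design_table`.
#' @param responses Data frame or matrix of responses, one column per
#'   lipid subclass, rows aligned with the design.
#' @return Named list of `ffd_fit` objects.
#' @export
fit_ffd_all <- function(design, responses) {
  responses <- as.data.frame(responses)
  stats::setNames(
    lapply(names(responses), function(nm) fit_ffd(design, responses[[nm]], nm)),
    names(responses)
  )
}

#' Scale each response column to the [0, 1] range
#'
#' The pretreatment used before clustering and model fitting:
#' `x -> (x - min) / (max - min)` per column. Constant columns are
#' rejected because the scaling is undefined for them.
#'
#' @param responses Data frame or matrix of numeric columns.
#' @return Data frame of the same shape with every column spanning
#'   exactly [0, 1]; attribute `"scaled"` set to `TRUE` and the original
#'   ranges kept in attribute `"ranges"`.
#' @examples
#' range_scale_responses(data.frame(a = c(2, 4, 6)))  # 0, 0.5, 1
#' @export
range_scale_responses <- function(responses) {
  df <- as.data.frame(responses)
  rng <- lapply(df, range)
  const <- vapply(rng, function(r) r[1] == r[2], logical(1))
  if (any(const)) {
    stop("cannot range-scale constant column(s): ",
         paste(names(df)[const], collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(lapply(df, function(x) (x - min(x)) / (max(x) - min(x))))
  names(out) <- names(df)
  rownames(out) <- rownames(df)
  attr(out, "scaled") <- TRUE
  attr(out, "ranges") <- rng
  out
}

#' Summarize significant factorial coefficients across responses
#'
#' Builds the study's significance table: responses whose overall model
#' p-value passes the threshold become columns; rows are the 8 model
#' terms; entries are coefficient values, blanked (`NA`) when the
#' coefficient is not significant at the 0.05 level. Responses failing
#' the model test are listed separately — they show no significant
#' dependence on the extraction conditions.
#'
#' @param fits List of `ffd_fit` objects sharing a design.
#' @param keep_if_model_p Retention threshold on the overall model
#'   p-value (default 0.05).
#' @return An object of class `significance_table`: list with `wide`
#'   (data frame term x retained response, ns blanked), `tiers` (same
#'   shape, entries in ns/p05/p01), `long` (response, term, value,
#'   p_value, tier for every retained response), `retained`,
#'   `not_significant`, `model_stats` (r2_adj and p_model per response).
#' @export
significance_table <- function(fits, keep_if_model_p = 0.05) {
  if (length(fits) == 0L) stop("empty fit list", call. = FALSE)
  lapply(fits, function(f) stopifnot(inherits(f, "ffd_fit")))
  nms <- vapply(fits, `[[`, character(1), "response_name")
  p_model <- vapply(fits, `[[`, numeric(1), "p_model")
  keep <- !is.na(p_model) & p_model <= keep_if_model_p

  terms <- ffd_terms()
  wide <- as.data.frame(matrix(NA_real_, length(terms), sum(keep),
                               dimnames = list(terms, nms[keep])))
  tiers <- as.data.frame(matrix("ns", length(terms), sum(keep),
                                dimnames = list(terms, nms[keep])),
                         stringsAsFactors = FALSE)
  long <- NULL
  for (nm in nms[keep]) {
    cf <- fits[[which(nms == nm)]]$coefficients
    sig <- cf$tier != "ns"
    wide[cf$term[sig], nm] <- cf$value[sig]
    tiers[cf$term, nm] <- cf$tier
    long <- rbind(long, data.frame(response = nm, term = cf$term,
                                   value = cf$value, p_value = cf$p_value,
                                   tier = cf$tier, stringsAsFactors = FALSE))
  }
  structure(
    list(
      wide = wide, tiers = tiers, long = long,
      retained = nms[keep], not_significant = nms[!keep],
      model_stats = data.frame(
        response = nms,
        r2_adj = vapply(fits, `[[`, numeric(1), "r2_adj"),
        p_model = p_model, retained = keep,
        stringsAsFactors = FALSE, row.names = NULL
      )
    ),
    class = "significance_table"
  )
}

#' @export
print.significance_table <- function(x, ...) {
  cat("<significance_table>", length(x$retained), "response(s) retained")
  if (length(x$not_significant)) {
    cat("; no significant dependence:", paste(x$not_significant, collapse = ", "))
  }
  cat("\n")
  w <- x$wide
  w[] <- lapply(w, function(col) ifelse(is.na(col), "", sprintf("%.3f", col)))
  print(w)
  invisible(x)
}

#' Export a significance table as delimited text
#'
#' Writes the wide (ns blanked) layout and, alongside it, a
#' machine-readable long table `<path>_long.tsv` with unrounded values.
#'
#' @param x A `significance_table`.
#' @param path Path of the wide-format file.
#' @return Invisibly, `path`.
#' @export
write_significance_table <- function(x, path) {
  stopifnot(inherits(x, "significance_table"))
  w <- cbind(term = rownames(x$wide), x$wide)
  utils::write.table(w, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  long_path <- sub("(\\.[a-zA-Z0-9]+)?$", "_long.tsv", path)
  utils::write.table(x$long, long_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
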