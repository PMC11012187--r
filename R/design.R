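#' Define an extraction factor with its coded range
#'
#' A factor specification maps the coded levels -1/0/+1 of a two-level
#' design onto real experimental units. The defaults of
#' [mae_factors()] are the three MAE factors: solvent-to-solid ratio
#' (mL/g), extraction time (min) and temperature (degrees C).
#'
#' @param name Factor name (used as column prefix in design tables).
#' @param low Real value at coded -1.
#' @param high Real value at coded +1; must exceed `low`.
#' @param units Unit string, for reporting only.
#' @return An object of class `factor_spec` with fields `name`, `low`,
#'   `high`, `units`, `center` ((low+high)/2) and `half_range`
#'   ((high-low)/2).
#' @examples
#' factor_spec("temperature_C", 50, 80, "degC")
#' @export
factor_spec <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(low) || !is.finite(high)) {
    stop("factor '", name, "': low and high must be finite", call. = FALSE)
  }
  if (low >= high) {
    stop("factor '", name, "': low (", low, ") must be strictly below high (",
         high, ")", call. = FALSE)
  }
  structure(
    list(name = name, low = low, high = high, units = units,
         center = (low + high) / 2, half_range = (high - low) / 2),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: [%g, %g] %s (center %g)\n",
              x$name, x$low, x$high, x$units, x$center))
  invisible(x)
}

#' Default MAE factor set
#'
#' The three factors screened for microwave-assisted lipid extraction:
#' solvent-to-solid ratio 16--32 mL/g, time 6--30 min, temperature
#' 50--80 degrees C. The coded center (0,0,0) is 24 mL/g, 18 min, 65 degC.
#'
#' @return List of three `factor_spec` objects.
#' @export
mae_factors <- function() {
  list(
    factor_spec("solvent_to_solid", 16, 32, "mL/g"),
    factor_spec("time_min", 6, 30, "min"),
    factor_spec("temperature_C", 50, 80, "degC")
  )
}

#' Convert coded levels to real factor units (and back)
#'
#' The affine map `real = center + coded * half_range`. Coded values
#' outside [-1, 1] are extrapolated with a warning.
#'
#' @param coded Numeric vector of coded levels.
#' @param factor A `factor_spec`.
#' @return Numeric vector in real units.
#' @examples
#' coded_to_real(0, factor_spec("ratio", 16, 32))   # 24
#' coded_to_real(-1, factor_spec("temp", 50, 80))   # 50
#' @export
coded_to_real <- function(coded, factor) {
  stopifnot(inherits(factor, "factor_spec"), is.numeric(coded))
  if (any(abs(coded) > 1 + 1e-12)) {
    warning("coded value outside [-1, 1] for factor '", factor$name,
            "': extrapolating", call. = FALSE)
  }
  factor$center + coded * factor$half_range
}

#' @rdname coded_to_real
#' @param real Numeric vector in real units.
#' @export
real_to_coded <- function(real, factor) {
  stopifnot(inherits(factor, "factor_spec"), is.numeric(real))
  (real - factor$center) / factor$half_range
}

#' Build a two-level full factorial design with center replicates
#'
#' Enumerates all `2^k` corner combinations of coded -1/+1 levels in
#' standard Yates order (first factor varies fastest) and appends
#' `n_center` replicates of the coded center (0, ..., 0). For the three
#' MAE factors with three center replicates this is the 11-run design
#' used for extraction optimization.
#'
#' @param factors List of `factor_spec` objects (1 to 6 factors).
#' @param n_center Number of center-point replicates (>= 0).
#' @return A data frame of class `design_table` with columns `run_id`,
#'   one coded column `<name>_coded` and one real column `<name>` per
#'   factor, and `is_center`. The factor list is attached as attribute
#'   `"factors"`.
#' @examples
#' d <- build_full_factorial(mae_factors(), n_center = 3)
#' nrow(d)  # 11
#' @export
build_full_factorial <- function(factors, n_center = 0L) {
  stopifnot(is.list(factors), length(factors) >= 1L, length(factors) <= 6L)
  lapply(factors, function(f) stopifnot(inherits(f, "factor_spec")))
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate factor names: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  }
  if (n_center < 0) stop("n_center must be >= 0", call. = FALSE)
  k <- length(factors)

  # Yates standard order: first factor alternates fastest.
  corners <- expand.grid(rep(list(c(-1, 1)), k), KEEP.OUT.ATTRS = FALSE)
  names(corners) <- nm
  centers <- as.data.frame(matrix(0, nrow = n_center, ncol = k,
                                  dimnames = list(NULL, nm)))
  coded <- rbind(corners, centers)
  n <- nrow(coded)

  des <- data.frame(run_id = c(sprintf("run%02d", seq_len(2^k)),
                               if (n_center > 0) sprintf("center%d", seq_len(n_center))),
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    des[[paste0(nm[j], "_coded")]] <- coded[[j]]
    des[[nm[j]]] <- coded_to_real(coded[[j]], factors[[j]])
  }
  des$is_center <- c(rep(FALSE, 2^k), rep(TRUE, n_center))
  attr(des, "factors") <- factors
  class(des) <- c("design_table", "data.frame")
  des
}

#' Coded-level matrix of a design
#'
#' @param design A `design_table`.
#' @return Numeric matrix (runs x factors) of coded levels.
#' @export
design_coded <- function(design) {
  stopifnot(inherits(design, "design_table"))
  nm <- design_factor_names(design)
  as.matrix(design[paste0(nm, "_coded")])
}

#' @rdname design_coded
#' @export
design_factor_names <- function(design) {
  vapply(attr(design, "factors"), `[[`, character(1), "name")
}

#' Reorder design rows to match an external run listing
#'
#' Printed experimental matrices often list the 8 factorial corners in a
#' non-standard order. This utility permutes a design's rows to match a
#' target table of coded levels (one row per run), matching corners by
#' their coded triples; center replicates keep their relative order.
#'
#' @param design A `design_table`.
#' @param coded_target Matrix or data frame of coded levels, one row per
#'   design row, columns in factor order.
#' @return The reordered `design_table`.
#' @export
reorder_to_match <- function(design, coded_target) {
  stopifnot(inherits(design, "design_table"))
  tgt <- as.matrix(coded_target)
  cur <- design_coded(design)
  if (!identical(dim(tgt), dim(cur))) {
    stop("coded_target must have the same dimensions as the design", call. = FALSE)
  }
  key <- function(m) apply(m, 1, paste, collapse = "/")
  ck <- key(cur); tk <- key(tgt)
  if (!setequal(unique(ck), unique(tk))) {
    stop("coded_target rows are not a permutation of the design rows", call. = FALSE)
  }
  perm <- integer(nrow(cur))
  used <- rep(FALSE, nrow(cur))
  for (i in seq_along(tk)) {
    j <- which(ck == tk[i] & !used)[1]
    if (is.na(j)) stop("coded_target repeats a run more often than the design",
                       call. = FALSE)
    perm[i] <- j
    used[j] <- TRUE
  }
  out <- design[perm, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "factors") <- attr(design, "factors")
  class(out) <- class(design)
  out
}

#' Model matrix of the 8-term three-factor interaction model
#'
#' Expands a three-factor design into the fixed column basis
#' `(1, x1, x2, x3, x1:x2, x1:x3, x2:x3, x1:x2:x3)` on coded levels.
#' Interactions are elementwise products, so over the 8 factorial
#' corners all non-intercept columns are mutually orthogonal with
#' integer entries.
#'
#' @param design A `design_table` with exactly 3 factors, or a numeric
#'   matrix of coded levels with 3 columns.
#' @return Numeric matrix (runs x 8) with column names
#'   `b0, b1, b2, b3, b12, b13, b23, b123`.
#' @export
ffd_model_matrix <- function(design) {
  x <- if (inherits(design, "design_table")) design_coded(design) else as.matrix(design)
  if (ncol(x) != 3L) {
    stop("the 8-term interaction model requires exactly 3 factors, got ",
         ncol(x), call. = FALSE)
  }
  out <- cbind(1, x[, 1], x[, 2], x[, 3],
               x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3],
               x[, 1] * x[, 2] * x[, 3])
  colnames(out) <- ffd_terms()
  rownames(out) <- NULL
  out
}

#' Names of the 8 model terms, in basis order
#' @return Character vector `c("b0","b1","b2","b3","b12","b13","b23","b123")`.
#' @export
ffd_terms <- function() c("b0", "b1", "b2", "b3", "b12", "b13", "b23", "b123")

#' Read or write a design table as delimited text
#'
#' The file keeps one row per run with `run_id`, coded columns, real
#' columns and `is_center`. Factor ranges are recovered on read from the
#' coded/real column pair of each factor, so a written design round-trips.
#'
#' @param design A `design_table`.
#' @param path File path.
#' @param units Optional character vector of units for `read_design`.
#' @return `read_design` returns a `design_table`; `write_design`
#'   invisibly returns `path`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_table"))
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, units = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  coded_cols <- grep("_coded$", names(df), value = TRUE)
  nm <- sub("_coded$", "", coded_cols)
  if (length(nm) == 0L || !all(nm %in% names(df))) {
    stop("file does not look like a design table (need <name>_coded/<name> pairs)",
         call. = FALSE)
  }
  factors <- vector("list", length(nm))
  for (j in seq_along(nm)) {
    cc <- df[[coded_cols[j]]]
    rr <- df[[nm[j]]]
    # solve the affine map from two distinct coded levels
    lv <- !duplicated(cc)
    if (sum(lv) < 2L) stop("factor '", nm[j], "' has a single coded level",
                           call. = FALSE)
    i1 <- which(lv)[1]; i2 <- which(lv)[2]
    slope <- (rr[i2] - rr[i1]) / (cc[i2] - cc[i1])
    center <- rr[i1] - slope * cc[i1]
    factors[[j]] <- factor_spec(nm[j], center - slope, center + slope,
                                units = if (is.null(units)) "" else units[j])
  }
  attr(df, "factors") <- factors
  class(df) <- c("design_table", "data.frame")
  df
}
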