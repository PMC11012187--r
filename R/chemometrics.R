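#' Principal component analysis with a fixed sign convention
#'
#' Thin wrapper around [stats::prcomp()] that records the pretreatment,
#' reports explained variance in percent, and resolves the sign
#' indeterminacy of each component deterministically: the
#' largest-magnitude loading of every component is made positive.
#'
#' @param data Numeric matrix or data frame, samples in rows.
#' @param center Mean-center columns (default TRUE).
#' @param scale Divide columns by their standard deviation (autoscaling;
#'   default TRUE — subclass abundance sums span orders of magnitude).
#' @param ncomp Number of components to keep (default: all,
#'   `min(n - center, p)`).
#' @return An object of class `pca_model`: list with `loadings`
#'   (variables x components), `scores` (samples x components),
#'   `explained_variance_pct`, `center`, `scale`, `sdev`.
#' @export
pca <- function(data, center = TRUE, scale = TRUE, ncomp = NULL) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("data must be numeric", call. = FALSE)
  if (anyNA(x)) stop("data contains missing values", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(x) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("cannot autoscale constant column(s): ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  pc <- stats::prcomp(x, center = center, scale. = scale)
  total_var <- sum(pc$sdev^2)
  k <- ncomp %||% length(pc$sdev)
  k <- min(k, length(pc$sdev))

  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic orientation: dominant loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      loadings = loadings, scores = scores,
      explained_variance_pct = 100 * pc$sdev[seq_len(k)]^2 / total_var,
      center = if (isTRUE(center)) pc$center else FALSE,
      scale = if (isTRUE(scale)) pc$scale else FALSE,
      sdev = pc$sdev[seq_len(k)]
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", nrow(x$scores), "samples,", nrow(x$loadings),
      "variables,", ncol(x$scores), "components\n")
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Average-linkage hierarchical clustering on squared Euclidean distances
#'
#' UPGMA clustering of samples using the squared Euclidean distance, the
#' configuration used to group solvent-screening extractions after
#' range scaling to [0, 1]. Average linkage applied to squared distances
#' makes every merge height the mean pairwise squared Euclidean distance
#' between the two groups joined.
#'
#' @param data Numeric matrix or data frame, samples in rows (typically
#'   range-scaled, see [range_scale_responses()]).
#' @return An object of class `hca_tree`: list with `merge` (n-1 x 2, in
#'   [stats::hclust()] convention: negative = leaf index), `height`
#'   (squared-Euclidean linkage distances), `labels`, `order`, and the
#'   underlying `hclust` object as `$hclust`.
#' @export
hca_average_linkage <- function(data) {
  x <- as.matrix(data)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("data contains non-finite entries", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  d2 <- stats::dist(x)^2
  hc <- stats::hclust(d2, method = "average")
  structure(
    list(merge = hc$merge, height = hc$height,
         labels = hc$labels %||% as.character(seq_len(nrow(x))),
         order = hc$order, hclust = hc),
    class = "hca_tree"
  )
}

#' @export
print.hca_tree <- function(x, ...) {
  cat("<hca_tree>", length(x$labels), "leaves,",
      length(x$height), "merges; heights",
      sprintf("%.3g .. %.3g", min(x$height), max(x$height)), "\n")
  invisible(x)
}

#' Cut a cluster tree at a height
#'
#' Clusters are the connected groups formed by applying every merge with
#' height strictly below the cut; a cut placed exactly at a merge height
#' leaves that merge unapplied.
#'
#' @param tree An `hca_tree`.
#' @param height Non-negative cut height (squared-Euclidean scale).
#' @return Integer vector of cluster labels (1-based, numbered in leaf
#'   order of first appearance), named by leaf labels.
#' @export
cut_tree <- function(tree, height) {
  stopifnot(inherits(tree, "hca_tree"), is.numeric(height), height >= 0)
  n <- length(tree$labels)
  # union-find over merges below the cut
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_rep <- integer(n - 1L)  # representative leaf of each internal node
  for (m in seq_len(n - 1L)) {
    a <- tree$merge[m, 1]; b <- tree$merge[m, 2]
    ra <- if (a < 0) -a else node_rep[a]
    rb <- if (b < 0) -b else node_rep[b]
    if (tree$height[m] < height) {
      parent[find(ra)] <- find(rb)
    }
    node_rep[m] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- match(roots, unique(roots))
  stats::setNames(cl, tree$labels)
}

#' Export a cluster tree in Newick format
#'
#' Branch lengths follow the ultrametric interpretation of the linkage
#' heights (each node sits at half its merge height, as in
#' [ape::as.phylo.hclust()]).
#'
#' @param tree An `hca_tree`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
hca_to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hca_tree"))
  phy <- ape::as.phylo(tree$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
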