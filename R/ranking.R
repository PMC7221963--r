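# Activity ranking: standard scores, the relative antioxidant capacity
# index (RACI), correlation-distance average-linkage clustering and heatmap
# matrix preparation.

#' Standard scores (z-scores)
#'
#' `(x - mean) / sd` using the sample standard deviation (n - 1 denominator);
#' the result has mean 0 and SD 1.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return standardized vector.
#' @export
standard_scores <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Construct an activity matrix
#'
#' Samples by metrics, with a declared orientation per metric: ID50-style
#' columns are `"lower-better"`, ORAC-style columns `"higher-better"`.
#'
#' @param values numeric matrix (samples x metrics) with dimnames.
#' @param orientation character vector per column, `"lower-better"` or
#'   `"higher-better"`.
#' @return object of class `activity_matrix`.
#' @export
activity_matrix <- function(values, orientation) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2, all(is.finite(values)),
            length(orientation) == ncol(values))
  orientation <- vapply(orientation, match.arg, character(1),
                        choices = c("lower-better", "higher-better"))
  structure(list(values = values, orientation = unname(orientation)),
            class = "activity_matrix")
}

#' Relative antioxidant capacity index
#'
#' Standard scores are computed per metric column; columns where lower raw
#' values mean more activity (ID50) are negated after scoring, so larger
#' oriented scores always mean more antioxidant. The RACI is the per-sample
#' mean of the oriented scores, and sums to zero over samples.
#'
#' @param m an [activity_matrix].
#' @return list of class `raci_result` with `z` (oriented samples x metrics
#'   standard scores) and `raci` (named per-sample index).
#' @export
raci <- function(m) {
  stopifnot(inherits(m, "activity_matrix"))
  z <- apply(m$values, 2, standard_scores)
  flip <- m$orientation == "lower-better"
  z[, flip] <- -z[, flip, drop = FALSE]
  dimnames(z) <- dimnames(m$values)
  structure(list(z = z, raci = rowMeans(z)), class = "raci_result")
}

#' Pearson correlation distance between matrix rows
#'
#' `D(i, j) = 1 - r(row_i, row_j)`: 0 for identical profiles, 2 for exactly
#' anti-correlated ones.
#'
#' @param m numeric matrix; every row must have positive SD.
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 1, stats::sd)
  if (any(!is.finite(sds) | sds == 0)) {
    stop("constant rows have no defined correlation distance")
  }
  d <- 1 - stats::cor(t(m))
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates with the unweighted mean of all between-cluster pairwise
#' distances as merge height (UPGMA). Merge heights are non-decreasing and
#' there are exactly n - 1 merges for n leaves.
#'
#' @param D symmetric distance matrix (or `dist`).
#' @return an object of class `hclust` (merge matrix, heights, leaf order).
#' @export
average_linkage <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12)) {
      stop("distance matrix must be square and symmetric")
    }
    D <- stats::as.dist(D)
  }
  stats::hclust(D, method = "average")
}

#' Serialize a dendrogram to newick
#'
#' Branch lengths are merge-height differences (ultrametric tree).
#'
#' @param hc an `hclust` object, e.g. from [average_linkage()].
#' @param path optional file to write to.
#' @return newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Row-scaled, dendrogram-ordered heatmap matrix
#'
#' Rows are centered and scaled to unit variance, then both axes are ordered
#' by average-linkage dendrograms on correlation distance (computed on the
#' scaled matrix), the pre-processing used for the activity heatmap.
#'
#' @param values numeric matrix with >= 2 non-constant rows and columns.
#' @return list with `scaled` (reordered scaled matrix), `row_order`,
#'   `col_order` (leaf orders), `row_hclust`, `col_hclust`.
#' @export
heatmap_matrix <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2, ncol(values) >= 2)
  scaled <- t(apply(values, 1, standard_scores))
  dimnames(scaled) <- dimnames(values)
  row_hc <- average_linkage(correlation_distance(scaled))
  col_hc <- average_linkage(correlation_distance(t(scaled)))
  list(scaled = scaled[row_hc$order, col_hc$order, drop = FALSE],
       row_order = row_hc$order, col_order = col_hc$order,
       row_hclust = row_hc, col_hclust = col_hc)
}
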