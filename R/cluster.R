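#' Pairwise distances between binary protein fingerprints
#'
#' Distances on the 0/1 incidence rows of a protein-region feature matrix.
#' Cosine distance is `1 - a.b / (|a||b|)`, Jaccard is
#' `1 - |intersection| / |union|`, Dice is `1 - 2|intersection| / (|a|+|b|)`.
#' An isolate with no features at all gets distance 1 to every other isolate
#' (including another empty one) and 0 to itself.
#'
#' @param matrix a [bin_features()] feature matrix with >= 2 isolates.
#' @param metric one of `"cosine"` (default), `"jaccard"`, `"dice"`.
#' @return A symmetric numeric matrix with isolate ids as dimnames and a
#'   `"metric"` attribute.
#' @export
distance_matrix <- function(matrix, metric = c("cosine", "jaccard", "dice")) {
  stopifnot(inherits(matrix, "feature_matrix"))
  metric <- match.arg(metric)
  a <- matrix$incidence
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 isolates to compute distances")
  storage.mode(a) <- "double"
  inter <- tcrossprod(a)          # |a_i intersect a_j|
  sizes <- diag(inter)
  d <- switch(metric,
    cosine = {
      denom <- sqrt(sizes %o% sizes)
      s <- ifelse(denom > 0, inter / denom, 0)
      1 - s
    },
    jaccard = {
      uni <- outer(sizes, sizes, `+`) - inter
      s <- ifelse(uni > 0, inter / uni, 0)
      1 - s
    },
    dice = {
      denom <- outer(sizes, sizes, `+`)
      s <- ifelse(denom > 0, 2 * inter / denom, 0)
      1 - s
    })
  empty <- sizes == 0
  if (any(empty)) {
    d[empty, ] <- 1
    d[, empty] <- 1
  }
  diag(d) <- 0
  dimnames(d) <- list(matrix$isolate_ids, matrix$isolate_ids)
  attr(d, "metric") <- metric
  d
}

#' Build the pseudo-phylogenetic dendrogram
#'
#' Standard agglomerative hierarchical clustering of the isolate distance
#' matrix via [stats::hclust()]; `"ward"` maps to Ward's criterion on squared
#' distances (`"ward.D2"`). The result is deterministic for a given input
#' (ties are resolved by `hclust`'s fixed scan order over node indices).
#'
#' @param dist symmetric distance matrix (zero diagonal, no `NaN`), e.g. from
#'   [distance_matrix()], or a [stats::dist] object.
#' @param linkage one of `"average"` (UPGMA, default), `"ward"`,
#'   `"complete"`.
#' @return An `hclust` object with the distance metric recorded in
#'   `dist.method`.
#' @export
build_dendrogram <- function(dist, linkage = c("average", "ward", "complete")) {
  linkage <- match.arg(linkage)
  if (is.matrix(dist)) {
    if (anyNA(dist)) stop("distance matrix contains NA/NaN")
    if (!isSymmetric(unname(dist)) || any(diag(dist) != 0))
      stop("distance matrix must be symmetric with zero diagonal")
    metric <- attr(dist, "metric")
    dist <- stats::as.dist(dist)
    if (!is.null(metric)) attr(dist, "method") <- metric
  } else if (inherits(dist, "dist")) {
    if (anyNA(dist)) stop("distance matrix contains NA/NaN")
  } else stop("'dist' must be a matrix or a dist object")
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(dist, method = method)
}

#' Cut the dendrogram into pseudo-phylogenetic groups
#'
#' `mode = "height"` keeps together every connected subtree whose internal
#' merges all lie at or below `value`; `mode = "k"` removes the `k - 1`
#' highest merges to obtain exactly `k` groups. The cut itself is a manual,
#' user-supplied choice: picking a height that approximates species-level
#' branching is left to the analyst.
#'
#' @param dendrogram an `hclust` from [build_dendrogram()].
#' @param mode `"height"` or `"k"`.
#' @param value cut height (>= 0) or requested group count in
#'   `1..n_leaves`.
#' @return An object of class `"group_assignment"`: a list with `group_of`
#'   (named integer vector mapping isolate_id to group index), `n_groups`,
#'   `cut_mode` and `cut_value`.
#' @export
cut_dendrogram <- function(dendrogram, mode = c("height", "k"), value) {
  stopifnot(inherits(dendrogram, "hclust"))
  mode <- match.arg(mode)
  n <- length(dendrogram$labels)
  if (mode == "k") {
    value <- as.integer(value)
    if (value < 1L || value > n)
      stop("k must be between 1 and the number of isolates (", n, ")")
    groups <- stats::cutree(dendrogram, k = value)
  } else {
    if (value < 0) stop("cut height must be >= 0")
    groups <- stats::cutree(dendrogram, h = value)
  }
  group_assignment(groups, cut_mode = mode, cut_value = value)
}

#' Construct a group assignment
#'
#' Wraps a named isolate-to-group mapping (for instance a [stats::cutree()]
#' result, or a planted ground-truth partition) with its provenance.
#'
#' @param group_of named integer vector, values in `1..n_groups`, every group
#'   nonempty.
#' @param cut_mode,cut_value how the partition was obtained.
#' @return A `"group_assignment"` object.
#' @export
group_assignment <- function(group_of, cut_mode = "manual", cut_value = NA) {
  g <- as.integer(group_of)
  names(g) <- names(group_of)
  if (is.null(names(g)) || any(!nzchar(names(g))))
    stop("'group_of' must be named by isolate_id")
  ng <- max(g)
  if (!setequal(unique(g), seq_len(ng)))
    stop("group indices must cover 1..n_groups with every group nonempty")
  structure(list(group_of = g, n_groups = ng, cut_mode = cut_mode,
                 cut_value = cut_value),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %d isolates in %d groups (cut: %s = %s)\n",
              length(x$group_of), x$n_groups, x$cut_mode,
              format(x$cut_value)))
  sizes <- table(x$group_of)
  cat(sprintf("  group sizes: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Write a group assignment as a delimited table
#'
#' Tab-separated columns `isolate_id` and `group`.
#'
#' @param assignment a [cut_dendrogram()] result.
#' @param path output path.
#' @export
write_group_table <- function(assignment, path) {
  stopifnot(inherits(assignment, "group_assignment"))
  utils::write.table(
    data.frame(isolate_id = names(assignment$group_of),
               group = unname(assignment$group_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
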