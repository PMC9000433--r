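#' Greedy isolate prioritization within one pseudo-phylogenetic group
#'
#' The core selection rule: among the group's members, pick the isolate
#' carrying the most small-molecule mass features, remove that isolate and
#' its features from the group, and iterate until the selected isolates
#' jointly carry at least `threshold` of the group's distinct features.
#' Because features already captured are removed before each iteration, every
#' pick maximizes the count of still-uncovered features; ties are broken by
#' the lexicographically smallest isolate id, members contributing no new
#' feature are never selected, and the stop comparison is inclusive
#' (`captured / |U| >= threshold`), so a threshold of 1 terminates exactly at
#' full coverage. Features accumulate isolate-by-isolate, not one at a time,
#' so the final captured fraction can overshoot the threshold.
#'
#' @param members nonempty character vector of isolate ids.
#' @param np_matrix the collection-wide small-molecule [bin_features()]
#'   matrix.
#' @param threshold target captured fraction in (0, 1].
#' @param group_id integer group identifier carried into the result.
#' @param min_select minimum number of isolates to select even when the
#'   group has no small-molecule features at all (0 or 1); with 1, the
#'   lexicographically smallest member represents the group.
#' @return An object of class `"group_selection"`: list with `group_id`,
#'   `universe_size` (distinct features across members), ordered `selected`,
#'   `cumulative_captured` (running distinct-feature counts),
#'   `captured_fraction` (1 by convention for an empty universe),
#'   `captured_features` (collection-wide feature ids) and `n_members`.
#' @examples
#' # members A{f1,f2,f3}, B{f3,f4}, C{f5}: A first (3 features), then the
#' # B/C tie at one new feature each resolves to B; 4/5 = 0.8 >= 0.75.
#' @export
prioritize_group <- function(members, np_matrix, threshold, group_id = 1L,
                             min_select = 0L) {
  stopifnot(inherits(np_matrix, "feature_matrix"))
  members <- as.character(members)
  if (!length(members)) stop("empty group: no members")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a fraction in (0, 1]")
  unknown <- setdiff(members, np_matrix$isolate_ids)
  if (length(unknown))
    stop("unknown isolate(s): ", paste(unknown, collapse = ", "))

  inc <- np_matrix$incidence[match(members, np_matrix$isolate_ids), ,
                             drop = FALSE]
  rownames(inc) <- members
  universe <- which(colSums(inc) > 0)
  u_size <- length(universe)

  selected <- character(0)
  cumulative <- integer(0)
  captured <- integer(0)

  if (u_size > 0L) {
    inc <- inc[, universe, drop = FALSE]  # columns renamed to universe ids
    remaining <- sort(members)            # lexicographic tie-break order
    uncovered <- rep(TRUE, u_size)
    repeat {
      if (length(captured) / u_size >= threshold) break
      gains <- vapply(remaining,
                      function(m) sum(inc[m, ] == 1L & uncovered), 1L)
      if (!length(gains) || max(gains) == 0L) break  # unreachable by design
      pick <- remaining[which.max(gains)]  # first of ties = smallest id
      new_feats <- which(inc[pick, ] == 1L & uncovered)
      uncovered[new_feats] <- FALSE
      captured <- c(captured, universe[new_feats])
      selected <- c(selected, pick)
      cumulative <- c(cumulative, length(captured))
      remaining <- setdiff(remaining, pick)
    }
  } else if (min_select > 0L) {
    selected <- sort(members)[1L]
    cumulative <- 0L
  }

  structure(list(
    group_id = as.integer(group_id),
    universe_size = u_size,
    selected = selected,
    cumulative_captured = cumulative,
    captured_fraction = if (u_size > 0L) length(captured) / u_size else 1,
    captured_features = sort(as.integer(captured)),
    n_members = length(members)),
    class = "group_selection")
}

#' @export
print.group_selection <- function(x, ...) {
  cat(sprintf("<group_selection> group %d: %d/%d isolates selected, %d/%d features captured (%.1f%%)\n",
              x$group_id, length(x$selected), x$n_members,
              length(x$captured_features), x$universe_size,
              100 * x$captured_fraction))
  if (length(x$selected))
    cat("  order: ", paste(x$selected, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Prioritize every group of a collection
#'
#' Applies [prioritize_group()] to each group of the assignment in ascending
#' group id and aggregates the collection-level totals. The selection is
#' strictly per-group: no joint optimization across groups is attempted.
#'
#' @param assignment a [cut_dendrogram()] / [group_assignment()] partition
#'   whose isolates all appear in `np_matrix`.
#' @param np_matrix the collection-wide small-molecule [bin_features()]
#'   matrix.
#' @param threshold target captured fraction in (0, 1] (the study-scale runs
#'   here use 0.75).
#' @param min_select passed to [prioritize_group()].
#' @return An object of class `"library_selection"`: list with `per_group`
#'   (one `group_selection` per group), `n_isolates_total`,
#'   `n_selected_total`, `n_features_total` (distinct small-molecule
#'   features over the assignment's isolates), `n_features_captured` (size of
#'   the union of captured sets) and `threshold`.
#' @export
prioritize_all <- function(assignment, np_matrix, threshold,
                           min_select = 0L) {
  stopifnot(inherits(assignment, "group_assignment"),
            inherits(np_matrix, "feature_matrix"))
  isolates <- names(assignment$group_of)
  unknown <- setdiff(isolates, np_matrix$isolate_ids)
  if (length(unknown))
    stop("unknown isolate(s): ", paste(unknown, collapse = ", "))

  per_group <- lapply(seq_len(assignment$n_groups), function(g)
    prioritize_group(isolates[assignment$group_of == g], np_matrix,
                     threshold, group_id = g, min_select = min_select))

  inc <- np_matrix$incidence[match(isolates, np_matrix$isolate_ids), ,
                             drop = FALSE]
  captured_union <- sort(unique(unlist(lapply(per_group,
                                              `[[`, "captured_features"))))
  structure(list(
    per_group = per_group,
    n_isolates_total = length(isolates),
    n_selected_total = sum(vapply(per_group,
                                  function(g) length(g$selected), 1L)),
    n_features_total = sum(colSums(inc) > 0),
    n_features_captured = length(captured_union),
    captured_features = captured_union,
    threshold = threshold),
    class = "library_selection")
}

#' @export
print.library_selection <- function(x, ...) {
  cat(sprintf("<library_selection> threshold %.2f\n", x$threshold))
  cat(sprintf("  %d of %d isolates selected across %d groups (%d%% reduction)\n",
              x$n_selected_total, x$n_isolates_total, length(x$per_group),
              percent_reduction(x$n_isolates_total, x$n_selected_total)))
  if (x$n_features_total > 0)
    cat(sprintf("  %d of %d distinct small-molecule features captured (%d%%)\n",
                x$n_features_captured, x$n_features_total,
                percent_captured(x$n_features_captured, x$n_features_total)))
  invisible(x)
}

#' @export
summary.library_selection <- function(object, ...) {
  df <- data.frame(
    group_id = vapply(object$per_group, `[[`, 1L, "group_id"),
    n_members = vapply(object$per_group, `[[`, 1L, "n_members"),
    n_selected = vapply(object$per_group,
                        function(g) length(g$selected), 1L),
    universe_size = vapply(object$per_group, `[[`, 1L, "universe_size"),
    captured_fraction = vapply(object$per_group, `[[`, 1,
                               "captured_fraction"))
  print(object)
  cat("\n")
  df
}

#' Percent reduction in library size
#'
#' `round(100 * (n_total - n_selected) / n_total)` with half-up rounding to
#' an integer percentage — e.g. keeping 189 of 819 isolates is a 77%
#' reduction.
#'
#' @param n_total positive integer, collection size.
#' @param n_selected selected count, `0 <= n_selected <= n_total`.
#' @return Integer percentage.
#' @export
percent_reduction <- function(n_total, n_selected) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_selected < 0 || n_selected > n_total)
    stop("n_selected must lie in [0, n_total]")
  as.integer(round_half_up(100 * (n_total - n_selected) / n_total))
}

#' Percent of the feature universe captured
#'
#' `round(100 * n_captured / n_features_total)` with half-up rounding — e.g.
#' 5455 of 6624 features is 82%.
#'
#' @param n_captured captured feature count.
#' @param n_features_total positive total feature count.
#' @return Integer percentage.
#' @export
percent_captured <- function(n_captured, n_features_total) {
  if (n_features_total <= 0) stop("n_features_total must be positive")
  if (n_captured < 0 || n_captured > n_features_total)
    stop("n_captured must lie in [0, n_features_total]")
  as.integer(round_half_up(100 * n_captured / n_features_total))
}

#' Compare three library selections
#'
#' Three-way comparison of selections made from the same collection (e.g.
#' two manual curators and the automated algorithm): all seven Venn regions
#' of the captured-feature sets, per-selection isolate counts, and pairwise
#' isolate-count differences.
#'
#' @param a,b,c each a list with elements `isolates` (character vector) and
#'   `captured` (vector of collection-wide feature ids); a
#'   `library_selection` is accepted and converted.
#' @param labels names for the three selections.
#' @return An object of class `"selection_comparison"`: list with `venn`
#'   (named counts `a_only`, `b_only`, `c_only`, `ab_only`, `ac_only`,
#'   `bc_only`, `abc`), `isolate_counts` and `isolate_diffs` (named pairwise
#'   differences).
#' @export
compare_selections <- function(a, b, c, labels = c("a", "b", "c")) {
  as_sel <- function(x) {
    if (inherits(x, "library_selection"))
      x <- list(isolates = unlist(lapply(x$per_group, `[[`, "selected"),
                                  use.names = FALSE),
                captured = x$captured_features)
    stopifnot(is.list(x), all(c("isolates", "captured") %in% names(x)))
    x
  }
  a <- as_sel(a); b <- as_sel(b); c <- as_sel(c)
  A <- unique(a$captured); B <- unique(b$captured); C <- unique(c$captured)
  venn <- c(
    a_only = length(setdiff(A, union(B, C))),
    b_only = length(setdiff(B, union(A, C))),
    c_only = length(setdiff(C, union(A, B))),
    ab_only = length(setdiff(intersect(A, B), C)),
    ac_only = length(setdiff(intersect(A, C), B)),
    bc_only = length(setdiff(intersect(B, C), A)),
    abc = length(intersect(A, intersect(B, C))))
  counts <- c(length(a$isolates), length(b$isolates), length(c$isolates))
  names(counts) <- labels
  pairs <- utils::combn(3L, 2L)
  diffs <- counts[pairs[1L, ]] - counts[pairs[2L, ]]
  names(diffs) <- paste0(labels[pairs[1L, ]], "-", labels[pairs[2L, ]])
  structure(list(venn = venn, isolate_counts = counts,
                 isolate_diffs = diffs),
            class = "selection_comparison")
}

#' @export
print.selection_comparison <- function(x, ...) {
  cat("<selection_comparison>\n  captured-feature Venn regions:\n")
  print(x$venn)
  cat("  isolate counts:\n")
  print(x$isolate_counts)
  cat("  pairwise isolate-count differences:\n")
  print(x$isolate_diffs)
  invisible(x)
}
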