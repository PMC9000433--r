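#' Build a metabolite association network for one group
#'
#' A MAN is a bipartite graph linking the isolates of one pseudo-phylogenetic
#' group to the small-molecule mass features they carry. Features are defined
#' collection-wide (one binning pass over all isolates) and restricted to the
#' group, so feature ids are comparable across groups; a feature enters the
#' network only through an edge, while an isolate with no small-molecule
#' features stays in the network with degree zero.
#'
#' @param group_members character vector of isolate ids in the group.
#' @param np_matrix the collection-wide small-molecule [bin_features()]
#'   matrix.
#' @param group_id integer group identifier.
#' @return An object of class `"man"`: list with `group_id`, `isolates`,
#'   `features` (integer feature ids), `edges` (data frame `isolate_id`,
#'   `feature_id`) and annotation slots `selected`/`captured` (`NULL` until
#'   [annotate_man()]).
#' @export
build_man <- function(group_members, np_matrix, group_id) {
  stopifnot(inherits(np_matrix, "feature_matrix"))
  group_members <- as.character(group_members)
  unknown <- setdiff(group_members, np_matrix$isolate_ids)
  if (length(unknown))
    stop("unknown isolate(s): ", paste(unknown, collapse = ", "))
  iso <- sort(group_members)
  sub <- np_matrix$incidence[match(iso, np_matrix$isolate_ids), ,
                             drop = FALSE]
  idx <- which(sub == 1L, arr.ind = TRUE)
  edges <- data.frame(isolate_id = iso[idx[, 1L]],
                      feature_id = as.integer(idx[, 2L]))
  edges <- edges[order(edges$isolate_id, edges$feature_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(group_id = as.integer(group_id), isolates = iso,
                 features = sort(unique(edges$feature_id)), edges = edges,
                 selected = NULL, captured = NULL),
            class = "man")
}

#' @export
print.man <- function(x, ...) {
  cat(sprintf("<man> group %d: %d isolates, %d features, %d edges%s\n",
              x$group_id, length(x$isolates), length(x$features),
              nrow(x$edges),
              if (is.null(x$selected)) "" else " (annotated)"))
  invisible(x)
}

#' Annotate a MAN with a selection outcome
#'
#' Flags each isolate node as selected or not, and each feature node as
#' captured (adjacent to at least one selected isolate) or missed — the
#' blue/grey isolate and green/orange feature classes used when such
#' networks are drawn.
#'
#' @param man a [build_man()] network.
#' @param selection a [prioritize_group()] result for the same group.
#' @return The annotated `"man"`.
#' @export
annotate_man <- function(man, selection) {
  stopifnot(inherits(man, "man"), inherits(selection, "group_selection"))
  if (!identical(man$group_id, selection$group_id))
    stop("group mismatch: MAN is group ", man$group_id,
         ", selection is group ", selection$group_id)
  sel <- man$isolates %in% selection$selected
  names(sel) <- man$isolates
  cap_ids <- unique(man$edges$feature_id[man$edges$isolate_id %in%
                                           selection$selected])
  cap <- man$features %in% cap_ids
  names(cap) <- as.character(man$features)
  man$selected <- sel
  man$captured <- cap
  man
}
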