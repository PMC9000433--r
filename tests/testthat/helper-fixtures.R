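# Shared fixture builders and the independent greedy oracle.

# Build a small-molecule feature matrix from named per-isolate feature-index
# sets, going through the real peaklist -> consensus -> split -> bin path.
# Feature index f maps to mass 200 + f Da, so bin feature_id equals the rank
# of f among all indices used, and bin mz_center recovers f exactly.
fm_from_sets <- function(sets) {
  lists <- lapply(names(sets), function(id) {
    f <- sets[[id]]
    pl <- peaklist(200 + f, rep(1, length(f)), isolate_id = id,
                   replicate_id = "r1")
    split_regions(merge_replicates(list(pl), tol = 0.1,
                                   min_presence = 1))$np
  })
  bin_features(lists, tol = 0.2)
}

# Map a feature matrix's bin ids back to the original feature indices used
# by fm_from_sets.
bin_to_index <- function(fm, feature_ids) {
  as.integer(round(fm$bins$mz_center[feature_ids] - 200))
}

# Independent brute-force simulation of the selection rule, written over
# plain feature sets: recount uncovered features each round, take the
# maximum, break ties by the lexicographically smallest id, stop as soon as
# the captured fraction reaches the threshold (inclusive); isolates offering
# nothing new are never taken.
greedy_oracle <- function(sets, threshold) {
  universe <- sort(unique(unlist(sets)))
  if (!length(universe))
    return(list(selected = character(0), cumulative = integer(0),
                fraction = 1, captured = integer(0)))
  remaining <- sets
  captured <- integer(0)
  selected <- character(0)
  cumulative <- integer(0)
  while (length(captured) / length(universe) < threshold) {
    gains <- vapply(remaining,
                    function(s) length(setdiff(s, captured)), 1L)
    if (!length(gains) || max(gains) == 0L) break
    pick <- sort(names(remaining)[gains == max(gains)])[1L]
    captured <- union(captured, remaining[[pick]])
    selected <- c(selected, pick)
    cumulative <- c(cumulative, length(captured))
    remaining[[pick]] <- NULL
  }
  list(selected = selected, cumulative = cumulative,
       fraction = length(captured) / length(universe),
       captured = sort(captured))
}

# Random per-isolate feature sets (possibly empty) for property tests.
random_sets <- function(n_iso, n_feat, p = 0.4) {
  sets <- lapply(seq_len(n_iso), function(i)
    which(stats::runif(n_feat) < p))
  names(sets) <- sprintf("I%02d", seq_len(n_iso))
  sets
}

# Run prioritize_group over a sets fixture and translate captured bin ids
# back to original feature indices.
run_greedy <- function(sets, threshold) {
  fm <- fm_from_sets(sets)
  sel <- prioritize_group(names(sets), fm, threshold)
  sel$captured_index <- sort(bin_to_index(fm, sel$captured_features))
  sel
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
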