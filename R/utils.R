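# Single-linkage 1-D clustering: split a sorted vector wherever the gap
# between consecutive values exceeds tol. Returns integer cluster ids
# aligned with the *input* order.
gap_cluster <- function(x, tol) {
  stopifnot(is.numeric(x), tol > 0)
  if (!length(x)) return(integer(0))
  o <- order(x)
  xs <- x[o]
  ids_sorted <- cumsum(c(1L, as.integer(diff(xs) > tol)))
  ids <- integer(length(x))
  ids[o] <- ids_sorted
  ids
}

# Half-up rounding to integer (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# For each value of x, distance to the nearest value of ref (ref may be
# unsorted). Used for blank subtraction and truth matching.
nearest_dist <- function(x, ref) {
  if (!length(ref)) return(rep(Inf, length(x)))
  ref <- sort(ref)
  i <- findInterval(x, ref)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(ref))
  pmin(abs(x - ref[lo]), abs(x - ref[hi]))
}
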