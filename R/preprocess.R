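#' Mass-region bounds
#'
#' The protein fingerprint region spans 2000-15,000 Da (inclusive at both
#' ends) and is used for pseudo-phylogenetic grouping; the small-molecule
#' (natural product) region spans 200 Da up to but excluding 2000 Da and
#' feeds the metabolite association networks. The 2000.0 Da boundary belongs
#' to the protein region only, so every peak has exactly one region.
#'
#' @format A list with elements `protein` and `np`, each `c(low, high)` in
#'   Daltons.
#' @export
mass_regions <- list(protein = c(low = 2000, high = 15000),
                     np = c(low = 200, high = 2000))

#' Pick peaks from a profile spectrum
#'
#' Detects local intensity maxima over a `±halfwindow`-point window whose
#' baseline-subtracted signal-to-noise ratio reaches `snr_min`. The baseline
#' is a 101-point rolling median of the intensity trace and the noise is the
#' median absolute deviation of the intensity (scaled by 1.4826 to estimate a
#' Gaussian standard deviation). When the MAD is zero (a mostly-flat trace),
#' any point above the baseline counts as above threshold.
#'
#' @param mz strictly increasing numeric vector (length >= 3).
#' @param intensity numeric vector, same length as `mz`.
#' @param snr_min minimum signal-to-noise ratio for a reported peak.
#' @param halfwindow half width, in points, of the local-maximum window.
#' @param isolate_id,replicate_id identifiers for the returned [peaklist].
#' @return A [peaklist] whose peaks carry their estimated `snr`.
#' @export
pick_peaks <- function(mz, intensity, snr_min = 4, halfwindow = 10L,
                       isolate_id = "unknown",
                       replicate_id = NA_character_) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have the same length")
  n <- length(mz)
  if (n < 3L) stop("profile spectrum must have at least 3 points")
  if (any(diff(mz) <= 0)) stop("'mz' must be strictly increasing")

  k <- min(101L, if (n %% 2L == 1L) n else n - 1L)
  baseline <- stats::runmed(intensity, k, endrule = "median")
  noise <- stats::mad(intensity)  # 1.4826 * median absolute deviation
  signal <- intensity - baseline
  snr <- if (noise > 0) signal / noise else ifelse(signal > 0, Inf, 0)

  hw <- as.integer(halfwindow)
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (snr[i] < snr_min) next
    win <- max(1L, i - hw):min(n, i + hw)
    m <- max(intensity[win])
    if (intensity[i] < m) next
    # leftmost point of a plateau wins; a flat window is not a peak
    if (m == min(intensity[win])) next
    if (any(intensity[win[win < i]] == m)) next
    idx <- c(idx, i)
  }
  peaklist(mz[idx], intensity[idx], isolate_id = isolate_id,
           replicate_id = replicate_id, snr = snr[idx])
}

#' Merge technical replicates into a consensus peak list
#'
#' Peaks across replicates of one isolate are matched by single-linkage
#' grouping of their m/z values: sorted pooled m/z values belong to one
#' cluster as long as consecutive gaps stay within `tol`. Each cluster yields
#' one consensus peak with intensity-weighted mean m/z, mean intensity, and a
#' presence fraction (distinct replicates contributing / number of
#' replicates). Clusters seen in fewer than `min_presence` of the replicates
#' are discarded; the default 2/3 keeps peaks present in at least two of
#' three technical replicates.
#'
#' @param replicates list of [peaklist] objects sharing one `isolate_id`.
#' @param tol matching tolerance in Daltons (> 0).
#' @param min_presence minimum presence fraction in (0, 1].
#' @return A `consensus_peaklist` (region still unsplit; see
#'   [split_regions()]).
#' @export
merge_replicates <- function(replicates, tol, min_presence = 2 / 3) {
  if (!length(replicates)) stop("empty replicate sequence")
  stopifnot(all(vapply(replicates, inherits, TRUE, "peaklist")),
            tol > 0, min_presence > 0, min_presence <= 1)
  ids <- vapply(replicates, `[[`, "", "isolate_id")
  if (length(unique(ids)) != 1L)
    stop("replicates mix isolate_ids: ", paste(unique(ids), collapse = ", "))
  n_rep <- length(replicates)

  mz <- unlist(lapply(replicates, function(p) p$peaks$mz))
  inten <- unlist(lapply(replicates, function(p) p$peaks$intensity))
  rep_of <- rep(seq_len(n_rep),
                vapply(replicates, function(p) nrow(p$peaks), 1L))
  if (!length(mz))
    return(new_consensus(ids[1L],
                         data.frame(mz = numeric(0), intensity = numeric(0),
                                    presence = numeric(0)), n_rep))

  cl <- gap_cluster(mz, tol)
  cons <- do.call(rbind, lapply(split(seq_along(mz), cl), function(i) {
    w <- inten[i]
    data.frame(
      mz = if (sum(w) > 0) sum(mz[i] * w) / sum(w) else mean(mz[i]),
      intensity = mean(inten[i]),
      presence = length(unique(rep_of[i])) / n_rep)
  }))
  cons <- cons[cons$presence >= min_presence, , drop = FALSE]
  new_consensus(ids[1L], cons, n_rep)
}

#' Subtract matrix-blank peaks from a consensus list
#'
#' Removes every consensus peak whose m/z lies within `tol` of any peak in
#' the blank; all other peaks are unchanged. MALDI matrix cluster ions
#' dominate the small-molecule region, so running a matrix-only spot and
#' subtracting it is common practice; the pipeline leaves this off by
#' default.
#'
#' @param consensus,blank `consensus_peaklist` objects.
#' @param tol matching tolerance in Daltons (> 0).
#' @return The filtered `consensus_peaklist`.
#' @export
subtract_blank <- function(consensus, blank, tol) {
  stopifnot(inherits(consensus, "consensus_peaklist"),
            inherits(blank, "consensus_peaklist"), tol > 0)
  keep <- nearest_dist(consensus$peaks$mz, blank$peaks$mz) > tol
  new_consensus(consensus$isolate_id,
                consensus$peaks[keep, , drop = FALSE],
                consensus$n_replicates, consensus$region)
}

#' Split a consensus list into protein and small-molecule regions
#'
#' The small-molecule (np) list holds peaks with 200 <= m/z < 2000 Da; the
#' protein list holds 2000 <= m/z <= 15,000 Da. Peaks outside 200-15,000 Da
#' are dropped with a message reporting their count.
#'
#' @param consensus an unsplit `consensus_peaklist`.
#' @return A list with `consensus_peaklist` elements `protein` and `np`.
#' @export
split_regions <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_peaklist"))
  mz <- consensus$peaks$mz
  in_np <- mz >= mass_regions$np["low"] & mz < mass_regions$np["high"]
  in_prot <- mz >= mass_regions$protein["low"] &
    mz <= mass_regions$protein["high"]
  n_drop <- sum(!in_np & !in_prot)
  if (n_drop > 0)
    message(sprintf("split_regions: dropped %d peak(s) outside 200-15000 Da (isolate %s)",
                    n_drop, consensus$isolate_id))
  list(
    protein = new_consensus(consensus$isolate_id,
                            consensus$peaks[in_prot, , drop = FALSE],
                            consensus$n_replicates, "protein"),
    np = new_consensus(consensus$isolate_id,
                       consensus$peaks[in_np, , drop = FALSE],
                       consensus$n_replicates, "np"))
}
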