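#' Construct a peak list for one isolate/replicate
#'
#' A peak list is the raw unit of input: the centroided peaks observed in one
#' technical replicate of one bacterial isolate. Peaks are stored sorted by
#' m/z; duplicate m/z values within one list are forbidden (readers collapse
#' them before construction).
#'
#' @param mz numeric vector of mass-to-charge values in Daltons; all > 0.
#' @param intensity numeric vector of non-negative intensities (arbitrary
#'   units), same length as `mz`.
#' @param isolate_id non-empty character scalar identifying the isolate.
#' @param replicate_id character scalar identifying the technical replicate.
#' @param snr optional numeric vector of signal-to-noise ratios; `NA` when the
#'   list was picked upstream of this package.
#' @return An object of class `"peaklist"`: a list with elements `isolate_id`,
#'   `replicate_id` and `peaks` (a data frame with columns `mz`, `intensity`,
#'   `snr`, sorted by increasing `mz`).
#' @examples
#' pl <- peaklist(c(500.1, 300.2), c(10, 5), isolate_id = "A",
#'                replicate_id = "r1")
#' pl$peaks$mz  # sorted: 300.2 500.1
#' @export
peaklist <- function(mz, intensity, isolate_id, replicate_id = NA_character_,
                     snr = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have the same length")
  if (anyNA(mz) || anyNA(intensity))
    stop("'mz' and 'intensity' must not contain NA")
  if (any(mz <= 0)) stop("all mz values must be > 0")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (!is.character(isolate_id) || length(isolate_id) != 1L ||
      is.na(isolate_id) || !nzchar(isolate_id))
    stop("'isolate_id' must be a non-empty character scalar")
  if (is.null(snr)) snr <- rep(NA_real_, length(mz))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; snr <- as.numeric(snr)[o]
  if (anyDuplicated(mz))
    stop("duplicate mz values within one peak list are forbidden")
  structure(
    list(isolate_id = isolate_id,
         replicate_id = as.character(replicate_id),
         peaks = data.frame(mz = mz, intensity = intensity, snr = snr)),
    class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> isolate %s, replicate %s: %d peaks",
              x$isolate_id, x$replicate_id, nrow(x$peaks)))
  if (nrow(x$peaks))
    cat(sprintf(" (m/z %.4g-%.4g)", min(x$peaks$mz), max(x$peaks$mz)))
  cat("\n")
  invisible(x)
}

# consensus list constructor, internal: validation shared by merge/subtract/split
new_consensus <- function(isolate_id, peaks, n_replicates,
                          region = NA_character_) {
  stopifnot(is.data.frame(peaks),
            all(c("mz", "intensity", "presence") %in% names(peaks)))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(isolate_id = isolate_id, region = region, peaks = peaks,
         n_replicates = as.integer(n_replicates)),
    class = "consensus_peaklist")
}

#' @export
print.consensus_peaklist <- function(x, ...) {
  cat(sprintf("<consensus_peaklist> isolate %s (%s region): %d peaks from %d replicates\n",
              x$isolate_id,
              if (is.na(x$region)) "unsplit" else x$region,
              nrow(x$peaks), x$n_replicates))
  invisible(x)
}
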