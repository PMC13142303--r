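#' Construct a compartment track
#'
#' A per-bin continuous compartment score, A-positive. The sign of the score
#' is the hard call: positive = A, negative = B, zero = unassigned. Scores are
#' defined exactly on unmasked bins.
#'
#' @param binning a `genome_binning`.
#' @param score numeric per-bin score; `NA` on masked bins.
#' @param mask logical per-bin validity; defaults to `!is.na(score)`.
#' @param orientation_source one of "gc", "seed_track", "coarse_parent",
#'   "arbitrary".
#' @param inherited logical per-bin flag: score copied from a coarser rung
#'   rather than estimated at this one.
#' @param incoherent flag set by callers that detect a failed track.
#' @return an object of class `compartment_track`.
#' @export
compartment_track <- function(binning, score, mask = !is.na(score),
                              orientation_source = "arbitrary",
                              inherited = NULL, incoherent = FALSE) {
  stopifnot(length(score) == n_bins(binning), length(mask) == n_bins(binning))
  score[!mask] <- NA_real_
  if (is.null(inherited)) inherited <- rep(FALSE, n_bins(binning))
  structure(list(binning = binning, score = score, mask = mask,
                 resolution = binning$bin_size,
                 orientation_source = orientation_source,
                 inherited = inherited, incoherent = incoherent),
            class = "compartment_track")
}

#' @export
print.compartment_track <- function(x, ...) {
  cat(sprintf(
    "<compartment_track> %d bp, %d/%d bins scored (%d inherited), A: %d, B: %d%s\n",
    x$resolution, sum(x$mask), n_bins(x$binning), sum(x$inherited & x$mask),
    sum(x$score > 0, na.rm = TRUE), sum(x$score < 0, na.rm = TRUE),
    if (isTRUE(x$incoherent)) " [INCOHERENT]" else ""))
  invisible(x)
}

#' Hard A/B labels of a track
#' @param track a `compartment_track`.
#' @return integer per bin: +1 (A), -1 (B), 0 (unassigned), NA (masked).
#' @export
hard_labels <- function(track) {
  lab <- sign(track$score)
  lab[!track$mask] <- NA
  lab
}

#' IQR-normalize a compartment track
#'
#' Rescales scores to `(score - median) / IQR`, computed over the unmasked
#' bins of the whole track, so tracks from different samples or callers share
#' a scale. Quantiles use mid-interpolation (R `quantile` type 5). The result
#' has median 0 and IQR 1; the mask is preserved. Idempotent up to floating
#' point.
#'
#' @param track a `compartment_track`.
#' @return the normalized `compartment_track`.
#' @export
iqr_normalize <- function(track) {
  v <- track$score[track$mask]
  if (length(v) < 4) stop("need >= 4 unmasked bins to IQR-normalize")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 5, names = FALSE)
  iqr <- q[3] - q[1]
  if (iqr == 0) stop("degenerate score distribution: IQR is 0")
  out <- track
  out$score <- (track$score - q[2]) / iqr
  out
}

# flip all signs so that cor(score, ref) >= 0; returns list(track, cor)
.orient_track <- function(track, ref, source) {
  ok <- track$mask & !is.na(ref)
  r <- if (sum(ok) >= 3 && stats::sd(track$score[ok]) > 0 &&
           stats::sd(ref[ok]) > 0)
    stats::cor(track$score[ok], ref[ok]) else NA_real_
  if (!is.na(r) && r < 0) track$score <- -track$score
  track$orientation_source <- source
  list(track = track, cor = if (is.na(r)) NA_real_ else abs(r))
}

#' Write a track as bedGraph
#'
#' One `chrom start end score` line per unmasked bin, 0-based half-open,
#' scores at full double precision so a read-back reproduces them bit-exactly.
#'
#' @param track a `compartment_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  b <- track$binning$bins[track$mask, ]
  s <- track$score[track$mask]
  writeLines(sprintf("%s\t%d\t%d\t%.17g", b$chrom, as.integer(b$start),
                     as.integer(b$end), s), path)
  invisible(path)
}

#' Read a bedGraph file as a compartment track
#'
#' @param path bedGraph path.
#' @param binning a `genome_binning` matching the file's intervals.
#' @return a `compartment_track`; bins absent from the file are masked.
#' @export
read_bedgraph <- function(path, binning) {
  if (!file.exists(path)) stop("cannot read bedGraph: ", path)
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  score <- rep(NA_real_, n_bins(binning))
  idx <- bin_index(binning, dt$chrom, dt$start)
  if (anyNA(idx)) stop("bedGraph interval outside binning")
  score[idx] <- dt$score
  compartment_track(binning, score)
}

#' Per-bin GC track from a bedGraph file
#'
#' Convenience reader returning a bare numeric vector aligned to the binning
#' (NA where the file has no interval), for use as an orientation track.
#'
#' @inheritParams read_bedgraph
#' @return numeric vector of length `n_bins(binning)`.
#' @export
read_gc_track <- function(path, binning) {
  read_bedgraph(path, binning)$score
}

# aggregate a per-bin numeric track (e.g. GC) to a coarser binning by mean
.aggregate_track_mean <- function(values, fine, coarse) {
  par <- .parent_of(fine, coarse)
  out <- rep(NA_real_, n_bins(coarse))
  m <- tapply(values, par, mean, na.rm = TRUE)
  out[as.integer(names(m))] <- as.numeric(m)
  out[is.nan(out)] <- NA_real_
  out
}
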