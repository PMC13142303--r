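#' Bundle per-condition compartment tracks
#'
#' Validates that the tracks share one binning and IQR-normalizes each, so
#' scores are comparable across conditions.
#'
#' @param tracks named list of `compartment_track`s, one per condition.
#' @return an object of class `condition_track_set`.
#' @export
condition_track_set <- function(tracks) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list (one name per condition)")
  if (length(tracks) < 1) stop("need at least one condition")
  b <- tracks[[1]]$binning
  for (t in tracks) if (!.same_binning(t$binning, b))
    stop("all condition tracks must share one binning")
  structure(list(tracks = lapply(tracks, iqr_normalize),
                 conditions = names(tracks), binning = b),
            class = "condition_track_set")
}

#' A-compartment fraction of an interval set
#'
#' An interval is called A when the mean score of its overlapping unmasked
#' bins is positive, B when negative; intervals that are fully masked or have
#' mean exactly 0 are unscored. Returns `fraction_A = A / (A + B)`.
#'
#' @param track a `compartment_track`.
#' @param intervals data frame with columns chrom, start, end (0-based
#'   half-open).
#' @return list with `fraction_A`, `n_A`, `n_B`, `n_scored`, `n_unscored`.
#' @export
interval_compartment_fraction <- function(track, intervals) {
  means <- vapply(seq_len(nrow(intervals)), function(k) {
    idx <- .bins_overlapping(track$binning, intervals$chrom[k],
                             intervals$start[k], intervals$end[k])
    v <- track$score[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  n_A <- sum(means > 0, na.rm = TRUE)
  n_B <- sum(means < 0, na.rm = TRUE)
  if (n_A + n_B == 0) stop("no scorable intervals")
  list(fraction_A = n_A / (n_A + n_B), n_A = n_A, n_B = n_B,
       n_scored = n_A + n_B, n_unscored = nrow(intervals) - n_A - n_B)
}

#' Differential compartment track for one condition
#'
#' Per bin unmasked in every condition: the focal condition's
#' (IQR-normalized) score minus the mean score of the other conditions.
#'
#' @param set a `condition_track_set` with at least 2 conditions.
#' @param focal focal condition name.
#' @return numeric per-bin vector (`NA` outside the shared support).
#' @export
delta_track <- function(set, focal) {
  stopifnot(inherits(set, "condition_track_set"))
  if (length(set$conditions) < 2) stop("need >= 2 conditions")
  if (!focal %in% set$conditions) stop("unknown condition: ", focal)
  shared <- Reduce(`&`, lapply(set$tracks, `[[`, "mask"))
  others <- setdiff(set$conditions, focal)
  om <- rowMeans(do.call(cbind, lapply(set$tracks[others], `[[`, "score")))
  d <- set$tracks[[focal]]$score - om
  d[!shared] <- NA_real_
  d
}

#' Enrichment of condition-unique intervals in the focal compartment signal
#'
#' For each condition, the observed statistic is the mean over that
#' condition's unique intervals of the differential score (focal minus mean
#' of the other conditions) at those intervals. The null reassigns the
#' pooled intervals to conditions at random (`n_perm` label shuffles,
#' preserving per-condition interval counts and genomic positions — the
#' uniqueness-to-condition hypothesis, not genomic position, is what is
#' tested) and recomputes the statistic. One-sided add-one p-value in the
#' direction of A-gain: `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param set a `condition_track_set`.
#' @param unique_intervals named list (per condition) of interval data
#'   frames (chrom, start, end).
#' @param n_perm permutation count (a warning is issued below 100).
#' @param seed integer RNG seed.
#' @return data frame with one row per condition: `condition`,
#'   `observed_delta`, `p`, `n_intervals`.
#' @export
unique_interval_enrichment <- function(set, unique_intervals, n_perm = 1000L,
                                       seed = 1L) {
  stopifnot(inherits(set, "condition_track_set"))
  if (!all(set$conditions %in% names(unique_intervals)))
    stop("unique_intervals must cover every condition")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-value resolution")
  set.seed(as.integer(seed))
  conds <- set$conditions
  # interval-level mean of each condition's delta track, for all pooled intervals
  deltas <- lapply(conds, function(cc) delta_track(set, cc))
  names(deltas) <- conds
  pool <- do.call(rbind, lapply(conds, function(cc) {
    iv <- unique_intervals[[cc]]
    cbind(iv[, c("chrom", "start", "end")], condition = cc)
  }))
  ivmean <- function(dvec) vapply(seq_len(nrow(pool)), function(k) {
    idx <- .bins_overlapping(set$binning, pool$chrom[k],
                             pool$start[k], pool$end[k])
    v <- dvec[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  dmat <- vapply(conds, function(cc) ivmean(deltas[[cc]]), numeric(nrow(pool)))
  out <- lapply(conds, function(cc) {
    own <- pool$condition == cc & !is.na(dmat[, cc])
    n_own <- sum(own)
    if (n_own == 0) stop("condition ", cc, " has no scorable unique interval")
    obs <- mean(dmat[own, cc])
    usable <- which(!is.na(dmat[, cc]))
    null <- vapply(seq_len(n_perm), function(.) {
      mean(dmat[sample(usable, n_own), cc])
    }, numeric(1))
    data.frame(condition = cc, observed_delta = obs,
               p = (1 + sum(null >= obs)) / (1 + n_perm),
               n_intervals = n_own, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank transcription-factor activity from compartment uniqueness
#'
#' Scores each TF by how condition-unique the focal condition's compartment
#' signal is (i) at the TF's motif sites and (ii) over its known target-gene
#' bodies: each component is the mean differential score over the relevant
#' bins, converted to a descending rank across TFs (ties get average ranks),
#' and the combined rank is the rank of the mean of the two component ranks.
#' TFs missing one component are ranked on the other alone and flagged.
#'
#' @param set a `condition_track_set`.
#' @param focal focal condition name.
#' @param motif_sites named list (per TF) of motif-site interval data frames.
#' @param targets named list (per TF) of target gene names.
#' @param genes data frame of gene intervals with a `name` column resolving
#'   the target names.
#' @return data frame ordered by `combined_rank`: `tf`, `motif_component`,
#'   `target_component`, `motif_rank`, `target_rank`, `combined_rank`,
#'   `partial` (TRUE when one component is missing).
#' @export
tf_activity_rank <- function(set, focal, motif_sites, targets, genes) {
  tfs <- union(names(motif_sites), names(targets))
  if (length(tfs) == 0) stop("no TFs to score")
  d <- delta_track(set, focal)
  dtrack <- compartment_track(set$binning, d)
  motif_component <- vapply(tfs, function(tf) {
    iv <- motif_sites[[tf]]
    if (is.null(iv) || nrow(iv) == 0) return(NA_real_)
    idx <- unique(unlist(lapply(seq_len(nrow(iv)), function(k)
      .bins_overlapping(set$binning, iv$chrom[k], iv$start[k], iv$end[k]))))
    v <- d[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  target_component <- vapply(tfs, function(tf) {
    tg <- targets[[tf]]
    if (is.null(tg)) return(NA_real_)
    gsel <- genes[genes$name %in% tg, , drop = FALSE]
    if (nrow(gsel) == 0) return(NA_real_)
    gs <- gene_scores(dtrack, gsel)
    if (all(is.na(gs))) NA_real_ else mean(gs, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(motif_component) & is.na(target_component)))
    stop("no scorable TFs")
  rk <- function(v) { r <- rank(-v, na.last = "keep", ties.method = "average"); r }
  motif_rank <- rk(motif_component)
  target_rank <- rk(target_component)
  mean_rank <- rowMeans(cbind(motif_rank, target_rank), na.rm = TRUE)
  combined <- rank(mean_rank, ties.method = "average")
  out <- data.frame(tf = tfs, motif_component = motif_component,
                    target_component = target_component,
                    motif_rank = motif_rank, target_rank = target_rank,
                    combined_rank = combined,
                    partial = is.na(motif_component) | is.na(target_component),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$combined_rank), ]
}
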