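#' Mean square difference between two compartment tracks
#'
#' Mean of `(score1 - score2)^2` over bins unmasked in both tracks. Use
#' `iqr = TRUE` for cross-method comparisons (preference caller vs
#' eigenvector): the two scores live on different scales and are
#' IQR-normalized first; same-pipeline comparisons can stay on raw scores.
#'
#' @param t1,t2 `compartment_track`s on the same binning.
#' @param iqr IQR-normalize both tracks before comparing.
#' @return nonnegative real.
#' @export
msd <- function(t1, t2, iqr = FALSE) {
  if (!.same_binning(t1$binning, t2$binning))
    stop("tracks are on different binnings")
  if (iqr) { t1 <- iqr_normalize(t1); t2 <- iqr_normalize(t2) }
  ok <- t1$mask & t2$mask
  if (!any(ok)) stop("tracks share no unmasked bins")
  mean((t1$score[ok] - t2$score[ok])^2)
}

#' Passage-to-replicate MSD ratio
#'
#' Compares track variability between biological passages with variability
#' between replicates: a precise caller shows a high ratio (small replicate
#' noise, preserved passage differences).
#'
#' @param passage_pairs,replicate_pairs lists of 2-element lists of
#'   `compartment_track`s sharing one binning.
#' @param iqr passed to [msd()].
#' @return list with `ratio`, per-group mean MSDs and standard deviations.
#'   `ratio` is `Inf` (with a warning) when the replicate mean MSD is 0.
#' @export
passage_replicate_ratio <- function(passage_pairs, replicate_pairs,
                                    iqr = FALSE) {
  g <- function(pairs) vapply(pairs, function(p) msd(p[[1]], p[[2]], iqr = iqr),
                              numeric(1))
  pm <- g(passage_pairs); rm_ <- g(replicate_pairs)
  if (mean(rm_) == 0) {
    warning("replicate mean MSD is 0; ratio is infinite")
    ratio <- Inf
  } else ratio <- mean(pm) / mean(rm_)
  list(ratio = ratio,
       passage_mean = mean(pm), passage_sd = stats::sd(pm),
       replicate_mean = mean(rm_), replicate_sd = stats::sd(rm_))
}

#' Classify per-bin compartment flips between two callers
#'
#' Categorizes every bin unmasked in both tracks by its sign pair: `AA`
#' (A in both), `BB`, `AtoB` (A in the first, B in the second), `BtoA`, or
#' `unscored` (zero score in either). The categories partition the shared
#' unmasked support.
#'
#' @param t1,t2 `compartment_track`s on the same binning.
#' @return list with `category` (per-bin factor, NA outside the shared
#'   support) and `counts` (named vector over the five categories).
#' @export
classify_flips <- function(t1, t2) {
  if (!.same_binning(t1$binning, t2$binning))
    stop("tracks are on different binnings")
  lv <- c("AA", "BB", "AtoB", "BtoA", "unscored")
  ok <- t1$mask & t2$mask
  s1 <- sign(t1$score); s2 <- sign(t2$score)
  cat <- rep(NA_character_, length(ok))
  cat[ok & (s1 == 0 | s2 == 0)] <- "unscored"
  cat[ok & s1 > 0 & s2 > 0] <- "AA"
  cat[ok & s1 < 0 & s2 < 0] <- "BB"
  cat[ok & s1 > 0 & s2 < 0] <- "AtoB"
  cat[ok & s1 < 0 & s2 > 0] <- "BtoA"
  category <- factor(cat, levels = lv)
  list(category = category, counts = table(category))
}

#' Relative A/B contact ratio of bins
#'
#' For each requested bin, the ratio of its mean O/E contact with A-labeled
#' bins to its mean O/E contact with B-labeled bins (labels from `track`),
#' with the same short-range exclusion as the preference score. Values above
#' 1 mean the bin's contact geometry is A-like; used to adjudicate which
#' caller's label matches the map at flip bins.
#'
#' @param oe an `oe_matrix`.
#' @param track a `compartment_track` supplying the A/B labels.
#' @param bins global bin indices to score (default all).
#' @param min_distance_bins exclusion radius in bins.
#' @return numeric vector of ratios (`NA` where invalid), named by bin index.
#' @export
relative_contact_ratio <- function(oe, track, bins = seq_len(n_bins(oe$binning)),
                                   min_distance_bins = 10L) {
  if (!.same_binning(oe$binning, track$binning))
    stop("track and matrix are on different binnings")
  lab <- hard_labels(track)
  out <- rep(NA_real_, n_bins(oe$binning))
  for (ch in unique(oe$binning$bins$chrom[bins])) {
    idx <- chrom_bins(oe$binning, ch)
    a_loc <- which(lab[idx] %in% 1)
    b_loc <- which(lab[idx] %in% -1)
    if (length(a_loc) == 0 || length(b_loc) == 0) next
    s <- .pref_scores(oe$values[[ch]], .expected_matrix(oe, ch), a_loc, b_loc,
                      .md_eff(min_distance_bins, length(idx)),
                      min_contacts = 0)
    # back out the two means from the bounded contrast: r = (1+s)/(1-s)
    r <- (1 + s$score) / (1 - s$score)
    r[!is.finite(r) | r < 0] <- NA_real_
    # exact ratio where s = 1 (pure A contact) is infinite; keep it
    r[!is.na(s$score) & s$score == 1] <- Inf
    out[idx] <- r
  }
  stats::setNames(out[bins], bins)
}

#' Metagene compartment profile
#'
#' Averages an IQR-normalized compartment track over scaled gene
#' coordinates: for each gene, the track is sampled at `n_points` evenly
#' spaced positions in each of the three segments
#' `[TSS - GL, TSS)`, `[TSS, TTS)`, `[TTS, TTS + GL)` (GL = gene length),
#' with minus-strand genes reversed so position runs 5' to 3'. Per-position
#' means and standard deviations are taken across the genes of each group;
#' samples beyond chromosome ends are missing and excluded position-wise.
#'
#' @param track a `compartment_track`; IQR normalization is applied
#'   internally (idempotent if already normalized).
#' @param genes data frame with columns chrom, start, end, strand and group.
#' @param n_points samples per segment.
#' @return named list per group of `metagene_profile` objects: `position`
#'   (scaled, in gene lengths relative to the TSS), `mean`, `sd`, `n_genes`.
#'   Groups with no usable gene are omitted with a warning.
#' @export
metagene_profile <- function(track, genes, n_points = 100L) {
  track <- iqr_normalize(track)
  stopifnot(all(c("chrom", "start", "end", "strand", "group") %in% names(genes)))
  npt <- as.integer(n_points)
  sample_gene <- function(chrom, start, end, strand) {
    gl <- end - start
    segs <- rbind(c(start - gl, start), c(start, end), c(end, end + gl))
    pos <- unlist(lapply(seq_len(3), function(s) {
      segs[s, 1] + (seq_len(npt) - 0.5) / npt * (segs[s, 2] - segs[s, 1])
    }))
    if (strand == "-") pos <- rev(pos)
    idx <- bin_index(track$binning, rep(chrom, length(pos)), floor(pos))
    v <- rep(NA_real_, length(pos))
    inb <- !is.na(idx)
    v[inb] <- track$score[idx[inb]]
    v
  }
  out <- list()
  for (grp in unique(genes$group)) {
    g <- genes[genes$group == grp & genes$end > genes$start, , drop = FALSE]
    if (nrow(g) == 0) {
      warning("group '", grp, "' has no usable genes; omitted")
      next
    }
    m <- t(mapply(sample_gene, g$chrom, g$start, g$end, g$strand))
    out[[grp]] <- structure(list(
      position = c((seq_len(npt) - 0.5) / npt - 1,   # flank, in GL units
                   (seq_len(npt) - 0.5) / npt,       # body (TSS=0, TTS=1)
                   (seq_len(npt) - 0.5) / npt + 1),
      mean = apply(m, 2, mean, na.rm = TRUE),
      sd = apply(m, 2, stats::sd, na.rm = TRUE),
      n_genes = nrow(g)), class = "metagene_profile")
  }
  if (length(out) == 0) stop("no group has usable genes")
  out
}
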