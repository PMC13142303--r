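#' Configuration for the preference-based compartment caller
#'
#' @param resolution_ladder descending bin sizes (bp) for the coarse-to-fine
#'   cascade. Each coarser size must be an integer multiple of the next finer
#'   one.
#' @param max_iter maximum refinement iterations per resolution.
#' @param convergence_frac stop refining once the fraction of bins flipping
#'   label in an iteration falls below this.
#' @param min_distance_bins short-range exclusion radius: contacts closer
#'   than this many bins are excluded from preference scoring, separating
#'   compartment-scale signal from TAD-scale contacts.
#' @param min_contacts_per_bin coverage floor: a bin is scored at a
#'   resolution only if at least this many contacts enter its score;
#'   otherwise it inherits the coarser rung's score.
#' @param min_cell_contacts minimum contacts for a single cell to be called.
#' @param flip_evidence_z evidence requirement for label flips: a bin's label
#'   is reassigned to the sign of its preference score only when
#'   `|score| > flip_evidence_z / sqrt(coverage)` — approximately
#'   `flip_evidence_z` sampling standard deviations of the score at that
#'   coverage. Low-coverage bins therefore retain their current assignment
#'   (initialization or inherited parent label) unless the map provides
#'   decisive evidence against it; on deep maps the threshold is negligible
#'   and labels follow the score sign. 0 disables the check.
#' @param seed integer seed for any stochastic tie-breaking.
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(resolution_ladder = c(250000, 50000, 25000, 5000, 1000),
                          max_iter = 20L, convergence_frac = 0.001,
                          min_distance_bins = 10L, min_contacts_per_bin = 10,
                          min_cell_contacts = 5000L, flip_evidence_z = 2,
                          seed = 1L) {
  resolution_ladder <- sort(unique(as.numeric(resolution_ladder)),
                            decreasing = TRUE)
  if (length(resolution_ladder) > 1) {
    ratio <- utils::head(resolution_ladder, -1) / utils::tail(resolution_ladder, -1)
    if (any(ratio != round(ratio)))
      stop("each ladder rung must be an integer multiple of the next finer one")
  }
  structure(list(resolution_ladder = resolution_ladder,
                 max_iter = as.integer(max_iter),
                 convergence_frac = convergence_frac,
                 min_distance_bins = as.integer(min_distance_bins),
                 min_contacts_per_bin = min_contacts_per_bin,
                 min_cell_contacts = as.integer(min_cell_contacts),
                 flip_evidence_z = flip_evidence_z,
                 seed = as.integer(seed)),
            class = "caller_config")
}

#' Reference A/B bin sets
#'
#' The current sets of bins labeled A and B, against which each bin's
#' interaction preference is scored during refinement.
#'
#' @param a_bins,b_bins disjoint integer sets of global bin indices.
#' @return an object of class `reference_sets`.
#' @export
reference_sets <- function(a_bins, b_bins) {
  a_bins <- sort(unique(as.integer(a_bins)))
  b_bins <- sort(unique(as.integer(b_bins)))
  if (length(intersect(a_bins, b_bins)) > 0)
    stop("reference sets must be disjoint")
  if (length(a_bins) == 0 || length(b_bins) == 0)
    stop("both reference sets must be nonempty")
  structure(list(a_bins = a_bins, b_bins = b_bins), class = "reference_sets")
}

#' Initialize reference A/B sets
#'
#' With a GC track, bins above their chromosome's median GC become A and the
#' rest (including ties) become B — GC is the field's standard A-orienting
#' covariate. Without one, initial labels are taken from the sign of the
#' eigenvector baseline at this resolution (orientation arbitrary; it is
#' fixed later by the refinement's orientation step).
#'
#' @param oe an `oe_matrix`.
#' @param gc_track optional per-bin GC values.
#' @return a `reference_sets`.
#' @export
initialize_labels <- function(oe, gc_track = NULL) {
  if (sum(oe$mask) < 4) stop("need >= 4 unmasked bins to initialize")
  lab <- rep(0L, n_bins(oe$binning))
  if (!is.null(gc_track)) {
    stopifnot(length(gc_track) == n_bins(oe$binning))
    for (ch in oe$binning$chrom_names) {
      idx <- chrom_bins(oe$binning, ch)
      use <- oe$mask[idx] & !is.na(gc_track[idx])
      if (!any(use)) next
      med <- stats::median(gc_track[idx][use])
      lab[idx][use] <- ifelse(gc_track[idx][use] > med, 1L, -1L)
    }
  } else {
    pc <- eigenvector_compartments(oe)
    lab[pc$mask] <- as.integer(sign(pc$score[pc$mask]))
  }
  if (sum(lab == 1L) < 2 || sum(lab == -1L) < 2)
    stop("degenerate initialization: fewer than 2 bins per reference set")
  reference_sets(which(lab == 1L), which(lab == -1L))
}

# Vectorized preference scores for one chromosome.
# vals: dense O/E with NA at masked/absent; evals: matching matrix of
# expected counts (the O/E denominators); a_loc/b_loc: local (per-chrom)
# reference indices.
#
# abar/bbar are geometric means of the per-pair O/E values: each pair
# contributes its shrunk log-ratio log((c + tau) / (e + tau)), averaged with
# saturating inverse-variance weights w = e / (1 + e / e_sat), and the two
# reference-set means are contrasted as (abar - bbar) / (abar + bbar).
# The log scale makes the contrast robust to multiplicative confounders
# shared by subsets of reference bins (e.g. chromosome-arm-level contact
# enrichment): a bin-pair factor adds to the log-mean instead of multiplying
# into it, so its influence is bounded by the arm-composition imbalance of
# the reference sets rather than by the factor's size. The weights give
# sparse pairs (e << e_sat) their Poisson precision e, so near-empty
# long-range pairs cannot dominate, while well-covered pairs get an equal
# vote. The shrinkage constant tau keeps zero-count pairs finite and
# vanishes as coverage grows. Coverage is the raw contact count entering
# the score. Returns list(score, coverage); score NA where invalid.
.pref_scores <- function(vals, evals, a_loc, b_loc, min_dist, min_contacts,
                         e_sat = 1.0, tau = 0.5) {
  n <- nrow(vals)
  valid <- !is.na(vals) & !is.na(evals)
  cnt <- vals * evals             # observed counts (for coverage)
  cnt[!valid] <- 0
  w <- evals / (1 + evals / e_sat)
  w[!valid] <- 0
  wx <- w * log((cnt + tau) / (evals + tau))   # weighted shrunk log O/E
  wx[!valid] <- 0
  a <- numeric(n); a[a_loc] <- 1
  b <- numeric(n); b[b_loc] <- 1
  sumXA <- as.vector(wx %*% a); sumWA <- as.vector(w %*% a)
  sumXB <- as.vector(wx %*% b); sumWB <- as.vector(w %*% b)
  covA <- as.vector(cnt %*% a);  covB <- as.vector(cnt %*% b)
  # remove the short-range band |i - j| < min_dist (includes j = i, so a bin
  # never scores against itself)
  for (k in seq(-(min_dist - 1L), min_dist - 1L)) {
    i <- seq_len(n); j <- i + k
    ok <- j >= 1L & j <= n
    ii <- i[ok]; jj <- j[ok]
    xv <- wx[cbind(ii, jj)]; wv <- w[cbind(ii, jj)]; cv <- cnt[cbind(ii, jj)]
    sumXA[ii] <- sumXA[ii] - xv * a[jj]; sumWA[ii] <- sumWA[ii] - wv * a[jj]
    sumXB[ii] <- sumXB[ii] - xv * b[jj]; sumWB[ii] <- sumWB[ii] - wv * b[jj]
    covA[ii] <- covA[ii] - cv * a[jj];   covB[ii] <- covB[ii] - cv * b[jj]
  }
  abar <- ifelse(sumWA > 0, exp(sumXA / sumWA), NA_real_)
  bbar <- ifelse(sumWB > 0, exp(sumXB / sumWB), NA_real_)
  coverage <- covA + covB
  score <- (abar - bbar) / (abar + bbar)
  score[!is.finite(score)] <- NA_real_
  score[coverage < min_contacts] <- NA_real_
  list(score = pmin(pmax(score, -1), 1), coverage = coverage)
}

# effective short-range exclusion: capped at a quarter of the chromosome so
# short chromosomes (few bins at coarse resolutions) remain scorable
.md_eff <- function(min_dist, n) max(1L, min(as.integer(min_dist), n %/% 4L))

# absolute correlation of a track's scores with a covariate (NA if undefined)
.gc_coherence <- function(track, covariate) {
  ok <- track$mask & !is.na(covariate)
  if (sum(ok) < 4 || stats::sd(track$score[ok]) == 0 ||
      stats::sd(covariate[ok]) == 0) return(NA_real_)
  abs(stats::cor(track$score[ok], covariate[ok]))
}

# expected-count matrix aligned with oe$values for one chromosome
.expected_matrix <- function(oe, ch) {
  v <- oe$values[[ch]]
  d <- abs(row(v) - col(v))
  e <- matrix(oe$expected[[ch]][d + 1L], nrow(v), ncol(v))
  e[is.na(v)] <- NA_real_
  e
}

#' Interaction-preference score of one bin
#'
#' The core per-bin statistic: with `abar` the geometric mean O/E contact of
#' bin `i` with the current A reference bins at genomic distance of at least
#' `min_distance_bins` bins, and `bbar` likewise over B, the score is
#' `(abar - bbar) / (abar + bbar)` — a bounded, A-positive, depth-invariant
#' (in expectation) contrast of contact preference for the two nuclear
#' environments. Per-pair log-ratios are shrunk by half a count and averaged
#' with precision weights that saturate at one expected contact, so the
#' statistic stays defined and stable on sparse maps; the log scale bounds
#' the influence of multiplicative confounders such as arm-level contact
#' enrichment. `NA` (invalid, not 0) when the denominator is 0 or fewer than
#' `min_contacts` contacts enter the score.
#'
#' @param oe an `oe_matrix`.
#' @param refs a `reference_sets`.
#' @param i global bin index.
#' @param min_distance_bins short-range exclusion radius in bins.
#' @param min_contacts coverage floor in contacts.
#' @return score in `[-1, 1]`, or `NA` if the bin cannot be scored.
#' @export
preference_score <- function(oe, refs, i, min_distance_bins = 10L,
                             min_contacts = 0) {
  if (!oe$mask[i]) return(NA_real_)
  ch <- oe$binning$bins$chrom[i]
  idx <- chrom_bins(oe$binning, ch)
  loc <- function(g) match(intersect(g, idx), idx)
  s <- .pref_scores(oe$values[[ch]], .expected_matrix(oe, ch),
                    loc(refs$a_bins), loc(refs$b_bins),
                    .md_eff(min_distance_bins, length(idx)), min_contacts)
  s$score[match(i, idx)]
}

#' Iteratively refine compartment labels at one resolution
#'
#' Repeatedly scores every unmasked bin against the current A/B reference
#' sets and reassigns labels by score sign (zero-score and unscorable bins
#' keep their previous label — hysteresis that prevents oscillation), until
#' the fraction of flipping bins drops below `cfg$convergence_frac` or
#' `cfg$max_iter` is reached. Chromosomes are refined independently. The
#' returned track carries the final scores, sign-oriented so that its
#' correlation with `gc_track` (when given) is nonnegative.
#'
#' @param oe an `oe_matrix`.
#' @param refs initial `reference_sets`.
#' @param cfg a `caller_config`.
#' @param gc_track optional per-bin values used only for final orientation.
#' @param orientation_source label recorded on the track.
#' @return list with `track` (a `compartment_track`) and `iterations`
#'   (named per-chromosome iteration counts).
#' @export
refine_labels <- function(oe, refs, cfg = caller_config(), gc_track = NULL,
                          orientation_source = if (is.null(gc_track)) "arbitrary" else "gc") {
  b <- oe$binning
  score_all <- rep(NA_real_, n_bins(b))
  iters <- stats::setNames(integer(length(b$chrom_names)), b$chrom_names)
  for (ch in b$chrom_names) {
    idx <- chrom_bins(b, ch)
    lab <- rep(0L, length(idx))
    lab[match(intersect(refs$a_bins, idx), idx)] <- 1L
    lab[match(intersect(refs$b_bins, idx), idx)] <- -1L
    lab[!oe$mask[idx]] <- 0L
    if (sum(lab == 1L) == 0 || sum(lab == -1L) == 0) next
    vals <- oe$values[[ch]]
    evals <- .expected_matrix(oe, ch)
    scores <- rep(NA_real_, length(idx))
    for (it in seq_len(cfg$max_iter)) {
      iters[ch] <- it
      s <- .pref_scores(vals, evals, which(lab == 1L), which(lab == -1L),
                        .md_eff(cfg$min_distance_bins, length(idx)),
                        cfg$min_contacts_per_bin)
      new_lab <- lab
      scored <- !is.na(s$score) & s$score != 0
      # unlabeled bins adopt the score sign outright; labeled bins flip only
      # on decisive evidence (score beyond its sampling noise)
      thr <- cfg$flip_evidence_z / sqrt(pmax(s$coverage, 1))
      adopt <- scored & lab == 0L
      flip <- scored & lab != 0L & sign(s$score) != lab & abs(s$score) > thr
      new_lab[adopt | flip] <- as.integer(sign(s$score[adopt | flip]))
      if (sum(new_lab == 1L) == 0 || sum(new_lab == -1L) == 0) {
        warning(sprintf("reference set emptied on %s; reverting to previous labels", ch))
        break
      }
      flipped <- if (any(scored)) mean(new_lab[scored] != lab[scored]) else 0
      lab <- new_lab
      scores <- s$score
      if (flipped < cfg$convergence_frac) break
    }
    # within the evidence band the score's sign is not identified, so the
    # retained label supplies the sign and the data the magnitude
    keep <- !is.na(scores) & lab != 0L
    scores[keep] <- abs(scores[keep]) * lab[keep]
    score_all[idx] <- scores
  }
  track <- compartment_track(b, score_all)
  if (!is.null(gc_track)) {
    track <- .orient_track(track, gc_track, orientation_source)$track
  } else {
    track$orientation_source <- orientation_source
  }
  list(track = track, iterations = iters)
}

#' Call compartments with the coarse-to-fine cascade
#'
#' Runs the full caller: aggregates the contact matrix to every rung of the
#' resolution ladder, refines labels at the coarsest rung (initialized from
#' GC, or from the eigenvector baseline if no GC track is given), then walks
#' down the ladder. At each finer rung every child bin inherits its parent
#' bin's label as the starting reference assignment and is re-scored with the
#' finer matrix; child bins that cannot be scored (coverage below the floor)
#' keep the parent's score unchanged and are flagged `inherited` — this is
#' what keeps fine-resolution tracks dense at modest sequencing depth.
#'
#' @param contacts a `contact_matrix` at the finest bin size of interest.
#' @param cfg a `caller_config`; ladder rungs finer than the contact matrix
#'   or not commensurate with it are dropped.
#' @param gc_track optional per-bin GC values at the contact matrix's
#'   resolution, used for initialization and orientation.
#' @param blacklist optional BED data frame of regions to mask.
#' @return named list (by resolution) of `compartment_track`s, coarsest
#'   first.
#' @export
call_compartments <- function(contacts, cfg = caller_config(),
                              gc_track = NULL, blacklist = NULL) {
  if (!is.null(blacklist)) contacts <- mask_blacklist(contacts, blacklist)
  fine_bs <- contacts$binning$bin_size
  ladder <- cfg$resolution_ladder
  ladder <- ladder[ladder >= fine_bs & ladder %% fine_bs == 0]
  if (length(ladder) == 0)
    stop("no ladder rung is commensurate with the contact matrix bin size")
  tracks <- list()
  parent <- NULL
  parent_spent <- FALSE  # set once a rung fails entirely; finer rungs inherit
  for (res in ladder) {
    mc <- aggregate_contacts(contacts, res)
    gc_res <- if (!is.null(gc_track))
      .aggregate_track_mean(gc_track, contacts$binning, mc$binning) else NULL
    if (parent_spent) {
      tracks[[as.character(res)]] <- .project_track(parent, mc$binning)
      parent <- tracks[[as.character(res)]]
      next
    }
    oe <- observed_over_expected(mc)
    cfg_rung <- cfg
    if (is.null(parent)) {
      # the coarsest rung has no parent to inherit from: score every bin
      # with whatever coverage it has rather than masking it
      cfg_rung$min_contacts_per_bin <- 0
      refs <- initialize_labels(oe, gc_res)
      init_track <- NULL
    } else if (isTRUE(parent$incoherent) && !is.null(gc_res)) {
      # the parent lost coherence with the orientation covariate (e.g. it
      # locked onto an arm-level pattern): restart this rung from the GC
      # prior instead of inheriting a suspect sign pattern
      init_track <- .project_track(parent, mc$binning)
      refs <- initialize_labels(oe, gc_res)
    } else {
      init_track <- .project_track(parent, mc$binning)
      lab <- sign(init_track$score)
      lab[is.na(lab)] <- 0
      ok <- lab != 0 & oe$mask
      if (sum(lab[ok] == 1) < 2 || sum(lab[ok] == -1) < 2) {
        warning(sprintf("rung %d has no usable initialization; inheriting parent track", res))
        tracks[[as.character(res)]] <- init_track
        parent <- init_track
        parent_spent <- TRUE
        next
      }
      refs <- reference_sets(which(ok & lab == 1), which(ok & lab == -1))
    }
    rr <- refine_labels(oe, refs, cfg_rung, gc_track = gc_res,
                        orientation_source = if (!is.null(gc_res)) "gc" else
                          if (is.null(parent)) "arbitrary" else "coarse_parent")
    tr <- rr$track
    # With a GC covariate available, guard against the parent projection
    # steering refinement into a non-compartment basin (e.g. an arm-level
    # pattern): also refine from the GC prior and keep whichever result is
    # more coherent with GC, preferring the parent-initialized one at ties.
    if (!is.null(gc_res) && !is.null(init_track)) {
      alt <- tryCatch(
        refine_labels(oe, initialize_labels(oe, gc_res), cfg_rung,
                      gc_track = gc_res)$track,
        error = function(e) NULL)
      gcc_p <- .gc_coherence(tr, gc_res)
      gcc_g <- if (is.null(alt)) NA_real_ else .gc_coherence(alt, gc_res)
      if (is.finite(gcc_p) && is.finite(gcc_g) && gcc_g > gcc_p + 0.1) {
        message(sprintf(paste("rung %d: GC-initialized refinement is more",
                              "GC-coherent (%.2f vs parent-initialized %.2f);",
                              "adopting it"), res, gcc_g, gcc_p))
        tr <- alt
      }
    }
    if (!any(tr$mask)) {
      if (is.null(parent)) stop("no scorable bins at the coarsest rung")
      warning(sprintf("rung %d has no scorable bins; inheriting parent track", res))
      tracks[[as.character(res)]] <- init_track
      parent <- init_track
      parent_spent <- TRUE
      next
    }
    if (is.null(gc_res) && !is.null(init_track)) {
      tr <- .orient_track(tr, init_track$score, "coarse_parent")$track
    }
    if (!is.null(gc_res) && any(tr$mask)) {
      ok <- tr$mask & !is.na(gc_res)
      gcc <- if (sum(ok) >= 4 && stats::sd(tr$score[ok]) > 0)
        abs(stats::cor(tr$score[ok], gc_res[ok])) else NA_real_
      if (is.finite(gcc) && gcc < 0.1) {
        tr$incoherent <- TRUE
        warning(sprintf(paste("rung %d lost GC coherence (|r| = %.3f);",
                              "finer rungs will restart from the GC prior"),
                        res, gcc))
      }
    }
    if (!is.null(init_track)) {
      fill <- !tr$mask & init_track$mask
      tr$score[fill] <- init_track$score[fill]
      tr$mask[fill] <- TRUE
      tr$inherited[fill] <- TRUE
    }
    tracks[[as.character(res)]] <- tr
    parent <- tr
  }
  tracks
}

# project a parent track's scores onto a finer binning (every child bin
# inherits its parent's score); inherited flags set on all filled bins
.project_track <- function(parent, fine_binning) {
  par <- .parent_of(fine_binning, parent$binning)
  score <- parent$score[par]
  tr <- compartment_track(fine_binning, score,
                          orientation_source = parent$orientation_source)
  tr$inherited <- tr$mask
  tr$incoherent <- parent$incoherent
  tr
}
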