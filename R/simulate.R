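#' Specification of a synthetic plaid Hi-C map
#'
#' Defines a simulated Hi-C experiment on one or more chromosomes with
#' planted A/B compartment labels: contact weights decay with genomic
#' distance as a power law and are multiplied by `affinity` when the two bins
#' share a compartment label, producing the plaid (checkerboard) pattern that
#' same-compartment loci generate in real distance-normalized maps. Optional
#' components add an arm-level block factor orthogonal to compartments
#' (`arm_split`), a second condition in which a set of bins flips label
#' (`condition_shift`), and promoter-restricted extra A-affinity at
#' designated TSS bins (`tss_bins`), emulating the TSS-limited A signal of
#' paused genes.
#'
#' Default labels are alternating A/B blocks with geometrically distributed
#' lengths (mean `mean_block` bins), drawn deterministically from `seed`.
#'
#' @param n_bins bins per chromosome.
#' @param bin_size bin width in bp.
#' @param chroms chromosome names.
#' @param labels optional integer per-bin labels (+1 = A, -1 = B) overriding
#'   the generated blocks.
#' @param mean_block mean planted block length in bins.
#' @param decay_exponent power-law distance-decay exponent.
#' @param affinity same-label contact weight multiplier (>= 1).
#' @param depth total contact count for bulk sampling.
#' @param arm_split add an arm-level factor: bins in the same chromosome half
#'   get their weight multiplied by `arm_boost`.
#' @param arm_boost same-arm multiplier used when `arm_split` is TRUE.
#' @param condition_shift integer vector of global bin indices whose label is
#'   flipped in the second condition.
#' @param tss_bins global bin indices receiving promoter-like extra
#'   A-affinity.
#' @param tss_boost multiplier applied to contacts between a TSS bin and
#'   A-labeled bins.
#' @param seed integer seed controlling label generation and sampling.
#' @return an object of class `synthetic_map_spec`.
#' @export
synthetic_map_spec <- function(n_bins = 400, bin_size = 25000,
                               chroms = "chrS", labels = NULL,
                               mean_block = 10, decay_exponent = -1.0,
                               affinity = 2.0, depth = 1e6,
                               arm_split = FALSE, arm_boost = 6.0,
                               condition_shift = NULL,
                               tss_bins = NULL, tss_boost = 4.0,
                               seed = 1L) {
  stopifnot(affinity >= 1, depth >= 1, n_bins >= 4)
  lens <- stats::setNames(rep(n_bins * bin_size, length(chroms)), chroms)
  binning <- genome_binning(lens, bin_size)
  if (is.null(labels)) {
    set.seed(as.integer(seed))
    labels <- unlist(lapply(seq_along(chroms), function(k) {
      lab <- integer(0)
      cur <- if (stats::runif(1) < 0.5) 1L else -1L
      while (length(lab) < n_bins) {
        len <- 1L + stats::rgeom(1, prob = 1 / mean_block)
        lab <- c(lab, rep(cur, len))
        cur <- -cur
      }
      lab[seq_len(n_bins)]
    }), use.names = FALSE)
  }
  stopifnot(length(labels) == n_bins(binning), all(labels %in% c(-1L, 1L)))
  structure(list(binning = binning, labels = as.integer(labels),
                 decay_exponent = decay_exponent, affinity = affinity,
                 depth = depth, arm_split = arm_split, arm_boost = arm_boost,
                 condition_shift = condition_shift,
                 tss_bins = tss_bins, tss_boost = tss_boost,
                 seed = as.integer(seed)),
            class = "synthetic_map_spec")
}

#' Flip planted labels at the condition-shift bins
#'
#' Returns the second-condition version of a spec: labels at
#' `spec$condition_shift` are flipped and the seed offset so samples are
#' independent draws.
#'
#' @param spec a `synthetic_map_spec` with non-NULL `condition_shift`.
#' @param seed_offset added to the spec seed for the shifted condition.
#' @return a `synthetic_map_spec`.
#' @export
apply_condition_shift <- function(spec, seed_offset = 1000L) {
  if (is.null(spec$condition_shift)) stop("spec has no condition_shift")
  spec2 <- spec
  spec2$labels[spec$condition_shift] <- -spec2$labels[spec$condition_shift]
  spec2$seed <- as.integer((spec$seed + seed_offset) %% .Machine$integer.max)
  spec2
}

#' Sample a block-structured condition shift
#'
#' Picks whole planted blocks at random until about `frac` of all bins are
#' covered, and returns their bin indices for use as `condition_shift`.
#' Flipping whole blocks keeps the second condition's labels block-structured
#' (a flipped block is still a block), as real cell-type compartment
#' differences are.
#'
#' @param spec a `synthetic_map_spec`.
#' @param frac target fraction of bins to shift.
#' @param seed integer RNG seed.
#' @return integer vector of global bin indices.
#' @export
sample_block_shift <- function(spec, frac = 0.25, seed = 1L) {
  set.seed(as.integer(seed))
  runs <- .label_runs(spec$labels)
  ord <- sample.int(nrow(runs))
  target <- frac * n_bins(spec$binning)
  picked <- integer(0)
  for (k in ord) {
    if (length(picked) >= target) break
    picked <- c(picked, runs$start[k]:runs$end[k])
  }
  sort(picked)
}

#' Per-pair contact probabilities of a synthetic map
#'
#' Unnormalized weight of pair (i, j), i != j, on one chromosome:
#' `|i-j|^decay_exponent * (affinity if labels match else 1)`, times
#' `arm_boost` for same-arm pairs when `arm_split` is set, times `tss_boost`
#' when one bin is a TSS bin and the other is A-labeled. Weights are
#' normalized so the sum over unordered intrachromosomal pairs across all
#' chromosomes is 1.
#'
#' @param spec a `synthetic_map_spec`.
#' @return named list per chromosome of symmetric probability matrices
#'   (diagonal 0).
#' @export
contact_probabilities <- function(spec) {
  b <- spec$binning
  wmats <- lapply(b$chrom_names, function(ch) {
    idx <- chrom_bins(b, ch)
    lab <- spec$labels[idx]
    n <- length(idx)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- matrix(0, n, n)
    w[d > 0] <- d[d > 0]^spec$decay_exponent
    same <- outer(lab, lab, "==")
    w[same] <- w[same] * spec$affinity
    if (isTRUE(spec$arm_split)) {
      arm <- seq_len(n) > n / 2
      samearm <- outer(arm, arm, "==")
      w[samearm] <- w[samearm] * spec$arm_boost
    }
    if (!is.null(spec$tss_bins)) {
      tss <- idx %in% spec$tss_bins
      hit <- (outer(tss, lab == 1L, "&") | outer(lab == 1L, tss, "&")) & d > 0
      w[hit] <- w[hit] * spec$tss_boost
    }
    w
  })
  tot <- sum(vapply(wmats, function(w) sum(w[upper.tri(w)]), numeric(1)))
  out <- lapply(wmats, function(w) w / tot)
  names(out) <- b$chrom_names
  out
}

#' Sample a bulk contact matrix from a synthetic map
#'
#' Multinomial draw of exactly `spec$depth` contacts over unordered
#' intrachromosomal pairs, deterministic given the spec seed.
#'
#' @param spec a `synthetic_map_spec`.
#' @return a `contact_matrix`.
#' @export
sample_bulk <- function(spec) {
  probs <- contact_probabilities(spec)
  set.seed(spec$seed)
  pl <- .pair_list(probs)
  draw <- as.vector(stats::rmultinom(1, size = spec$depth, prob = pl$p))
  counts <- lapply(seq_along(probs), function(k) {
    sel <- pl$chrom == k & draw > 0
    .sym_from_triples(pl$i[sel], pl$j[sel], draw[sel], nrow(probs[[k]]))
  })
  names(counts) <- spec$binning$chrom_names
  contact_matrix(spec$binning, counts)
}

# flatten upper-triangle pair probabilities across chromosomes
.pair_list <- function(probs) {
  parts <- lapply(seq_along(probs), function(k) {
    w <- probs[[k]]
    ut <- which(upper.tri(w), arr.ind = TRUE)
    data.frame(chrom = k, i = ut[, 1], j = ut[, 2], p = w[ut])
  })
  do.call(rbind, parts)
}

#' Sample sparse single-cell contact lists from a synthetic map
#'
#' Independent multinomial draws per cell from the same pair distribution,
#' with per-cell seeds derived deterministically from the spec seed and the
#' cell index. Contacts are reported as 1-based positions at bin starts
#' (pairs-file convention).
#'
#' @param spec a `synthetic_map_spec`.
#' @param n_cells number of cells.
#' @param contacts_per_cell contacts per cell.
#' @param ids optional cell identifiers.
#' @return list of `single_cell_contacts` objects: each has `cell_id`,
#'   `contacts` (data frame chrom1, pos1, chrom2, pos2) and `n_contacts`.
#' @export
sample_cells <- function(spec, n_cells, contacts_per_cell, ids = NULL) {
  probs <- contact_probabilities(spec)
  pl <- .pair_list(probs)
  starts <- spec$binning$bins$start
  off <- spec$binning$offset[spec$binning$chrom_names]
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(n_cells))
  lapply(seq_len(n_cells), function(cx) {
    set.seed(.cell_seed(spec$seed, cx))
    hit <- sample.int(nrow(pl), size = contacts_per_cell, replace = TRUE,
                      prob = pl$p)
    ch <- spec$binning$chrom_names[pl$chrom[hit]]
    g1 <- off[pl$chrom[hit]] + pl$i[hit]
    g2 <- off[pl$chrom[hit]] + pl$j[hit]
    structure(list(cell_id = ids[cx],
                   contacts = data.frame(chrom1 = ch, pos1 = starts[g1] + 1,
                                         chrom2 = ch, pos2 = starts[g2] + 1,
                                         stringsAsFactors = FALSE),
                   n_contacts = contacts_per_cell),
              class = "single_cell_contacts")
  })
}

.cell_seed <- function(seed, cell_index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * cell_index) %%
               .Machine$integer.max)
}

#' Synthetic GC-content track for a simulated map
#'
#' Maps planted labels to GC 0.55 (A) / 0.40 (B) plus Gaussian noise
#' (sd 0.03), so GC-based initialization and orientation are informative but
#' imperfect, as for real GC tracks.
#'
#' @param spec a `synthetic_map_spec`.
#' @param noise_sd Gaussian noise standard deviation.
#' @return numeric per-bin GC values.
#' @export
simulated_gc_track <- function(spec, noise_sd = 0.03) {
  set.seed(as.integer((spec$seed + 271828) %% .Machine$integer.max))
  ifelse(spec$labels == 1L, 0.55, 0.40) +
    stats::rnorm(n_bins(spec$binning), sd = noise_sd)
}

#' Planted gene fixture for metagene and signature analyses
#'
#' Places non-overlapping genes on the simulated chromosomes and returns them
#' as stranded BED-like intervals with group labels. "elongating" genes sit
#' entirely inside planted A blocks (A signal across the body); "paused"
#' genes sit inside B blocks and are meant to be combined with a TSS-bin
#' affinity boost (`tss_bins`/`tss_boost` on the spec) so that only the first
#' bin carries A signal. Strands alternate so both orientations are covered;
#' the TSS bin of a minus-strand gene is its last bin.
#'
#' @param spec a `synthetic_map_spec`.
#' @param n_per_group genes per group.
#' @param gene_len_bins gene length in bins.
#' @return list with `genes` (data frame chrom, start, end, name, group,
#'   strand) and `tss_bins` (global indices of the paused genes' TSS bins, to
#'   be passed back into `synthetic_map_spec`).
#' @export
simulated_genes <- function(spec, n_per_group = 20, gene_len_bins = 4) {
  b <- spec$binning
  bs <- b$bin_size
  runs <- .label_runs(spec$labels)
  pick <- function(lab_val, n_needed) {
    ok <- runs[runs$len >= gene_len_bins + 2 & runs$value == lab_val, ]
    ok[seq_len(min(nrow(ok), n_needed)), , drop = FALSE]
  }
  mk <- function(rows, group) {
    if (nrow(rows) == 0) return(NULL)
    first <- rows$start + 1L  # leave one flanking bin inside the block
    data.frame(
      bin0 = first,
      chrom = b$bins$chrom[first],
      start = b$bins$start[first],
      end = b$bins$start[first] + gene_len_bins * bs,
      group = group, stringsAsFactors = FALSE)
  }
  el <- mk(pick(1L, n_per_group), "elongating")
  pa <- mk(pick(-1L, n_per_group), "paused")
  g <- rbind(el, pa)
  g$strand <- rep_len(c("+", "-"), nrow(g))
  g$name <- sprintf("gene%03d", seq_len(nrow(g)))
  tss_bin <- ifelse(g$strand == "+", g$bin0, g$bin0 + gene_len_bins - 1L)
  list(genes = g[, c("chrom", "start", "end", "name", "group", "strand")],
       tss_bins = tss_bin[g$group == "paused"])
}

# run-length view of a label vector with global start indices
.label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L,
             end = ends, len = r$lengths)
}

#' Write planted labels as a BED file
#'
#' One line per planted block with the label in the name column ("A"/"B"),
#' for downstream accuracy scoring of recovered tracks.
#'
#' @param spec a `synthetic_map_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(spec, path) {
  b <- spec$binning
  rows <- lapply(b$chrom_names, function(ch) {
    idx <- chrom_bins(b, ch)
    runs <- .label_runs(spec$labels[idx])
    data.frame(chrom = ch, start = b$bins$start[idx[runs$start]],
               end = b$bins$end[idx[runs$end]],
               name = ifelse(runs$value == 1L, "A", "B"))
  })
  dt <- do.call(rbind, rows)
  writeLines(sprintf("%s\t%d\t%d\t%s", dt$chrom, as.integer(dt$start),
                     as.integer(dt$end), dt$name), path)
  invisible(path)
}

#' Accuracy of a track against planted labels
#'
#' Fraction of unmasked, hard-labeled bins whose sign matches the planted
#' label, reported for both global orientations; `best = TRUE` (default)
#' returns the better of the two, mirroring the sign ambiguity of
#' unoriented callers.
#'
#' @param track a `compartment_track` (any resolution commensurate with the
#'   spec's).
#' @param spec the `synthetic_map_spec` that generated the data.
#' @param best return max over global sign; otherwise use the track's
#'   orientation as-is.
#' @return fraction in `[0, 1]`.
#' @export
label_accuracy <- function(track, spec, best = TRUE) {
  truth <- spec$labels
  if (track$resolution != spec$binning$bin_size) {
    # majority planted label within each track bin
    par <- .parent_of(spec$binning, track$binning)
    agg <- tapply(truth, par, function(v) sign(sum(v)))
    truth <- rep(NA_integer_, n_bins(track$binning))
    truth[as.integer(names(agg))] <- as.integer(agg)
  }
  lab <- hard_labels(track)
  ok <- !is.na(lab) & lab != 0 & !is.na(truth) & truth != 0
  if (!any(ok)) return(NA_real_)
  acc <- mean(lab[ok] == truth[ok])
  if (best) max(acc, 1 - acc) else acc
}
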