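#' Bin a single cell's contacts into a contact matrix
#'
#' @param cell a `single_cell_contacts` object (or data frame with columns
#'   chrom1, pos1, chrom2, pos2; 1-based positions).
#' @param binning a `genome_binning`.
#' @return a `contact_matrix`.
#' @export
bin_cell_contacts <- function(cell, binning) {
  df <- if (inherits(cell, "single_cell_contacts")) cell$contacts else cell
  tmp <- tempfile(fileext = ".pairs")
  on.exit(unlink(tmp))
  data.table::fwrite(df, tmp, sep = "\t", col.names = FALSE)
  suppressMessages(read_pairs(tmp, binning))
}

#' Call compartments directly on one single cell
#'
#' One-pass preference scoring of an individual sparse contact map: contacts
#' are binned, O/E is computed against the cell's own decay curve with
#' log-spaced distance bands (individual diagonals are too sparse per cell),
#' the A/B reference sets come from a GC median split, and every covered bin
#' is scored once. Bins with no informative contacts are masked, never
#' inherited — per-cell sparsity must stay visible in the output.
#'
#' @param cell a `single_cell_contacts` object.
#' @param binning a `genome_binning` (25 kb is the default working
#'   resolution for single cells).
#' @param gc_track per-bin GC values for initialization and orientation.
#' @param cfg a `caller_config`; `max_iter` is forced to the `passes` value.
#' @param passes refinement passes (default 1: a direct preference call).
#' @param n_bands log-spaced distance bands for the per-cell decay curve.
#' @return a `compartment_track`, or `NULL` (with a message) when the cell
#'   has fewer than `cfg$min_cell_contacts` usable contacts.
#' @export
call_compartments_cell <- function(cell, binning, gc_track,
                                   cfg = caller_config(), passes = 1L,
                                   n_bands = 50L) {
  m <- bin_cell_contacts(cell, binning)
  if (total_contacts(m) < cfg$min_cell_contacts) {
    message(sprintf("cell %s skipped: %d contacts < minimum %d",
                    if (inherits(cell, "single_cell_contacts")) cell$cell_id else "?",
                    as.integer(total_contacts(m)), cfg$min_cell_contacts))
    return(NULL)
  }
  oe <- observed_over_expected(m, n_bands = n_bands)
  refs <- initialize_labels(oe, gc_track)
  cfg$max_iter <- as.integer(passes)
  # the per-cell call is direct: the GC split only builds the reference
  # sets, the reported sign is the cell's own preference score
  cfg$flip_evidence_z <- 0
  rr <- refine_labels(oe, refs, cfg, gc_track = gc_track)
  tr <- rr$track
  tr$mask <- tr$mask & m$mask       # zero-coverage bins stay masked
  tr$score[!tr$mask] <- NA_real_
  tr
}

#' Mean compartment score per gene
#'
#' @param track a `compartment_track`.
#' @param genes data frame with columns chrom, start, end and (optionally)
#'   name; 0-based half-open intervals.
#' @return named numeric vector, one entry per gene (`NA` when all of a
#'   gene's bins are masked).
#' @export
gene_scores <- function(track, genes) {
  nm <- if ("name" %in% names(genes)) genes$name else
    sprintf("gene%04d", seq_len(nrow(genes)))
  out <- vapply(seq_len(nrow(genes)), function(k) {
    idx <- .bins_overlapping(track$binning, genes$chrom[k],
                             genes$start[k], genes$end[k])
    v <- track$score[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, nm)
}

#' Rank differentially compartmentalized genes between two cell groups
#'
#' Per gene, the difference of group means of per-cell gene scores (missing
#' cells excluded per gene); the signature is the `size` genes with the
#' largest absolute difference, each with direction `+` (A-specific in group
#' 1) or `-`. Genes scorable in less than `min_frac` of the cells of either
#' group are excluded. This is a ranking, not a formal test: no per-gene
#' p-values are produced.
#'
#' @param group1_scores,group2_scores matrices (cells x genes) of per-cell
#'   gene scores with shared gene columns, e.g. rows of [gene_scores()]
#'   outputs.
#' @param size signature size.
#' @param min_frac minimum fraction of cells per group in which a gene must
#'   be scorable.
#' @return an object of class `gene_signature`: data frame with `gene`,
#'   `direction` (+1/-1), `difference`, ordered by |difference|. Truncated
#'   with a warning when fewer than `size` genes qualify.
#' @export
rank_differential_genes <- function(group1_scores, group2_scores, size = 150L,
                                    min_frac = 0.25) {
  stopifnot(identical(colnames(group1_scores), colnames(group2_scores)))
  f1 <- colMeans(!is.na(group1_scores))
  f2 <- colMeans(!is.na(group2_scores))
  ok <- f1 >= min_frac & f2 >= min_frac
  diff <- colMeans(group1_scores, na.rm = TRUE) -
    colMeans(group2_scores, na.rm = TRUE)
  diff[!ok] <- NA_real_
  ord <- order(abs(diff), decreasing = TRUE, na.last = NA)
  if (length(ord) < size)
    warning(sprintf("only %d of %d requested genes qualify; signature truncated",
                    length(ord), size))
  top <- utils::head(ord, size)
  structure(data.frame(gene = colnames(group1_scores)[top],
                       direction = as.integer(sign(diff[top])),
                       difference = unname(diff[top]),
                       stringsAsFactors = FALSE),
            class = c("gene_signature", "data.frame"))
}

#' Score one cell against a gene-compartment signature
#'
#' Mean over the signature genes scorable in the cell of
#' `direction * gene score`.
#'
#' @param cell_gene_scores named per-gene scores of one cell.
#' @param sig a `gene_signature`.
#' @return real, or `NA` when no signature gene is scorable.
#' @export
signature_score <- function(cell_gene_scores, sig) {
  v <- cell_gene_scores[sig$gene] * sig$direction
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' ROC curve and AUC
#'
#' Threshold-sweep ROC with AUC under the Mann-Whitney tie convention:
#' `AUC = P(score_pos > score_neg) + 0.5 * P(equal)`, computed via midranks
#' (equivalently, the trapezoidal rule on the tied-threshold curve). Cells
#' with missing scores are excluded.
#'
#' @param scores per-cell real scores.
#' @param labels per-cell binary labels (logical, or coercible; `TRUE`/1 is
#'   the positive class).
#' @return list with `curve` (data frame fpr, tpr ordered by threshold) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  list(curve = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)), auc = auc)
}
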