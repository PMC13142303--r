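#' Eigenvector (PC1) compartment caller
#'
#' The conventional compartment caller used as a benchmark: per chromosome,
#' the Pearson correlation matrix of the unmasked rows of the O/E matrix is
#' formed and its first principal component (leading eigenvector) is returned
#' as the per-bin score, rescaled so the maximum absolute score is 1. The
#' sign is oriented by correlation with the GC track when one is given. Rows
#' with zero variance are masked rather than imputed — hiding them would hide
#' exactly the sparsity failure this baseline exhibits at low depth.
#'
#' A track is flagged `incoherent` when more than half of the bins end up
#' masked or when the absolute GC correlation is below 0.1: the PC1 then does
#' not represent a usable A/B axis (at low depth or when other variance
#' components such as chromosome-arm organization dominate).
#'
#' @param oe an `oe_matrix`.
#' @param gc_track optional per-bin GC values for sign orientation.
#' @return a `compartment_track`; attribute-like fields `incoherent` and
#'   `gc_correlation` record the coherence diagnosis.
#' @export
eigenvector_compartments <- function(oe, gc_track = NULL) {
  b <- oe$binning
  score <- rep(NA_real_, n_bins(b))
  if (sum(oe$mask) < 4) {
    warning("fewer than 4 usable bins; returning a fully masked track")
    tr <- compartment_track(b, score)
    tr$incoherent <- TRUE
    return(tr)
  }
  for (ch in b$chrom_names) {
    idx <- chrom_bins(b, ch)
    use <- which(oe$mask[idx])
    if (length(use) < 4) next
    v <- oe$values[[ch]][use, use, drop = FALSE]
    sds <- apply(v, 1, stats::sd, na.rm = TRUE)
    ok <- is.finite(sds) & sds > 0
    if (sum(ok) < 4) next
    v <- v[ok, ok, drop = FALSE]
    # absent distances carry no O/E information; impute the matrix mean so
    # the result is invariant to positive rescaling
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    cc <- stats::cor(t(v))
    ev <- eigen(cc, symmetric = TRUE)
    pc1 <- ev$vectors[, 1]
    score[idx[use[ok]]] <- pc1 / max(abs(pc1))
  }
  tr <- compartment_track(b, score)
  masked_frac <- 1 - mean(tr$mask)
  gc_cor <- NA_real_
  if (!is.null(gc_track) && any(tr$mask)) {
    or <- .orient_track(tr, gc_track, "gc")
    tr <- or$track
    gc_cor <- or$cor
  }
  tr$incoherent <- masked_frac > 0.5 ||
    (!is.na(gc_cor) && gc_cor < 0.1) ||
    !any(tr$mask)
  tr$gc_correlation <- gc_cor
  tr
}
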