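#' Fixed-width genome binning
#'
#' Partition a set of chromosomes into consecutive fixed-width bins. Bins are
#' 0-based half-open intervals `[start, end)`; the last bin of each chromosome
#' may be shorter than `bin_size`. Bins are indexed 1..n_bins in chromosome
#' order; per-chromosome index ranges are contiguous.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names are the chromosome identifiers, order is preserved.
#' @param bin_size bin width in bp.
#' @return an object of class `genome_binning`.
#' @export
genome_binning <- function(chrom_lengths, bin_size) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicate chromosome names")
  bin_size <- as.integer(bin_size)
  stopifnot(bin_size >= 1L, all(chrom_lengths >= 1))
  chroms <- names(chrom_lengths)
  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  starts <- unlist(lapply(nb, function(k) as.numeric(seq_len(k) - 1L) * bin_size),
                   use.names = FALSE)
  chrom <- rep(chroms, nb)
  end <- pmin(starts + bin_size, rep(unname(as.numeric(chrom_lengths)), nb))
  offset <- c(0L, cumsum(nb))[seq_along(chroms)]
  names(offset) <- chroms
  structure(list(
    chrom_names   = chroms,
    chrom_lengths = stats::setNames(as.numeric(chrom_lengths), chroms),
    bin_size      = bin_size,
    bins          = data.frame(chrom = chrom, start = starts, end = end,
                               stringsAsFactors = FALSE),
    n_per_chrom   = stats::setNames(nb, chroms),
    offset        = offset
  ), class = "genome_binning")
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("<genome_binning> %d chromosome(s), bin_size=%d, %d bins\n",
              length(x$chrom_names), x$bin_size, n_bins(x)))
  invisible(x)
}

#' Number of bins in a binning
#' @param binning a `genome_binning`.
#' @return integer bin count.
#' @export
n_bins <- function(binning) nrow(binning$bins)

#' Map genomic positions to bin indices
#'
#' @param binning a `genome_binning`.
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return 1-based global bin index; `NA` for unknown chromosomes or positions
#'   outside the chromosome.
#' @export
bin_index <- function(binning, chrom, pos) {
  off <- binning$offset[chrom]
  len <- binning$chrom_lengths[chrom]
  idx <- off + floor(pos / binning$bin_size) + 1L
  idx[is.na(off) | pos < 0 | pos >= len] <- NA_integer_
  as.integer(unname(idx))
}

#' Global bin indices of one chromosome
#' @param binning a `genome_binning`.
#' @param chrom chromosome name.
#' @return 1-based global indices of the chromosome's bins, in order.
#' @export
chrom_bins <- function(binning, chrom) {
  if (!chrom %in% binning$chrom_names) stop("unknown chromosome: ", chrom)
  binning$offset[[chrom]] + seq_len(binning$n_per_chrom[[chrom]])
}

#' Coarsen a binning
#'
#' @param binning a `genome_binning`.
#' @param new_size new bin width; must be an integer multiple of the current
#'   width.
#' @return a `genome_binning` at `new_size`.
#' @export
coarsen_binning <- function(binning, new_size) {
  if (new_size %% binning$bin_size != 0)
    stop(sprintf("new bin size %d is not a multiple of current %d",
                 new_size, binning$bin_size))
  genome_binning(binning$chrom_lengths, new_size)
}

# map each bin of `fine` to the index of its containing bin in `coarse`
.parent_of <- function(fine, coarse) {
  bin_index(coarse, fine$bins$chrom, fine$bins$start)
}

.same_binning <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    identical(unname(a$chrom_lengths), unname(b$chrom_lengths)) &&
    a$bin_size == b$bin_size
}

# bins overlapped by a 0-based half-open interval; integer(0) if none
.bins_overlapping <- function(binning, chrom, start, end) {
  if (!chrom %in% binning$chrom_names) return(integer(0))
  len <- binning$chrom_lengths[[chrom]]
  s <- max(0, start); e <- min(len, end)
  if (e <= s) return(integer(0))
  first <- floor(s / binning$bin_size)
  last  <- ceiling(e / binning$bin_size) - 1
  binning$offset[[chrom]] + (first:last) + 1L
}
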