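#' Construct a contact matrix
#'
#' A `contact_matrix` stores one symmetric nonnegative sparse count matrix per
#' chromosome (intrachromosomal contacts only), plus optional per-bin
#' balancing weights and a per-bin validity mask. Bins with zero marginal
#' count are masked; a blacklist can mask further bins.
#'
#' @param binning a `genome_binning`.
#' @param counts named list (one entry per chromosome) of symmetric sparse or
#'   dense square matrices of nonnegative counts.
#' @param weights optional per-bin positive balancing factors (global vector,
#'   length `n_bins(binning)`).
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(binning, counts, weights = NULL) {
  stopifnot(inherits(binning, "genome_binning"))
  counts <- lapply(binning$chrom_names, function(ch) {
    m <- counts[[ch]]
    nb <- binning$n_per_chrom[[ch]]
    if (is.null(m)) m <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              x = numeric(0), dims = c(nb, nb))
    m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
    if (!isTRUE(all.equal(dim(m), c(nb, nb))))
      stop("counts dimension mismatch on ", ch)
    if (max(abs(m - Matrix::t(m))) > 0) stop("counts not symmetric on ", ch)
    m
  })
  names(counts) <- binning$chrom_names
  if (!is.null(weights)) stopifnot(length(weights) == n_bins(binning),
                                   all(weights[!is.na(weights)] > 0))
  obj <- structure(list(binning = binning, counts = counts,
                        weights = weights, mask = NULL),
                   class = "contact_matrix")
  obj$mask <- .coverage_mask(obj)
  obj
}

# TRUE for bins with nonzero marginal
.coverage_mask <- function(m) {
  unlist(lapply(m$binning$chrom_names, function(ch) {
    Matrix::rowSums(m$counts[[ch]]) > 0
  }), use.names = FALSE)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d chromosome(s) at %d bp, %s contacts, %d/%d bins valid\n",
              length(x$binning$chrom_names), x$binning$bin_size,
              format(total_contacts(x), big.mark = ","),
              sum(x$mask), n_bins(x$binning)))
  invisible(x)
}

#' Total contact count
#'
#' Counts each unordered pair once (upper triangle plus diagonal).
#' @param m a `contact_matrix`.
#' @return numeric total.
#' @export
total_contacts <- function(m) {
  sum(vapply(m$counts, function(cm) {
    (sum(cm) + sum(Matrix::diag(cm))) / 2
  }, numeric(1)))
}

#' Mask bins falling in a blacklist
#'
#' @param m a `contact_matrix`.
#' @param blacklist data frame with columns chrom, start, end (0-based
#'   half-open), e.g. from [read_bed()].
#' @return the matrix with additional bins masked.
#' @export
mask_blacklist <- function(m, blacklist) {
  for (k in seq_len(nrow(blacklist))) {
    idx <- .bins_overlapping(m$binning, blacklist$chrom[k],
                             blacklist$start[k], blacklist$end[k])
    m$mask[idx] <- FALSE
  }
  m
}

#' Aggregate a contact matrix to a coarser bin size
#'
#' Sums counts of child bins into their containing parent bins. Total contact
#' count is conserved.
#'
#' @param m a `contact_matrix`.
#' @param new_size coarser bin size, an integer multiple of the current one.
#' @return a `contact_matrix` at `new_size`.
#' @export
aggregate_contacts <- function(m, new_size) {
  if (new_size == m$binning$bin_size) return(m)
  coarse <- coarsen_binning(m$binning, new_size)
  fac <- as.integer(new_size / m$binning$bin_size)
  counts <- lapply(m$binning$chrom_names, function(ch) {
    cm <- m$counts[[ch]]
    nb <- coarse$n_per_chrom[[ch]]
    grp <- (seq_len(nrow(cm)) - 1L) %/% fac + 1L
    tm <- Matrix::sparseMatrix(i = grp, j = seq_along(grp), x = 1,
                               dims = c(nb, length(grp)))
    agg <- tm %*% cm %*% Matrix::t(tm)
    # the block sum counts each within-parent unordered pair twice but child
    # self-contacts once; restore the one-entry-per-contact diagonal
    child_diag <- as.vector(tm %*% Matrix::diag(cm))
    Matrix::diag(agg) <- (Matrix::diag(agg) + child_diag) / 2
    agg
  })
  names(counts) <- m$binning$chrom_names
  out <- contact_matrix(coarse, counts)
  # carry blacklist-style masking up: a parent is masked only if all children are
  child_mask <- m$mask
  par <- .parent_of(m$binning, coarse)
  any_valid <- tapply(child_mask, par, any)
  extra <- rep(TRUE, n_bins(coarse))
  extra[as.integer(names(any_valid))] <- as.logical(any_valid)
  out$mask <- out$mask & extra
  out
}

#' Binomially downsample a contact matrix
#'
#' Thins each pair count with the given retention probability, keeping the
#' matrix symmetric. Deterministic given `seed`.
#'
#' @param m a `contact_matrix`.
#' @param fraction retention probability in (0, 1].
#' @param seed integer RNG seed.
#' @return a thinned `contact_matrix`.
#' @export
downsample_contacts <- function(m, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(m)
  set.seed(as.integer(seed))
  counts <- lapply(m$binning$chrom_names, function(ch) {
    tr <- .upper_triples(m$counts[[ch]])
    if (nrow(tr) == 0) return(m$counts[[ch]])
    kept <- stats::rbinom(nrow(tr), size = as.integer(tr$x), prob = fraction)
    .sym_from_triples(tr$i, tr$j, kept, nrow(m$counts[[ch]]))
  })
  names(counts) <- m$binning$chrom_names
  contact_matrix(m$binning, counts, weights = m$weights)
}

# upper-triangle (i <= j) triples of a sparse matrix
.upper_triples <- function(cm) {
  tm <- methods::as(methods::as(cm, "TsparseMatrix"), "generalMatrix")
  keep <- tm@i <= tm@j
  data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, x = tm@x[keep])
}

# symmetric sparse matrix from upper-triangle triples
.sym_from_triples <- function(i, j, x, n) {
  keep <- x != 0
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  off <- i != j
  Matrix::sparseMatrix(i = c(i, j[off]), j = c(j, i[off]), x = c(x, x[off]),
                       dims = c(n, n))
}
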