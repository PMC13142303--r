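#' Read contacts from a pairs file
#'
#' Reads a 4-column tab- or space-separated pairs file (chrom1, pos1, chrom2,
#' pos2; one contact per line; positions 1-based as in the pairs-file
#' convention; optionally gzipped) into a per-chromosome symmetric contact
#' matrix. Interchromosomal pairs and pairs on chromosomes absent from the
#' binning are dropped with a message reporting how many.
#'
#' @param path pairs file path.
#' @param binning a `genome_binning` defining chromosomes and bin size.
#' @return a `contact_matrix`.
#' @export
read_pairs <- function(path, binning) {
  if (!file.exists(path)) stop("cannot read pairs file: ", path)
  dt <- .fread_pairs(path)
  if (nrow(dt) == 0) stop("empty pairs file: ", path)
  known <- dt$chrom1 %in% binning$chrom_names & dt$chrom2 %in% binning$chrom_names
  if (any(!known))
    message(sum(!known), " pair(s) on unknown chromosomes dropped")
  dt <- dt[known, ]
  intra <- dt$chrom1 == dt$chrom2
  if (any(!intra))
    message(sum(!intra), " interchromosomal pair(s) dropped")
  dt <- dt[intra, ]
  # pairs positions are 1-based; bins are 0-based half-open
  counts <- lapply(binning$chrom_names, function(ch) {
    sel <- dt$chrom1 == ch
    nb <- binning$n_per_chrom[[ch]]
    if (!any(sel))
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(nb, nb)))
    loc <- binning$offset[[ch]]
    b1 <- bin_index(binning, ch, dt$pos1[sel] - 1) - loc
    b2 <- bin_index(binning, ch, dt$pos2[sel] - 1) - loc
    ok <- !is.na(b1) & !is.na(b2)
    if (any(!ok)) message(sum(!ok), " pair(s) beyond chromosome end dropped")
    b1 <- b1[ok]; b2 <- b2[ok]
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    agg <- stats::aggregate(list(x = rep(1, length(lo))),
                            by = list(i = lo, j = hi), FUN = sum)
    .sym_from_triples(agg$i, agg$j, agg$x, nb)
  })
  names(counts) <- binning$chrom_names
  contact_matrix(binning, counts)
}

# fread a 4-column pairs file, decompressing .gz through a connection
.fread_pairs <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), header = FALSE, sep = "auto",
                      col.names = c("chrom1", "pos1", "chrom2", "pos2"),
                      colClasses = list(character = c(1, 3)))
  } else {
    data.table::fread(path, header = FALSE, sep = "auto",
                      col.names = c("chrom1", "pos1", "chrom2", "pos2"),
                      colClasses = list(character = c(1, 3)))
  }
}

#' Write contacts as a pairs file
#'
#' Each unordered pair is written `count` times as one line per contact, with
#' 1-based positions at the bin start. `read_pairs()` of the output restores
#' the same nonzero triples.
#'
#' @param m a `contact_matrix`.
#' @param path output path (".gz" suffix gzips).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(m, path) {
  rows <- lapply(m$binning$chrom_names, function(ch) {
    tr <- .upper_triples(m$counts[[ch]])
    if (nrow(tr) == 0) return(NULL)
    starts <- m$binning$bins$start[chrom_bins(m$binning, ch)]
    idx <- rep(seq_len(nrow(tr)), times = as.integer(tr$x))
    data.table::data.table(chrom1 = ch, pos1 = starts[tr$i[idx]] + 1,
                           chrom2 = ch, pos2 = starts[tr$j[idx]] + 1)
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a binned contact matrix from bin-pair triples
#'
#' Text alternative to binned HDF5 matrices: a header line
#' `# bin_size=<bp>` followed by tab-separated `chrom bin1 bin2 count`
#' records with 0-based per-chromosome bin indices (upper triangle
#' sufficient). An optional `# weights` section may follow, giving per-bin
#' balancing factors as `chrom bin weight`.
#'
#' @param path triples file path.
#' @param binning a `genome_binning`; its bin size must match the file header.
#' @return a `contact_matrix`.
#' @export
read_triples <- function(path, binning) {
  if (!file.exists(path)) stop("cannot read matrix file: ", path)
  lines <- readLines(path)
  hdr <- grep("^# *bin_size=", lines, value = TRUE)
  if (length(hdr) != 1) stop("missing '# bin_size=' header in ", path)
  bs <- as.integer(sub("^# *bin_size=", "", hdr))
  if (bs != binning$bin_size)
    stop(sprintf("bin size mismatch: file has %d, binning has %d",
                 bs, binning$bin_size))
  wstart <- grep("^# *weights", lines)
  body <- lines[!startsWith(lines, "#")]
  if (length(wstart) == 1) {
    nbefore <- sum(!startsWith(lines[seq_len(wstart)], "#"))
    wlines <- body[seq_along(body) > nbefore]
    body <- body[seq_len(nbefore)]
  } else wlines <- character(0)
  dt <- data.table::fread(text = body, header = FALSE,
                          col.names = c("chrom", "bin1", "bin2", "count"))
  counts <- lapply(binning$chrom_names, function(ch) {
    sel <- dt$chrom == ch
    nb <- binning$n_per_chrom[[ch]]
    if (!any(sel))
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(nb, nb)))
    lo <- pmin(dt$bin1[sel], dt$bin2[sel]) + 1L
    hi <- pmax(dt$bin1[sel], dt$bin2[sel]) + 1L
    if (any(hi > nb)) stop("bin index beyond chromosome end in ", path)
    .sym_from_triples(lo, hi, dt$count[sel], nb)
  })
  names(counts) <- binning$chrom_names
  weights <- NULL
  if (length(wlines) > 0) {
    wd <- data.table::fread(text = wlines, header = FALSE,
                            col.names = c("chrom", "bin", "weight"))
    weights <- rep(NA_real_, n_bins(binning))
    weights[binning$offset[wd$chrom] + wd$bin + 1L] <- wd$weight
  }
  contact_matrix(binning, counts, weights = weights)
}

#' Write a binned contact matrix as bin-pair triples
#'
#' @param m a `contact_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triples <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_size=%d", m$binning$bin_size), con)
  for (ch in m$binning$chrom_names) {
    tr <- .upper_triples(m$counts[[ch]])
    if (nrow(tr) == 0) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, tr$i - 1L, tr$j - 1L,
                       format(tr$x, scientific = FALSE, trim = TRUE)), con)
  }
  if (!is.null(m$weights)) {
    writeLines("# weights", con)
    ok <- which(!is.na(m$weights))
    ch <- m$binning$bins$chrom[ok]
    writeLines(sprintf("%s\t%d\t%.17g", ch, ok - m$binning$offset[ch] - 1L,
                       m$weights[ok]), con)
  }
  invisible(path)
}

#' Read contacts, dispatching on file content
#'
#' Files starting with a `# bin_size=` header are parsed as bin-pair triples
#' ([read_triples()]); anything else as a 4-column pairs file
#' ([read_pairs()]).
#'
#' @param path input path.
#' @param binning a `genome_binning`.
#' @return a `contact_matrix`.
#' @export
read_contacts <- function(path, binning) {
  if (!file.exists(path)) stop("cannot read contacts file: ", path)
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, n = 1)
  if (length(first) > 0 && grepl("^# *bin_size=", first))
    read_triples(path, binning)
  else
    read_pairs(path, binning)
}

#' Read a BED file
#'
#' @param path BED path (>= 3 columns; 0-based half-open). Column 4 is taken
#'   as `name`, column 6 as `strand` when present.
#' @return data frame with columns chrom, start, end and optionally name,
#'   strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  dt <- data.table::fread(path, header = FALSE)
  out <- data.frame(chrom = as.character(dt[[1]]), start = dt[[2]],
                    end = dt[[3]], stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 6) out$strand <- as.character(dt[[6]])
  out
}

#' Expected contact count by genomic distance
#'
#' For each chromosome, the expected count at bin distance d is the arithmetic
#' mean of counts over all unmasked pairs (i, j) with |i - j| = d. Distances
#' with no unmasked pair are `NA` (absent). When the matrix carries balancing
#' weights and `use_weights = TRUE`, counts are weighted by `w_i * w_j` first.
#'
#' Setting `n_bands` pools distances into that many log-spaced bands and
#' assigns each band's mean to all its distances; this is the variant used for
#' sparse per-cell maps where individual diagonals are empty.
#'
#' @param m a `contact_matrix`.
#' @param use_weights apply balancing weights if present.
#' @param n_bands optional number of log-spaced distance bands.
#' @return named list per chromosome of expected values indexed by distance
#'   `0..(nbins-1)` (element d+1 is distance d).
#' @export
expected_by_distance <- function(m, use_weights = !is.null(m$weights),
                                 n_bands = NULL) {
  if (!any(m$mask)) stop("all bins are masked")
  out <- lapply(m$binning$chrom_names, function(ch) {
    idx <- chrom_bins(m$binning, ch)
    msk <- m$mask[idx]
    n <- length(idx)
    cm <- as.matrix(m$counts[[ch]])
    if (use_weights && !is.null(m$weights)) {
      w <- m$weights[idx]
      w[is.na(w)] <- 0
      cm <- cm * outer(w, w)
    }
    valid <- outer(msk, msk, "&")
    d <- abs(row(cm) - col(cm))
    sums <- rep(0, n); cnts <- rep(0, n)
    tab_s <- tapply(cm[valid], d[valid], sum)
    tab_c <- table(d[valid])
    dd <- as.integer(names(tab_s))
    sums[dd + 1L] <- as.numeric(tab_s)
    cnts[dd + 1L] <- as.numeric(tab_c)
    exp_d <- ifelse(cnts > 0, sums / cnts, NA_real_)
    if (!is.null(n_bands)) {
      band <- .distance_bands(n, n_bands)
      bs <- tapply(sums, band, sum)
      bc <- tapply(cnts, band, sum)
      bmean <- ifelse(bc > 0, bs / bc, NA_real_)
      exp_d <- as.numeric(bmean[as.character(band)])
      exp_d[cnts == 0 & is.na(exp_d)] <- NA_real_
    }
    exp_d
  })
  names(out) <- m$binning$chrom_names
  out
}

# log-spaced band id for distances 0..(n-1)
.distance_bands <- function(n, n_bands) {
  d <- 0:(n - 1)
  edges <- unique(round(exp(seq(0, log(max(1, n - 1)), length.out = n_bands + 1))))
  band <- findInterval(d, edges, rightmost.closed = TRUE)
  band[d == 0] <- 0L
  band
}

#' Observed/expected contact matrix
#'
#' Divides each count by the expected count at its genomic distance, removing
#' the polymer distance-decay background. Entries at absent distances or
#' touching masked bins are `NA`. By construction the mean of unmasked values
#' on every represented diagonal is 1 (exactly so without distance banding).
#'
#' @inheritParams expected_by_distance
#' @return an object of class `oe_matrix`: list with `binning`, per-chromosome
#'   dense `values` (NA = masked/absent), and per-bin `mask`.
#' @export
observed_over_expected <- function(m, use_weights = !is.null(m$weights),
                                   n_bands = NULL) {
  expd <- expected_by_distance(m, use_weights = use_weights, n_bands = n_bands)
  values <- lapply(m$binning$chrom_names, function(ch) {
    idx <- chrom_bins(m$binning, ch)
    msk <- m$mask[idx]
    cm <- as.matrix(m$counts[[ch]])
    if (use_weights && !is.null(m$weights)) {
      w <- m$weights[idx]
      w[is.na(w)] <- 0
      cm <- cm * outer(w, w)
    }
    d <- abs(row(cm) - col(cm))
    e <- expd[[ch]][d + 1L]
    v <- cm / e
    v[!outer(msk, msk, "&")] <- NA_real_
    dim(v) <- dim(cm)
    v
  })
  names(values) <- m$binning$chrom_names
  structure(list(binning = m$binning, values = values, mask = m$mask,
                 expected = expd),
            class = "oe_matrix")
}

#' @export
print.oe_matrix <- function(x, ...) {
  cat(sprintf("<oe_matrix> %d chromosome(s) at %d bp, %d/%d bins valid\n",
              length(x$binning$chrom_names), x$binning$bin_size,
              sum(x$mask), n_bins(x$binning)))
  invisible(x)
}
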