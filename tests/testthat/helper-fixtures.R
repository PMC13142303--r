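# Shared fixtures, computed once per test run and memoised.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# the default study map: one 10 Mb chromosome at 25 kb, plaid blocks of
# geometric mean length 10 bins, affinity 2, deep (1e7) sampling
dense_spec <- function() memo("dense_spec",
  synthetic_map_spec(n_bins = 400, bin_size = 25000, depth = 1e7,
                     affinity = 2, seed = 5))

dense_map <- function() memo("dense_map", sample_bulk(dense_spec()))

dense_gc <- function() memo("dense_gc", simulated_gc_track(dense_spec()))

test_ladder <- function() c(250000, 50000, 25000)

dense_tracks <- function() memo("dense_tracks",
  call_compartments(dense_map(), caller_config(resolution_ladder = test_ladder()),
                    gc_track = dense_gc()))

# hand-built O/E object on a small binning in which the focal bin's row has
# value `a_val` against every A-reference bin and `b_val` against every
# B-reference bin (other entries 1), with constant expected counts
flat_oe <- function(n = 30, focal = 1, a_val = 1.5, b_val = 0.5, e_val = 1e6,
                    a_bins = seq(3, n, 2), b_bins = seq(4, n, 2)) {
  b <- genome_binning(c(chrT = n * 1000), 1000)
  v <- matrix(1, n, n)
  v[focal, a_bins] <- a_val; v[a_bins, focal] <- a_val
  v[focal, b_bins] <- b_val; v[b_bins, focal] <- b_val
  diag(v) <- 0
  structure(list(binning = b, values = list(chrT = v),
                 mask = rep(TRUE, n),
                 expected = list(chrT = rep(e_val, n))),
            class = "oe_matrix")
}

# a contact matrix built from an explicit dense symmetric count matrix
cm_from_dense <- function(mat, bin_size = 1000, chrom = "chrT") {
  b <- genome_binning(stats::setNames(nrow(mat) * bin_size, chrom), bin_size)
  contact_matrix(b, stats::setNames(list(mat), chrom))
}

# quick single-chromosome track from a score vector
track_from_scores <- function(score, bin_size = 1000, chrom = "chrT") {
  b <- genome_binning(stats::setNames(length(score) * bin_size, chrom), bin_size)
  compartment_track(b, score)
}

bins_as_intervals <- function(bins, binning) {
  data.frame(chrom = binning$bins$chrom[bins],
             start = binning$bins$start[bins],
             end = binning$bins$end[bins])
}

# Two-population single-cell fixtures: one 20 Mb chromosome at 25 kb, a
# quarter of the bins block-shifted between populations, 50k contacts/cell.
sc_spec1 <- function() memo("sc_spec1", {
  s <- synthetic_map_spec(n_bins = 800, bin_size = 25000, depth = 2e6,
                          affinity = 2, seed = 30)
  s$condition_shift <- sample_block_shift(s, frac = 0.25, seed = 30)
  s
})
sc_spec2 <- function() memo("sc_spec2", apply_condition_shift(sc_spec1()))
sc_gc <- function() memo("sc_gc", simulated_gc_track(sc_spec1()))
sc_genes <- function() memo("sc_genes", {
  b <- sc_spec1()$binning
  data.frame(chrom = b$bins$chrom, start = b$bins$start, end = b$bins$end,
             name = sprintf("g%03d", seq_len(n_bins(b))))
})
sc_cells <- function(pop, n) memo(sprintf("sc_cells_%d_%d", pop, n), {
  spec <- if (pop == 1) sc_spec1() else sc_spec2()
  sample_cells(spec, n, 50000, ids = sprintf("p%d_c%02d", pop, seq_len(n)))
})
sc_tracks <- function(pop, n) memo(sprintf("sc_tracks_%d_%d", pop, n), {
  lapply(sc_cells(pop, n), call_compartments_cell, sc_spec1()$binning, sc_gc(),
         caller_config())
})

# Two-condition bulk fixture: 15% of bins block-shifted, deep maps
reg_set <- function() memo("reg_set", {
  s1 <- synthetic_map_spec(n_bins = 400, bin_size = 25000, depth = 2e6,
                           affinity = 2, seed = 19)
  s1$condition_shift <- sample_block_shift(s1, frac = 0.15, seed = 19)
  s2 <- apply_condition_shift(s1)
  gc <- simulated_gc_track(s1)
  cfg <- caller_config(resolution_ladder = test_ladder())
  t1 <- call_compartments(sample_bulk(s1), cfg, gc_track = gc)[["25000"]]
  t2 <- call_compartments(sample_bulk(s2), cfg, gc_track = gc)[["25000"]]
  list(spec1 = s1, spec2 = s2, raw1 = t1, raw2 = t2,
       set = condition_track_set(list(c1 = t1, c2 = t2)))
})
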