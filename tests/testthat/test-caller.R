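test_that("GC initialization splits at the chromosome median, ties to B", {
  oe <- flat_oe(n = 4)
  refs <- initialize_labels(oe, c(0.6, 0.3, 0.7, 0.2))
  expect_equal(refs$a_bins, c(1L, 3L))
  expect_equal(refs$b_bins, c(2L, 4L))
  expect_error(initialize_labels(oe, rep(0.5, 4)), "degenerate")
})

test_that("eigenvector initialization agrees with planted labels on a coarse map", {
  spec <- synthetic_map_spec(n_bins = 400, bin_size = 25000, depth = 1e6,
                             affinity = 2, seed = 3)
  mc <- aggregate_contacts(sample_bulk(spec), 250000)
  refs <- initialize_labels(observed_over_expected(mc))
  lab <- rep(0L, n_bins(mc$binning))
  lab[refs$a_bins] <- 1L; lab[refs$b_bins] <- -1L
  tr <- compartment_track(mc$binning, ifelse(lab == 0, NA, as.numeric(lab)))
  expect_gte(label_accuracy(tr, spec), 0.8)   # up to global sign
})

test_that("preference score is the forced contrast of reference means", {
  oe <- flat_oe(n = 40, focal = 1, a_val = 1.5, b_val = 0.5)
  expect_equal(preference_score(oe, reference_sets(seq(3, 40, 2), seq(4, 40, 2)),
                                1, min_distance_bins = 1), 0.5,
               tolerance = 1e-5)
  oe2 <- flat_oe(n = 40, focal = 1, a_val = 0.8, b_val = 0.8)
  expect_equal(preference_score(oe2, reference_sets(seq(3, 40, 2), seq(4, 40, 2)),
                                1, min_distance_bins = 1), 0,
               tolerance = 1e-12)
  # masked focal bin and empty-after-exclusion references are invalid, not 0
  oe$mask[1] <- FALSE
  expect_true(is.na(preference_score(oe, reference_sets(seq(3, 40, 2), seq(4, 40, 2)), 1)))
  oe3 <- flat_oe(n = 40)
  expect_true(is.na(preference_score(oe3, reference_sets(2, 3), 1,
                                     min_distance_bins = 10)))
})

test_that("short-range exclusion removes the focal bin's neighborhood", {
  # references only inside the exclusion radius leave nothing to score against
  oe <- flat_oe(n = 40, focal = 20)
  expect_true(is.na(preference_score(oe, reference_sets(c(19, 21), c(18, 22)),
                                     20, min_distance_bins = 5)))
  expect_false(is.na(preference_score(oe, reference_sets(c(19, 21, 1), c(18, 22, 40)),
                                      20, min_distance_bins = 5)))
})

test_that("planted A bins score positive and B bins negative on a dense map", {
  spec <- synthetic_map_spec(n_bins = 200, bin_size = 25000, depth = 5e6,
                             affinity = 2, seed = 11)
  oe <- observed_over_expected(sample_bulk(spec))
  refs <- reference_sets(which(spec$labels == 1L), which(spec$labels == -1L))
  sc <- vapply(seq_len(200), function(i) preference_score(oe, refs, i), numeric(1))
  expect_gt(mean(sc[spec$labels == 1L], na.rm = TRUE), 0)
  expect_lt(mean(sc[spec$labels == -1L], na.rm = TRUE), 0)
})

test_that("refinement is a fixed point on a noiseless plaid sign pattern", {
  spec <- synthetic_map_spec(n_bins = 60, bin_size = 25000, depth = 1,
                             affinity = 2, seed = 1)
  p <- contact_probabilities(spec)$chrS * 1e6   # noiseless expected counts
  m <- cm_from_dense(p, bin_size = 25000, chrom = "chrS")
  oe <- observed_over_expected(m)
  refs <- reference_sets(which(spec$labels == 1L), which(spec$labels == -1L))
  rr <- refine_labels(oe, refs, caller_config())
  expect_equal(max(rr$iterations), 1)          # converged in one pass
  expect_equal(label_accuracy(rr$track, spec), 1)  # labels unchanged
})

test_that("refinement recovers planted labels from a corrupted initialization", {
  spec <- synthetic_map_spec(n_bins = 400, bin_size = 25000, depth = 1e6,
                             affinity = 2, seed = 5)
  oe <- observed_over_expected(sample_bulk(spec))
  set.seed(5)
  lab <- spec$labels
  flip <- sample(400, 80)                      # corrupt 20%
  lab[flip] <- -lab[flip]
  rr <- refine_labels(oe, reference_sets(which(lab == 1L), which(lab == -1L)),
                      caller_config(), gc_track = simulated_gc_track(spec))
  expect_gte(label_accuracy(rr$track, spec), 0.99)
})

test_that("refinement always terminates within max_iter", {
  spec <- synthetic_map_spec(n_bins = 100, bin_size = 25000, depth = 2e4,
                             affinity = 1.2, seed = 9)
  oe <- observed_over_expected(sample_bulk(spec))
  cfg <- caller_config(max_iter = 7)
  rr <- refine_labels(oe, reference_sets(which(spec$labels == 1L),
                                         which(spec$labels == -1L)), cfg)
  expect_lte(max(rr$iterations), 7)
})

test_that("a global sign flip of the initialization yields the same track", {
  spec <- synthetic_map_spec(n_bins = 200, bin_size = 25000, depth = 1e6,
                             affinity = 2, seed = 21)
  oe <- observed_over_expected(sample_bulk(spec))
  gc <- simulated_gc_track(spec)
  r1 <- refine_labels(oe, reference_sets(which(spec$labels == 1L),
                                         which(spec$labels == -1L)),
                      caller_config(), gc_track = gc)
  r2 <- refine_labels(oe, reference_sets(which(spec$labels == -1L),
                                         which(spec$labels == 1L)),
                      caller_config(), gc_track = gc)
  expect_equal(r1$track$score, r2$track$score, tolerance = 1e-12)
})

test_that("GC-oriented tracks correlate nonnegatively with GC", {
  tr <- dense_tracks()[["25000"]]
  gc <- dense_gc()
  expect_gte(stats::cor(tr$score[tr$mask], gc[tr$mask]), 0)
  expect_equal(tr$orientation_source, "gc")
})

test_that("cascade keeps a consistent sign pattern on a dense noiseless map", {
  # aperiodic blocks aligned to the coarse rung (strictly periodic blocks
  # would be absorbed entirely by the distance normalization)
  pat <- c(1L, 1L, -1L, 1L, -1L, -1L, 1L, -1L, 1L, 1L, -1L, -1L)
  spec <- synthetic_map_spec(n_bins = 120, bin_size = 25000, depth = 1,
                             labels = rep(pat, each = 10),
                             affinity = 2, seed = 1)
  p <- contact_probabilities(spec)$chrS * 1e7
  m <- cm_from_dense(round(p), bin_size = 25000, chrom = "chrS")
  tracks <- call_compartments(m, caller_config(resolution_ladder = c(250000, 50000, 25000)),
                              gc_track = simulated_gc_track(spec))
  # blocks are 250 kb: every rung must show the same 10-bin-periodic pattern
  for (res in names(tracks)) expect_equal(label_accuracy(tracks[[res]], spec), 1)
})

test_that("the fine rung resolves blocks the coarse rung cannot represent", {
  # alternating 50 kb and 25 kb blocks are invisible at 250 kb
  lab <- rep(c(1L, 1L, -1L, 1L, -1L, -1L), length.out = 400)
  spec <- synthetic_map_spec(n_bins = 400, bin_size = 25000, depth = 5e6,
                             labels = lab, affinity = 2, seed = 9)
  tracks <- call_compartments(sample_bulk(spec),
                              caller_config(resolution_ladder = test_ladder()),
                              gc_track = simulated_gc_track(spec))
  expect_gte(label_accuracy(tracks[["25000"]], spec), 0.95)
  # the coarse rung, projected back to fine bins, cannot represent them
  proj <- abcall:::.project_track(tracks[["250000"]], spec$binning)
  expect_lt(label_accuracy(proj, spec), 0.9)
})

test_that("inherited fraction grows monotonically at low depth", {
  spec <- dense_spec()
  m <- downsample_contacts(dense_map(), 1e-4, seed = 2)   # ~1e3 contacts
  # at this depth fine rungs legitimately warn that they only inherit
  tracks <- suppressWarnings(
    call_compartments(m, caller_config(resolution_ladder = test_ladder()),
                      gc_track = dense_gc()))
  inh <- vapply(tracks, function(t) mean(t$inherited[t$mask]), numeric(1))
  expect_true(all(diff(inh) >= 0))
  expect_gt(inh[["25000"]], 0.5)              # fine rungs mostly inherited
})

test_that("recovery accuracy degrades monotonically with depth (3 seeds)", {
  cfg <- caller_config(resolution_ladder = test_ladder())
  for (sd in 1:3) {
    spec <- synthetic_map_spec(n_bins = 400, bin_size = 25000, depth = 1e7,
                               affinity = 2, seed = sd)
    m <- sample_bulk(spec)
    gc <- simulated_gc_track(spec)
    accs <- vapply(c(1, 0.1, 0.01, 0.001), function(f) {
      md <- if (f == 1) m else downsample_contacts(m, f, seed = sd + 10)
      label_accuracy(call_compartments(md, cfg, gc_track = gc)[["25000"]], spec)
    }, numeric(1))
    expect_true(all(diff(accs) <= 0.02))       # nonincreasing within MC noise
  }
})

test_that("caller hard labels match PC1 signs on dense noiseless plaid maps", {
  for (sd in c(1, 2)) {
    spec <- synthetic_map_spec(n_bins = 150, bin_size = 25000, depth = 1,
                               affinity = 2, seed = sd)
    p <- contact_probabilities(spec)$chrS * 1e7
    m <- cm_from_dense(p, bin_size = 25000, chrom = "chrS")
    oe <- observed_over_expected(m)
    gc <- simulated_gc_track(spec)
    pc <- eigenvector_compartments(oe, gc)
    rr <- refine_labels(oe, initialize_labels(oe, gc), caller_config(),
                        gc_track = gc)
    ok <- pc$mask & rr$track$mask & sign(pc$score) != 0
    agree <- mean(sign(pc$score[ok]) == sign(rr$track$score[ok]))
    expect_gte(max(agree, 1 - agree), 0.99)
  }
})

test_that("IQR normalization matches the quantile oracle and is affine-invariant", {
  tr <- track_from_scores(c(-1, 0, 0, 1))
  out <- iqr_normalize(tr)
  # mid-interpolation (type 5) quantiles: q25 = -0.5, q75 = 0.5, IQR = 1
  expect_equal(stats::quantile(c(-1, 0, 0, 1), c(0.25, 0.75), type = 5,
                               names = FALSE), c(-0.5, 0.5))
  expect_equal(out$score, c(-1, 0, 0, 1))

  set.seed(2)
  x <- rnorm(100)
  t1 <- iqr_normalize(track_from_scores(x))
  q <- stats::quantile(t1$score, c(0.25, 0.5, 0.75), type = 5, names = FALSE)
  expect_equal(q[2], 0, tolerance = 1e-12)    # median 0
  expect_equal(q[3] - q[1], 1, tolerance = 1e-12)  # IQR 1
  t2 <- iqr_normalize(track_from_scores(3.7 * x - 2.2))
  expect_equal(t2$score, t1$score, tolerance = 1e-12)  # affine invariance
  expect_error(iqr_normalize(track_from_scores(rep(c(1, 1, 1, 1, 2), 4))))
  expect_error(iqr_normalize(track_from_scores(rep(2, 10))), "degenerate|IQR")
})
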