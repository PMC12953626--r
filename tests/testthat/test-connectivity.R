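test_that("dbWPLI reproduces the hand-computed and degenerate cases", {
  expect_equal(dbwpli(rep(0.7, 2)), 1)     # constant lag, any n
  expect_equal(dbwpli(rep(-0.2, 9)), 1)
  expect_equal(dbwpli(c(0, 0, 0)), 0)      # zero-denominator convention
  expect_equal(dbwpli(c(1, -1)), -1)       # ((0)^2 - 2) / ((2)^2 - 2)
  expect_error(dbwpli(1), "at least 2")
  expect_error(dbwpli(c(1, NA)), "non-finite")
})

test_that("per-bin |dbWPLI| never exceeds 1 on random inputs", {
  set.seed(1)
  for (i in 1:200) {
    I <- rnorm(sample(2:40, 1), sd = runif(1, 0.1, 10))
    expect_lte(abs(dbwpli(I)), 1 + 1e-12)
  }
})

test_that("independent channels give near-zero dbWPLI that shrinks with n", {
  set.seed(2)
  null_mean <- function(n_ep, reps = 30) {
    mean(vapply(seq_len(reps), function(r) {
      I <- Im(complex(real = rnorm(n_ep), imaginary = rnorm(n_ep)) *
                Conj(complex(real = rnorm(n_ep), imaginary = rnorm(n_ep))))
      abs(dbwpli(I))
    }, numeric(1)))
  }
  m50 <- null_mean(50)
  m500 <- null_mean(500)
  expect_lt(m500, m50)        # debiasing: null level decreases with epochs
  expect_lt(m500, 0.05)
})

test_that("band scores are scale invariant and orientation invariant", {
  set.seed(3)
  coef <- random_coef(40, 3, 10)
  sp <- make_spectra(coef, freqs = 0:9, channels = c("a", "b", "c"))
  band <- band_spec("theta", 3, 5)
  s_ab <- band_dbwpli(sp, c("a", "b"), band)
  # scaling either channel by a positive constant changes nothing
  coef2 <- coef; coef2[, 1, ] <- coef2[, 1, ] * 37.5
  sp2 <- make_spectra(coef2, freqs = 0:9, channels = c("a", "b", "c"))
  expect_equal(band_dbwpli(sp2, c("a", "b"), band), s_ab, tolerance = 1e-12)
  # pair orientation is irrelevant after the absolute value
  expect_equal(band_dbwpli(sp, c("b", "a"), band), s_ab, tolerance = 1e-12)
})

test_that("band averaging matches the per-bin oracle and the bin grid", {
  set.seed(4)
  coef <- random_coef(60, 2, 11)
  sp <- make_spectra(coef, freqs = 0:10, channels = c("a", "b"))
  # single-bin band equals |dbwpli| at that bin
  I4 <- Im(coef[, 1, 5] * Conj(coef[, 2, 5]))  # 4 Hz is index 5 of 0:10
  expect_equal(band_dbwpli(sp, c("a", "b"), band_spec("x", 4, 4)),
               abs(dbwpli(I4)))
  # theta band = mean over bins {3,4,5} of |dbwpli|, computed independently
  per_bin <- vapply(c(3, 4, 5), function(f) {
    abs(dbwpli(Im(coef[, 1, f + 1] * Conj(coef[, 2, f + 1]))))
  }, numeric(1))
  expect_equal(band_dbwpli(sp, c("a", "b"), band_spec("theta", 3, 5)),
               mean(per_bin))
  # signed-first averaging option
  per_bin_s <- vapply(c(3, 4, 5), function(f) {
    dbwpli(Im(coef[, 1, f + 1] * Conj(coef[, 2, f + 1])))
  }, numeric(1))
  expect_equal(band_dbwpli(sp, c("a", "b"), band_spec("theta", 3, 5),
                           abs_first = FALSE), abs(mean(per_bin_s)))
  expect_error(band_dbwpli(sp, c("a", "b"), band_spec("hi", 20, 60)), "bins")
})

test_that("a constant 45-degree lag at 4 Hz drives the theta band score", {
  fs <- 200
  set.seed(5)
  t <- (0:(60 * fs - 1)) / fs
  # stochastic-amplitude 4 Hz carrier plus small noise; y lags x by 45 degrees
  env <- stats::filter(rnorm(length(t)), 0.995, method = "recursive")
  x <- env * cos(2 * pi * 4 * t) + rnorm(length(t), 0, 0.05)
  y <- env * cos(2 * pi * 4 * t - pi / 4) + rnorm(length(t), 0, 0.05)
  rec <- continuous_recording(rbind(x = x, y = y), fs = fs)
  sp <- compute_spectra(rec, segment_epochs(rec), freqs = 3:5)
  score <- band_dbwpli(sp, c("x", "y"), band_spec("theta", 3, 5))
  bin4 <- abs(dbwpli(Im(sp$coef[, 1, 2] * Conj(sp$coef[, 2, 2]))))
  expect_gt(bin4, 0.9)                  # the 4 Hz bin carries the coupling
  expect_equal(score, mean(vapply(1:3, function(k)
    abs(dbwpli(Im(sp$coef[, 1, k] * Conj(sp$coef[, 2, k])))), numeric(1))))
})

test_that("seed topography equals a brute-force pair-and-AoI average", {
  lay <- load_layout(default_montage(), default_selected_ids())
  aoi <- assign_aois(lay)
  set.seed(6)
  coef <- random_coef(30, 26, 9)
  sp <- make_spectra(coef, freqs = 0:8, channels = lay$electrode_id)
  band <- band_spec("theta", 3, 5)
  topo <- seed_topography(sp, aoi, band)
  # independent brute force: loop pairs, seeds, bins with the scalar dbwpli()
  brute <- vapply(aoi$aoi_levels, function(a) {
    els <- aoi$assignments$electrode_id[aoi$assignments$aoi == a]
    mean(vapply(els, function(e) {
      mean(vapply(aoi$seed_ids, function(s) {
        ei <- match(e, sp$channels); si <- match(s, sp$channels)
        mean(vapply(c(3, 4, 5), function(f) {
          abs(dbwpli(Im(coef[, ei, f + 1] * Conj(coef[, si, f + 1]))))
        }, numeric(1)))
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(topo$values, brute, tolerance = 1e-12)
  expect_equal(topo$form, "raw")
  expect_true(all(topo$values >= 0 & topo$values <= 1))
})

test_that("identical pair scores propagate unchanged through the averaging", {
  lay <- load_layout(default_montage(), default_selected_ids())
  aoi <- assign_aois(lay)
  # constant imaginary cross-spectrum against both seeds: every pair scores 1
  n_ep <- 20
  coef <- array(complex(real = 1), dim = c(n_ep, 26, 5))
  # give non-seeds a +90 degree rotation so Im(cross) is a nonzero constant
  nonseed <- !lay$electrode_id %in% aoi$seed_ids
  coef[, nonseed, ] <- coef[, nonseed, ] * exp(1i * pi / 4)
  sp <- make_spectra(coef, freqs = 0:4, channels = lay$electrode_id)
  topo <- seed_topography(sp, aoi, band_spec("lo", 2, 4))
  expect_equal(unname(topo$values), rep(1, 6), tolerance = 1e-12)
})

test_that("channel mismatches are reported", {
  lay <- load_layout(default_montage(), default_selected_ids())
  aoi <- assign_aois(lay)
  sp <- make_spectra(random_coef(10, 3, 5), freqs = 0:4,
                     channels = c("Oz", "POz", "L01"))
  expect_error(seed_topography(sp, aoi, band_spec("lo", 2, 4)), "L02")
})
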