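test_that("cohort generation is deterministic under a fixed master seed", {
  c1 <- simulate_cohort(small_config(seed = 5))
  c2 <- simulate_cohort(small_config(seed = 5))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$kappa, c2$kappa)
  r1 <- simulate_recording(c1, "P002", "social")
  r2 <- simulate_recording(c2, "P002", "social")
  expect_identical(r1$recording$samples, r2$recording$samples)
  expect_identical(r1$mask, r2$mask)
  # a different master seed changes the cohort
  c3 <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(c1$kappa, c3$kappa))
})

test_that("a zero-coupling cohort yields near-null topographies", {
  cfg <- cohort_config(n_per_group = c(el_high = 1, el_low = 0, ll = 0),
                       duration_s = 40,
                       coupling_base = c(step1 = 0, step2 = 0, step3 = 0),
                       nondominant_scale = 0, elevated = list(),
                       kappa_jitter_sd = 0, inattention_rate = 0, seed = 3)
  coh <- simulate_cohort(cfg)
  sim <- simulate_recording(coh, "P001", "nonsocial")
  sp <- compute_spectra(sim$recording, segment_epochs(sim$recording),
                        freqs = 3:8)
  aoi <- assign_aois(load_layout(default_montage(), default_selected_ids()))
  topo <- seed_topography(sp, aoi, default_bands()$theta)
  expect_true(all(topo$values < 0.1))
  expect_true(all(coh$truth[, grep("_near$|_far$", names(coh$truth))] >= 0))
})

test_that("near-unity coupling with weak noise saturates the planted band", {
  cfg <- cohort_config(n_per_group = c(el_high = 0, el_low = 0, ll = 1),
                       duration_s = 40, noise_sd = 0.05,
                       coupling_base = c(step1 = 0.98, step2 = 0.98, step3 = 0.98),
                       nondominant_scale = 1, elevated = list(),
                       kappa_jitter_sd = 0, inattention_rate = 0, seed = 4)
  coh <- simulate_cohort(cfg)
  sim <- simulate_recording(coh, "P001", "social")
  sp <- compute_spectra(sim$recording, segment_epochs(sim$recording),
                        freqs = 3:5)
  aoi <- assign_aois(load_layout(default_montage(), default_selected_ids()))
  topo <- seed_topography(sp, aoi, default_bands()$theta)
  expect_true(all(topo$values > 0.85))
})

test_that("recovered connectivity increases monotonically with planted kappa", {
  kappas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  scores <- pop <- numeric(length(kappas))
  aoi <- assign_aois(load_layout(default_montage(), default_selected_ids()))
  for (i in seq_along(kappas)) {
    cfg <- cohort_config(n_per_group = c(el_high = 0, el_low = 0, ll = 1),
                         duration_s = 60,
                         coupling_base = c(step1 = kappas[i], step2 = kappas[i],
                                           step3 = kappas[i]),
                         nondominant_scale = 1, elevated = list(),
                         kappa_jitter_sd = 0, inattention_rate = 0,
                         seed = 20 + i)
    coh <- simulate_cohort(cfg)
    sim <- simulate_recording(coh, "P001", "nonsocial")
    sp <- compute_spectra(sim$recording, segment_epochs(sim$recording),
                          freqs = 3:5)
    scores[i] <- mean(seed_topography(sp, aoi, default_bands()$theta)$values)
    pop[i] <- population_band_score(cfg, "theta")(kappas[i])
  }
  expect_gt(cor(scores, kappas, method = "spearman"), 0.95)
  # and the measured scores track the population (ground-truth) mapping
  expect_lt(max(abs(scores - pop)), 0.12)
})

test_that("population band score is a monotone deterministic map of kappa", {
  cfg <- small_config()
  f1 <- population_band_score(cfg, "theta")
  f2 <- population_band_score(cfg, "theta")
  kg <- seq(0, 1, by = 0.05)
  expect_identical(f1(kg), f2(kg))
  expect_true(all(diff(f1(kg)) >= -1e-9))
  expect_equal(f1(0), 0, tolerance = 5e-3)  # independent channels: null score
  expect_true(all(f1(kg) >= -1e-9 & f1(kg) <= 1))
})

test_that("attention masks realize the configured inattention rate", {
  cfg <- cohort_config(n_per_group = c(el_high = 10, el_low = 0, ll = 0),
                       duration_s = 120, seed = 8)
  coh <- simulate_cohort(cfg)
  rates <- vapply(sprintf("P%03d", 1:10), function(p) {
    m <- simulate_recording(coh, p, "social")$mask
    sum(m$end_s - m$start_s) / cfg$duration_s
  }, numeric(1))
  expect_lt(abs(mean(rates) - cfg$inattention_rate), 0.06)
})

test_that("the outcome model plants the configured association", {
  coh <- simulate_cohort(cohort_config(seed = 12))
  tr <- coh$truth
  expect_true(all(tr$ados_css_total >= 0 & tr$ados_css_total <= 10))
  expect_true(all(tr$ados_css_total == round(tr$ados_css_total)))
  expect_true(all(tr$likelihood[tr$group == "ll"] == 0))
  expect_true(all(tr$likelihood[tr$group != "ll"] == 1))
  # positive association with the planted far variable
  expect_gt(cor(tr$theta_nonsocial_far, tr$ados_css_total), 0.3)
  # gmls correlates with its planted variable
  expect_gt(cor(tr$gamma_social_far, tr$gmls), 0.15)
  # elevated group has higher true far-connectivity in theta/non-social
  expect_gt(mean(tr$theta_nonsocial_far[tr$group == "el_high"]),
            mean(tr$theta_nonsocial_far[tr$group == "el_low"]))
})

test_that("the fast topography path is internally consistent", {
  sim <- simulate_modeling_table(small_config(seed = 31))
  expect_equal(nrow(sim$table), 9)
  expect_true(all(modeling_variable_names() %in% names(sim$table)))
  for (key in names(sim$flipped)) {
    fl <- sim$flipped[[key]]
    nm <- sim$normalized[[key]]
    expect_equal(unname(sqrt(rowSums(nm^2))), rep(1, nrow(nm)), tolerance = 1e-12)
    expect_true(all(apply(fl, 1, function(v) max(v[4:6]) >= max(v[1:3]))))
    # Near/Far columns in the table come from the flipped matrices
    expect_equal(unname(sim$table[[paste0(key, "_near")]]),
                 unname(fl[, "step1R"]))
    expect_equal(unname(sim$table[[paste0(key, "_far")]]),
                 unname(fl[, "step3R"]))
  }
  # null cohorts remove the planted group elevation
  nul <- simulate_modeling_table(small_config(seed = 31), null = TRUE,
                                 conditions = "theta_nonsocial")
  expect_null(nul$table)
  expect_named(nul$flipped, "theta_nonsocial")
})

test_that("derived seeds are stable, distinct and in the 31-bit range", {
  s1 <- derive_seed(1, 5, 2)
  expect_identical(s1, derive_seed(1, 5, 2))
  expect_false(s1 == derive_seed(1, 5, 3))
  expect_false(s1 == derive_seed(2, 5, 2))
  ss <- vapply(1:500, function(k) derive_seed(99, k), integer(1))
  expect_true(all(ss >= 1 & ss < 2^31))
  expect_equal(length(unique(ss)), 500)
})
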