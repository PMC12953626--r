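# Synthetic cohort generator. Continuous EEG is synthesized in the frequency
# domain: each band oscillator is a stationary Gaussian process with a
# raised-cosine band power spectrum (filtered-noise carrier, so the
# epoch-wise cross-spectral statistics are non-degenerate). A channel coupled
# to the seed at strength kappa receives kappa * e^{-i*phi} times the seed
# oscillator's spectral coefficients plus sqrt(1 - kappa^2) of an independent
# oscillator, then white sensor noise is added. Because the construction is
# Gaussian and linear, the population dbWPLI of any planted coupling follows
# from the epoch-coefficient covariance and is computed here as well; those
# population scores define the generator's ground truth (true Near/Far
# values, outcome model).

#' Configuration of a synthetic cohort
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' three groups (EL-HighADOS/EL-LowADOS/LL) of a 60-infant cohort, 500 Hz
#' sampling, 180 s per stimulus condition (3 x 1-min clips), infancy bands
#' with carriers at 4/7/40 Hz, a near-to-far declining seed-coupling profile
#' with a participant-specific dominant side (unilateral topographies),
#' elevated theta/non-social far-lateral coupling in the EL-HighADOS group,
#' 20% inattention, and an outcome linear in the true (population)
#' theta/non-social Far-Connectivity.
#'
#' @param n_per_group Named sizes for `el_high`, `el_low`, `ll`.
#' @param fs Sampling rate (Hz).
#' @param duration_s Duration per stimulus condition (s).
#' @param bands Band specs, see [default_bands()].
#' @param band_amp Oscillator amplitude per band (relative to unit-SD sensor
#'   noise).
#' @param noise_sd White sensor-noise SD.
#' @param phase_lag Seed-to-lateral phase lag (radians).
#' @param coupling_base Baseline kappa per step (dominant side).
#' @param nondominant_scale Multiplier for the non-dominant side's kappa.
#' @param elevated List of planted group effects, each
#'   `list(group, band, stimulus, step, delta)`.
#' @param kappa_jitter_sd Participant-level SD of kappa around its mean.
#' @param inattention_rate Expected masked fraction of each recording.
#' @param lookaway_mean_s Mean length of one inattention interval (s).
#' @param outcome Outcome-model parameters: intercept, covariate effects,
#'   named slopes `gamma` on the *true* Near/Far scores, residual SD.
#' @param gmls_model Slope/SD of the Global Motion Laterality Score model.
#' @param seed Master seed; all sub-streams derive from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(el_high = 12, el_low = 28, ll = 20),
                          fs = 500, duration_s = 180,
                          bands = default_bands(),
                          band_amp = c(theta = 6, alpha = 5, gamma = 10),
                          noise_sd = 1,
                          phase_lag = pi / 4,
                          coupling_base = c(step1 = 0.45, step2 = 0.35, step3 = 0.30),
                          nondominant_scale = 0.45,
                          elevated = list(list(group = "el_high", band = "theta",
                                               stimulus = "nonsocial", step = 3,
                                               delta = 0.35)),
                          kappa_jitter_sd = 0.08,
                          inattention_rate = 0.2,
                          lookaway_mean_s = 3,
                          outcome = list(intercept = 1, beta_sex = 0.9,
                                         beta_likelihood = 1.0,
                                         gamma = c(theta_nonsocial_far = 5),
                                         sigma = 1.3),
                          gmls_model = list(variable = "gamma_social_far",
                                            delta = 0.3, sigma = 0.9),
                          seed = 1L) {
  abort_if(any(n_per_group < 0), "group sizes must be >= 0")
  abort_if(any(coupling_base < 0 | coupling_base > 1), "kappa must be in [0, 1]")
  abort_if(inattention_rate < 0 || inattention_rate >= 1,
           "inattention rate must be in [0, 1)")
  structure(list(n_per_group = n_per_group, fs = fs, duration_s = duration_s,
                 bands = bands, band_amp = band_amp, noise_sd = noise_sd,
                 phase_lag = phase_lag, coupling_base = coupling_base,
                 nondominant_scale = nondominant_scale, elevated = elevated,
                 kappa_jitter_sd = kappa_jitter_sd,
                 inattention_rate = inattention_rate,
                 lookaway_mean_s = lookaway_mean_s,
                 outcome = outcome, gmls_model = gmls_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Raised-cosine band power-spectral shape with 0.5 Hz rolloff margins.
band_psd_shape <- function(f, band, margin = 0.5) {
  w <- numeric(length(f))
  inside <- f >= band$lo_hz & f <= band$hi_hz
  w[inside] <- 1
  lo_edge <- f >= band$lo_hz - margin & f < band$lo_hz
  w[lo_edge] <- cos((band$lo_hz - f[lo_edge]) / margin * pi / 2)^2
  hi_edge <- f > band$hi_hz & f <= band$hi_hz + margin
  w[hi_edge] <- cos((f[hi_edge] - band$hi_hz) / margin * pi / 2)^2
  w
}

# Spectral-coefficient variances v_k (upper-half bins) for a unit-variance
# band process of n samples at rate fs, plus the bin indices (2..n/2 scale).
band_spectrum <- function(band, fs, n) {
  k <- 1:(n %/% 2 - 1)
  f <- k * fs / n
  shape <- band_psd_shape(f, band)
  idx <- which(shape > 0)
  v <- shape[idx]
  v <- v / sum(v) * n^2 / 2  # unit process variance: (2/n^2) * sum(v) = 1
  list(k = k[idx], v = v)
}

# ACF (lags 0..L-1) of the band process, from its spectral synthesis model.
band_acf <- function(band, fs, n, L) {
  sp <- band_spectrum(band, fs, n)
  l <- 0:(L - 1)
  # r_l = (2/n^2) * sum_k v_k cos(2 pi k l / n)
  (2 / n^2) * as.vector(cos(2 * pi * outer(l, sp$k) / n) %*% sp$v)
}

# Variance of the Hann-windowed epoch DFT coefficient of the band process at
# each integer analysis frequency (Hz), for 1-s epochs of L samples.
epoch_bin_variance <- function(band, fs, n, L, freqs_hz) {
  r <- band_acf(band, fs, n, L)
  w <- as.numeric(signal::hanning(L))
  cl <- vapply(0:(L - 1), function(l)
    sum(w[1:(L - l)] * w[(1 + l):L]), numeric(1))
  m <- freqs_hz * L / fs  # cycles per epoch
  vapply(m, function(mm)
    cl[1] * r[1] + 2 * sum(cl[-1] * r[-1] * cos(2 * pi * mm * (1:(L - 1)) / L)),
    numeric(1))
}

# Population |dbWPLI| of a coupled pair at one bin: seed A = s*sqrt(snr)+n1,
# channel B = sqrt(snr)*(kappa e^{-i phi} s + sqrt(1-kappa^2) o) + n2 with
# standard complex Gaussians; the estimator converges to
# (E I)^2 / (E |I|)^2 with I = Im(A conj B). Monte-Carlo over a fixed set of
# standardized draws (seeded internally, so the ground truth is a fixed
# deterministic function of the configuration).
pop_dbwpli_grid <- function(snr_bins, phi, kappa_grid, n_mc = 30000L,
                            mc_seed = 20260919L) {
  draws <- with_seed(mc_seed, {
    m <- n_mc
    list(s = complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) / sqrt(2),
         o = complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) / sqrt(2),
         n1 = complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) / sqrt(2),
         n2 = complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) / sqrt(2))
  })
  out <- matrix(0, length(kappa_grid), length(snr_bins))
  rot <- exp(-1i * phi)
  for (b in seq_along(snr_bins)) {
    a <- sqrt(snr_bins[b])
    A <- a * draws$s + draws$n1
    for (j in seq_along(kappa_grid)) {
      k <- kappa_grid[j]
      B <- a * (k * rot * draws$s + sqrt(1 - k^2) * draws$o) + draws$n2
      I <- Im(A * Conj(B))
      out[j, b] <- mean(I)^2 / mean(abs(I))^2
    }
  }
  rowMeans(out)  # band average over bins
}

#' Population band dbWPLI as a function of coupling strength
#'
#' Returns the deterministic mapping kappa -> population band-averaged
#' |dbWPLI| implied by the generator's spectral model (cached per band and
#' configuration; interpolated from a kappa grid).
#'
#' @param config A `cohort_config`.
#' @param band_name `"theta"`, `"alpha"` or `"gamma"`.
#' @return A function of kappa (vectorized).
#' @export
population_band_score <- function(config, band_name) {
  band <- config$bands[[band_name]]
  n <- round(config$fs * config$duration_s)
  L <- round(config$fs)  # 1-s epochs
  key <- paste("pop", band_name, config$fs, config$duration_s,
               config$band_amp[[band_name]], config$noise_sd,
               round(config$phase_lag, 6), band$lo_hz, band$hi_hz, sep = "_")
  cache_get_or_compute(key, function() {
    freqs <- seq(ceiling(band$lo_hz), floor(band$hi_hz))
    v_bin <- epoch_bin_variance(band, config$fs, n, L, freqs)
    w <- as.numeric(signal::hanning(L))
    nu <- config$noise_sd^2 * sum(w^2)
    snr <- (config$band_amp[[band_name]]^2) * v_bin / nu
    kg <- seq(0, 1, by = 0.025)
    pop <- pop_dbwpli_grid(snr, config$phase_lag, kg)
    fun <- stats::splinefun(kg, pop, method = "monoH.FC")
    function(kappa) fun(pmin(pmax(kappa, 0), 1))
  })
}

band_stim_grid <- function() {
  expand.grid(band = c("theta", "alpha", "gamma"),
              stimulus = c("social", "nonsocial"),
              stringsAsFactors = FALSE)
}

# Mean kappa per AoI for one participant x band x stimulus.
kappa_profile <- function(config, group, band, stimulus, dominant_side) {
  base <- config$coupling_base
  lev <- aoi_levels(length(base))
  k <- stats::setNames(numeric(length(lev)), lev)
  for (st in seq_along(base)) {
    k[paste0("step", st, dominant_side)] <- base[[st]]
    other <- if (dominant_side == "R") "L" else "R"
    k[paste0("step", st, other)] <- base[[st]] * config$nondominant_scale
  }
  for (ef in config$elevated) {
    if (ef$group == group && ef$band == band && ef$stimulus == stimulus) {
      k[paste0("step", ef$step, dominant_side)] <-
        k[paste0("step", ef$step, dominant_side)] + ef$delta
    }
  }
  pmin(pmax(k, 0), 0.98)
}

#' Simulate a synthetic cohort
#'
#' Draws participants (group, sex, age, autism-likelihood, dominant
#' coupling side), per-participant seed-coupling strengths for every band x
#' stimulus x AoI, the implied ground-truth topographies and Near/Far scores
#' (population dbWPLI), and the outcome and Global Motion Laterality Score
#' from the configured linear models. Recordings are not materialized (a full
#' cohort would occupy gigabytes); regenerate any of them deterministically
#' with [simulate_recording()].
#'
#' @param config A `cohort_config`.
#' @return A `synthetic_cohort`: `participants`, `kappa` (participant x
#'   band x stimulus x AoI array), `truth` (modelling-style table of true
#'   Near/Far scores with covariates, outcome and gmls), `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  abort_if(!inherits(config, "cohort_config"), "`config` must be a cohort_config")
  n <- sum(config$n_per_group)
  abort_if(n == 0, "zero participants")
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  grid <- band_stim_grid()
  lev <- aoi_levels(length(config$coupling_base))
  ids <- sprintf("P%03d", seq_len(n))
  kap <- array(NA_real_, dim = c(n, nrow(grid), length(lev)),
               dimnames = list(ids, paste(grid$band, grid$stimulus, sep = "_"), lev))
  participants <- with_seed(derive_seed(config$seed, 101L), {
    data.frame(participant = ids, group = groups,
               sex = stats::rbinom(n, 1, 0.5),
               likelihood = as.integer(groups %in% c("el_high", "el_low")),
               age_5mo = round(stats::rnorm(n, 152, 7)),
               dominant_side = sample(c("L", "R"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  with_seed(derive_seed(config$seed, 202L), {
    for (i in seq_len(n)) {
      for (g in seq_len(nrow(grid))) {
        mu <- kappa_profile(config, groups[i], grid$band[g], grid$stimulus[g],
                            participants$dominant_side[i])
        kap[i, g, ] <- pmin(pmax(mu + stats::rnorm(length(mu), 0,
                                                   config$kappa_jitter_sd), 0), 0.98)
      }
    }
  })
  # ground-truth topographies: population band scores of the planted kappas
  truth_vars <- list()
  far_col <- paste0("step", length(config$coupling_base), "R")
  for (g in seq_len(nrow(grid))) {
    popf <- population_band_score(config, grid$band[g])
    tops <- matrix(popf(as.numeric(kap[, g, ])), n, dimnames = list(ids, lev))
    fl <- flip_rows(normalize_rows(tops))
    truth_vars[[paste(grid$band[g], grid$stimulus[g], "near", sep = "_")]] <- fl[, "step1R"]
    truth_vars[[paste(grid$band[g], grid$stimulus[g], "far", sep = "_")]] <- fl[, far_col]
  }
  truth <- cbind(participants, as.data.frame(truth_vars))
  truth <- with_seed(derive_seed(config$seed, 303L), {
    oc <- config$outcome
    lin <- oc$intercept + oc$beta_sex * truth$sex +
      oc$beta_likelihood * truth$likelihood
    for (v in names(oc$gamma)) lin <- lin + oc$gamma[[v]] * truth[[v]]
    truth$ados_css_total <- pmin(pmax(round(lin + stats::rnorm(n, 0, oc$sigma)), 0), 10)
    gm <- config$gmls_model
    gv <- truth[[gm$variable]]
    truth$gmls <- gm$delta * as.numeric(scale(gv)) + stats::rnorm(n, 0, gm$sigma)
    truth
  })
  structure(list(config = config, participants = participants, kappa = kap,
                 truth = truth, aoi_levels = lev, conditions = grid),
            class = "synthetic_cohort")
}

#' Simulate one participant's recording and attention mask
#'
#' Deterministically regenerates the continuous EEG (26-channel synthetic
#' occipital montage: Oz, POz plus 24 lateral electrodes) and the inattention
#' mask for one participant x stimulus from the cohort's derived seeds.
#'
#' @param cohort A `synthetic_cohort`.
#' @param participant Participant id (e.g. `"P007"`).
#' @param stimulus `"social"` or `"nonsocial"`.
#' @return List with `recording` (a `continuous_recording`) and `mask`
#'   (an `attention_mask`).
#' @export
simulate_recording <- function(cohort, participant, stimulus) {
  abort_if(!inherits(cohort, "synthetic_cohort"), "`cohort` must be a synthetic_cohort")
  cfg <- cohort$config
  i <- match(participant, cohort$participants$participant)
  abort_if(is.na(i), "unknown participant: ", participant)
  ci <- match(stimulus, c("social", "nonsocial"))
  abort_if(is.na(ci), "stimulus must be 'social' or 'nonsocial'")
  lay_aoi <- cache_get_or_compute("default_layout_aoi", function() {
    lay <- load_layout(default_montage(), default_selected_ids())
    list(lay = lay, aoi = assign_aois(lay))
  })
  lay <- lay_aoi$lay
  aoi <- lay_aoi$aoi
  n <- round(cfg$fs * cfg$duration_s)
  n_ch <- nrow(lay)
  chan <- lay$electrode_id
  kap_i <- cohort$kappa[i, , ]
  rot <- exp(-1i * cfg$phase_lag)
  rec_seed <- derive_seed(cfg$seed, 1000L + i, ci)
  seed_ch <- lay$is_seed
  ch_aoi <- aoi$assignments$aoi[match(chan, aoi$assignments$electrode_id)]
  samples <- with_seed(rec_seed, {
    spec_ch <- matrix(complex(real = 0), n, n_ch)  # full spectra, upper half filled
    for (bn in names(cfg$bands)) {
      sp <- band_spectrum(cfg$bands[[bn]], cfg$fs, n)
      nb <- length(sp$k)
      amp <- cfg$band_amp[[bn]]
      sv <- sqrt(sp$v)
      Cs <- sv * complex(real = stats::rnorm(nb),
                         imaginary = stats::rnorm(nb)) / sqrt(2)
      lat <- which(!seed_ch)
      O <- (matrix(complex(real = stats::rnorm(nb * length(lat)),
                           imaginary = stats::rnorm(nb * length(lat))),
                   nb) / sqrt(2)) * sv
      kv <- kap_i[paste(bn, stimulus, sep = "_"), ch_aoi[lat]]
      row <- sp$k + 1L
      spec_ch[row, seed_ch] <- spec_ch[row, seed_ch] + amp * Cs
      contrib <- (amp * rot * Cs) %o% kv +
        O * rep(amp * sqrt(1 - kv^2), each = nb)
      spec_ch[row, lat] <- spec_ch[row, lat] + contrib
    }
    # conjugate-symmetric completion, inverse FFT per channel, sensor noise
    up <- 2:(n %/% 2)
    spec_ch[n + 2L - up, ] <- Conj(spec_ch[up, ])
    x <- Re(stats::mvfft(spec_ch, inverse = TRUE)) / n
    t(x) + stats::rnorm(n * n_ch, 0, cfg$noise_sd)
  })
  rownames(samples) <- chan
  mask <- with_seed(derive_seed(cfg$seed, 5000L + i, ci), {
    ne <- stats::rpois(1, cfg$duration_s * cfg$inattention_rate / cfg$lookaway_mean_s)
    if (ne == 0) attention_mask() else {
      st <- stats::runif(ne, 0, cfg$duration_s)
      en <- pmin(st + stats::rexp(ne, 1 / cfg$lookaway_mean_s), cfg$duration_s)
      keep <- en > st
      attention_mask(st[keep], en[keep])
    }
  })
  list(recording = continuous_recording(samples, cfg$fs, chan,
                                        participant_id = participant,
                                        stimulus = stimulus),
       mask = mask)
}

#' Fast topography-level cohort (no EEG synthesis)
#'
#' Draws each participant's 6-AoI topographies directly as the population
#' (ground-truth) scores plus independent Gaussian measurement noise,
#' normalizes and flips them, and assembles the modelling table. This is the
#' statistically faithful shortcut for testing the inference layer
#' (permutation calibration, selection, model fits) at scale without paying
#' for signal synthesis.
#'
#' @param config A `cohort_config`.
#' @param measurement_sd SD of the additive AoI-score measurement noise
#'   (emulating finite-epoch dbWPLI estimation error). Default 0.02.
#' @param null If `TRUE`, planted group effects are removed so all groups are
#'   exchangeable (for calibration studies).
#' @param seed Overrides the config's master seed.
#' @param conditions Optional subset of `band_stimulus` keys (e.g.
#'   `"theta_nonsocial"`) to generate; default all six.
#' @return List with `table` (modelling table; `NULL` unless all conditions
#'   were generated), `raw`, `flipped` and `normalized` (per band x
#'   stimulus: participant x AoI matrices), `truth`, `cohort`.
#' @export
simulate_modeling_table <- function(config = cohort_config(),
                                    measurement_sd = 0.02, null = FALSE,
                                    seed = config$seed, conditions = NULL) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  if (null) cfg$elevated <- list()
  cohort <- simulate_cohort(cfg)
  grid <- cohort$conditions
  keys <- paste(grid$band, grid$stimulus, sep = "_")
  use <- if (is.null(conditions)) seq_len(nrow(grid)) else match(conditions, keys)
  abort_if(anyNA(use), "unknown condition key(s)")
  lev <- cohort$aoi_levels
  ids <- cohort$participants$participant
  n <- length(ids)
  far_col <- paste0("step", length(cfg$coupling_base), "R")
  raw_l <- list(); flipped <- list(); normalized <- list(); vars <- list()
  with_seed(derive_seed(cfg$seed, 404L), {
    for (g in use) {
      popf <- population_band_score(cfg, grid$band[g])
      raw <- matrix(popf(as.numeric(cohort$kappa[, g, ])), n,
                    dimnames = list(ids, lev))
      raw <- pmax(raw + matrix(stats::rnorm(n * length(lev), 0, measurement_sd), n), 0)
      nm <- normalize_rows(raw)
      fl <- flip_rows(nm)
      raw_l[[keys[g]]] <- raw
      normalized[[keys[g]]] <- nm
      flipped[[keys[g]]] <- fl
      vars[[paste0(keys[g], "_near")]] <- fl[, "step1R"]
      vars[[paste0(keys[g], "_far")]] <- fl[, far_col]
    }
  })
  table <- NULL
  if (length(use) == nrow(grid)) {
    table <- cbind(data.frame(participant = ids, stringsAsFactors = FALSE),
                   as.data.frame(vars)[, modeling_variable_names()],
                   cohort$truth[, c("sex", "likelihood", "age_5mo", "group",
                                    "ados_css_total", "gmls")])
    rownames(table) <- NULL
  }
  list(table = table, raw = raw_l, flipped = flipped, normalized = normalized,
       truth = cohort$truth, cohort = cohort)
}
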