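# Debiased weighted phase-lag index (dbWPLI) connectivity and its aggregation
# into seed-anchored 6-AoI topographies. dbWPLI is built from the imaginary
# part of epoch-wise cross-spectra, so zero-lag (volume-conducted) coupling
# contributes nothing, and the debiasing keeps its expectation near zero for
# independent signals even at modest epoch counts.

#' Frequency band specification
#'
#' @param name Band name.
#' @param lo_hz,hi_hz Inclusive band edges in Hz.
#' @return A `band_spec` list.
#' @export
band_spec <- function(name, lo_hz, hi_hz) {
  abort_if(!(lo_hz > 0) || hi_hz < lo_hz, "need 0 < lo_hz <= hi_hz")
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz), class = "band_spec")
}

#' Default infant frequency bands
#'
#' Theta 3-5 Hz, alpha 6-8 Hz and whole gamma 20-60 Hz, the canonical
#' infancy-adjusted bands for this analysis.
#'
#' @return Named list of `band_spec`s.
#' @export
default_bands <- function() {
  list(theta = band_spec("theta", 3, 5),
       alpha = band_spec("alpha", 6, 8),
       gamma = band_spec("gamma", 20, 60))
}

#' Debiased WPLI from per-epoch imaginary cross-spectrum values
#'
#' The estimator is `((sum I)^2 - sum I^2) / ((sum |I|)^2 - sum I^2)` over the
#' n epoch-wise imaginary cross-spectrum values I. It can be negative; the
#' pipeline takes absolute values downstream. A zero denominator (no imaginary
#' coupling evidence at all) returns 0 by convention.
#'
#' @param imag_cross Numeric vector of per-epoch imaginary cross-spectrum
#'   values (length >= 2).
#' @return The debiased squared-WPLI estimate (signed).
#' @examples
#' dbwpli(c(1, -1))       # -1
#' dbwpli(rep(0.3, 10))   # 1: perfectly consistent lag
#' @export
dbwpli <- function(imag_cross) {
  abort_if(length(imag_cross) < 2L, "dbWPLI needs at least 2 epochs")
  abort_if(!all(is.finite(imag_cross)), "non-finite imaginary cross-spectrum")
  s1 <- sum(imag_cross)
  s2 <- sum(imag_cross^2)
  sa <- sum(abs(imag_cross))
  den <- sa^2 - s2
  if (den <= 0) return(0)
  (s1^2 - s2) / den
}

# Vectorized dbWPLI over the columns of an epoch x bin matrix.
dbwpli_cols <- function(I) {
  s1 <- colSums(I)
  s2 <- colSums(I^2)
  sa <- colSums(abs(I))
  den <- sa^2 - s2
  out <- numeric(ncol(I))
  ok <- den > 0
  out[ok] <- (s1[ok]^2 - s2[ok]) / den[ok]
  out
}

band_bins <- function(spec, band) {
  which(spec$freqs >= band$lo_hz - 1e-9 & spec$freqs <= band$hi_hz + 1e-9 &
          spec$freqs > 1e-9)  # DC excluded from all band computations
}

#' Band-averaged absolute dbWPLI for one electrode pair
#'
#' dbWPLI is computed per frequency bin inside the band (inclusive edges; 1-s
#' epochs give a 1 Hz bin grid, so theta = 3, 4, 5 Hz) and the per-bin scores
#' are averaged. By default the absolute value is taken per bin before
#' averaging; `abs_first = FALSE` instead averages the signed per-bin scores
#' and takes the absolute value of the mean.
#'
#' @param spec An `epoch_spectra`.
#' @param pair Character or integer vector of length 2 naming the two
#'   channels; the cross-spectrum is `coef[a] * Conj(coef[b])`.
#' @param band A `band_spec`.
#' @param abs_first Take |dbWPLI| per bin before band averaging. Default TRUE.
#' @return Band connectivity score in `[0, 1]`.
#' @export
band_dbwpli <- function(spec, pair, band, abs_first = TRUE) {
  abort_if(!inherits(spec, "epoch_spectra"), "`spec` must be an epoch_spectra")
  abort_if(length(pair) != 2L, "`pair` must name two channels")
  idx <- if (is.numeric(pair)) as.integer(pair) else match(pair, spec$channels)
  abort_if(anyNA(idx) || any(idx < 1 | idx > length(spec$channels)),
           "channel(s) not present: ", paste(pair[is.na(idx)], collapse = ", "))
  bins <- band_bins(spec, band)
  abort_if(length(bins) == 0L, "band [", band$lo_hz, ", ", band$hi_hz,
           "] Hz has no frequency bins in the spectra")
  abort_if(spec$n_epochs < 2L, "need at least 2 epochs")
  I <- Im(spec$coef[, idx[1], bins, drop = FALSE] *
            Conj(spec$coef[, idx[2], bins, drop = FALSE]))
  I <- matrix(I, nrow = spec$n_epochs)
  per_bin <- dbwpli_cols(I)
  if (abs_first) mean(abs(per_bin)) else abs(mean(per_bin))
}

#' Seed-anchored 6-AoI dbWPLI topography for one band
#'
#' Three-stage averaging: (1) band dbWPLI between every non-seed electrode and
#' each of the two seeds; (2) the two seed scores are averaged per electrode;
#' (3) electrode scores are averaged within each AoI. The result is the raw
#' 6-AoI topography ordered `step3L, step2L, step1L, step1R, step2R, step3R`.
#'
#' @param spec An `epoch_spectra` whose channels cover the AoI map.
#' @param aoi An `aoi_map` from [assign_aois()].
#' @param band A `band_spec`.
#' @param abs_first Passed to [band_dbwpli()].
#' @return A `condition_topography` with `form = "raw"`.
#' @export
seed_topography <- function(spec, aoi, band, abs_first = TRUE) {
  abort_if(!inherits(aoi, "aoi_map"), "`aoi` must be an aoi_map")
  need <- c(aoi$seed_ids, aoi$assignments$electrode_id)
  missing <- setdiff(need, spec$channels)
  abort_if(length(missing) > 0, "spectra lack channel(s): ",
           paste(missing, collapse = ", "))
  abort_if(spec$n_epochs < 2L, "need at least 2 epochs")
  bins <- band_bins(spec, band)
  abort_if(length(bins) == 0L, "band has no frequency bins in the spectra")
  seed_idx <- match(aoi$seed_ids, spec$channels)
  el_idx <- match(aoi$assignments$electrode_id, spec$channels)
  # per electrode: mean over the two seeds of the band score
  el_score <- matrix(0, length(el_idx), length(seed_idx))
  for (s in seq_along(seed_idx)) {
    Cs <- Conj(spec$coef[, seed_idx[s], bins, drop = FALSE])
    dim(Cs) <- c(spec$n_epochs, length(bins))
    for (e in seq_along(el_idx)) {
      Ce <- spec$coef[, el_idx[e], bins, drop = FALSE]
      dim(Ce) <- c(spec$n_epochs, length(bins))
      per_bin <- dbwpli_cols(Im(Ce * Cs))
      el_score[e, s] <- if (abs_first) mean(abs(per_bin)) else abs(mean(per_bin))
    }
  }
  el_mean <- rowMeans(el_score)
  lev <- aoi$aoi_levels
  vals <- vapply(lev, function(a) mean(el_mean[aoi$assignments$aoi == a]),
                 numeric(1))
  condition_topography(vals, form = "raw", band = band$name,
                       stimulus = spec$stimulus,
                       participant_id = spec$participant_id,
                       n_epochs = spec$n_epochs)
}

#' Construct a condition topography
#'
#' @param values Named numeric vector of AoI scores in canonical order
#'   (`step3L` ... `step3R`).
#' @param form One of `"raw"`, `"normalized"`, `"flipped"`.
#' @param band,stimulus,participant_id,n_epochs Metadata.
#' @param flipped Logical: was the pattern mirrored (only meaningful for
#'   `form = "flipped"`).
#' @return A `condition_topography`.
#' @export
condition_topography <- function(values, form = c("raw", "normalized", "flipped"),
                                 band = NA_character_, stimulus = NA_character_,
                                 participant_id = NA_character_,
                                 n_epochs = NA_integer_, flipped = NA) {
  form <- match.arg(form)
  abort_if(!is.numeric(values) || length(values) %% 2 != 0,
           "`values` must be numeric with one entry per AoI")
  lev <- aoi_levels(length(values) %/% 2)
  if (is.null(names(values))) names(values) <- lev
  abort_if(!identical(names(values), lev),
           "`values` must be ordered ", paste(lev, collapse = ", "))
  structure(list(values = values, form = form, band = band,
                 stimulus = stimulus, participant_id = participant_id,
                 n_epochs = n_epochs, flipped = flipped),
            class = "condition_topography")
}

#' @export
print.condition_topography <- function(x, ...) {
  cat(sprintf("topography [%s] %s/%s (%s epochs)\n", x$form,
              x$band, x$stimulus, x$n_epochs))
  print(round(x$values, 4))
  invisible(x)
}

#' Write topographies as a long-format table
#'
#' @param topos List of `condition_topography` objects.
#' @param path Output TSV path, or `NULL` to return the data frame.
#' @return The long data frame (`participant`, `band`, `stimulus`, `form`,
#'   `aoi`, `value`, `n_epochs`), invisibly when written.
#' @export
write_topographies <- function(topos, path = NULL) {
  rows <- lapply(topos, function(t) {
    data.frame(participant = t$participant_id, band = t$band,
               stimulus = t$stimulus, form = t$form,
               aoi = names(t$values), value = unname(t$values),
               n_epochs = t$n_epochs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
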