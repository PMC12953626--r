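# Shared fixture builders. Everything is generated in code; nothing binary.

# Write a montage file from a data frame (label, x, y, z); returns the path.
write_montage <- function(df, sep = "\t") {
  path <- tempfile(fileext = ".sfp")
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# A toy +/- x mirror-symmetric montage: 3 electrodes per side + 2 midline.
toy_montage_df <- function() {
  data.frame(
    label = c("Oz", "POz", "L1", "L2", "L3", "R1", "R2", "R3"),
    x = c(0, 0, -1, -2, -3, 1, 2, 3),
    y = c(-9, -8.5, -8, -7.5, -7, -8, -7.5, -7),
    z = c(0, 1, 0.5, 1, 1.5, 0.5, 1, 1.5)
  )
}

toy_layout <- function() {
  load_layout(write_montage(toy_montage_df()),
              c("L1", "L2", "L3", "R1", "R2", "R3"))
}

# A minimal epoch_spectra object with given complex coefficient array.
make_spectra <- function(coef, freqs, channels,
                         participant = "P1", stimulus = "social") {
  structure(list(coef = coef, freqs = freqs, starts = seq_len(dim(coef)[1]),
                 channels = channels, fs = NA, epoch_s = 1,
                 n_epochs = dim(coef)[1],
                 participant_id = participant, stimulus = stimulus),
            class = "epoch_spectra")
}

# Random complex Gaussian array (epochs x channels x freqs).
random_coef <- function(n_ep, n_ch, n_fr) {
  array(complex(real = rnorm(n_ep * n_ch * n_fr),
                imaginary = rnorm(n_ep * n_ch * n_fr)),
        dim = c(n_ep, n_ch, n_fr))
}

# A raw condition topography from a plain numeric 6-vector.
topo6 <- function(v, form = "raw", ...) {
  condition_topography(stats::setNames(v, aoi_levels(3)), form = form, ...)
}

# Small cohort config for fast tests.
small_config <- function(...) {
  cohort_config(n_per_group = c(el_high = 3, el_low = 3, ll = 3),
                duration_s = 30, ...)
}
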