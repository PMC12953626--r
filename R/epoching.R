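# Epoching of cleaned continuous EEG: attention masking, overlapping 1-s
# segmentation, Hann tapering and per-epoch Fourier spectra. Filtering,
# artifact rejection and channel repair are upstream concerns (HAPPE-style
# preprocessing) and are deliberately not re-implemented here.

#' Construct a continuous multichannel recording
#'
#' @param samples Numeric channel x time matrix of cleaned EEG.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels (one per row).
#' @param participant_id,stimulus Optional identifiers carried through the
#'   pipeline (`stimulus` is typically `"social"` or `"nonsocial"`).
#' @return A `continuous_recording` object.
#' @export
continuous_recording <- function(samples, fs, channels = rownames(samples),
                                 participant_id = NA_character_,
                                 stimulus = NA_character_) {
  abort_if(!is.matrix(samples) || !is.numeric(samples),
           "`samples` must be a numeric channel x time matrix")
  abort_if(!all(is.finite(samples)), "`samples` contains non-finite values")
  abort_if(!is.numeric(fs) || length(fs) != 1L || fs <= 0, "`fs` must be > 0")
  abort_if(ncol(samples) < fs, "recording must contain at least 1 s of data")
  channels <- channels %||% paste0("ch", seq_len(nrow(samples)))
  abort_if(length(channels) != nrow(samples),
           "`channels` must name every row of `samples`")
  structure(list(samples = samples, fs = fs, channels = as.character(channels),
                 participant_id = participant_id, stimulus = stimulus,
                 duration_s = ncol(samples) / fs),
            class = "continuous_recording")
}

#' Construct an attention mask of inattention intervals
#'
#' Intervals are half-open `[start, end)` times in seconds during which the
#' infant was *not* attending; overlapping or touching intervals are merged.
#'
#' @param start_s,end_s Numeric vectors of interval bounds (seconds).
#' @return An `attention_mask` data frame with columns `start_s`, `end_s`.
#' @export
attention_mask <- function(start_s = numeric(), end_s = numeric()) {
  abort_if(length(start_s) != length(end_s), "start/end lengths differ")
  abort_if(any(!is.finite(c(start_s, end_s))), "mask bounds must be finite")
  abort_if(any(end_s <= start_s), "mask intervals must satisfy start < end")
  abort_if(any(start_s < 0), "mask intervals must start at time >= 0")
  if (length(start_s)) {
    ord <- order(start_s)
    start_s <- start_s[ord]; end_s <- end_s[ord]
    ms <- start_s[1]; me <- end_s[1]; out_s <- numeric(); out_e <- numeric()
    for (i in seq_along(start_s)[-1]) {
      if (start_s[i] <= me) me <- max(me, end_s[i])
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start_s[i]; me <- end_s[i] }
    }
    start_s <- c(out_s, ms); end_s <- c(out_e, me)
  }
  structure(data.frame(start_s = start_s, end_s = end_s),
            class = c("attention_mask", "data.frame"))
}

#' Segment a recording into overlapping epochs, rejecting inattentive ones
#'
#' Candidate epochs start on a fixed grid from t = 0 with stride
#' `epoch_s * (1 - overlap)`. An epoch is rejected iff the fraction of its
#' span covered by the inattention mask *strictly* exceeds
#' `max_bad_fraction` (a 50%-masked epoch is kept).
#'
#' @param rec A `continuous_recording`.
#' @param mask An `attention_mask`, or `NULL` for none.
#' @param epoch_s Epoch length in seconds. Default 1.
#' @param overlap Fractional overlap between successive epochs in `[0, 1)`.
#'   Default 0.5.
#' @param max_bad_fraction Maximum tolerated masked fraction. Default 0.5.
#' @return Numeric vector of retained epoch start times (seconds); may be
#'   empty.
#' @examples
#' rec <- continuous_recording(matrix(rnorm(2000), 2), fs = 100)
#' segment_epochs(rec, attention_mask(0, 0.6))
#' @export
segment_epochs <- function(rec, mask = NULL, epoch_s = 1.0, overlap = 0.5,
                           max_bad_fraction = 0.5) {
  abort_if(!inherits(rec, "continuous_recording"), "`rec` must be a continuous_recording")
  abort_if(overlap < 0 || overlap >= 1, "`overlap` must be in [0, 1)")
  abort_if(epoch_s <= 0 || epoch_s > rec$duration_s,
           "`epoch_s` must be positive and fit in the recording")
  stride <- epoch_s * (1 - overlap)
  n <- floor((rec$duration_s - epoch_s) / stride + 1e-9) + 1
  starts <- (seq_len(n) - 1) * stride
  if (is.null(mask) || nrow(mask) == 0L) return(starts)
  abort_if(!inherits(mask, "attention_mask"), "`mask` must be an attention_mask")
  abort_if(any(mask$end_s > rec$duration_s + 1e-9),
           "mask extends beyond the recording")
  bad <- vapply(starts, function(s) {
    sum(pmax(0, pmin(mask$end_s, s + epoch_s) - pmax(mask$start_s, s)))
  }, numeric(1))
  starts[bad / epoch_s <= max_bad_fraction + 1e-12]
}

#' Gate participants on a minimum number of surviving epochs
#'
#' A participant is retained for a condition iff its epoch count reaches
#' `min_epochs`; overall retention requires every condition in
#' `require_conditions`.
#'
#' @param counts Data frame with columns `participant`, `condition`,
#'   `n_epochs`.
#' @param min_epochs Minimum surviving epochs per condition. Default 90.
#' @param require_conditions Conditions a participant must pass; defaults to
#'   all conditions present in `counts`.
#' @return Data frame, one row per participant: `participant`, `retained`,
#'   `reason` (`""` when retained).
#' @export
min_epoch_gate <- function(counts, min_epochs = 90L,
                           require_conditions = unique(counts$condition)) {
  abort_if(!all(c("participant", "condition", "n_epochs") %in% names(counts)),
           "`counts` needs columns participant, condition, n_epochs")
  abort_if(any(counts$n_epochs < 0), "epoch counts must be >= 0")
  res <- lapply(split(counts, counts$participant), function(d) {
    miss <- setdiff(require_conditions, d$condition)
    d <- d[d$condition %in% require_conditions, , drop = FALSE]
    low <- d$condition[d$n_epochs < min_epochs]
    bad <- c(if (length(miss)) paste0("missing condition ", miss),
             if (length(low)) paste0(low, ": ", d$n_epochs[match(low, d$condition)],
                                     " < ", min_epochs, " epochs"))
    data.frame(participant = d$participant[1] %||% NA_character_,
               retained = length(bad) == 0L,
               reason = paste(bad, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compute per-epoch Fourier spectra of Hann-tapered segments
#'
#' Each epoch is tapered by a Hann window and discrete-Fourier transformed.
#' For 1-s epochs the frequency resolution is 1 Hz. Only the one-sided
#' spectrum is returned; the DC bin is kept in the output but is excluded
#' from all band computations downstream.
#'
#' @param rec A `continuous_recording`.
#' @param starts Epoch start times from [segment_epochs()].
#' @param epoch_s Epoch length in seconds. Default 1.
#' @param window `"hann"` (default), `"none"`, or a numeric taper of epoch
#'   length.
#' @param freqs Optional numeric vector of frequencies (Hz) to compute;
#'   `NULL` (default) returns the full one-sided spectrum. Restricting to the
#'   analysis bands avoids computing bins that are never used.
#' @return An `epoch_spectra` object: complex array `coef` of dimension
#'   epoch x channel x frequency, plus `freqs`, `starts`, `channels`, `fs`,
#'   `epoch_s`, `n_epochs`.
#' @export
compute_spectra <- function(rec, starts, epoch_s = 1.0, window = "hann",
                            freqs = NULL) {
  abort_if(!inherits(rec, "continuous_recording"), "`rec` must be a continuous_recording")
  abort_if(!all(is.finite(rec$samples)), "non-finite samples")
  n <- round(epoch_s * rec$fs)
  abort_if(n < 2, "epoch too short for the sampling rate")
  nt <- ncol(rec$samples)
  idx0 <- round(starts * rec$fs)
  abort_if(any(idx0 < 0) || any(idx0 + n > nt), "epoch start(s) out of range")
  w <- if (identical(window, "hann")) as.numeric(signal::hanning(n))
       else if (identical(window, "none")) rep(1, n)
       else { abort_if(length(window) != n, "numeric taper must have epoch length"); as.numeric(window) }
  all_freqs <- (0:(n %/% 2)) / epoch_s
  if (is.null(freqs)) freqs <- all_freqs
  bins <- match(round(freqs * epoch_s), round(all_freqs * epoch_s))
  abort_if(anyNA(bins), "requested frequency outside the one-sided spectrum")
  n_ep <- length(starts); n_ch <- nrow(rec$samples)
  if (n_ep == 0L) {
    coef <- array(complex(real = 0), dim = c(0, n_ch, length(freqs)))
  } else {
    # gather all epochs of all channels into one n x (n_ep*n_ch) matrix, then
    # a single windowed DFT against the requested bins
    iv <- as.vector(outer(seq_len(n), idx0, "+"))  # epoch-major sample index
    gather <- rec$samples[, iv, drop = FALSE]      # n_ch x (n * n_ep)
    dim(gather) <- c(n_ch, n, n_ep)
    gather <- aperm(gather, c(2, 1, 3))            # n x n_ch x n_ep
    dim(gather) <- c(n, n_ch * n_ep)
    gather <- gather * w
    # windowed DFT against the requested bins, via two real BLAS products
    ang <- -2 * pi * outer(0:(n - 1), bins - 1) / n
    coef_mat <- crossprod(gather, cos(ang)) + 1i * crossprod(gather, sin(ang))
    coef <- array(coef_mat, dim = c(n_ch, n_ep, length(freqs)))
    coef <- aperm(coef, c(2, 1, 3))                # epoch x channel x freq
  }
  structure(list(coef = coef, freqs = freqs, starts = starts,
                 channels = rec$channels, fs = rec$fs, epoch_s = epoch_s,
                 n_epochs = n_ep,
                 participant_id = rec$participant_id, stimulus = rec$stimulus),
            class = "epoch_spectra")
}
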