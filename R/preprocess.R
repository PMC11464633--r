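# Filtering and artifact handling applied before any feature extraction.
# All filters are zero-phase (forward-backward) Butterworth designs applied
# per channel with reflect padding, so channel order and timing never change.

# Forward-backward application with reflect padding of `pad` samples
# (default 3 filter time-constants) to suppress edge transients.
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    head_ref <- 2 * x[1L] - x[(pad + 1L):2L]
    tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else {
    xp <- x
  }
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1L):(pad + n)]
}

apply_iir <- function(rec, filt, pad) {
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    out$data[i, ] <- filtfilt_padded(filt, rec$data[i, ], pad)
  }
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (effective 8th order, zero
#' group delay by construction) with reflect padding. Used with 1-30 Hz for
#' EEG, 1-40 Hz for ECG and 20-200 Hz for EMG.
#'
#' @param rec a [recording()] (or a plain numeric vector with `fs` given).
#' @param low,high passband edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate; taken from the recording when omitted.
#' @param order filter order of each pass (default 4).
#' @return filtered recording (or vector).
#' @export
bandpass <- function(rec, low, high, fs = NULL, order = 4L) {
  if (inherits(rec, "recording")) fs <- rec$sampling_rate
  stopifnot(!is.null(fs), low > 0, low < high)
  if (high >= fs / 2) {
    stop("filter-design: high edge ", high, " Hz >= Nyquist (", fs / 2, " Hz)")
  }
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  pad <- ceiling(3 * fs / low)
  if (inherits(rec, "recording")) apply_iir(rec, filt, pad)
  else filtfilt_padded(filt, rec, pad)
}

#' Zero-phase Butterworth low-pass filter
#' @inheritParams bandpass
#' @param cutoff -3 dB corner frequency (Hz).
#' @export
lowpass <- function(rec, cutoff, fs = NULL, order = 4L) {
  if (inherits(rec, "recording")) fs <- rec$sampling_rate
  stopifnot(!is.null(fs), cutoff > 0, cutoff < fs / 2)
  filt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- ceiling(3 * fs / cutoff)
  if (inherits(rec, "recording")) apply_iir(rec, filt, pad)
  else filtfilt_padded(filt, rec, pad)
}

#' Notch comb for power-line interference
#'
#' Places a zero-phase 2nd-order Butterworth band-stop (+/- 1 Hz, so the
#' -3 dB width is 2 Hz) at the base frequency and every harmonic up to
#' `min(up_to, fs/2 - 2)` Hz.
#'
#' @inheritParams bandpass
#' @param base base frequency in Hz (default 60, mains in the study region).
#' @param up_to highest harmonic to notch (Hz).
#' @return filtered recording (or vector).
#' @export
notch_comb <- function(rec, base = 60, up_to = 200, fs = NULL) {
  if (inherits(rec, "recording")) fs <- rec$sampling_rate
  stopifnot(!is.null(fs), base > 0)
  if (base >= fs / 2) stop("filter-design: notch base >= Nyquist")
  freqs <- notch_frequencies(base, up_to, fs)
  out <- rec
  for (f0 in freqs) {
    filt <- signal::butter(2, c(f0 - 1, f0 + 1) / (fs / 2), type = "stop")
    pad <- ceiling(3 * fs / f0)
    out <- if (inherits(out, "recording")) apply_iir(out, filt, pad)
           else filtfilt_padded(filt, out, pad)
  }
  out
}

#' @rdname notch_comb
#' @export
notch_frequencies <- function(base, up_to, fs) {
  lim <- min(up_to, fs / 2 - 2)
  if (lim < base) return(numeric(0))
  seq(base, lim, by = base)
}

# ---- artifact masks ---------------------------------------------------------

#' Artifact mask: spans of signal excluded from epoching
#'
#' @param onset,duration numeric vectors in seconds.
#' @param channel character vector of channel labels, or `"all"`.
#' @return data.frame of class `artifact_mask`.
#' @export
artifact_mask <- function(onset = numeric(0), duration = numeric(0),
                          channel = rep("all", length(onset))) {
  stopifnot(length(onset) == length(duration),
            length(channel) == length(onset), all(duration >= 0))
  structure(data.frame(onset = onset, duration = duration, channel = channel,
                       stringsAsFactors = FALSE),
            class = c("artifact_mask", "data.frame"))
}

#' Attach an artifact mask to a recording
#'
#' Masked spans are marked missing and excluded from all downstream epoching
#' (an epoch overlapping a masked span is dropped); sample values are left
#' untouched elsewhere.
#'
#' @param rec a [recording()].
#' @param mask an [artifact_mask()]; spans must lie inside the recording.
#' @return the recording with the mask attached.
#' @export
apply_artifact_mask <- function(rec, mask) {
  stopifnot(inherits(rec, "recording"), inherits(mask, "artifact_mask"))
  dur <- recording_duration(rec)
  if (nrow(mask) && any(mask$onset < 0 | mask$onset + mask$duration > dur + 1e-9)) {
    stop("artifact mask outside the recording")
  }
  rec$bad_segments <- mask
  rec
}

#' Automatic amplitude-based artifact detection
#'
#' Deterministic stand-in for visual artifact inspection: flags 1-s windows
#' whose robust amplitude z-score (peak absolute amplitude against the channel
#' median absolute deviation) exceeds `z_threshold`. A user-supplied
#' annotations file can override it.
#'
#' @param rec a filtered [recording()].
#' @param z_threshold robust z threshold (default 5).
#' @return an [artifact_mask()] with per-channel spans.
#' @export
auto_artifact_mask <- function(rec, z_threshold = 5) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  win <- round(fs)             # 1-s windows
  nwin <- floor(ncol(rec$data) / win)
  onsets <- numeric(0); durs <- numeric(0); chans <- character(0)
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    med <- stats::median(x)
    sigma <- stats::mad(x)
    if (sigma <= 0) sigma <- stats::sd(x)
    if (sigma <= 0) next
    dev <- matrix(abs(x[seq_len(nwin * win)] - med), nrow = win)
    peak <- apply(dev, 2L, max)
    hit <- which(peak / sigma > z_threshold)
    if (length(hit)) {
      onsets <- c(onsets, (hit - 1L) * win / fs)
      durs <- c(durs, rep(win / fs, length(hit)))
      chans <- c(chans, rep(rec$channel_labels[i], length(hit)))
    }
  }
  artifact_mask(onsets, durs, chans)
}

# Epoch offsets inside `window` that avoid masked spans. Epochs are placed on
# the window's own grid; an epoch overlapping any masked span (for the given
# channel or "all") is dropped. Returns absolute start times (s).
clean_epoch_starts <- function(window, epoch_length, overlap, bad_segments,
                               channel = NULL) {
  offs <- make_epochs(interval_duration(window), epoch_length, overlap)
  starts <- unname(window[1L]) + as.numeric(offs)
  if (is.null(bad_segments) || nrow(bad_segments) == 0L) return(starts)
  keep <- rep(TRUE, length(starts))
  bs <- bad_segments
  if (!is.null(channel)) {
    bs <- bs[bs$channel == "all" | bs$channel == channel, , drop = FALSE]
  }
  for (j in seq_len(nrow(bs))) {
    b0 <- bs$onset[j]; b1 <- bs$onset[j] + bs$duration[j]
    keep <- keep & !(starts < b1 & (starts + epoch_length) > b0)
  }
  starts[keep]
}

# ---- ocular component removal ----------------------------------------------

# Symmetric FastICA (tanh contrast) on channels x samples data.
# Deterministic under a fixed seed; component count equals channel count.
fastica_decompose <- function(X, max_iter = 200L, tol = 1e-6, seed = 1L,
                              max_samples = 32768L) {
  nc <- nrow(X)
  Xc <- X - rowMeans(X)
  # estimate the unmixing matrix on a decimated copy (the blink component is
  # low-frequency, so a regular subsample suffices); apply it to all samples
  stride <- max(1L, ceiling(ncol(Xc) / max_samples))
  Xs <- Xc[, seq(1L, ncol(Xc), by = stride), drop = FALSE]
  C <- Xs %*% t(Xs) / ncol(Xs)
  eg <- eigen(C, symmetric = TRUE)
  # keep only the numerically full-rank subspace (e.g. after a previous
  # component removal the data are rank-deficient by one)
  keep <- eg$values > max(eg$values) * 1e-10
  if (sum(keep) < 2L) stop("decomposition: rank-deficient data")
  vals <- eg$values[keep]
  vecs <- eg$vectors[, keep, drop = FALSE]
  nc <- sum(keep)
  K <- diag(1 / sqrt(vals), nc) %*% t(vecs)          # whitening (nc x ch)
  Z <- K %*% Xs
  W <- with_seed(seed, matrix(stats::rnorm(nc * nc), nc, nc))
  sym_orth <- function(W) {
    s <- svd(W); s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmix <- W %*% K                   # sources = unmix %*% Xc
  mixing <- vecs %*% diag(sqrt(vals), nc) %*% t(W)   # channels x components
  list(sources = unmix %*% Xc, mixing = mixing, unmixing = unmix,
       means = rowMeans(X))
}

#' Remove the ocular (blink) independent component
#'
#' Decomposes band-passed EEG into as many independent components as channels
#' (FastICA, tanh contrast, deterministic under `seed`), scores every
#' component by absolute correlation with a blink proxy (the mean of Fp1 and
#' Fp2 low-passed at 4 Hz), and zeroes exactly the single top-scoring
#' component before reconstructing. At most one component is ever removed; if
#' the top score is below `threshold` nothing is removed and the recording is
#' returned unchanged (with attribute `ocular_removed = FALSE`).
#'
#' The default threshold is 0.75: blink components in frontal-dominant
#' recordings score above 0.9, while on blink-free data a source aligned with
#' the Fp1+Fp2 direction of ordinary delta background can reach an absolute
#' correlation of ~0.6, so 0.75 separates the two regimes cleanly.
#'
#' @param rec an EEG [recording()] including channels Fp1 and Fp2, already
#'   band-pass filtered.
#' @param threshold minimum |correlation| with the blink proxy.
#' @param seed RNG seed for the ICA initialisation.
#' @return the reconstructed recording; attributes `ocular_removed` (logical)
#'   and `ocular_score` (the top score) record what happened.
#' @export
remove_ocular_component <- function(rec, threshold = 0.75, seed = 1L) {
  stopifnot(inherits(rec, "recording"), rec$modality == "EEG")
  if (!all(c("Fp1", "Fp2") %in% rec$channel_labels)) {
    stop("remove_ocular_component: needs Fp1 and Fp2")
  }
  fs <- rec$sampling_rate
  proxy <- lowpass(colMeans(rec$data[c("Fp1", "Fp2"), , drop = FALSE]),
                   cutoff = 4, fs = fs)
  dec <- fastica_decompose(rec$data, seed = seed)
  scores <- abs(apply(dec$sources, 1L, stats::cor, y = proxy))
  top <- which.max(scores)
  out <- rec
  if (scores[top] >= threshold) {
    S <- dec$sources
    S[top, ] <- 0
    out$data <- dec$mixing %*% S + dec$means
    rownames(out$data) <- rec$channel_labels
    attr(out, "ocular_removed") <- TRUE
  } else {
    attr(out, "ocular_removed") <- FALSE
  }
  attr(out, "ocular_score") <- unname(scores[top])
  out
}
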