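# Facial-EMG amplitude (RMS) and mean-frequency (MNF) analysis.
#
# Pipeline: 20-200 Hz band-pass, 60-Hz notch comb, 2-s epochs with 1-s
# overlap inside the central windows, per-epoch RMS z-scored to PRE, and the
# period MNF from the mean-then-normalized Welch PSD (per-epoch Hann 1-s
# segments, 50% overlap -> 1-Hz grid, both 20 and 200 Hz on-grid).

EMG_EPOCH_LENGTH <- 2
EMG_EPOCH_OVERLAP <- 1
EMG_WELCH_SEG <- 1
EMG_BAND <- c(20, 200)

#' Root-mean-square amplitude of one epoch
#'
#' @param x numeric vector (one cleaned 2-s epoch).
#' @return `sqrt(mean(x^2))`.
#' @export
epoch_rms <- function(x) sqrt(mean(x^2))

#' Mean frequency of a period's EMG spectrum
#'
#' Per-epoch Welch PSDs are averaged arithmetically across the period's
#' epochs, the mean spectrum is normalized by its total power (Simpson
#' integral over 20-200 Hz), and the MNF is the spectral centroid over the
#' 20-200 Hz grid. Set `per_epoch = TRUE` for the alternative
#' mean-of-per-epoch-MNFs reading (the two agree for stationary signals).
#'
#' @param epochs list of single-channel epoch vectors.
#' @param fs sampling rate, >= 512 Hz (Nyquist gate for the 200 Hz edge).
#' @param per_epoch average per-epoch MNFs instead of pooling spectra.
#' @return list `MNF` (Hz) and `psd` (normalized period spectrum).
#' @export
period_mnf <- function(epochs, fs, per_epoch = FALSE) {
  if (fs < 512) {
    stop("gate: EMG frequency analysis requires sampling_rate >= 512 Hz")
  }
  stopifnot(length(epochs) >= 1L)
  lens <- lengths(epochs)
  if (length(unique(lens)) == 1L && length(epochs) > 1L) {
    # equal-length epochs: one vectorized pass
    wm <- welch_many(unlist(epochs, use.names = FALSE), fs,
                     starts_idx = (seq_along(epochs) - 1L) * lens[1L] + 1L,
                     epoch_len_s = lens[1L] / fs, seg_len_s = EMG_WELCH_SEG)
    psds <- lapply(seq_along(epochs), function(i) {
      structure(list(freq = wm$freq, density = wm$density[, i]),
                class = "spectral_estimate")
    })
  } else {
    psds <- lapply(epochs, welch_psd, fs = fs, seg_length = EMG_WELCH_SEG,
                   overlap_frac = 0.5)
  }
  mean_density <- Reduce(`+`, lapply(psds, `[[`, "density")) / length(psds)
  psd <- structure(list(freq = psds[[1L]]$freq, density = mean_density),
                   class = "spectral_estimate")
  total <- band_power(psd, EMG_BAND)
  if (total <= 0) stop("period_mnf: zero in-band power")
  psd$density <- psd$density / total
  mnf <- if (per_epoch) {
    mean(vapply(psds, spectral_centroid, numeric(1), band = EMG_BAND,
                tol = 1))
  } else {
    spectral_centroid(psd, EMG_BAND)
  }
  list(MNF = mnf, psd = psd)
}

#' RMS and MNF summary of one EMG session
#'
#' @param rec an EMG [recording()] (raw; filtered internally: 20-200 Hz
#'   band-pass then 60-Hz notch comb). Requires `sampling_rate >= 512`.
#' @param segmentation a [period_segmentation()].
#' @param window_minutes central-window targets (minutes).
#' @param per_epoch_mnf see [period_mnf()].
#' @return list with `epochs` (data.frame `period`, `epoch_start`, `rms`,
#'   `rms_z`), `features` (period-level `rms_z` mean and `MNF`) and `deltas`
#'   (pairwise, first minus second).
#' @export
emg_session_summary <- function(rec, segmentation,
                                window_minutes = c(pre = 5, mti = 15,
                                                   post = 5),
                                per_epoch_mnf = FALSE) {
  stopifnot(inherits(rec, "recording"), rec$modality == "EMG")
  if (!emg_eligible(rec)) {
    stop("gate: EMG analysis requires sampling_rate >= 512 Hz")
  }
  fs <- rec$sampling_rate
  filt <- notch_comb(bandpass(rec, EMG_BAND[1L], EMG_BAND[2L]),
                     base = 60, up_to = EMG_BAND[2L])
  x <- filt$data[1L, ]
  ep_rows <- list(); mnf_rows <- list()
  for (p in c("pre", "mti", "post")) {
    win <- central_window(segmentation[[p]], window_minutes[[p]])
    starts <- clean_epoch_starts(win, EMG_EPOCH_LENGTH, EMG_EPOCH_OVERLAP,
                                 filt$bad_segments)
    if (length(starts) == 0L) {
      stop("empty-period: no surviving EMG epochs in ", toupper(p))
    }
    epochs <- lapply(starts, function(st) {
      x[interval_sample_idx(c(st, st + EMG_EPOCH_LENGTH), fs, length(x))]
    })
    ep_rows[[p]] <- data.frame(
      period = p, epoch_start = starts,
      rms = vapply(epochs, epoch_rms, numeric(1)), stringsAsFactors = FALSE)
    mnf_rows[[p]] <- period_mnf(epochs, fs, per_epoch = per_epoch_mnf)
  }
  ep <- do.call(rbind, ep_rows)
  ep$rms_z <- zscore_to_pre(ep$rms, ep$period == "pre", label = "EMG RMS")
  features <- do.call(rbind, lapply(c("pre", "mti", "post"), function(p) {
    data.frame(period = p, feature = c("rms_z", "mnf"),
               value = c(mean(ep$rms_z[ep$period == p]), mnf_rows[[p]]$MNF),
               stringsAsFactors = FALSE)
  }))
  pairs <- list(c("mti", "pre"), c("post", "pre"), c("mti", "post"))
  deltas <- do.call(rbind, lapply(pairs, function(pr) {
    a <- features[features$period == pr[1L], ]
    b <- features[features$period == pr[2L], ]
    data.frame(pair = paste(pr[1L], pr[2L], sep = "-"), feature = a$feature,
               delta = a$value - b$value[match(a$feature, b$feature)],
               stringsAsFactors = FALSE)
  }))
  list(epochs = ep, features = features, deltas = deltas,
       psd = lapply(mnf_rows, `[[`, "psd"))
}
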