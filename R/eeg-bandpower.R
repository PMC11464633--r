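# Per-epoch spectral band power, PRE-referenced z-scoring, and per-period
# topographic contrasts.
#
# Epoching: 3-s epochs with 1.5-s overlap inside the central analysis window
# of each period (5/15/5 min targets; shorter periods are used whole).
# Welch dialect per epoch: Hann-windowed 2-s segments with 50% overlap and
# density scaling -> 0.5-Hz grid on which every band edge of the default
# scheme lies at an even pair offset, making Simpson band powers exactly
# additive over the partition.

EEG_EPOCH_LENGTH <- 3
EEG_EPOCH_OVERLAP <- 1.5
EEG_WELCH_SEG <- 2

#' Welch PSD of one analysis epoch
#'
#' @param x single-channel signal of one epoch.
#' @param fs sampling rate (Hz).
#' @param seg_length Welch segment length in seconds (default 2 s, giving a
#'   0.5 Hz grid and two averages per 3-s epoch).
#' @return a `spectral_estimate`.
#' @export
epoch_psd <- function(x, fs, seg_length = EEG_WELCH_SEG) {
  welch_psd(x, fs, seg_length = seg_length, overlap_frac = 0.5)
}

# Vectorized many-epoch Welch: density matrix (freq x epoch) for all epochs
# of one channel at once via mvfft. Numerically identical to calling
# welch_psd() per epoch (same window, scaling and averaging).
welch_many <- function(x, fs, starts_idx, epoch_len_s, seg_len_s) {
  nper <- round(seg_len_s * fs)
  nep_len <- round(epoch_len_s * fs)
  seg_offs <- seq(0L, nep_len - nper, by = nper %/% 2L)
  w <- bh_window(nper)
  scale <- fs * sum(w^2)
  nfreq <- nper %/% 2L + 1L
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  # columns: all segments of all epochs
  col_starts <- as.vector(outer(seg_offs, starts_idx, `+`))
  segmat <- matrix(x[as.vector(outer(0:(nper - 1L), col_starts, `+`))],
                   nrow = nper)
  segmat <- sweep(segmat, 2L, colMeans(segmat))   # detrend
  spec <- abs(stats::mvfft(segmat * w)[seq_len(nfreq), , drop = FALSE])^2 /
    scale * dbl
  # average the segments of each epoch
  ns <- length(seg_offs)
  dens <- spec %*% (diag(length(starts_idx)) %x% rep(1 / ns, ns))
  list(freq = (seq_len(nfreq) - 1L) * fs / nper, density = dens)
}

# Simpson quadrature weights over the grid slice low <= f <= high
simpson_weights <- function(freq, low, high) {
  df <- freq[2L] - freq[1L]
  sel <- which(freq >= low - df / 2 * 1e-6 & freq <= high + df / 2 * 1e-6)
  n <- length(sel)
  w <- numeric(length(freq))
  if (n < 2L) return(w)
  h <- df
  if (n == 2L) { w[sel] <- h / 2; return(w) }
  m <- n - 1L
  ww <- numeric(n)
  if (m %% 2L == 0L) {
    idx <- seq(1L, n - 2L, by = 2L)
    ww[idx] <- ww[idx] + h / 3
    ww[idx + 1L] <- ww[idx + 1L] + 4 * h / 3
    ww[idx + 2L] <- ww[idx + 2L] + h / 3
  } else {
    if (n > 3L) {
      idx <- seq(1L, n - 3L, by = 2L)
      ww[idx] <- ww[idx] + h / 3
      ww[idx + 1L] <- ww[idx + 1L] + 4 * h / 3
      ww[idx + 2L] <- ww[idx + 2L] + h / 3
    }
    ww[n - 1L] <- ww[n - 1L] + h / 2
    ww[n] <- ww[n] + h / 2
  }
  w[sel] <- ww
  w
}

#' z-score a per-epoch series against its PRE baseline
#'
#' `z = (x - mean_PRE) / sd_PRE` applied to every epoch, PRE included, so the
#' PRE epochs have mean 0 and (sample) SD 1 by construction. The SD uses the
#' n-1 denominator.
#'
#' @param x numeric per-epoch values.
#' @param pre logical vector, `TRUE` for PRE epochs (>= 2 required).
#' @param label diagnostic label used in error messages.
#' @return numeric z-scores, same length as `x`.
#' @export
zscore_to_pre <- function(x, pre, label = "series") {
  stopifnot(length(x) == length(pre), is.logical(pre))
  if (sum(pre) < 2L) stop("zscore_to_pre: need >= 2 PRE epochs for ", label)
  m <- mean(x[pre]); s <- stats::sd(x[pre])
  if (!is.finite(s) || s <= 0) {
    stop("degenerate-baseline: PRE SD is zero for ", label)
  }
  (x - m) / s
}

#' Band-power series of one EEG session
#'
#' Runs the per-period pipeline: central window extraction, 3 s / 1.5 s
#' epoching (epochs overlapping artifact-masked spans or period boundaries are
#' dropped), per-epoch Welch PSD, Simpson band power for every band of the
#' scheme, then per-channel/band z-scoring against PRE.
#'
#' @param rec a filtered EEG [recording()].
#' @param segmentation a [period_segmentation()].
#' @param scheme a [band_scheme()].
#' @param window_minutes central-window targets per period (minutes).
#' @return object of class `band_power_series`: data.frame with columns
#'   `period`, `epoch_start`, `channel`, `band`, `power`, `z`.
#' @export
eeg_band_power_series <- function(rec, segmentation, scheme = band_scheme(),
                                  window_minutes = c(pre = 5, mti = 15,
                                                     post = 5)) {
  stopifnot(inherits(rec, "recording"), rec$modality == "EEG",
            inherits(segmentation, "period_segmentation"))
  fs <- rec$sampling_rate
  nb <- nrow(scheme)
  rows <- list()
  for (p in c("pre", "mti", "post")) {
    win <- central_window(segmentation[[p]], window_minutes[[p]])
    starts <- clean_epoch_starts(win, EEG_EPOCH_LENGTH, EEG_EPOCH_OVERLAP,
                                 rec$bad_segments, channel = NULL)
    if (length(starts) == 0L) {
      stop("empty-period: no surviving epochs in ", toupper(p))
    }
    starts_idx <- floor(starts * fs + 1e-9) + 1L
    wmat <- NULL
    for (ch in rec$channel_labels) {
      wm <- welch_many(rec$data[ch, ], fs, starts_idx,
                       EEG_EPOCH_LENGTH, EEG_WELCH_SEG)
      if (is.null(wmat)) {
        wmat <- t(vapply(seq_len(nb), function(b) {
          simpson_weights(wm$freq, scheme$low[b], scheme$high[b])
        }, numeric(length(wm$freq))))
      }
      pw <- wmat %*% wm$density              # bands x epochs
      rows[[length(rows) + 1L]] <- data.frame(
        period = p,
        epoch_start = rep(starts, each = nb),
        channel = ch,
        band = rep(scheme$band, length(starts)),
        power = as.vector(pw), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$z <- NA_real_
  for (ch in unique(out$channel)) {
    for (b in unique(out$band)) {
      sel <- out$channel == ch & out$band == b
      out$z[sel] <- zscore_to_pre(out$power[sel], out$period[sel] == "pre",
                                  label = paste(ch, b))
    }
  }
  class(out) <- c("band_power_series", "data.frame")
  out
}

#' Per-period mean z-scores of a band-power series
#'
#' @param series a [eeg_band_power_series()] result (or any data.frame with
#'   `period`, `channel`, `band`, `z`).
#' @return data.frame `period` x `channel` x `band` with column `mean_z`.
#' @export
period_summary <- function(series) {
  stopifnot(all(c("period", "channel", "band", "z") %in% names(series)))
  agg <- stats::aggregate(z ~ period + channel + band, data = series,
                          FUN = mean)
  names(agg)[names(agg) == "z"] <- "mean_z"
  agg
}

#' Topographic group contrast of period-mean z-scores
#'
#' For each channel and band takes the per-recording period-mean z difference
#' (e.g. MTI - PRE), reports its group mean and SD, a two-sided permutation
#' p-value for the unpaired comparison of the two period means, and the
#' Benjamini-Hochberg adjustment across the electrodes within each band.
#'
#' @param summaries list of [period_summary()] data.frames, one per recording
#'   (>= 2 recordings).
#' @param contrast `"mti_pre"` or `"post_pre"`.
#' @param n_perm number of permutations (default 1600).
#' @param seed global RNG seed; per-cell seeds are derived by hashing the
#'   (seed, channel, band, contrast) tuple so results are order-independent.
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame of class `topographic_contrast` with columns `channel`,
#'   `band`, `mean_change`, `sd_change`, `p`, `p_adjusted`, `significant`.
#' @export
topographic_contrast <- function(summaries, contrast = c("mti_pre", "post_pre"),
                                 n_perm = 1600L, seed = 1L, alpha = 0.05) {
  contrast <- match.arg(contrast)
  if (length(summaries) < 2L) {
    stop("insufficient-replication: need >= 2 recordings")
  }
  a_period <- if (contrast == "mti_pre") "mti" else "post"
  first <- summaries[[1L]]
  cells <- unique(first[, c("channel", "band")])
  res <- list()
  for (k in seq_len(nrow(cells))) {
    ch <- cells$channel[k]; b <- cells$band[k]
    pick <- function(s, per) {
      s$mean_z[s$channel == ch & s$band == b & s$period == per]
    }
    av <- vapply(summaries, pick, numeric(1), per = a_period)
    bv <- vapply(summaries, pick, numeric(1), per = "pre")
    pt <- permutation_test(av, bv, n_perm = n_perm,
                           seed = derive_seed(seed, ch, b, contrast))
    res[[k]] <- data.frame(channel = ch, band = b,
                           mean_change = mean(av - bv),
                           sd_change = stats::sd(av - bv),
                           p = pt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- NA_real_
  for (b in unique(out$band)) {
    sel <- out$band == b
    out$p_adjusted[sel] <- bh_fdr(out$p[sel])
  }
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("topographic_contrast", "data.frame")
  out
}
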