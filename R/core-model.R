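#' @keywords internal
"_PACKAGE"

# ---- time intervals ---------------------------------------------------------
# Time is represented in seconds with half-open intervals [start, end).
# Sample indices are 0-based; index of `end` is floor(end * fs).

#' Construct a half-open time interval
#'
#' @param start,end interval bounds in seconds, `start < end`.
#' @return numeric length-2 vector of class `time_interval`.
#' @keywords internal
time_interval <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, is.finite(start), is.finite(end))
  start <- unname(start); end <- unname(end)
  if (end <= start) {
    stop("invalid-segmentation: empty interval [", start, ", ", end, ")")
  }
  structure(c(start = start, end = end), class = "time_interval")
}

interval_duration <- function(interval) {
  unname(interval[2L] - interval[1L])
}

#' Central analysis window of a period
#'
#' Returns the centered sub-interval of the requested length. A period shorter
#' than the target is used in its entirety. When the trim is an odd number of
#' half-samples the extra time goes to the right edge, so the result is
#' deterministic.
#'
#' @param interval half-open interval `c(start, end)` in seconds.
#' @param target_minutes desired window length in minutes (> 0).
#' @return half-open interval of class `time_interval`, always inside `interval`.
#' @export
#' @examples
#' central_window(c(0, 600), 5)   # [150, 450)
#' central_window(c(0, 200), 5)   # the whole period
central_window <- function(interval, target_minutes) {
  interval <- as_interval(interval)
  stopifnot(is.numeric(target_minutes), length(target_minutes) == 1L,
            target_minutes > 0)
  target <- target_minutes * 60
  dur <- interval_duration(interval)
  if (dur <= target) return(interval)
  trim <- (dur - target) / 2
  time_interval(unname(interval[1L]) + trim, unname(interval[1L]) + trim + target)
}

as_interval <- function(x) {
  if (inherits(x, "time_interval")) return(x)
  stopifnot(is.numeric(x), length(x) == 2L)
  time_interval(x[1L], x[2L])
}

# ---- period segmentation ----------------------------------------------------

#' PRE / MTI / POST segmentation of a session
#'
#' @param pre,mti,post half-open intervals in seconds; must be ordered,
#'   non-overlapping and non-empty.
#' @param duration optional recording duration; when given, all intervals must
#'   lie inside `[0, duration)`.
#' @return object of class `period_segmentation` (named list of intervals).
#' @export
period_segmentation <- function(pre, mti, post, duration = NULL) {
  pre <- as_interval(pre); mti <- as_interval(mti); post <- as_interval(post)
  if (!(pre[2L] <= mti[1L] && mti[2L] <= post[1L])) {
    stop("invalid-segmentation: periods must be ordered PRE < MTI < POST ",
         "and non-overlapping")
  }
  if (!is.null(duration)) {
    if (pre[1L] < 0 || post[2L] > duration + 1e-9) {
      stop("invalid-segmentation: periods exceed the recording duration")
    }
  }
  structure(list(pre = pre, mti = mti, post = post),
            class = "period_segmentation")
}

#' Build a segmentation from period annotations
#'
#' Period boundaries come from annotations labelled PRE / MTI / POST
#' (case-insensitive, via `label_map`); absent labels are an error rather than
#' being inferred.
#'
#' @param annotations data.frame with columns `onset`, `duration`, `label`.
#' @param duration recording duration in seconds (optional bound check).
#' @param label_map named character vector mapping period names `pre`, `mti`,
#'   `post` to annotation labels.
#' @return `period_segmentation`.
#' @export
segmentation_from_annotations <- function(annotations, duration = NULL,
                                          label_map = c(pre = "PRE",
                                                        mti = "MTI",
                                                        post = "POST")) {
  stopifnot(is.data.frame(annotations),
            all(c("onset", "duration", "label") %in% names(annotations)))
  pick <- function(period) {
    hit <- which(toupper(trimws(annotations$label)) ==
                   toupper(label_map[[period]]))
    if (length(hit) != 1L) {
      stop("invalid-segmentation: expected exactly one '", label_map[[period]],
           "' annotation, found ", length(hit))
    }
    on <- annotations$onset[hit]
    time_interval(on, on + annotations$duration[hit])
  }
  period_segmentation(pick("pre"), pick("mti"), pick("post"),
                      duration = duration)
}

#' @export
print.period_segmentation <- function(x, ...) {
  for (p in names(x)) {
    cat(sprintf("%-4s [%9.3f, %9.3f) s  (%.1f s)\n", toupper(p),
                x[[p]][1L], x[[p]][2L], interval_duration(x[[p]])))
  }
  invisible(x)
}

# ---- band scheme ------------------------------------------------------------

#' EEG frequency band scheme
#'
#' Default bands: Delta 1-4, Theta 4-8, Alpha 8-12, SlowBeta 12-18,
#' FastBeta 18-30 Hz. Bands must be contiguous and non-overlapping and cover
#' the full analysis range.
#'
#' @param bands data.frame with columns `band`, `low`, `high` (Hz).
#' @return data.frame of class `band_scheme`.
#' @export
band_scheme <- function(bands = default_bands()) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low >= bands$high)) stop("band scheme: low must be < high")
  if (nrow(bands) > 1L &&
      any(abs(bands$high[-nrow(bands)] - bands$low[-1L]) > 1e-9)) {
    stop("band scheme: bands must be contiguous and non-overlapping")
  }
  structure(bands, class = c("band_scheme", "data.frame"))
}

#' @rdname band_scheme
#' @export
default_bands <- function() {
  data.frame(band = c("Delta", "Theta", "Alpha", "SlowBeta", "FastBeta"),
             low  = c(1, 4, 8, 12, 18),
             high = c(4, 8, 12, 18, 30),
             stringsAsFactors = FALSE)
}

# ---- epoching ---------------------------------------------------------------

#' Sliding-window epoch offsets
#'
#' Offsets are `0, step, 2*step, ...` with `step = epoch_length - overlap`;
#' the last epoch ends at or before `segment_duration` and any trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param segment_duration source segment length (s), at least one epoch long.
#' @param epoch_length epoch length (s).
#' @param overlap overlap between consecutive epochs (s), `0 <= overlap <
#'   epoch_length`.
#' @return object of class `epoch_set`: numeric vector of start offsets with
#'   attributes `epoch_length` and `overlap`.
#' @export
#' @examples
#' make_epochs(9, 3, 1.5)   # offsets 0, 1.5, 3, 4.5, 6
make_epochs <- function(segment_duration, epoch_length, overlap) {
  stopifnot(is.numeric(segment_duration), is.numeric(epoch_length),
            is.numeric(overlap), epoch_length > 0, overlap >= 0)
  if (overlap >= epoch_length) stop("epoching: overlap must be < epoch_length")
  if (segment_duration < epoch_length - 1e-9) {
    stop("too-short: segment (", segment_duration,
         " s) shorter than one epoch (", epoch_length, " s)")
  }
  step <- epoch_length - overlap
  n <- floor((segment_duration - epoch_length) / step + 1e-9) + 1L
  structure((seq_len(n) - 1L) * step,
            epoch_length = epoch_length, overlap = overlap,
            class = "epoch_set")
}

# ---- recordings -------------------------------------------------------------

EEG_MONTAGE <- c("Fp1", "Fp2", "T3", "T4", "C3", "C4", "O1", "O2")

#' A uniformly sampled multichannel recording
#'
#' @param data numeric matrix, channels x samples; all values finite.
#' @param sampling_rate sampling rate in Hz (>= 256 for EEG/ECG).
#' @param modality one of `"EEG"`, `"ECG"`, `"EMG"`.
#' @param channel_labels character vector, one per row of `data`. EEG labels
#'   must come from the 8-electrode 10-20 montage
#'   (Fp1, Fp2, T3, T4, C3, C4, O1, O2).
#' @param annotations optional data.frame (`onset`, `duration`, `label`).
#' @param unit physical unit of the samples; defaults to uV for EEG/EMG and
#'   mV for ECG.
#' @param bad_segments optional artifact mask (see [artifact_mask()]).
#' @return object of class `recording`.
#' @export
recording <- function(data, sampling_rate, modality,
                      channel_labels = rownames(data),
                      annotations = NULL, unit = NULL, bad_segments = NULL) {
  modality <- match.arg(toupper(modality), c("EEG", "ECG", "EMG"))
  if (is.numeric(data) && is.null(dim(data))) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("recording: non-finite samples")
  stopifnot(length(sampling_rate) == 1L, is.finite(sampling_rate),
            sampling_rate > 0)
  if (modality %in% c("EEG", "ECG") && sampling_rate < 256) {
    stop("recording: ", modality, " requires sampling_rate >= 256 Hz")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0(modality, seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("recording: channel_labels length must equal the channel count")
  }
  if (modality == "EEG" && !all(channel_labels %in% EEG_MONTAGE)) {
    stop("recording: EEG channels must be from the montage ",
         paste(EEG_MONTAGE, collapse = ", "))
  }
  if (is.null(unit)) unit <- if (modality == "ECG") "mV" else "uV"
  rownames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 modality = modality, channel_labels = channel_labels,
                 annotations = annotations, unit = unit,
                 bad_segments = bad_segments),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<%s recording> %d channel(s) x %d samples @ %g Hz (%s), %.1f s\n",
              x$modality, nrow(x$data), ncol(x$data), x$sampling_rate, x$unit,
              recording_duration(x)))
  invisible(x)
}

#' @export
#' @rdname recording
recording_duration <- function(x) ncol(x$data) / x$sampling_rate

#' Is a recording eligible for EMG frequency analysis?
#'
#' EMG analysis covers 20-200 Hz, so only recordings sampled at >= 512 Hz
#' satisfy the Nyquist requirement.
#'
#' @param x a `recording`.
#' @return logical scalar.
#' @export
emg_eligible <- function(x) {
  x$modality == "EMG" && x$sampling_rate >= 512
}

# Sample-index range of an interval: 0-based start floor(start*fs),
# exclusive end floor(end*fs). Returned as 1-based R column indices.
interval_sample_idx <- function(interval, fs, n_samples) {
  i0 <- floor(interval[1L] * fs + 1e-9)
  i1 <- floor(interval[2L] * fs + 1e-9)
  i1 <- min(i1, n_samples)
  if (i1 <= i0) stop("invalid-segmentation: interval has no samples")
  (i0 + 1L):i1
}

#' One session of a study participant
#'
#' Container holding the available modality recordings, the period
#' segmentation, and an optional reference to the session's clinical scores.
#'
#' @param patient patient identifier.
#' @param session session index (1 or 2).
#' @param recordings named list of [recording()] objects (names `eeg`, `ecg`,
#'   `emg`; at least one present).
#' @param segmentation a [period_segmentation()] valid for every recording.
#' @param clinical optional clinical-score reference.
#' @return object of class `session_record`.
#' @export
session_record <- function(patient, session, recordings, segmentation,
                           clinical = NULL) {
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  if (!all(names(recordings) %in% c("eeg", "ecg", "emg"))) {
    stop("session_record: recordings must be named eeg/ecg/emg")
  }
  for (rec in recordings) {
    stopifnot(inherits(rec, "recording"))
    if (segmentation$post[2L] > recording_duration(rec) + 1e-6) {
      stop("invalid-segmentation: segmentation exceeds the ",
           rec$modality, " recording")
    }
  }
  structure(list(patient = patient, session = session,
                 recordings = recordings, segmentation = segmentation,
                 clinical = clinical),
            class = "session_record")
}

# Local RNG scope: runs `expr` under a fixed seed and restores the caller's
# RNG state afterwards, so generators are pure functions of (profile, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit string hash (djb2 variant) used to derive
# per-comparison RNG seeds from (global seed, labels...).
derive_seed <- function(seed, ...) {
  s <- paste(c(format(seed), vapply(list(...), as.character, "")),
             collapse = "|")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  as.integer(h)
}
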