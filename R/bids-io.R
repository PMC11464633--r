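# Reading and writing sessions in a BIDS-EEG style layout
# (sub-*/ses-*/eeg/*_eeg.vhdr|.edf with *_channels.tsv and *_events.tsv).
# Because the three modalities are sampled at different rates they are stored
# as separate files distinguished by the acq- entity (acq-eeg/ecg/emg).
# Supported raw formats: BrainVision (binary IEEE float32 / int16, or ASCII)
# and EDF; anything else is an unsupported-format error.

# ---- BrainVision ------------------------------------------------------------

write_brainvision <- function(rec, path_base) {
  vhdr <- paste0(path_base, ".vhdr")
  vmrk <- paste0(path_base, ".vmrk")
  dat <- paste0(path_base, ".eeg")
  nm <- basename(path_base)
  nch <- nrow(rec$data)
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", nm, ".eeg"),
    paste0("MarkerFile=", nm, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$sampling_rate, digits = 15)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    vapply(seq_len(nch), function(i) {
      sprintf("Ch%d=%s,,1,%s", i, rec$channel_labels[i], rec$unit)
    }, character(1)))
  writeLines(lines, vhdr)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", nm, ".eeg"),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,00000000000000000000"), vmrk)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(c(vhdr = vhdr, vmrk = vmrk, data = dat))
}

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list(); channels <- list(); section <- ""
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) { section <- ln; next }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- substr(ln, 1L, eq - 1L); val <- substr(ln, eq + 1L, nchar(ln))
    if (section == "[Channel Infos]") channels[[key]] <- val
    else kv[[key]] <- val
  }
  list(kv = kv, channels = channels)
}

read_brainvision <- function(vhdr_path) {
  hdr <- parse_vhdr(vhdr_path)
  kv <- hdr$kv
  nch <- as.integer(kv$NumberOfChannels)
  fs <- 1e6 / as.numeric(kv$SamplingInterval)
  chinfo <- lapply(hdr$channels, function(v) strsplit(v, ",")[[1L]])
  labels <- unname(vapply(chinfo, `[`, character(1), 1L))
  resolution <- unname(vapply(chinfo, function(v) {
    r <- suppressWarnings(as.numeric(v[3L]))
    if (is.na(r)) 1 else r
  }, numeric(1)))
  data_path <- file.path(dirname(vhdr_path), kv$DataFile)
  fmt <- toupper(kv$DataFormat %||% "BINARY")
  orient <- toupper(kv$DataOrientation %||% "MULTIPLEXED")
  if (fmt == "BINARY") {
    bfmt <- toupper(kv$BinaryFormat %||% "IEEE_FLOAT_32")
    sz <- file.info(data_path)$size
    con <- file(data_path, "rb")
    on.exit(close(con))
    raw_vals <- if (bfmt == "IEEE_FLOAT_32") {
      readBin(con, "numeric", n = sz %/% 4L, size = 4L, endian = "little")
    } else if (bfmt == "INT_16") {
      readBin(con, "integer", n = sz %/% 2L, size = 2L, signed = TRUE,
              endian = "little")
    } else stop("unsupported-format: BinaryFormat ", bfmt)
    ns <- length(raw_vals) %/% nch
    mat <- if (orient == "MULTIPLEXED") {
      matrix(raw_vals[seq_len(ns * nch)], nrow = nch)
    } else {
      t(matrix(raw_vals[seq_len(ns * nch)], ncol = nch))
    }
  } else if (fmt == "ASCII") {
    tab <- utils::read.table(data_path, header = FALSE)
    mat <- if (orient == "MULTIPLEXED") t(as.matrix(tab)) else as.matrix(tab)
    if (nrow(mat) != nch) mat <- t(mat)
  } else stop("unsupported-format: DataFormat ", fmt)
  mat <- mat * resolution
  rownames(mat) <- labels
  list(data = mat, sampling_rate = fs, labels = labels)
}

# ---- EDF --------------------------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  stopifnot(abs(fs - round(fs)) < 1e-9)
  nch <- nrow(rec$data)
  spr <- as.integer(round(fs))            # 1-s records
  n_rec <- floor(ncol(rec$data) / spr)
  dmin <- -32768; dmax <- 32767
  pmin <- apply(rec$data, 1L, min); pmax <- apply(rec$data, 1L, max)
  span <- pmax - pmin
  pmin <- pmin - 0.01 * pmax(span, 1e-6)
  pmax <- pmax + 0.01 * pmax(span, 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate 01-JAN-2020 X X X", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256L * (1L + nch), 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(nch, 4)
  for (i in seq_len(nch)) wr(rec$channel_labels[i], 16)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(rec$unit, 8)
  for (i in seq_len(nch)) wr(format(pmin[i], digits = 6), 8)
  for (i in seq_len(nch)) wr(format(pmax[i], digits = 6), 8)
  for (i in seq_len(nch)) wr(dmin, 8)
  for (i in seq_len(nch)) wr(dmax, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(spr, 8)
  for (i in seq_len(nch)) wr("", 32)
  gain <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      seg <- rec$data[i, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- as.integer(round((seg - pmin[i]) * gain[i] + dmin))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)
  units <- vapply(seq_len(nch), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("unsupported-format: per-signal sampling rates differ")
  }
  fs <- spr[1L] / rec_dur
  out <- matrix(NA_real_, nrow = nch, ncol = n_rec * spr[1L])
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      out[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (dig - dmin[i]) * gain[i] + pmin[i]
    }
  }
  rownames(out) <- labels
  list(data = out, sampling_rate = fs, labels = labels, units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- session writer ---------------------------------------------------------

bids_base <- function(root, sub, ses, acq) {
  dir <- file.path(root, sprintf("sub-%02d", sub), sprintf("ses-%02d", ses),
                   "eeg")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file.path(dir, sprintf("sub-%02d_ses-%02d_task-mar_acq-%s", sub, ses, acq))
}

#' Write one synthetic session into the BIDS-style layout
#'
#' Writes each modality as its own data file (`acq-eeg`/`acq-ecg`/`acq-emg`)
#' with the accompanying `_channels.tsv` (name, type, units,
#' sampling_frequency) and `_events.tsv` (PRE/MTI/POST onsets and durations),
#' plus an optional ground-truth sidecar JSON.
#'
#' @param session a [session_record()].
#' @param root dataset root directory.
#' @param format `"brainvision"` (float32 binary) or `"edf"` (16-bit).
#' @param ground_truth optional list serialized as the sidecar JSON.
#' @return invisibly, the paths written.
#' @export
write_bids_session <- function(session, root, format = c("brainvision", "edf"),
                               ground_truth = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(session, "session_record"))
  sub <- session$patient; ses <- session$session
  seg <- session$segmentation
  paths <- character(0)
  for (mod in names(session$recordings)) {
    rec <- session$recordings[[mod]]
    base <- bids_base(root, sub, ses, mod)
    if (format == "brainvision") {
      write_brainvision(rec, base)
      paths <- c(paths, paste0(base, "_eeg.vhdr"))
      # BIDS suffix naming: rename the triplet to *_eeg.*
      for (ext in c(".vhdr", ".vmrk", ".eeg")) {
        file.rename(paste0(base, ext), paste0(base, "_eeg", ext))
      }
      fix_brainvision_links(paste0(base, "_eeg"))
    } else {
      write_edf(rec, paste0(base, "_eeg.edf"))
      paths <- c(paths, paste0(base, "_eeg.edf"))
    }
    utils::write.table(
      data.frame(name = rec$channel_labels, type = rec$modality,
                 units = rec$unit, sampling_frequency = rec$sampling_rate),
      paste0(base, "_channels.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    ev <- data.frame(onset = c(seg$pre[1L], seg$mti[1L], seg$post[1L]),
                     duration = c(interval_duration(seg$pre),
                                  interval_duration(seg$mti),
                                  interval_duration(seg$post)),
                     trial_type = c("PRE", "MTI", "POST"))
    utils::write.table(ev, paste0(base, "_events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(ground_truth)) {
    gt_path <- file.path(root, sprintf("sub-%02d", sub),
                         sprintf("ses-%02d", ses),
                         sprintf("sub-%02d_ses-%02d_groundtruth.json",
                                 sub, ses))
    jsonlite::write_json(ground_truth, gt_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}

# rewrite DataFile/MarkerFile entries after the BIDS rename
fix_brainvision_links <- function(base) {
  nm <- basename(base)
  for (ext in c(".vhdr", ".vmrk")) {
    p <- paste0(base, ext)
    lines <- readLines(p, warn = FALSE)
    lines <- sub("^DataFile=.*", paste0("DataFile=", nm, ".eeg"), lines)
    lines <- sub("^MarkerFile=.*", paste0("MarkerFile=", nm, ".vmrk"), lines)
    writeLines(lines, p)
  }
}

# ---- discovery and loading --------------------------------------------------

#' Discover sessions under a BIDS-style dataset root
#'
#' One manifest per `sub-*/ses-*` pair containing at least one raw data file,
#' in lexicographic subject-then-session order. Non-BIDS folder names are
#' ignored.
#'
#' @param root readable dataset root directory.
#' @return list of `session_manifest` objects (dataset root, subject and
#'   session identifiers, per-modality data/channels/events paths).
#' @export
discover_sessions <- function(root) {
  stopifnot(dir.exists(root))
  subs <- sort(list.files(root, pattern = "^sub-[A-Za-z0-9]+$"))
  manifests <- list()
  for (sub in subs) {
    sess <- sort(list.files(file.path(root, sub),
                            pattern = "^ses-[A-Za-z0-9]+$"))
    for (ses in sess) {
      eegdir <- file.path(root, sub, ses, "eeg")
      if (!dir.exists(eegdir)) next
      raw <- sort(list.files(eegdir, pattern = "_eeg\\.(vhdr|edf)$",
                             full.names = TRUE))
      if (length(raw) == 0L) next
      files <- list()
      for (f in raw) {
        acq <- sub(".*_acq-([A-Za-z0-9]+)_.*", "\\1", basename(f))
        if (acq == basename(f)) acq <- "eeg"   # no acq entity
        base <- sub("_eeg\\.(vhdr|edf)$", "", f)
        files[[acq]] <- list(
          data = f,
          channels = paste0(base, "_channels.tsv"),
          events = paste0(base, "_events.tsv"))
      }
      manifests[[length(manifests) + 1L]] <- structure(
        list(root = root, subject = sub, session = ses, files = files),
        class = "session_manifest")
    }
  }
  if (length(manifests) == 0L) {
    stop("empty-dataset: no sub-*/ses-* sessions with raw data under ", root)
  }
  manifests
}

read_raw_any <- function(path) {
  if (grepl("\\.vhdr$", path)) read_brainvision(path)
  else if (grepl("\\.edf$", path)) read_edf(path)
  else stop("unsupported-format: ", basename(path))
}

# unit normalization targets per modality
normalize_units <- function(data, units, modality) {
  target <- if (modality == "ECG") "mV" else "uV"
  factor_to_uv <- function(u) {
    switch(tolower(gsub("µ", "u", u)),
           "uv" = 1, "mv" = 1e3, "v" = 1e6,
           stop("unsupported-format: unknown unit ", u))
  }
  scale <- vapply(units, factor_to_uv, numeric(1)) /
    if (target == "mV") 1e3 else 1
  data * scale
}

#' Load one session from its manifest
#'
#' Splits channels by the `type` column of `channels.tsv` (falling back to
#' ECG/EMG label prefixes, otherwise a channel-classification error), builds
#' the period segmentation from the events table, and normalizes units to uV
#' (EEG/EMG) and mV (ECG). EMG recordings sampled below 512 Hz are loaded but
#' flagged analysis-ineligible (see [emg_eligible()]).
#'
#' @param manifest a `session_manifest` from [discover_sessions()].
#' @param label_map period label map passed to
#'   [segmentation_from_annotations()].
#' @return a [session_record()].
#' @export
load_session <- function(manifest,
                         label_map = c(pre = "PRE", mti = "MTI",
                                       post = "POST")) {
  stopifnot(inherits(manifest, "session_manifest"))
  recs <- list()
  seg <- NULL
  for (acq in names(manifest$files)) {
    f <- manifest$files[[acq]]
    raw <- read_raw_any(f$data)
    chan <- if (file.exists(f$channels)) {
      utils::read.delim(f$channels, stringsAsFactors = FALSE)
    } else NULL
    types <- if (!is.null(chan) && "type" %in% names(chan)) {
      toupper(chan$type[match(raw$labels, chan$name)])
    } else {
      ifelse(grepl("^ECG", raw$labels, ignore.case = TRUE), "ECG",
             ifelse(grepl("^EMG", raw$labels, ignore.case = TRUE), "EMG",
                    ifelse(raw$labels %in% EEG_MONTAGE, "EEG", NA)))
    }
    if (any(is.na(types) | !types %in% c("EEG", "ECG", "EMG"))) {
      stop("channel-classification: cannot type channels ",
           paste(raw$labels[is.na(types) | !types %in% c("EEG", "ECG", "EMG")],
                 collapse = ", "))
    }
    units <- if (!is.null(chan) && "units" %in% names(chan)) {
      chan$units[match(raw$labels, chan$name)]
    } else if (!is.null(raw$units)) raw$units
    else rep("uV", length(raw$labels))
    if (!file.exists(f$events)) {
      stop("invalid-segmentation: missing events file for ", acq)
    }
    ev <- utils::read.delim(f$events, stringsAsFactors = FALSE)
    names(ev)[names(ev) == "trial_type"] <- "label"
    for (ty in unique(types)) {
      idx <- which(types == ty)
      dat <- normalize_units(raw$data[idx, , drop = FALSE], units[idx], ty)
      recs[[tolower(ty)]] <- recording(dat, raw$sampling_rate, ty,
                                       channel_labels = raw$labels[idx],
                                       annotations = ev)
      if (is.null(seg) || ty == "EEG") {
        seg <- segmentation_from_annotations(
          ev, duration = ncol(dat) / raw$sampling_rate + 1e-6,
          label_map = label_map)
      }
    }
  }
  session_record(patient = as.integer(sub("sub-0*", "", manifest$subject)),
                 session = as.integer(sub("ses-0*", "", manifest$session)),
                 recordings = recs, segmentation = seg)
}

# ---- results writer ---------------------------------------------------------

format_full <- function(x) {
  if (is.numeric(x)) vapply(x, function(v) sprintf("%.17g", v), character(1))
  else as.character(x)
}

#' Write tidy result tables and a run summary
#'
#' One TSV per table ("." decimal separator, UTF-8, Unix newlines, numerics
#' rendered with 17 significant digits so a write-read round trip is
#' lossless) plus a `run_summary.json` with the configuration hash, seed and
#' package version.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param overwrite allow replacing existing files (default `FALSE`:
#'   collisions are a refusal error).
#' @param config optional configuration list echoed (and hashed) into the
#'   run summary.
#' @param seed seed recorded in the run summary.
#' @return named character vector of written paths.
#' @export
write_results <- function(tables, out_dir, overwrite = FALSE, config = NULL,
                          seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    if (file.exists(p) && !overwrite) {
      stop("refusing to overwrite ", p, " (set overwrite = TRUE)")
    }
    tab <- as.data.frame(tables[[nm]])
    out <- as.data.frame(lapply(tab, format_full), stringsAsFactors = FALSE)
    names(out) <- names(tab)
    con <- file(p, "wb")
    writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
    if (nrow(out)) {
      writeLines(do.call(paste, c(unname(out), sep = "\t")), con, sep = "\n")
    }
    close(con)
    paths[nm] <- p
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  cfg_hash <- derive_seed(0L, paste(utils::capture.output(utils::str(config)),
                                    collapse = "\n"))
  jsonlite::write_json(
    list(config = config, config_hash = cfg_hash, seed = seed,
         package_version = as.character(utils::packageVersion("marphysio")),
         tables = names(tables)),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  paths["run_summary"] <- summary_path
  paths
}
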