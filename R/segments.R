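#' Build a segment table
#'
#' The canonical in-memory container for synchronized waveform segments is a
#' tibble with one row per segment and one list-column per channel. Every
#' channel vector within a row shares the sampling rate `fs` and length;
#' `ppg` and `abp` are the channels the pipeline requires, `ecg`, `vpg` and
#' `apg` are optional. Store-level metadata (source name, preprocessing
#' history) travels in the `"bp_metadata"` attribute.
#'
#' @param segment_id Character vector of unique segment identifiers.
#' @param subject_id Character vector of subject identifiers (recycled).
#' @param fs Sampling rate in Hz, shared by all channels of a record.
#' @param ppg,abp,ecg,vpg,apg Lists of numeric sample vectors (or `NULL` for
#'   absent optional channels).
#' @param metadata Named list; `source` and `history` entries are maintained
#'   by the pipeline stages.
#' @return A `segment_tbl` tibble.
#' @export
segment_tbl <- function(segment_id, subject_id, fs, ppg = NULL, abp = NULL,
                        ecg = NULL, vpg = NULL, apg = NULL,
                        metadata = list()) {
  n <- length(segment_id)
  as_chan <- function(x) {
    if (is.null(x)) return(vector("list", n))
    stopifnot(length(x) == n)
    lapply(x, as.numeric)
  }
  tbl <- tibble::tibble(
    segment_id = as.character(segment_id),
    subject_id = rep_len(as.character(subject_id), n),
    fs = rep_len(as.numeric(fs), n),
    ppg = as_chan(ppg), ecg = as_chan(ecg), abp = as_chan(abp),
    vpg = as_chan(vpg), apg = as_chan(apg)
  )
  metadata$history <- metadata$history %||% character()
  attr(tbl, "bp_metadata") <- metadata
  class(tbl) <- c("segment_tbl", class(tbl))
  validate_segments(tbl, require = character())
}

#' Validate a segment table
#'
#' Checks the container invariants: unique segment ids, positive shared `fs`,
#' finite samples, and equal channel lengths within each record. Required
#' channels are `ppg` and `abp` unless `require` says otherwise.
#'
#' @param segments A `segment_tbl`.
#' @param require Character vector of channels that must be present.
#' @return `segments`, invisibly unchanged, or an error naming the offending
#'   segment.
#' @export
validate_segments <- function(segments, require = c("ppg", "abp")) {
  if (nrow(segments) == 0) return(segments)
  if (anyDuplicated(segments$segment_id)) {
    abort("duplicate segment_id in segment table")
  }
  if (any(!is.finite(segments$fs) | segments$fs <= 0)) {
    abort("fs must be positive and finite")
  }
  for (i in seq_len(nrow(segments))) {
    chans <- present_channels(segments[i, ])
    if (!all(require %in% chans)) {
      abort(sprintf("segment %s: missing required channel(s) %s",
                    segments$segment_id[i],
                    paste(setdiff(require, chans), collapse = ", ")))
    }
    lens <- vapply(chans, function(ch) length(segments[[ch]][[i]]), 1L)
    if (length(unique(lens)) > 1L) {
      abort(sprintf("segment %s: channel length mismatch (%s)",
                    segments$segment_id[i],
                    paste(chans, lens, sep = "=", collapse = ", ")))
    }
    if (any(lens < 2L)) {
      abort(sprintf("segment %s: channels must have length >= 2",
                    segments$segment_id[i]))
    }
    bad <- chans[vapply(chans,
                        function(ch) any(!is.finite(segments[[ch]][[i]])), TRUE)]
    if (length(bad)) {
      abort(sprintf("segment %s: non-finite samples in %s",
                    segments$segment_id[i], paste(bad, collapse = ", ")))
    }
  }
  segments
}

present_channels <- function(row) {
  BP_CHANNELS[vapply(BP_CHANNELS,
                     function(ch) ch %in% names(row) &&
                       !is.null(row[[ch]][[1]]) && length(row[[ch]][[1]]) > 0,
                     TRUE)]
}

#' Segment-store metadata
#' @param segments A `segment_tbl`.
#' @return The metadata list (source, history flags, ...).
#' @export
segment_metadata <- function(segments) {
  attr(segments, "bp_metadata") %||% list(history = character())
}

#' Append a preprocessing-history flag
#' @param segments A `segment_tbl`.
#' @param flag Single character flag to append (history is append-only).
#' @return The segment table with updated metadata.
#' @export
add_history <- function(segments, flag) {
  md <- segment_metadata(segments)
  md$history <- c(md$history, flag)
  attr(segments, "bp_metadata") <- md
  segments
}

#' Read a segment store
#'
#' Two plain-text formats are supported. `"dir"` is the canonical store: a
#' directory holding `index.csv` (`segment_id,subject_id,fs`), one
#' `<channel>.csv` sample matrix per channel (rows aligned with the index),
#' optionally `labels.csv`, and `metadata.json`. `"csv-matrix"` is a bare
#' numeric matrix in one CSV file, one segment per row, all rows declared as
#' the single channel `kind`; the channel convention is never guessed from
#' the data.
#'
#' @param path Directory (for `"dir"`) or CSV file (for `"csv-matrix"`).
#' @param format `"dir"` or `"csv-matrix"`.
#' @param kind Channel kind for `"csv-matrix"` input (default `"ppg"`).
#' @param fs Sampling rate for `"csv-matrix"` input.
#' @return A `segment_tbl`; labels, if present, in attribute `"labels"`.
#' @export
read_store <- function(path, format = c("dir", "csv-matrix"),
                       kind = "ppg", fs = 125) {
  format <- match.arg(format)
  if (format == "csv-matrix") {
    if (!file.exists(path)) abort(sprintf("cannot read store: %s", path))
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    kind <- match.arg(kind, BP_CHANNELS)
    chan <- lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    args <- list(segment_id = sprintf("seg%04d", seq_len(nrow(m))),
                 subject_id = "unknown", fs = fs,
                 ppg = NULL, abp = NULL,
                 metadata = list(source = path, history = character()))
    args[[kind]] <- chan
    tbl <- do.call(segment_tbl, args)
    return(validate_segments(tbl, require = kind))
  }
  if (!dir.exists(path)) abort(sprintf("cannot read store: %s", path))
  idx <- readr::read_csv(file.path(path, "index.csv"), show_col_types = FALSE)
  chans <- intersect(BP_CHANNELS,
                     sub("\\.csv$", "", list.files(path, pattern = "\\.csv$")))
  read_chan <- function(ch) {
    f <- file.path(path, paste0(ch, ".csv"))
    if (!file.exists(f)) return(NULL)
    # base parser: correctly rounded doubles, so text round-trips bit-exact
    m <- as.matrix(utils::read.csv(f, header = FALSE))
    if (nrow(m) != nrow(idx)) {
      abort(sprintf("malformed store: %s has %d rows, index has %d",
                    ch, nrow(m), nrow(idx)))
    }
    lapply(seq_len(nrow(m)), function(i) {
      v <- unname(m[i, ])
      v[!is.na(v)] # ragged rows padded with NA on write
    })
  }
  md <- list(history = character())
  mdf <- file.path(path, "metadata.json")
  if (file.exists(mdf)) md <- jsonlite::read_json(mdf, simplifyVector = TRUE)
  md$history <- as.character(md$history %||% character())
  args <- c(list(segment_id = idx$segment_id, subject_id = idx$subject_id,
                 fs = idx$fs, metadata = md),
            stats::setNames(lapply(chans, read_chan), chans))
  if (!"ppg" %in% chans) args$ppg <- NULL
  if (!"abp" %in% chans) args$abp <- NULL
  tbl <- do.call(segment_tbl, args)
  tbl <- validate_segments(tbl, require = chans[1])
  lf <- file.path(path, "labels.csv")
  if (file.exists(lf)) {
    attr(tbl, "labels") <- readr::read_csv(lf, show_col_types = FALSE)
  }
  tbl
}

#' Write a segment store
#'
#' Inverse of [read_store()]. `"dir"` writes the canonical directory store
#' (full double precision, so a read-back is bit-identical); `"csv-matrix"`
#' writes a single channel as a bare matrix.
#'
#' @param segments Non-empty `segment_tbl`.
#' @param path Target directory or file.
#' @param format `"dir"` or `"csv-matrix"`.
#' @param kind Channel written in `"csv-matrix"` mode.
#' @param labels Optional labels tibble stored alongside the segments.
#' @export
write_store <- function(segments, path, format = c("dir", "csv-matrix"),
                        kind = "ppg", labels = NULL) {
  format <- match.arg(format)
  if (nrow(segments) == 0) abort("refusing to write an empty store")
  if (format == "csv-matrix") {
    chan <- segments[[match.arg(kind, BP_CHANNELS)]]
    m <- do.call(rbind, chan)
    readr::write_csv(as.data.frame(m), path, col_names = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    tibble::tibble(segment_id = segments$segment_id,
                   subject_id = segments$subject_id, fs = segments$fs),
    file.path(path, "index.csv"))
  for (ch in present_channels(segments[1, ])) {
    lens <- vapply(segments[[ch]], length, 1L)
    m <- matrix(NA_real_, nrow(segments), max(lens))
    for (i in seq_len(nrow(segments))) m[i, seq_len(lens[i])] <- segments[[ch]][[i]]
    # %.17g guarantees bit-exact double round-trip through text
    mc <- matrix(sprintf("%.17g", m), nrow(m))
    mc[is.na(m)] <- ""
    utils::write.table(mc, file.path(path, paste0(ch, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(segment_metadata(segments),
                       file.path(path, "metadata.json"), auto_unbox = TRUE)
  labels <- labels %||% attr(segments, "labels")
  if (!is.null(labels)) readr::write_csv(labels, file.path(path, "labels.csv"))
  invisible(path)
}

#' Resample a waveform
#'
#' Rate conversion with a zero-phase anti-aliasing low-pass (applied when
#' down-sampling), so channels stay mutually synchronized. The output length
#' is `round(length(x) * target_fs / fs)`.
#'
#' @param x Numeric sample vector.
#' @param fs Current sampling rate (Hz).
#' @param target_fs Desired sampling rate (Hz).
#' @param taps FIR length of the anti-aliasing filter.
#' @return Numeric vector at `target_fs`.
#' @export
resample_wave <- function(x, fs, target_fs, taps = 128) {
  if (!is.finite(fs) || fs <= 0 || !is.finite(target_fs) || target_fs <= 0) {
    abort("sampling rates must be positive")
  }
  if (target_fs == fs) return(x)
  n_out <- round(length(x) * target_fs / fs)
  if (target_fs < fs) {
    cutoff <- 0.8 * (target_fs / 2) / (fs / 2) # normalized to Nyquist
    h <- signal::fir1(taps, cutoff)
    x <- signal::filtfilt(filt = h, a = 1, x = x)
  }
  ratio <- fs / target_fs
  idx <- 1 + (seq_len(n_out) - 1) * ratio
  if (all(abs(idx - round(idx)) < 1e-9)) return(x[round(idx)])
  spline(seq_along(x), x, xout = idx, method = "natural")$y
}

#' Resample every channel of a segment table
#' @param segments A `segment_tbl`.
#' @param target_fs Target rate in Hz.
#' @return Resampled `segment_tbl` with updated `fs` and a history flag.
#' @export
resample_segments <- function(segments, target_fs) {
  for (ch in BP_CHANNELS) {
    if (!ch %in% names(segments)) next
    segments[[ch]] <- lapply(seq_len(nrow(segments)), function(i) {
      v <- segments[[ch]][[i]]
      if (is.null(v) || !length(v)) return(v)
      resample_wave(v, segments$fs[i], target_fs)
    })
  }
  segments$fs <- target_fs
  add_history(segments, sprintf("resampled_%g_Hz", target_fs))
}

#' Denormalize an externally recorded ABP channel
#'
#' External reBAP-style recordings store pressure in volts on a fixed
#' mmHg-per-volt scale; multiplying by the scale restores mmHg.
#'
#' @param segments A `segment_tbl` with an `abp` channel in volts.
#' @param scale mmHg per volt (reBAP convention: 100).
#' @return Segment table with `abp` in mmHg and a history flag.
#' @export
denormalize_abp <- function(segments, scale = 100) {
  if (!is.numeric(scale) || scale <= 0) abort("scale must be positive")
  if (all(vapply(segments$abp, is.null, TRUE))) {
    abort("denormalize_abp requires an abp channel")
  }
  segments$abp <- lapply(segments$abp, function(v) if (is.null(v)) v else v * scale)
  add_history(segments, sprintf("abp_denormalized_x%g", scale))
}
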