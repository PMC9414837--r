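# On-disk representation of a monitor data log: two CSV files sharing a
# prefix. "<prefix>_eeg.csv" holds the raw EEG (one row per sample at 128 Hz,
# header t_sample,eeg_uV[,eeg_uV_ch2]); "<prefix>_ann.csv" holds the
# per-second annotation stream (header t_s,bis,sqi,emg). All indices are
# 0-based; second t covers the half-open sample interval [t*fs, (t+1)*fs).

#' Construct a data log
#'
#' Bundles an EEG recording with its per-second annotation stream and checks
#' the alignment invariants: one annotation per whole second of EEG, strictly
#' increasing 0-based second indices, `bis` in `[0, 100]` or the monitor's
#' invalid sentinel (-3276.8), `sqi` in `[0, 100]`.
#'
#' @param samples Numeric vector of EEG amplitudes (microvolts).
#' @param annotations Tibble/data frame with columns `t_s`, `bis`, `sqi`,
#'   `emg`.
#' @param fs Sampling rate in Hz (default 128; the only rate the pipeline is
#'   calibrated for).
#' @param subject_id Opaque subject label.
#' @param channel Channel label (default `"CH2"`).
#' @return An object of class `ndoa_datalog`.
#' @export
new_datalog <- function(samples, annotations, fs = 128, subject_id = "S1",
                        channel = "CH2") {
  samples <- as.numeric(samples)
  stopifnot(fs > 0)
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("EEG samples must be finite", call. = FALSE)
  }
  annotations <- tibble::as_tibble(annotations)
  need <- c("t_s", "bis", "sqi", "emg")
  if (!all(need %in% names(annotations))) {
    stop("annotations need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  n_sec <- length(samples) %/% fs
  if (nrow(annotations) != n_sec) {
    stop("annotation count (", nrow(annotations), ") != floor(samples/fs) (",
         n_sec, ")", call. = FALSE)
  }
  if (n_sec > 0) {
    if (any(diff(annotations$t_s) <= 0) && n_sec > 1) {
      stop("annotation seconds must be strictly increasing", call. = FALSE)
    }
    bad_bis <- !(is_bis_sentinel(annotations$bis) |
                   (annotations$bis >= 0 & annotations$bis <= 100))
    if (any(bad_bis)) stop("bis outside [0,100] and not the sentinel", call. = FALSE)
    if (any(annotations$sqi < 0 | annotations$sqi > 100)) {
      stop("sqi outside [0,100]", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, annotations = annotations, fs = fs,
         subject_id = subject_id, channel = channel),
    class = "ndoa_datalog"
  )
}

#' @export
print.ndoa_datalog <- function(x, ...) {
  cat("<ndoa_datalog> subject", x$subject_id, "channel", x$channel, "\n")
  cat("  ", length(x$samples), "samples @", x$fs, "Hz =",
      length(x$samples) %/% x$fs, "s;", nrow(x$annotations), "annotations\n")
  inv <- sum(!valid_bis_mask(x$annotations))
  cat("  invalid-reference seconds:", inv, "\n")
  invisible(x)
}

# TRUE where bis equals the monitor's invalid sentinel (absolute tolerance
# 1e-6: the value round-trips through decimal text).
is_bis_sentinel <- function(bis) abs(bis - BIS_SENTINEL) < 1e-6

#' Mask of seconds with a usable reference value
#'
#' `FALSE` exactly where the reference is the invalid sentinel (-3276.8) or
#' the signal-quality indicator is below 15 (the monitor blanks its display
#' there); `TRUE` elsewhere.
#'
#' @param annotations Annotation tibble with columns `bis` and `sqi`.
#' @return Logical vector, one element per second.
#' @export
valid_bis_mask <- function(annotations) {
  !(is_bis_sentinel(annotations$bis) | annotations$sqi < 15)
}

.datalog_paths <- function(prefix) {
  list(eeg = paste0(prefix, "_eeg.csv"), ann = paste0(prefix, "_ann.csv"))
}

#' Read a data log from disk
#'
#' Reads the two-file CSV dialect written by [write_datalog()]. When the EEG
#' file carries two channels (`eeg_uV`, `eeg_uV_ch2`), `channel` selects one
#' (default CH2, the channel with the more consistent signal quality on the
#' supported monitors). The invalid-reference sentinel -3276.8 is preserved
#' verbatim, never coerced.
#'
#' @param prefix Path prefix; `<prefix>_eeg.csv` and `<prefix>_ann.csv` must
#'   exist.
#' @param channel `"CH1"` or `"CH2"` (used only for two-channel files).
#' @param fs Expected sampling rate. A file whose sample count implies a
#'   different rate than the annotation count is rejected unless
#'   `allow_any_fs = TRUE`.
#' @param subject_id Label attached to the recording (default: the prefix
#'   basename).
#' @param allow_any_fs Override the 128 Hz check.
#' @return An `ndoa_datalog`.
#' @export
read_datalog <- function(prefix, channel = c("CH2", "CH1"), fs = 128,
                         subject_id = basename(prefix), allow_any_fs = FALSE) {
  channel <- match.arg(channel)
  p <- .datalog_paths(prefix)
  for (f in unlist(p)) if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  eeg <- tryCatch(
    suppressWarnings(
      readr::read_csv(p$eeg, col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE)
    ),
    error = function(e) stop("malformed EEG file ", p$eeg, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  prob <- readr::problems(eeg)
  if (nrow(prob) > 0) {
    stop("parse error in ", p$eeg, " at line ", prob$row[1], ": ",
         prob$expected[1], call. = FALSE)
  }
  ann <- suppressWarnings(
    readr::read_csv(p$ann, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  prob <- readr::problems(ann)
  if (nrow(prob) > 0) {
    stop("parse error in ", p$ann, " at line ", prob$row[1], ": ",
         prob$expected[1], call. = FALSE)
  }
  col <- if (channel == "CH2" && "eeg_uV_ch2" %in% names(eeg)) "eeg_uV_ch2" else "eeg_uV"
  if (!col %in% names(eeg)) stop("EEG file lacks column ", col, call. = FALSE)
  samples <- eeg[[col]]
  implied <- if (nrow(ann) > 0) length(samples) / nrow(ann) else fs
  if (!allow_any_fs && nrow(ann) > 0 && abs(implied - 128) > 1e-9) {
    stop("unsupported sampling rate: ", implied, " Hz implied by the file ",
         "(the pipeline is calibrated for 128 Hz; pass allow_any_fs = TRUE ",
         "to override)", call. = FALSE)
  }
  new_datalog(samples, ann, fs = if (allow_any_fs) implied else fs,
              subject_id = subject_id, channel = channel)
}

#' Write a data log to disk
#'
#' Emits the two-file CSV dialect read by [read_datalog()]. Amplitudes are
#' written with enough digits to round-trip within 1e-9; the invalid
#' sentinel appears verbatim as `-3276.8`.
#'
#' @param log An `ndoa_datalog`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_datalog <- function(log, prefix) {
  stopifnot(inherits(log, "ndoa_datalog"))
  p <- .datalog_paths(prefix)
  eeg <- tibble::tibble(
    t_sample = seq_along(log$samples) - 1L,
    eeg_uV = format(log$samples, digits = 15, trim = TRUE, scientific = FALSE)
  )
  readr::write_csv(eeg, p$eeg, progress = FALSE)
  ann <- log$annotations
  ann$bis <- ifelse(is_bis_sentinel(ann$bis), "-3276.8",
                    format(ann$bis, digits = 15, trim = TRUE, scientific = FALSE))
  readr::write_csv(ann, p$ann, progress = FALSE)
  invisible(prefix)
}
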