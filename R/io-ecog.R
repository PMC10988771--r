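#' Construct an ECoG recording
#'
#' The in-memory carrier for intracranial recordings: a channels-by-samples
#' matrix of voltages (microvolt), the sampling rate, a channel table mapping
#' each channel to its strip and position along the strip, and trial markers
#' in sample units. Every preprocessing stage consumes and returns this type,
#' appending to its provenance record.
#'
#' @param samples Numeric matrix, channels x samples, row names = channel ids.
#' @param fs Sampling rate in Hz.
#' @param channels Tibble with columns `channel_id`, `strip_id`,
#'   `index_in_strip`; defaults are parsed from row names of the form
#'   `S<strip>E<index>`.
#' @param markers Tibble with columns `trial_id`, `condition` (one of
#'   `"rest"`, `"easy"`, `"hard"`), `onset`, `offset` (1-based sample indices,
#'   inclusive, onset < offset <= n samples), sorted by onset.
#' @param provenance Character vector of applied processing steps.
#'
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(samples, fs, channels = NULL, markers = NULL,
                           provenance = character()) {
  samples <- as.matrix(samples)
  if (is.null(rownames(samples)))
    rownames(samples) <- sprintf("ch%02d", seq_len(nrow(samples)))
  if (is.null(channels)) channels <- parse_channel_ids(rownames(samples))
  if (is.null(markers))
    markers <- tibble(trial_id = integer(), condition = character(),
                      onset = integer(), offset = integer())
  if (fs <= 0) abort("fs must be positive", class = "glio_argument_error")
  validate_markers(markers, ncol(samples))
  structure(list(samples = samples, fs = fs,
                 channels = as_tibble(channels),
                 markers = arrange(as_tibble(markers), .data$onset),
                 provenance = provenance),
            class = "ecog_recording")
}

parse_channel_ids <- function(ids) {
  m <- regmatches(ids, regexec("^S(\\d+)E(\\d+)$", ids))
  ok <- lengths(m) == 3
  tibble(channel_id = ids,
         strip_id = ifelse(ok, paste0("S", vapply(m, function(x) x[2] %||% NA_character_, "")), "S1"),
         index_in_strip = ifelse(ok, as.integer(vapply(m, function(x) x[3] %||% NA_character_, "")),
                                 seq_along(ids)))
}

validate_markers <- function(markers, n_samples) {
  need <- c("trial_id", "condition", "onset", "offset")
  if (!all(need %in% names(markers)))
    abort("markers need columns trial_id, condition, onset, offset",
          class = "glio_format_error")
  bad <- setdiff(unique(markers$condition), c("rest", "easy", "hard"))
  if (length(bad))
    abort(paste("unknown condition label(s):", paste(bad, collapse = ", ")),
          class = "glio_format_error")
  if (nrow(markers) && any(markers$onset >= markers$offset))
    abort("marker onsets must precede offsets", class = "glio_format_error")
  if (nrow(markers) && any(markers$offset > n_samples))
    abort("marker beyond recording length", class = "glio_range_error")
  if (nrow(markers) && any(markers$onset < 1))
    abort("marker onset before recording start", class = "glio_range_error")
  invisible(markers)
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs,
              nrow(x$markers)))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)

#' Read an ECoG recording with trial markers
#'
#' Accepts either EDF (European Data Format, 16-bit) or the package's
#' delimited-text fallback (first line `fs <TAB> <Hz>`, second line channel
#' ids, then one row per sample). Markers are a CSV with columns `trial_id`,
#' `condition` in rest/easy/hard, `onset_s`, `offset_s` (seconds); they are
#' converted to sample units (floor for onsets, so second 0 is sample 1) and
#' sorted by onset.
#'
#' @param path Recording file (`.edf` or text).
#' @param markers_path Marker CSV.
#' @return An [ecog_recording()].
#' @export
read_ecog <- function(path, markers_path = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    raw <- read_edf(path)
  } else {
    raw <- read_ecog_text(path)
  }
  markers <- NULL
  if (!is.null(markers_path)) {
    mk <- utils::read.csv(markers_path, stringsAsFactors = FALSE)
    need <- c("trial_id", "condition", "onset_s", "offset_s")
    if (!all(need %in% names(mk)))
      abort("marker file needs trial_id, condition, onset_s, offset_s",
            class = "glio_format_error")
    markers <- tibble(trial_id = mk$trial_id, condition = mk$condition,
                      onset = floor(mk$onset_s * raw$fs) + 1L,
                      offset = floor(mk$offset_s * raw$fs))
  }
  ecog_recording(raw$samples, raw$fs, markers = markers,
                 provenance = sprintf("read:%s", basename(path)))
}

#' Write an ECoG recording
#'
#' @param rec An [ecog_recording()].
#' @param path Output file; `.edf` selects EDF, anything else the text format.
#' @param markers_path Optional CSV path for the markers (seconds).
#' @return `path`, invisibly.
#' @export
write_ecog <- function(rec, path, markers_path = NULL) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) write_edf(rec, path)
  else write_ecog_text(rec, path)
  if (!is.null(markers_path)) {
    mk <- rec$markers
    utils::write.csv(
      data.frame(trial_id = mk$trial_id, condition = mk$condition,
                 onset_s = (mk$onset - 1) / rec$fs, offset_s = mk$offset / rec$fs),
      markers_path, row.names = FALSE)
  }
  invisible(path)
}

read_ecog_text <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  l1 <- strsplit(readLines(con, n = 1), "\t")[[1]]
  if (length(l1) != 2 || l1[1] != "fs")
    abort("text recording must start with 'fs<TAB><Hz>'", class = "glio_format_error")
  fs <- as.numeric(l1[2])
  ids <- strsplit(readLines(con, n = 1), "\t")[[1]]
  dat <- scan(con, what = double(), sep = "\t", quiet = TRUE)
  m <- matrix(dat, nrow = length(ids))   # stored sample-major: each row of file = one sample
  rownames(m) <- ids
  list(samples = m, fs = fs)
}

write_ecog_text <- function(rec, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("fs\t%.10g", rec$fs), con)
  writeLines(paste(rownames(rec$samples), collapse = "\t"), con)
  utils::write.table(t(rec$samples), con, sep = "\t", col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# --- minimal EDF (16-bit integer, single data record) ---------------------
# Standard 256-byte fixed header + 256 bytes per signal, then one data record
# holding all samples as little-endian int16 scaled between the per-channel
# physical min/max. Quantisation step is (max-min)/65535.

pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

# shortest numeric rendering that fits an 8-char EDF header field
edf_num8 <- function(v) {
  for (d in 7:1) {
    s <- formatC(v, digits = d, format = "g")
    if (nchar(s) <= 8) return(s)
  }
  substr(formatC(v, format = "e", digits = 0), 1, 8)
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples); nsamp <- ncol(rec$samples)
  con <- file(path, "wb"); on.exit(close(con))
  phys_min <- apply(rec$samples, 1, min); phys_max <- apply(rec$samples, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("gliocircuit", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44), pad(1, 8),
                pad(format(nsamp / rec$fs, digits = 8), 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rownames(rec$samples), pad, "", width = 16),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("uV", 8), ns), collapse = ""), con, eos = NULL)
  pmin_s <- vapply(phys_min, edf_num8, "")
  pmax_s <- vapply(phys_max, edf_num8, "")
  writeChar(paste0(vapply(pmin_s, pad, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax_s, pad, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(-32768, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(32767, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(nsamp, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("", 32), ns), collapse = ""), con, eos = NULL)
  # digitise against the bounds exactly as stored in the header
  pmin_n <- as.numeric(pmin_s); pmax_n <- as.numeric(pmax_s)
  for (i in seq_len(ns)) {
    g <- (pmax_n[i] - pmin_n[i]) / 65535
    dig <- as.integer(pmin0 <- round((rec$samples[i, ] - pmin_n[i]) / g) - 32768)
    dig <- pmax(pmin(dig, 32767L), -32768L)
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  ndr <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  rdv <- function(nc) vapply(seq_len(ns), function(i) rd(nc), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8)); rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  out <- matrix(0, ns, spr[1] * ndr)
  for (r in seq_len(ndr)) for (i in seq_len(ns)) {
    dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    out[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- pmin[i] + (dig - dmin[i]) * g
  }
  rownames(out) <- labels
  list(samples = out, fs = spr[1] / (dur / 1))
}
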