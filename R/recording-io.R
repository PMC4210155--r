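#' Multichannel gait recording
#'
#' A `gait_recording` holds uniformly sampled multichannel time series
#' (EMG and force-sensing-resistor channels) as a time-by-channel matrix,
#' with a sampling rate in Hz and unique channel labels. Time is implicit:
#' sample `i` occurs at `start + (i - 1) / rate` seconds.
#'
#' @param samples numeric matrix, one row per sample, one column per channel.
#' @param rate sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels, one per column.
#' @param start start time in seconds of the first sample.
#' @return An object of class `gait_recording`.
#' @examples
#' rec <- gait_recording(matrix(rnorm(20), 10, 2), rate = 10,
#'                       channels = c("EMG_L_RF", "FSR_L_heel"))
#' rec
#' @export
gait_recording <- function(samples, rate, channels = colnames(samples),
                           start = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (Hz)")
  if (is.null(channels))
    channels <- sprintf("ch%02d", seq_len(ncol(samples)))
  channels <- as.character(channels)
  if (length(channels) != ncol(samples))
    stop("'channels' must name every column of 'samples'")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (anyNA(samples))
    stop("recording contains missing values")
  colnames(samples) <- channels
  structure(list(samples = samples, rate = rate, channels = channels,
                 start = start),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              nrow(x$samples) / x$rate))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of a recording
#'
#' @param rec a [gait_recording()].
#' @param channel channel label.
#' @return Numeric vector of samples.
#' @export
rec_channel <- function(rec, channel) {
  stopifnot(inherits(rec, "gait_recording"))
  if (!channel %in% rec$channels)
    stop("no channel '", channel, "' in recording; available: ",
         paste(rec$channels, collapse = ", "))
  rec$samples[, channel]
}

#' Default 16-channel layout
#'
#' Column order used by the synthetic generator and the reader default:
#' eight EMG channels (left then right leg; TA, LG, RF, BF) followed by
#' eight FSR channels (left then right; heel, mt1, mt5, toe).
#'
#' @return Character vector of 16 channel labels.
#' @export
default_channel_schema <- function() {
  c(paste0("EMG_", rep(c("L", "R"), each = 4), "_",
           rep(c("TA", "LG", "RF", "BF"), 2)),
    paste0("FSR_", rep(c("L", "R"), each = 4), "_",
           rep(c("heel", "mt1", "mt5", "toe"), 2)))
}

.format_num <- function(x) sprintf("%.12g", x)

#' Write a recording to delimited ASCII
#'
#' Writes a plain ASCII matrix, one row per sample, comma delimited, with a
#' single `#`-prefixed header line naming the channels and stating the
#' sampling rate. The format is lossless to 1e-9 relative precision and
#' byte-deterministic for identical input.
#'
#' @param rec a [gait_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("# rate_hz=%s start_s=%s channels=%s",
                 .format_num(rec$rate), .format_num(rec$start),
                 paste(rec$channels, collapse = ","))
  writeLines(hdr, con, sep = "\n")
  if (nrow(rec$samples) > 0L) {
    lines <- apply(rec$samples, 1L,
                   function(r) paste(.format_num(r), collapse = ","))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a recording from delimited ASCII
#'
#' Accepts the canonical comma-delimited dialect written by
#' [write_recording()] (with a `#` header carrying rate and channel labels)
#' and bare whitespace- or comma-delimited numeric matrices without a
#' header, in which case `schema` and `rate` must describe the layout.
#' Ragged rows, non-numeric cells and missing values are rejected.
#'
#' @param path input file path.
#' @param schema character vector of expected channel labels; defaults to the
#'   header's labels, or [default_channel_schema()] for headerless files with
#'   16 columns.
#' @param rate sampling rate in Hz, required when the file has no header.
#' @return A [gait_recording()].
#' @export
read_recording <- function(path, schema = NULL, rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty recording file: ", path)
  start <- 0
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("rate_hz=([^ ]+)", first))[[1]]
    if (length(m) == 2L) rate <- as.numeric(m[2])
    m <- regmatches(first, regexec("start_s=([^ ]+)", first))[[1]]
    if (length(m) == 2L) start <- as.numeric(m[2])
    m <- regmatches(first, regexec("channels=([^ ]+)", first))[[1]]
    if (length(m) == 2L && is.null(schema))
      schema <- strsplit(m[2], ",", fixed = TRUE)[[1]]
  }
  if (is.null(rate))
    stop("sampling rate not in header; supply 'rate'")
  lines <- readLines(path)
  if (skip > 0L) lines <- lines[-seq_len(skip)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    if (is.null(schema)) stop("header-only file and no schema given")
    return(gait_recording(matrix(numeric(0), 0L, length(schema)),
                          rate = rate, channels = schema, start = start))
  }
  splitter <- if (grepl(",", lines[1], fixed = TRUE)) "," else "[[:space:]]+"
  cells <- strsplit(trimws(lines), splitter)
  ncol <- length(cells[[1]])
  lens <- lengths(cells)
  if (any(lens != ncol))
    stop(sprintf("ragged rows: row %d has %d fields, expected %d",
                 which(lens != ncol)[1], lens[lens != ncol][1], ncol))
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric or missing cell at row %d, column %d",
                 (bad - 1L) %/% ncol + 1L, (bad - 1L) %% ncol + 1L))
  }
  mat <- matrix(vals, ncol = ncol, byrow = TRUE)
  if (is.null(schema)) {
    schema <- if (ncol == 16L) default_channel_schema()
              else sprintf("ch%02d", seq_len(ncol))
  }
  if (length(schema) != ncol)
    stop(sprintf("file has %d columns but schema names %d channels",
                 ncol, length(schema)))
  gait_recording(mat, rate = rate, channels = schema, start = start)
}
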