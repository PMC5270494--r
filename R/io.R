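# Plain-text sweep-file format.
#
# A self-describing delimited file: '#'-prefixed header lines followed by a
# tab-separated payload. Three payload types share the dialect:
#   sweeps     raw sweep matrix, one sweep per row, no column header
#   ensemble   ensemble-averaged sweeps with metadata columns
#              (subject_id, channel, state, window_index, n_averaged,
#               v1..vK), with a column header row
#   continuous single signal column; markers listed in the header
# Sample indexing is 0-based and sweep extents are half-open
# [marker, marker + sweep_len).

SWEEP_FORMAT_VERSION <- "1"

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_header <- function(con, type, fields) {
  writeLines(sprintf("# assr-sweeps v%s", SWEEP_FORMAT_VERSION), con)
  writeLines(sprintf("# type: %s", type), con)
  for (k in names(fields)) {
    writeLines(sprintf("# %s: %s", k, fields[[k]]), con)
  }
}

parse_header <- function(lines) {
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) == 0) {
    stop_assr("Not an assr-sweeps file (no header).", class = "assr_format_error")
  }
  m <- regmatches(hdr[1], regexec("^# assr-sweeps v(\\S+)$", hdr[1]))[[1]]
  if (length(m) < 2) {
    stop_assr("Missing format signature line '# assr-sweeps v<version>'.",
              class = "assr_format_error")
  }
  if (!identical(m[2], SWEEP_FORMAT_VERSION)) {
    stop_assr(sprintf("Unsupported sweep-file version '%s' (this build reads version %s).",
                      m[2], SWEEP_FORMAT_VERSION), class = "assr_format_error")
  }
  kv <- list(version = m[2])
  for (line in hdr[-1]) {
    mm <- regmatches(line, regexec("^# ([^:]+): ?(.*)$", line))[[1]]
    if (length(mm) == 3) kv[[trimws(mm[2])]] <- mm[3]
  }
  kv
}

need_key <- function(hdr, key) {
  if (is.null(hdr[[key]])) {
    stop_assr(sprintf("Sweep-file header is missing key '%s'.", key),
              class = "assr_format_error")
  }
  hdr[[key]]
}

#' Write sweeps to the plain-text sweep-file format
#'
#' Accepts a `sweep_matrix` (raw sweeps) or an ensemble tibble
#' ([windowed_averages()] output); all metadata round-trips through
#' [read_sweeps()] and values survive to full double precision.
#'
#' @param x A `sweep_matrix` or ensemble tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (inherits(x, "sweep_matrix")) {
    if (nrow(x$data) == 0 || ncol(x$data) == 0) {
      stop_assr("Refusing to write an empty sweep matrix.",
                class = "assr_empty_error")
    }
    write_header(con, "sweeps", list(
      fs = fmt_num(x$fs), stim_rate = fmt_num(x$stim_rate),
      sweep_len = ncol(x$data), n_sweeps = nrow(x$data),
      subject = x$subject_id, channel = x$channel, state = x$state))
    utils::write.table(format(x$data, trim = TRUE, digits = 17),
                       con, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else if (is.data.frame(x)) {
    if (nrow(x) == 0) {
      stop_assr("Refusing to write an empty ensemble dataset.",
                class = "assr_empty_error")
    }
    lens <- lengths(x$values)
    stopifnot(length(unique(lens)) == 1)
    vals <- do.call(rbind, x$values)
    colnames(vals) <- paste0("v", seq_len(ncol(vals)))
    flat <- cbind(x[c("subject_id", "channel", "state", "window_index",
                      "n_averaged")], as.data.frame(vals))
    write_header(con, "ensemble", list(sweep_len = ncol(vals),
                                       n_rows = nrow(flat)))
    utils::write.table(flat, con, sep = "\t", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  } else {
    stop_assr("`x` must be a sweep_matrix or an ensemble tibble.")
  }
  invisible(path)
}

#' Read a sweep file written by [write_sweeps()]
#'
#' @param path File path.
#' @return A `sweep_matrix` or ensemble tibble, matching what was written.
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) stop_assr(paste0("No such file: ", path))
  lines <- readLines(path)
  hdr <- parse_header(lines)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  type <- need_key(hdr, "type")
  if (type == "sweeps") {
    sweep_len <- as.integer(need_key(hdr, "sweep_len"))
    n_sweeps <- as.integer(need_key(hdr, "n_sweeps"))
    data <- as.matrix(utils::read.delim(text = body, header = FALSE,
                                        colClasses = "numeric"))
    dimnames(data) <- NULL
    if (ncol(data) != sweep_len) {
      stop_assr(sprintf("Header sweep_len %d does not match payload width %d.",
                        sweep_len, ncol(data)), class = "assr_format_error")
    }
    if (nrow(data) != n_sweeps) {
      stop_assr(sprintf("Truncated payload: header promises %d sweeps, found %d.",
                        n_sweeps, nrow(data)), class = "assr_format_error")
    }
    new_sweep_matrix(data, as.numeric(need_key(hdr, "fs")),
                     as.numeric(need_key(hdr, "stim_rate")),
                     need_key(hdr, "subject"), need_key(hdr, "channel"),
                     need_key(hdr, "state"))
  } else if (type == "ensemble") {
    sweep_len <- as.integer(need_key(hdr, "sweep_len"))
    n_rows <- as.integer(need_key(hdr, "n_rows"))
    df <- utils::read.delim(text = body, header = TRUE,
                            stringsAsFactors = FALSE)
    vcols <- grep("^v[0-9]+$", names(df))
    if (length(vcols) != sweep_len) {
      stop_assr(sprintf("Header sweep_len %d does not match payload width %d.",
                        sweep_len, length(vcols)), class = "assr_format_error")
    }
    if (nrow(df) != n_rows) {
      stop_assr(sprintf("Truncated payload: header promises %d rows, found %d.",
                        n_rows, nrow(df)), class = "assr_format_error")
    }
    vals <- as.matrix(df[vcols])
    tibble::tibble(
      subject_id = as.character(df$subject_id),
      channel = as.character(df$channel),
      state = as.character(df$state),
      window_index = as.integer(df$window_index),
      n_averaged = as.integer(df$n_averaged),
      values = lapply(seq_len(nrow(vals)), function(i) unname(vals[i, ]))
    )
  } else {
    stop_assr(sprintf("Unknown payload type '%s'.", type),
              class = "assr_format_error")
  }
}

#' Write / read a continuous record in the sweep-file dialect
#'
#' One signal value per payload line; sampling rate, markers and metadata
#' live in the header. Markers are 0-based sample indices.
#'
#' @param record A `continuous_record`.
#' @param path File path.
#' @return `path` invisibly (write); a `continuous_record` (read).
#' @export
write_continuous <- function(record, path) {
  stopifnot(inherits(record, "continuous_record"))
  if (length(record$signal) == 0) {
    stop_assr("Refusing to write an empty signal.", class = "assr_empty_error")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  write_header(con, "continuous", list(
    fs = fmt_num(record$fs),
    stim_rate = fmt_num(record$stim_rate),
    n_samples = length(record$signal),
    markers = paste(record$markers, collapse = ","),
    subject = record$subject_id, channel = record$channel,
    state = record$state))
  writeLines(fmt_num(record$signal), con)
  invisible(path)
}

#' @rdname write_continuous
#' @export
read_continuous <- function(path) {
  lines <- readLines(path)
  hdr <- parse_header(lines)
  if (!identical(need_key(hdr, "type"), "continuous")) {
    stop_assr("Not a continuous-record file.", class = "assr_format_error")
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  markers_str <- need_key(hdr, "markers")
  markers <- if (nzchar(markers_str)) {
    as.integer(strsplit(markers_str, ",")[[1]])
  } else {
    integer(0)
  }
  as_continuous_record(as.numeric(body), fs = as.numeric(need_key(hdr, "fs")),
                       markers = markers, channel = need_key(hdr, "channel"),
                       subject_id = need_key(hdr, "subject"),
                       state = need_key(hdr, "state"),
                       stim_rate = as.numeric(need_key(hdr, "stim_rate")))
}

# Read every ensemble sweep file in a directory and bind the rows.
read_ensemble_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0) {
    stop_assr(paste0("No .tsv sweep files in ", dir))
  }
  dplyr::bind_rows(lapply(paths, read_sweeps))
}
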