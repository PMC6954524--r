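# File formats: ActiGraph-style epoch CSV (10-line header, one counts
# column), a plain two-column (timestamp,counts) dialect, tidy CSV for
# questionnaire responses, and YAML for simulation configs.

AG_HEADER_LINES <- 10L

#' Write an epoch count series as ActiGraph-style CSV
#'
#' Emits the classic 10-line header (start time/date, epoch period)
#' followed by one count per line.
#'
#' @param series A [count_epoch_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_actigraph_csv <- function(series, path) {
  start <- series$start
  hdr <- c(
    paste0(
      "------------ Data File Created By ActiGraph ActiLife ",
      "date format M/d/yyyy -----------"
    ),
    sprintf("Serial Number: SYN-%s", series$participant_id),
    sprintf("Start Time %s", format(start, "%H:%M:%S")),
    sprintf("Start Date %s", format(start, "%m/%d/%Y")),
    sprintf(
      "Epoch Period (hh:mm:ss) 00:00:%02d",
      series$epoch_length
    ),
    "Download Time 12:00:00",
    sprintf(
      "Download Date %s",
      format(series$return_date %||% as.Date(start), "%m/%d/%Y")
    ),
    "Current Memory Address: 0",
    "Current Battery Voltage: 4.07     Mode = 0",
    "--------------------------------------------------"
  )
  writeLines(c(hdr, format(series$counts, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' Read an epoch count series from CSV
#'
#' Accepts two dialects: the ActiGraph-style export (a 10-line header
#' holding the start time/date and epoch period, then one counts column)
#' and a plain two-column `timestamp,counts` CSV with ISO timestamps, in
#' which case the epoch length is inferred from the first two rows.
#'
#' @param path File path.
#' @param participant_id Identifier for the series (default: file name
#'   without extension).
#' @param delivery_date,return_date Optional protocol dates attached to
#'   the series.
#' @param tz Time zone for parsed timestamps.
#' @return A [count_epoch_series()].
#' @export
read_actigraph_csv <- function(path, participant_id = NULL,
                               delivery_date = NULL, return_date = NULL,
                               tz = "UTC") {
  participant_id <- participant_id %||% sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, "---")) {
    hdr <- readLines(path, n = AG_HEADER_LINES)
    grab <- function(pattern) {
      line <- grep(pattern, hdr, value = TRUE)[1]
      if (is.na(line)) {
        stop("malformed header: missing ", pattern, call. = FALSE)
      }
      trimws(sub(pattern, "", line))
    }
    start_time <- grab("^Start Time ")
    start_date <- grab("^Start Date ")
    epoch_str <- grab("^Epoch Period \\(hh:mm:ss\\) ")
    ep <- as.numeric(strsplit(epoch_str, ":", fixed = TRUE)[[1]])
    epoch_length <- ep[1] * 3600 + ep[2] * 60 + ep[3]
    start <- as.POSIXct(
      paste(start_date, start_time),
      format = "%m/%d/%Y %H:%M:%S", tz = tz
    )
    body <- utils::read.csv(
      path,
      skip = AG_HEADER_LINES, header = FALSE,
      colClasses = "numeric"
    )
    counts <- body[[1]]
  } else {
    body <- utils::read.csv(path, header = TRUE)
    if (!all(c("timestamp", "counts") %in% names(body))) {
      stop("plain dialect needs columns `timestamp` and `counts`", call. = FALSE)
    }
    ts <- as.POSIXct(body$timestamp, tz = tz)
    if (nrow(body) >= 2) {
      epoch_length <- as.numeric(difftime(ts[2], ts[1], units = "secs"))
    } else {
      epoch_length <- 5
    }
    start <- ts[1]
    counts <- body$counts
  }
  count_epoch_series(
    participant_id = participant_id, start = start, counts = counts,
    epoch_length = as.integer(epoch_length),
    delivery_date = delivery_date, return_date = return_date
  )
}

#' Read / write long-format questionnaire responses
#'
#' Thin CSV wrappers around the canonical long schema of
#' [validate_responses()].
#'
#' @param path CSV file path.
#' @return `read_responses_csv()`: a validated response tibble.
#' @export
read_responses_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_responses(out)
  out
}

#' @rdname read_responses_csv
#' @param responses A response tibble.
#' @export
write_responses_csv <- function(responses, path) {
  validate_responses(responses)
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation config as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config()`: a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$start_date <- as.Date(raw$start_date %||% "2019-04-01")
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$start_date <- format(out$start_date)
  yaml::write_yaml(out, path)
  invisible(path)
}
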