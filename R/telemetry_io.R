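#' @import data.table
#' @importFrom stats var sd pnorm rnorm runif rexp rlnorm rpois aggregate
#'   as.formula setNames coef residuals fitted AIC lm
#' @importFrom utils head tail
NULL

.dw_ts_format <- "%Y-%m-%dT%H:%M:%OS"
.dw_ts_out <- "%Y-%m-%dT%H:%M:%OS3Z"

#' Detection-log dialect description
#'
#' The canonical detection dialect is a CSV with header
#' `timestamp,antenna_id,tag_code` and ISO-8601 UTC timestamps. Vendor log
#' layouts are mapped onto it by overriding the column names, timestamp
#' format and timezone here.
#'
#' @param col_timestamp,col_antenna,col_tag column names in the source file.
#' @param ts_format `strptime` format for the timestamp column (`%OS` accepts
#'   fractional seconds).
#' @param tz timezone of the source timestamps; converted to UTC on read.
#' @param antenna_ids integer vector of valid antenna identifiers.
#' @return a list usable as the `dialect` argument of [read_detections()].
#' @export
detection_dialect <- function(col_timestamp = "timestamp",
                              col_antenna = "antenna_id",
                              col_tag = "tag_code",
                              ts_format = .dw_ts_format,
                              tz = "UTC",
                              antenna_ids = 1:3) {
  list(col_timestamp = col_timestamp, col_antenna = col_antenna,
       col_tag = col_tag, ts_format = ts_format, tz = tz,
       antenna_ids = as.integer(antenna_ids))
}

.parse_ts <- function(x, format = .dw_ts_format, tz = "UTC") {
  out <- as.POSIXct(strptime(as.character(x), format = format, tz = tz))
  attr(out, "tzone") <- "UTC"
  out
}

#' Read a PIT-reader detection log
#'
#' Reads a delimited detection log into an event table sorted by
#' `(tag_code, timestamp)`. Malformed rows (unparseable timestamp, empty tag
#' code, antenna id outside the configured set) are not silently dropped:
#' they are collected, with a reason, in the `rejects` attribute of the
#' result.
#'
#' @param path path to the detection CSV.
#' @param dialect a [detection_dialect()] describing the file layout.
#' @return a `data.frame` with columns `timestamp` (POSIXct, UTC),
#'   `antenna_id` (integer), `tag_code` (character), sorted by tag then time;
#'   attribute `rejects` holds a data.frame of rejected source rows with a
#'   `reason` column.
#' @export
read_detections <- function(path, dialect = detection_dialect()) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  raw <- data.table::fread(path, colClasses = "character", header = TRUE)
  need <- c(dialect$col_timestamp, dialect$col_antenna, dialect$col_tag)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("detection file missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- data.frame(timestamp = .parse_ts(character(0)),
                      antenna_id = integer(0), tag_code = character(0))
    attr(out, "rejects") <- .empty_rejects()
    return(out)
  }
  ts <- .parse_ts(raw[[dialect$col_timestamp]], dialect$ts_format, dialect$tz)
  ant <- suppressWarnings(as.integer(raw[[dialect$col_antenna]]))
  tag <- raw[[dialect$col_tag]]
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(reason) & (is.na(ant) | !(ant %in% dialect$antenna_ids))] <-
    "antenna_id outside configured set"
  reason[is.na(reason) & (is.na(tag) | !nzchar(tag))] <- "empty tag_code"
  bad <- !is.na(reason)
  rejects <- if (any(bad)) {
    cbind(as.data.frame(raw[bad, ]), reason = reason[bad], row = which(bad))
  } else .empty_rejects()
  out <- data.frame(timestamp = ts[!bad], antenna_id = ant[!bad],
                    tag_code = tag[!bad], stringsAsFactors = FALSE)
  out <- out[order(out$tag_code, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

.empty_rejects <- function() {
  data.frame(reason = character(0), row = integer(0))
}

#' Write detections in the canonical dialect
#'
#' Writes `timestamp,antenna_id,tag_code` with ISO-8601 UTC timestamps at
#' millisecond precision; reading the result back with the default dialect
#' and rewriting it reproduces the file byte-for-byte.
#'
#' @param events detection table as returned by [read_detections()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(events, path) {
  # format() truncates fractional seconds; add half a millisecond so the
  # printed millisecond is the rounded one
  lines <- c("timestamp,antenna_id,tag_code",
             paste(format(events$timestamp + 5e-4, .dw_ts_out, tz = "UTC"),
                   events$antenna_id, events$tag_code, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse sub-second re-detections
#'
#' PIT readers cycle at up to 10 Hz, so a fish holding near an antenna is
#' re-logged every tenth of a second. Per individual (antennas pooled, since
#' any antenna is a presence proxy), consecutive events closer than
#' `min_spacing_s` to the last kept event are dropped, keeping the first of
#' each run. With `min_spacing_s` well below the bout gap threshold this
#' cannot move bout boundaries.
#'
#' @param events detection table sorted by `(tag_code, timestamp)`.
#' @param min_spacing_s minimum spacing to keep, seconds (default 1);
#'   `0` returns the input unchanged.
#' @return the thinned detection table; idempotent.
#' @export
dedupe_detections <- function(events, min_spacing_s = 1) {
  if (min_spacing_s < 0) stop("min_spacing_s must be non-negative")
  if (min_spacing_s == 0 || nrow(events) < 2L) return(events)
  t <- as.numeric(events$timestamp)
  tag <- events$tag_code
  n <- length(t)
  keep <- logical(n)
  last <- -Inf
  last_tag <- NA_character_
  for (i in seq_len(n)) {
    if (!identical(tag[i], last_tag)) {
      if (!is.na(last_tag) && tag[i] < last_tag)
        stop("events not sorted by tag_code")
      keep[i] <- TRUE
      last <- t[i]
      last_tag <- tag[i]
    } else {
      if (t[i] < last) stop("events not sorted in time within individual")
      if (t[i] - last >= min_spacing_s) {
        keep[i] <- TRUE
        last <- t[i]
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read the tagging registry
#'
#' One row per tagged individual: tag code, species (`asp` or `bleak`), sex
#' (`female`, `male`, `unknown`; recorded in asp only), total length at
#' tagging (cm), weight (g, optional), scale-read age (years, asp only),
#' tagging date, and optional recapture length/date (both present or both
#' absent).
#'
#' @param path registry CSV path.
#' @return a `data.frame` of tag records.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- data.table::fread(path, data.table = FALSE)
  need <- c("tag_code", "species", "sex", "total_length_cm", "tagging_date")
  missing_cols <- setdiff(need, names(reg))
  if (length(missing_cols))
    stop("registry missing column(s): ", paste(missing_cols, collapse = ", "))
  dup <- unique(reg$tag_code[duplicated(reg$tag_code)])
  if (length(dup))
    stop("duplicate tag_code in registry: ", paste(dup, collapse = ", "))
  bad_sp <- setdiff(unique(reg$species), c("asp", "bleak"))
  if (length(bad_sp)) stop("unknown species: ", paste(bad_sp, collapse = ", "))
  reg$sex <- ifelse(is.na(reg$sex) | !nzchar(as.character(reg$sex)),
                    "unknown", as.character(reg$sex))
  bad_sex <- setdiff(unique(reg$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) stop("unknown sex code: ", paste(bad_sex, collapse = ", "))
  if (any(reg$total_length_cm <= 0, na.rm = TRUE))
    stop("non-positive total_length_cm in registry")
  reg$tagging_date <- as.Date(reg$tagging_date)
  for (col in c("weight_g", "age_years", "recapture_length_cm"))
    if (!col %in% names(reg)) reg[[col]] <- NA_real_
  if (!"recapture_date" %in% names(reg)) reg$recapture_date <- as.Date(NA)
  if (is.character(reg$recapture_date))
    reg$recapture_date[!nzchar(reg$recapture_date)] <- NA
  reg$recapture_date <- as.Date(reg$recapture_date)
  mismatched <- xor(is.na(reg$recapture_length_cm), is.na(reg$recapture_date))
  if (any(mismatched))
    stop("recapture length/date must be present together; offending tag(s): ",
         paste(reg$tag_code[mismatched], collapse = ", "))
  reg
}

#' Read the hourly water-temperature series
#'
#' Expects columns `timestamp` (ISO-8601 UTC) and `temp_c`. Timestamps must
#' be strictly increasing; gaps are accepted and remain visible downstream
#' (the design join flags bins with no temperature within 90 minutes).
#'
#' @param path temperature CSV path.
#' @return a `data.frame` with `timestamp` (POSIXct UTC) and `temp_c`.
#' @export
read_temperature <- function(path) {
  if (!file.exists(path)) stop("temperature file not found: ", path)
  tmp <- data.table::fread(path, data.table = FALSE)
  need <- c("timestamp", "temp_c")
  missing_cols <- setdiff(need, names(tmp))
  if (length(missing_cols))
    stop("temperature file missing column(s): ", paste(missing_cols, collapse = ", "))
  # fread may already have recognized ISO-8601 and parsed the column
  if (inherits(tmp$timestamp, "POSIXct")) {
    attr(tmp$timestamp, "tzone") <- "UTC"
  } else {
    tmp$timestamp <- .parse_ts(tmp$timestamp)
  }
  if (anyNA(tmp$timestamp)) stop("unparseable timestamp in temperature file")
  if (is.unsorted(tmp$timestamp, strictly = TRUE))
    stop("temperature timestamps must be strictly increasing")
  tmp
}
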