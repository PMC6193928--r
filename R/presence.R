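#' Segment detections into presence bouts
#'
#' An individual is considered continuously present while consecutive
#' detections (any antenna) fall within the gap threshold of one another;
#' a larger gap means the last detection was the departure. The boundary is
#' inclusive: a gap exactly equal to the threshold still merges. Bout start
#' and end are the first and last detection instants, so a single isolated
#' detection yields a zero-duration bout, which is retained.
#'
#' @param events detection table (possibly several individuals), sorted by
#'   time within each `tag_code`.
#' @param gap_hours maximum inter-detection gap within a bout, hours
#'   (default 2).
#' @return a `data.frame` with one row per bout: `tag_code`, `start`, `end`
#'   (POSIXct UTC), `n_detections`, `antennas_seen` (comma-joined sorted
#'   antenna ids).
#' @export
segment_bouts <- function(events, gap_hours = 2) {
  if (gap_hours <= 0) stop("gap_hours must be positive")
  gap_s <- gap_hours * 3600
  dt <- data.table::as.data.table(events)
  if (nrow(dt) == 0L) {
    return(data.frame(tag_code = character(0),
                      start = .parse_ts(character(0)),
                      end = .parse_ts(character(0)),
                      n_detections = integer(0),
                      antennas_seen = character(0)))
  }
  dt[, `:=`(.t = as.numeric(timestamp))]
  if (dt[, any(diff(.t) < 0), by = tag_code][, any(V1)])
    stop("events must be sorted in time within each individual")
  dt[, .bout := cumsum(c(TRUE, diff(.t) > gap_s)), by = tag_code]
  bouts <- dt[, .(start = timestamp[1L], end = timestamp[.N],
                  n_detections = .N,
                  antennas_seen = paste(sort(unique(antenna_id)), collapse = ",")),
              by = .(tag_code, .bout)]
  bouts[, .bout := NULL]
  out <- as.data.frame(bouts)
  attr(out$start, "tzone") <- "UTC"
  attr(out$end, "tzone") <- "UTC"
  out
}

#' Eligibility rules for bout filtering
#'
#' Long-lived asp tagged and detected in the same spawning season are
#' excluded — behaviour is analysed from one year after tagging — while for
#' short-lived bleak data from one day after tagging onward are used. Male
#' asp are excluded throughout (egg availability is a female quantity and
#' males are never limiting).
#'
#' @param asp_min_lag_days minimum tagging-to-bout lag for asp (default 365).
#' @param bleak_min_lag_days minimum lag for bleak (default 1).
#' @param drop_male_asp drop male asp bouts entirely (default TRUE).
#' @return a rules list for [apply_eligibility()].
#' @export
eligibility_rules <- function(asp_min_lag_days = 365,
                              bleak_min_lag_days = 1,
                              drop_male_asp = TRUE) {
  if (asp_min_lag_days < 0 || bleak_min_lag_days < 0)
    stop("lags must be non-negative")
  list(asp_min_lag_days = asp_min_lag_days,
       bleak_min_lag_days = bleak_min_lag_days,
       drop_male_asp = drop_male_asp)
}

#' Filter bouts by species-specific eligibility and clip to the season
#'
#' Joins the registry, applies the tagging-lag rules per species, drops male
#' asp, clips bouts to the season window, and collects bouts whose tag code
#' is absent from the registry into an `orphans` attribute instead of
#' failing.
#'
#' @param bouts output of [segment_bouts()].
#' @param registry tag registry ([read_registry()]).
#' @param rules an [eligibility_rules()] list.
#' @param season optional length-2 vector (POSIXct or coercible) giving the
#'   season window; bouts wholly outside are dropped, straddling bouts are
#'   clipped.
#' @return filtered bouts with `species` and `sex` columns added; attributes
#'   `orphans` (unknown-tag bouts) and `n_excluded` (counts by reason).
#' @export
apply_eligibility <- function(bouts, registry, rules = eligibility_rules(),
                              season = NULL) {
  b <- data.table::as.data.table(bouts)
  reg <- data.table::as.data.table(
    registry[, c("tag_code", "species", "sex", "tagging_date")])
  orphan <- !(b$tag_code %in% reg$tag_code)
  orphans <- as.data.frame(b[orphan])
  b <- b[!orphan]
  b <- reg[b, on = "tag_code"]
  excluded <- c(orphan_tag = sum(orphan))
  lag_days <- as.numeric(difftime(b$start, as.POSIXct(paste(b$tagging_date),
                                                      tz = "UTC"),
                                  units = "days"))
  min_lag <- ifelse(b$species == "asp", rules$asp_min_lag_days,
                    rules$bleak_min_lag_days)
  keep <- lag_days >= min_lag
  excluded["tagging_lag"] <- sum(!keep)
  b <- b[keep]
  if (rules$drop_male_asp) {
    male <- b$species == "asp" & b$sex == "male"
    excluded["male_asp"] <- sum(male)
    b <- b[!male]
  }
  if (!is.null(season)) {
    s0 <- as.POSIXct(season[1], tz = "UTC")
    s1 <- as.POSIXct(season[2], tz = "UTC")
    inside <- b$end >= s0 & b$start <= s1
    excluded["outside_season"] <- sum(!inside)
    b <- b[inside]
    b[, start := pmax(start, s0)]
    b[, end := pmin(end, s1)]
  }
  b[, tagging_date := NULL]
  out <- as.data.frame(b)
  attr(out, "orphans") <- orphans
  attr(out, "n_excluded") <- excluded
  out
}

#' Build a contiguous time-bin grid
#'
#' @param from,to window bounds (POSIXct or coercible), UTC; `from` is
#'   floored and `to` ceilinged to whole bins.
#' @param bin_minutes bin width in minutes (default 60).
#' @return a `data.frame` with `bin_start`, `bin_end` (POSIXct UTC).
#' @export
make_bins <- function(from, to, bin_minutes = 60) {
  w <- bin_minutes * 60
  f <- floor(as.numeric(as.POSIXct(from, tz = "UTC")) / w) * w
  t <- ceiling(as.numeric(as.POSIXct(to, tz = "UTC")) / w) * w
  if (t <= f) stop("empty bin grid")
  starts <- seq(f, t - w, by = w)
  data.frame(bin_start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
             bin_end = as.POSIXct(starts + w, origin = "1970-01-01", tz = "UTC"))
}

#' Fractional per-individual presence on a bin grid
#'
#' For each individual and bin, the fraction of the bin covered by the
#' individual's bouts. A zero-duration bout (single detection) counts as
#' full membership of its containing bin.
#'
#' @param bouts bout table (`tag_code`, `start`, `end`).
#' @param bins grid from [make_bins()]; bins must be contiguous and of equal
#'   width.
#' @return a `data.frame` `tag_code`, `bin_start`, `presence` in \[0, 1\];
#'   bins with zero presence for an individual are omitted.
#' @export
presence_matrix <- function(bouts, bins) {
  .check_grid(bins)
  ov <- .bout_bin_overlap(bouts, bins)
  w <- as.numeric(bins$bin_end[1]) - as.numeric(bins$bin_start[1])
  ov[, presence := pmin(1, ifelse(zero_dur, 1, overlap_s / w))]
  out <- ov[, .(presence = min(1, sum(presence))), by = .(tag_code, bin_start)]
  as.data.frame(out[order(tag_code, bin_start)])
}

.check_grid <- function(bins) {
  if (nrow(bins) == 0L) stop("empty bin grid")
  w <- as.numeric(bins$bin_end) - as.numeric(bins$bin_start)
  if (any(abs(w - w[1]) > 1e-9)) stop("bins must have equal width")
  if (nrow(bins) > 1L &&
      any(abs(diff(as.numeric(bins$bin_start)) - w[1]) > 1e-9))
    stop("bins must be contiguous")
}

# Overlap seconds of every bout with every bin it touches; zero-duration
# bouts are flagged and assigned to their containing bin.
.bout_bin_overlap <- function(bouts, bins) {
  b <- data.table::as.data.table(bouts)
  g0 <- as.numeric(bins$bin_start[1])
  w <- as.numeric(bins$bin_end[1]) - g0
  nb <- nrow(bins)
  b[, `:=`(s = as.numeric(start), e = as.numeric(end))]
  b <- b[e >= g0 & s <= g0 + nb * w]
  if (nrow(b) == 0L)
    return(data.table::data.table(tag_code = character(0), bin_start = bins$bin_start[0],
                                  overlap_s = numeric(0), zero_dur = logical(0)))
  b[, `:=`(i0 = pmax(0L, pmin(nb - 1L, as.integer(floor((s - g0) / w)))),
           i1 = pmax(0L, pmin(nb - 1L, as.integer(floor((e - g0) / w + 1e-12)))))]
  # single detections sitting exactly on a bin boundary belong to the bin
  # they open
  b[e - s == 0, i1 := i0]
  idx <- b[, .(bin_i = seq.int(i0, i1)), by = .(row = seq_len(nrow(b)))]
  out <- cbind(b[idx$row, .(tag_code, s, e)], bin_i = idx$bin_i)
  out[, `:=`(bs = g0 + bin_i * w)]
  out[, overlap_s := pmax(0, pmin(e, bs + w) - pmax(s, bs))]
  out[, zero_dur := e - s == 0]
  out[, .(tag_code,
          bin_start = as.POSIXct(bs, origin = "1970-01-01", tz = "UTC"),
          overlap_s, zero_dur)]
}
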