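#' Configuration of a synthetic spawning season
#'
#' Defaults emulate the field conditions the pipeline was built for: a
#' ~14-day early-April season, 230 tagged asp females (the larger study
#' year) making one to three short spawning-ground visits of about six
#' hours, 63% of visits nocturnal; 23 tagged bleak present through the
#' daylight hours, leaving before sunset and returning shortly before
#' sunrise, with an 8% chance per night of staying over; three synchronized
#' antennas logging at up to 10 reads per second; hourly water temperature
#' with a rising early-spring trend and a small diel cycle. Female total
#' length is drawn at 49.5 +/- 8.0 cm and males at 47.0 +/- 5.3 cm, with
#' scale ages consistent with the configured von Bertalanffy truth curve.
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param season_start,season_end season window (dates; end exclusive).
#' @param n_asp_females,n_asp_males,n_bleak individuals of each group.
#' @param n_asp_newly_tagged extra females tagged inside the season (they
#'   exercise the same-season exclusion rule downstream).
#' @param night_spawn_prob probability a female visit is nocturnal.
#' @param asp_visit_mean_h mean visit duration, hours.
#' @param visits_min,visits_max per-female visit count range.
#' @param date_decay per-day exponential decay of visit intensity across the
#'   season (plants the negative day-of-year effect on eggs).
#' @param bleak_day_presence probability a bleak spends a given day on the
#'   ground; `bleak_date_slope` adds a linear increase across the season
#'   (plants the positive day-of-year effect on bleak presence).
#' @param bleak_night_stay_prob probability a present bleak stays overnight.
#' @param passes_per_hour antenna-encounter rate while present.
#' @param burst_mean mean reads per antenna pass (at the reader cycle rate).
#' @param detection_rate_hz reader cycle rate (<= 10).
#' @param miss_prob probability an antenna pass leaves no record.
#' @param temp_start_c,temp_trend_c_per_day,temp_diel_amp_c,temp_noise_sd
#'   hourly temperature model.
#' @param growth_l_inf,growth_k,growth_t0 truth growth curve; `age_jitter_sd`
#'   is the SD of scale-reading noise around the curve-implied age.
#' @param female_tl_mean,female_tl_sd,male_tl_mean,male_tl_sd,bleak_tl_mean,bleak_tl_sd
#'   total length distributions, cm.
#' @param recapture_prob fraction of females recaptured in the season year.
#' @param gsi,egg_mass_g fecundity truth parameters.
#' @param lat,lon site coordinates for the diel geometry.
#' @return a validated config list for [generate_season()].
#' @export
synth_config <- function(seed = 1,
                         season_start = "2017-04-01",
                         season_end = "2017-04-15",
                         n_asp_females = 230, n_asp_males = 60,
                         n_asp_newly_tagged = 10, n_bleak = 23,
                         night_spawn_prob = 0.63,
                         asp_visit_mean_h = 6,
                         visits_min = 1, visits_max = 3,
                         date_decay = 0.08,
                         bleak_day_presence = 0.75,
                         bleak_date_slope = 0.015,
                         bleak_night_stay_prob = 0.08,
                         passes_per_hour = 6,
                         burst_mean = 3,
                         detection_rate_hz = 10,
                         miss_prob = 0,
                         temp_start_c = 7, temp_trend_c_per_day = 0.15,
                         temp_diel_amp_c = 0.8, temp_noise_sd = 0.1,
                         growth_l_inf = 85, growth_k = 0.18, growth_t0 = -0.5,
                         age_jitter_sd = 0.4,
                         female_tl_mean = 49.5, female_tl_sd = 8.0,
                         male_tl_mean = 47.0, male_tl_sd = 5.3,
                         bleak_tl_mean = 11.9, bleak_tl_sd = 1.0,
                         recapture_prob = 0.1,
                         gsi = 0.15, egg_mass_g = 0.0035,
                         lat = 49.578497, lon = 15.251671) {
  cfg <- as.list(environment())
  cfg$season_start <- as.Date(season_start)
  cfg$season_end <- as.Date(season_end)
  n_days <- as.numeric(cfg$season_end - cfg$season_start)
  if (n_days < 1) stop("season must span at least one day")
  for (p in c("night_spawn_prob", "bleak_day_presence",
              "bleak_night_stay_prob", "miss_prob", "recapture_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (any(unlist(cfg[c("n_asp_females", "n_asp_males", "n_bleak",
                       "n_asp_newly_tagged")]) < 0))
    stop("counts must be non-negative")
  if (cfg$detection_rate_hz <= 0 || cfg$detection_rate_hz > 10)
    stop("detection_rate_hz must be in (0, 10]")
  if (cfg$asp_visit_mean_h >= n_days * 24)
    stop("mean visit duration exceeds the season length")
  cfg$n_days <- n_days
  cfg
}

# seconds of [s, e] falling between sunrise and sunset, given solar windows
.day_seconds <- function(s, e, win) {
  rs <- as.numeric(win$sunrise); ss <- as.numeric(win$sunset)
  out <- numeric(length(s))
  for (d in seq_along(rs))
    out <- out + pmax(0, pmin(e, ss[d]) - pmax(s, rs[d]))
  out
}

# merge a female's visit intervals whenever the gap is within the bout rule
.merge_intervals <- function(s, e, gap_s = 7200) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] - me <= gap_s) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Generate a complete synthetic field season
#'
#' Produces the three canonical pipeline inputs (tag registry, detection
#' log, hourly temperature) plus a ground-truth record: every individual's
#' presence intervals, every female's fecundity, the realized nocturnal egg
#' fraction and the bleak day share. Female visits are placed inside a
#' night (probability `night_spawn_prob`) or day window of a season day,
#' with the visit centre drawn from a truncated normal around the window
#' centre — a circular-mixture shape whose containment in the window makes
#' the realized nocturnal egg fraction converge to `night_spawn_prob`.
#' Detections are emitted as antenna passes (Poisson in time, forced at
#' interval endpoints) with short read bursts snapped to the reader's
#' 10 Hz cycle grid, so no antenna ever logs faster than its cycle rate.
#'
#' @param config a [synth_config()] list.
#' @param out_dir optional directory; when given, writes `registry.csv`,
#'   `detections.csv`, `temperature.csv` and `truth.json` there.
#' @return list with `registry`, `detections`, `temperature` (data.frames)
#'   and `truth` (list).
#' @export
generate_season <- function(config = synth_config(), out_dir = NULL) {
  set.seed(config$seed)
  n_days <- config$n_days
  days <- config$season_start + seq_len(n_days) - 1
  yr <- as.integer(format(config$season_start, "%Y"))
  win <- solar_times(c(days[1] - 1, days, days[length(days)] + 1),
                     lat = config$lat, lon = config$lon)
  season_s <- as.numeric(as.POSIXct(paste(config$season_start), tz = "UTC"))
  season_e <- as.numeric(as.POSIXct(paste(config$season_end), tz = "UTC"))
  rise <- as.numeric(win$sunrise); sets <- as.numeric(win$sunset)
  # day window of season day d: [rise, set] of that date (win row d + 1);
  # night window following day d: [set_d, rise_{d+1}]
  day_win <- cbind(rise[1 + seq_len(n_days)], sets[1 + seq_len(n_days)])
  night_win <- cbind(sets[1 + seq_len(n_days)], rise[2 + seq_len(n_days)])

  day_weight <- exp(-config$date_decay * (seq_len(n_days) - 1))

  # right-skewed visit duration concentrated around the mean (CV ~ 1/3),
  # so the window cap below almost never binds and night and day visits
  # have the same duration distribution
  sdl <- 0.33
  draw_visit <- function(nocturnal) {
    d <- sample.int(n_days, 1, prob = day_weight)
    wnd <- if (nocturnal) night_win[d, ] else day_win[d, ]
    len <- wnd[2] - wnd[1]
    dur <- min(max(rlnorm(1, log(config$asp_visit_mean_h * 3600) - sdl^2 / 2,
                          sdl), 1800),
               0.95 * len)
    ctr <- rnorm(1, mean = mean(wnd), sd = len / 6)
    ctr <- min(max(ctr, wnd[1] + dur / 2), wnd[2] - dur / 2)
    c(ctr - dur / 2, ctr + dur / 2)
  }

  make_asp <- function(n, sex, newly_tagged = FALSE) {
    if (n == 0) return(NULL)
    tl <- pmin(pmax(rnorm(n,
                          if (sex == "female") config$female_tl_mean else config$male_tl_mean,
                          if (sex == "female") config$female_tl_sd else config$male_tl_sd),
                    28), 78)
    age_curve <- config$growth_t0 -
      log(pmax(1 - tl / config$growth_l_inf, 0.05)) / config$growth_k
    age <- pmax(2, round(age_curve + rnorm(n, 0, config$age_jitter_sd), 0))
    tagging <- if (newly_tagged)
      config$season_start + sample.int(max(n_days - 2, 1), n, replace = TRUE) - 1
    else
      config$season_start - 370 - sample.int(25, n, replace = TRUE)
    list(tl = tl, age = age, tagging = tagging)
  }

  ids <- function(prefix, n, from = 1)
    sprintf("%s%04d%07d", prefix, yr %% 10000, from - 1 + seq_len(n))

  fem <- make_asp(config$n_asp_females, "female")
  males <- make_asp(config$n_asp_males, "male")
  newf <- make_asp(config$n_asp_newly_tagged, "female", newly_tagged = TRUE)

  registry <- list()
  intervals <- list()  # per individual: matrix of raw presence intervals

  add_asp_group <- function(grp, sex, tag_ids) {
    for (i in seq_along(tag_ids)) {
      nv <- sample(seq(config$visits_min, config$visits_max), 1)
      noct <- runif(nv) < config$night_spawn_prob
      v <- t(vapply(noct, draw_visit, numeric(2)))
      intervals[[tag_ids[i]]] <<- v
    }
    elapsed_yr <- as.numeric(config$season_start - grp$tagging) / 365.25
    linf_i <- grp$tl / (1 - exp(-config$growth_k * (grp$age - config$growth_t0)))
    tl_spawn <- linf_i * (1 - exp(-config$growth_k *
                                    (grp$age + elapsed_yr - config$growth_t0)))
    recap <- sex == "female" & runif(length(tag_ids)) < config$recapture_prob &
      elapsed_yr > 0.5
    registry[[length(registry) + 1L]] <<- data.frame(
      tag_code = tag_ids, species = "asp", sex = sex,
      total_length_cm = round(grp$tl, 1),
      weight_g = round(length_to_weight(grp$tl), 0),
      age_years = grp$age,
      tagging_date = grp$tagging,
      recapture_length_cm = ifelse(recap, round(tl_spawn, 1), NA_real_),
      recapture_date = as.Date(ifelse(recap, as.character(config$season_start +
                                                            sample.int(n_days, length(tag_ids), replace = TRUE) - 1),
                                      NA)),
      stringsAsFactors = FALSE)
    tl_spawn
  }

  fem_ids <- ids("A", config$n_asp_females)
  male_ids <- ids("M", config$n_asp_males)
  newf_ids <- ids("N", config$n_asp_newly_tagged)
  tl_spawn_fem <- add_asp_group(fem, "female", fem_ids)
  if (config$n_asp_males > 0) add_asp_group(males, "male", male_ids)
  if (config$n_asp_newly_tagged > 0) add_asp_group(newf, "female", newf_ids)

  # bleak: diurnal presence with occasional overnight stays
  bleak_ids <- ids("B", config$n_bleak)
  if (config$n_bleak > 0) {
    btl <- pmax(rnorm(config$n_bleak, config$bleak_tl_mean, config$bleak_tl_sd), 8)
    btag_date <- config$season_start - 1 - sample.int(7, config$n_bleak, replace = TRUE)
    registry[[length(registry) + 1L]] <- data.frame(
      tag_code = bleak_ids, species = "bleak", sex = "unknown",
      total_length_cm = round(btl, 1),
      weight_g = round(0.01 * btl^3, 1),
      age_years = NA_real_, tagging_date = btag_date,
      recapture_length_cm = NA_real_, recapture_date = as.Date(NA),
      stringsAsFactors = FALSE)
    p_day <- pmin(config$bleak_day_presence +
                    config$bleak_date_slope * (seq_len(n_days) - 1), 1)
    for (i in seq_len(config$n_bleak)) {
      iv <- NULL
      for (d in seq_len(n_days)) {
        if (runif(1) < p_day[d]) {
          arrive <- day_win[d, 1] - runif(1, 0, 1800)
          depart <- day_win[d, 2] - runif(1, 0, 2700)
          iv <- rbind(iv, c(arrive, depart))
          if (runif(1) < config$bleak_night_stay_prob)
            iv <- rbind(iv, c(day_win[d, 2], night_win[d, 2]))
        }
      }
      if (!is.null(iv)) intervals[[bleak_ids[i]]] <- iv
    }
  }

  registry <- do.call(rbind, registry)

  # clip presence to the season window (visits drawn in the last night
  # window would otherwise spill past it)
  intervals <- lapply(intervals, function(iv) {
    iv[, 1] <- pmax(iv[, 1], season_s)
    iv[, 2] <- pmin(iv[, 2], season_e)
    iv[iv[, 2] > iv[, 1], , drop = FALSE]
  })
  intervals <- intervals[vapply(intervals, nrow, integer(1)) > 0]

  # detections: Poisson antenna passes with 10 Hz read bursts on the cycle grid
  tick <- 1 / config$detection_rate_hz
  det <- list()
  k <- 0L
  for (tag in names(intervals)) {
    iv <- intervals[[tag]]
    for (r in seq_len(nrow(iv))) {
      s <- iv[r, 1]; e <- iv[r, 2]
      npass <- rpois(1, (e - s) / 3600 * config$passes_per_hour)
      pt <- sort(c(s, runif(npass, s, e), e))
      if (config$miss_prob > 0)
        pt <- pt[runif(length(pt)) >= config$miss_prob]
      if (!length(pt)) next
      ant <- sample.int(3, length(pt), replace = TRUE)
      nb <- 1 + rpois(length(pt), max(config$burst_mean - 1, 0))
      times <- rep(pt, nb) + unlist(lapply(nb, function(m) (seq_len(m) - 1) * tick))
      k <- k + 1L
      det[[k]] <- data.table::data.table(t = round(times / tick) * tick,
                                         antenna_id = rep(ant, nb),
                                         tag_code = tag)
    }
  }
  detections <- data.table::rbindlist(det)
  # one read per antenna per reader cycle: a read colliding with an earlier
  # one (same antenna, same cycle) is served on the next free cycle
  data.table::setorder(detections, antenna_id, t)
  bump <- function(t) {
    for (i in seq_along(t)[-1])
      if (t[i] < t[i - 1] + tick * 0.999) t[i] <- t[i - 1] + tick
    t
  }
  detections[, t := bump(t), by = antenna_id]
  data.table::setorder(detections, t, antenna_id)
  detections <- data.frame(
    timestamp = as.POSIXct(detections$t, origin = "1970-01-01", tz = "UTC"),
    antenna_id = detections$antenna_id,
    tag_code = detections$tag_code, stringsAsFactors = FALSE)

  # hourly temperature, warming trend plus afternoon-peaked diel cycle
  th <- seq(season_s - 86400, season_e + 86400 - 3600, by = 3600)
  hrs <- (th %% 86400) / 3600
  dayn <- (th - season_s) / 86400
  temperature <- data.frame(
    timestamp = as.POSIXct(th, origin = "1970-01-01", tz = "UTC"),
    temp_c = round(config$temp_start_c + config$temp_trend_c_per_day * dayn +
                     config$temp_diel_amp_c * cos(2 * pi * (hrs - 14) / 24) +
                     rnorm(length(th), 0, config$temp_noise_sd), 2))

  # ground truth
  full_win <- win
  truth_bouts <- list()
  for (tag in names(intervals)) {
    m <- .merge_intervals(intervals[[tag]][, 1], intervals[[tag]][, 2])
    truth_bouts[[tag]] <- data.frame(tag_code = tag, start = m[, 1],
                                     end = m[, 2])
  }
  truth_bouts <- do.call(rbind, truth_bouts)
  rownames(truth_bouts) <- NULL
  w_fem <- length_to_weight(tl_spawn_fem)
  fec_fem <- fecundity(w_fem, config$gsi, config$egg_mass_g)
  tb_fem <- truth_bouts[truth_bouts$tag_code %in% fem_ids, ]
  dsec <- .day_seconds(tb_fem$start, tb_fem$end, full_win)
  tot <- tb_fem$end - tb_fem$start
  per_fem <- aggregate(cbind(day_s = dsec, tot_s = tot),
                       by = list(tag_code = tb_fem$tag_code), FUN = sum)
  fec_map <- setNames(fec_fem, fem_ids)[per_fem$tag_code]
  night_frac_i <- ifelse(per_fem$tot_s > 0,
                         1 - per_fem$day_s / per_fem$tot_s, NA)
  truth_night_egg_frac <- sum(fec_map * night_frac_i, na.rm = TRUE) /
    sum(fec_map[!is.na(night_frac_i)])
  tb_blk <- truth_bouts[truth_bouts$tag_code %in% bleak_ids, ]
  bleak_day_share <- NA_real_
  if (nrow(tb_blk)) {
    bd <- .day_seconds(tb_blk$start, tb_blk$end, full_win)
    per_blk <- aggregate(cbind(day_s = bd, tot_s = tb_blk$end - tb_blk$start),
                         by = list(tag_code = tb_blk$tag_code), FUN = sum)
    bleak_day_share <- mean(100 * per_blk$day_s / per_blk$tot_s)
  }
  truth <- list(
    bouts = data.frame(tag_code = truth_bouts$tag_code,
                       start = as.POSIXct(truth_bouts$start,
                                          origin = "1970-01-01", tz = "UTC"),
                       end = as.POSIXct(truth_bouts$end,
                                        origin = "1970-01-01", tz = "UTC")),
    fecundity = data.frame(tag_code = fem_ids, eggs = fec_fem,
                           tl_spawn_cm = tl_spawn_fem),
    night_egg_fraction = truth_night_egg_frac,
    bleak_day_share_pct = bleak_day_share,
    female_ids = fem_ids, bleak_ids = bleak_ids,
    season = c(as.character(config$season_start),
               as.character(config$season_end)),
    config = config[setdiff(names(config), "n_days")])

  out <- list(registry = registry, detections = detections,
              temperature = temperature, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(registry, file.path(out_dir, "registry.csv"),
                     row.names = FALSE, na = "")
    write_detections(detections, file.path(out_dir, "detections.csv"))
    utils::write.csv(
      data.frame(timestamp = format(temperature$timestamp, .dw_ts_out, tz = "UTC"),
                 temp_c = temperature$temp_c),
      file.path(out_dir, "temperature.csv"), row.names = FALSE)
    jsonlite::write_json(truth[c("night_egg_fraction", "bleak_day_share_pct",
                                 "season")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Tabulate the ground truth of a synthetic season
#'
#' @param truth the `truth` element of a [generate_season()] result.
#' @return a `data.frame` of named ground-truth quantities keyed to the
#'   pipeline outputs they validate.
#' @export
truth_report <- function(truth) {
  data.frame(
    quantity = c("night_egg_fraction", "bleak_day_share_pct",
                 "n_females", "n_bleak", "total_fecundity"),
    value = c(truth$night_egg_fraction, truth$bleak_day_share_pct,
              length(truth$female_ids), length(truth$bleak_ids),
              sum(truth$fecundity$eggs)))
}

#' Generate a multi-season synthetic study
#'
#' Concatenates the outputs of several [generate_season()] calls (distinct
#' individuals per season) into one registry, detection log and temperature
#' series — the shape of a two-year field campaign.
#'
#' @param configs list of [synth_config()] lists (use distinct seeds and
#'   season years).
#' @return list with merged `registry`, `detections`, `temperature`, and
#'   `truths` (one truth record per season).
#' @export
generate_study <- function(configs) {
  seasons <- lapply(configs, generate_season)
  list(registry = do.call(rbind, lapply(seasons, `[[`, "registry")),
       detections = do.call(rbind, lapply(seasons, `[[`, "detections")),
       temperature = do.call(rbind, lapply(seasons, `[[`, "temperature")),
       truths = lapply(seasons, `[[`, "truth"))
}
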