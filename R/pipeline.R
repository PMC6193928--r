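#' Assemble a full run configuration
#'
#' Collects every tunable of the chain — ingest, bout segmentation,
#' eligibility, diel geometry, growth/fecundity, model specification — with
#' the defaults used throughout the package. Inputs may be file paths (the
#' canonical CSV dialects) or in-memory data frames.
#'
#' @param detections,registry,temperature paths or data.frames.
#' @param seasons list of length-2 character vectors `c(start, end)` (end
#'   exclusive); one entry per monitored spawning season/year.
#' @param gap_hours bout gap threshold (hours).
#' @param min_spacing_s sub-second re-detection collapse spacing.
#' @param bin_minutes analysis bin width (minutes).
#' @param lat,lon,twilight diel geometry ([solar_times()]).
#' @param asp_min_lag_days,bleak_min_lag_days eligibility lags.
#' @param lw_a,lw_b length-weight coefficients.
#' @param gsi,egg_mass_g fecundity parameters.
#' @param reject_frac_max abort when more than this fraction of detection
#'   rows is rejected.
#' @param scale_response z-score the responses along with the covariates.
#' @param egg_random,bleak_random lme4 random-effect terms of the two
#'   models.
#' @param do_stepwise run backward AIC selection after the full fits.
#' @param seed seed for the (few) stochastic steps, e.g. permutation
#'   p-values.
#' @param out_dir optional output directory for the CSV/JSON bundle.
#' @return a run-config list for [run_pipeline()].
#' @export
run_config <- function(detections, registry, temperature, seasons,
                       gap_hours = 2, min_spacing_s = 1, bin_minutes = 60,
                       lat = 49.578497, lon = 15.251671,
                       twilight = "official",
                       asp_min_lag_days = 365, bleak_min_lag_days = 1,
                       lw_a = 0.00744, lw_b = 3.046,
                       gsi = 0.15, egg_mass_g = 0.0035,
                       reject_frac_max = 0.1,
                       scale_response = TRUE,
                       egg_random = "(1 | year)",
                       bleak_random = "(1 + date | bleak_id)",
                       do_stepwise = TRUE,
                       seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  if (!is.list(cfg$seasons[[1]]) && !is.vector(cfg$seasons[[1]]))
    stop("seasons must be a list of c(start, end) pairs")
  for (p in c("detections", "registry", "temperature"))
    if (is.character(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(p, " file not found: ", cfg[[p]])
  cfg
}

#' Read a YAML run configuration
#'
#' Maps a YAML document onto [run_config()]; unknown keys are an error so
#' typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a run-config list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  need <- c("detections", "registry", "temperature", "seasons")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("config missing: ", paste(miss, collapse = ", "))
  do.call(run_config, y)
}

.load_input <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full inference chain
#'
#' Ingest, collapse and segment the detection stream; apply eligibility;
#' project female length/weight/fecundity; allocate eggs over presence
#' time; label bins day/night; summarize diel shares; build, scale and fit
#' the two mixed models (with optional backward AIC selection); and compute
#' the Kendall correlation between daily egg and predator-presence totals.
#'
#' @param config a [run_config()] list.
#' @return a list with elements `bouts`, `fecundity`, `egg_series`,
#'   `bleak_presence`, `design_eggs`, `design_bleak`, `profile`,
#'   `model_eggs`, `model_bleak` (each a [stepwise_aic()] result when
#'   `do_stepwise`, else a [fit_lmm()]), `summary` (the headline numbers),
#'   and `manifest`. When `config$out_dir` is set the bundle is also
#'   written as CSV/JSON files; a failure leaves a `FAILED` marker file
#'   there.
#' @export
run_pipeline <- function(config) {
  ok <- FALSE
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    on.exit(if (!ok) writeLines("pipeline failed; partial outputs only",
                                file.path(config$out_dir, "FAILED")),
            add = TRUE)
  }
  detections <- .load_input(config$detections, read_detections)
  registry <- .load_input(config$registry, read_registry)
  temperature <- .load_input(config$temperature, read_temperature)
  rejects <- attr(detections, "rejects")
  if (!is.null(rejects) && nrow(rejects) > 0) {
    frac <- nrow(rejects) / (nrow(rejects) + nrow(detections))
    if (!is.null(config$out_dir))
      utils::write.csv(rejects, file.path(config$out_dir, "rejects.csv"),
                       row.names = FALSE)
    if (frac > config$reject_frac_max)
      stop(sprintf("%.1f%% of detection rows rejected (limit %.1f%%)",
                   100 * frac, 100 * config$reject_frac_max))
  }
  detections <- detections[order(detections$tag_code, detections$timestamp), ]
  events <- dedupe_detections(detections, config$min_spacing_s)
  bouts_all <- segment_bouts(events, config$gap_hours)
  rules <- eligibility_rules(config$asp_min_lag_days, config$bleak_min_lag_days)

  per_season <- lapply(config$seasons, function(se) {
    season <- as.POSIXct(paste(se, "00:00:00"), tz = "UTC")
    bouts <- apply_eligibility(bouts_all, registry, rules, season = season)
    fem_bouts <- bouts[bouts$species == "asp" & bouts$sex == "female", ]
    blk_bouts <- bouts[bouts$species == "bleak", ]
    fec <- female_fecundity(registry, target_date = as.Date(se[1]),
                            lw_a = config$lw_a, lw_b = config$lw_b,
                            gsi = config$gsi, egg_mass_g = config$egg_mass_g)
    fec <- fec[fec$tag_code %in% fem_bouts$tag_code, , drop = FALSE]
    fem_bouts <- fem_bouts[fem_bouts$tag_code %in% fec$tag_code, , drop = FALSE]
    bins <- make_bins(season[1], season[2], config$bin_minutes)
    bins <- label_bins(bins, config$lat, config$lon, config$twilight)
    eggs <- allocate_eggs(fem_bouts, fec, bins)
    blk_ids <- sort(unique(blk_bouts$tag_code))
    blk_pres <- presence_matrix(blk_bouts, bins)
    fem_pres <- presence_matrix(fem_bouts, bins)
    list(bouts = bouts, fec = fec, bins = bins, eggs = eggs,
         blk_pres = blk_pres, fem_pres = fem_pres, blk_ids = blk_ids,
         growth = attr(fec, "growth"))
  })

  bins_all <- do.call(rbind, lapply(per_season, `[[`, "bins"))
  eggs_all <- do.call(rbind, lapply(per_season, `[[`, "eggs"))
  i <- match(eggs_all$bin_start, bins_all$bin_start)
  night_frac <- bins_all$night_frac[i]
  date_grp <- as.Date(eggs_all$bin_start, tz = "UTC")
  egg_share <- night_share(eggs_all$bin_start, eggs_all$eggs,
                           night_frac, date_grp)
  blk_long <- do.call(rbind, lapply(per_season, `[[`, "blk_pres"))
  j <- match(blk_long$bin_start, bins_all$bin_start)
  blk_share <- night_share(blk_long$bin_start, blk_long$presence,
                           bins_all$night_frac[j], blk_long$tag_code)

  blk_binned <- aggregate(presence ~ bin_start, data = blk_long, FUN = sum)
  fem_long <- do.call(rbind, lapply(per_season, `[[`, "fem_pres"))
  profile <- data.frame(
    hour = 0:23,
    eggs_mean = diel_profile(eggs_all$bin_start, eggs_all$eggs)$mean,
    bleak_mean = diel_profile(blk_binned$bin_start, blk_binned$presence)$mean,
    females_mean = diel_profile(fem_long$bin_start, fem_long$presence)$mean)

  design_eggs <- do.call(rbind, lapply(per_season, function(ps)
    build_design(ps$eggs, ps$blk_pres, ps$blk_ids, temperature, ps$bins,
                 model = "eggs")))
  design_bleak <- do.call(rbind, lapply(per_season, function(ps)
    build_design(ps$eggs, ps$blk_pres, ps$blk_ids, temperature, ps$bins,
                 model = "bleak")))
  scale_cols_e <- c("period", "date", "bleak", "temp_c",
                    if (config$scale_response) "eggs")
  scale_cols_b <- c("period", "date", "eggs", "temp_c",
                    if (config$scale_response) "presence")
  de <- centre_scale(design_eggs, scale_cols_e)
  db <- centre_scale(design_bleak, scale_cols_b)
  if (!config$scale_response) {
    de$eggs <- design_eggs$eggs
    db$presence <- design_bleak$presence
  }
  fixed_e <- c("period", "date", "bleak", "temp_c")
  fixed_b <- c("period", "date", "eggs", "temp_c")
  model_eggs <- if (config$do_stepwise)
    stepwise_aic(de, fixed_e, config$egg_random, "eggs")
  else list(model = fit_lmm(de, fixed_e, config$egg_random, "eggs"),
            kept = fixed_e, dropped = character(0), trace = NULL)
  model_bleak <- if (config$do_stepwise)
    stepwise_aic(db, fixed_b, config$bleak_random, "presence")
  else list(model = fit_lmm(db, fixed_b, config$bleak_random, "presence"),
            kept = fixed_b, dropped = character(0), trace = NULL)

  ddt <- data.table::data.table(date = as.Date(design_eggs$bin_start, tz = "UTC"),
                                eggs = design_eggs$eggs,
                                bleak = design_eggs$bleak)
  daily <- ddt[, .(eggs = sum(eggs), bleak = sum(bleak)), by = date]
  tau <- kendall_tau(daily$eggs, daily$bleak, perm_seed = config$seed)

  summarize_fit <- function(m) {
    ct <- m$model$coefficients
    list(terms = setNames(as.list(round(ct$estimate, 6)), ct$term),
         p = setNames(as.list(signif(ct$p, 6)), ct$term),
         dropped = m$dropped,
         r2_marginal = round(m$model$r2_marginal, 6),
         r2_conditional = round(m$model$r2_conditional, 6),
         aic = round(m$model$aic, 3),
         singular = m$model$singular)
  }
  summary <- list(
    egg_night_share_pct = round(egg_share$mean_pct, 4),
    egg_night_share_sd_pct = round(egg_share$sd_pct, 4),
    bleak_night_share_pct = round(blk_share$mean_pct, 4),
    bleak_night_share_sd_pct = round(blk_share$sd_pct, 4),
    bleak_day_share_pct = round(100 - blk_share$mean_pct, 4),
    n_females_used = sum(vapply(per_season, function(ps) nrow(ps$fec),
                                integer(1))),
    n_bleak_used = length(unique(blk_long$tag_code)),
    kendall_tau_daily_eggs_bleak = round(tau$tau, 6),
    kendall_p = signif(tau$p, 6),
    model_eggs = summarize_fit(model_eggs),
    model_bleak = summarize_fit(model_bleak))

  manifest <- list(
    package_version = as.character(utils::packageVersion("driftwatch")),
    config = .manifest_config(config),
    inputs = .input_fingerprints(config),
    n_detections = nrow(detections), n_events_after_dedupe = nrow(events),
    n_rejected_rows = if (is.null(rejects)) 0L else nrow(rejects))

  out <- list(bouts = do.call(rbind, lapply(per_season, `[[`, "bouts")),
              fecundity = do.call(rbind, lapply(per_season, `[[`, "fec")),
              growth = lapply(per_season, `[[`, "growth"),
              egg_series = eggs_all, bleak_presence = blk_long,
              design_eggs = design_eggs, design_bleak = design_bleak,
              profile = profile, model_eggs = model_eggs,
              model_bleak = model_bleak, egg_share = egg_share,
              bleak_share = blk_share, summary = summary,
              manifest = manifest)
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  ok <- TRUE
  out
}

.manifest_config <- function(config) {
  keep <- !vapply(config, is.data.frame, logical(1))
  cfg <- config[keep]
  cfg[vapply(cfg, is.null, logical(1))] <- NULL
  cfg
}

.input_fingerprints <- function(config) {
  fp <- function(x) {
    if (is.character(x))
      list(path = x, md5 = unname(tools::md5sum(x)))
    else list(in_memory = TRUE, n_rows = nrow(x))
  }
  list(detections = fp(config$detections),
       registry = fp(config$registry),
       temperature = fp(config$temperature))
}

.write_bundle <- function(out, dir) {
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE, na = "")
  b <- out$bouts
  b$start <- format(b$start, .dw_ts_out, tz = "UTC")
  b$end <- format(b$end, .dw_ts_out, tz = "UTC")
  wcsv(b, "bouts.csv")
  wcsv(out$fecundity, "biomass.csv")
  es <- out$egg_series
  es$bin_start <- format(es$bin_start, .dw_ts_out, tz = "UTC")
  wcsv(es, "eggs_bins.csv")
  wcsv(out$profile, "diel_profile.csv")
  wcsv(out$model_eggs$model$coefficients, "model_eggs.csv")
  wcsv(out$model_bleak$model$coefficients, "model_bleak.csv")
  jsonlite::write_json(out$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
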