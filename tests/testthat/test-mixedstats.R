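sim_lmm <- function(n = 2000, n_groups = 20, beta = c(period = 0.4, x = 0.3),
                    sd_int = 0.3, sd_res = 1, null_cov = FALSE) {
  g <- factor(sample.int(n_groups, n, replace = TRUE))
  d <- data.frame(period = rbinom(n, 1, 0.5), x = rnorm(n),
                  z = rnorm(n), year = g)
  b_g <- rnorm(n_groups, 0, sd_int)
  d$y <- beta["period"] * d$period + beta["x"] * d$x +
    b_g[as.integer(g)] + rnorm(n, 0, sd_res)
  d
}

test_that("r2 plug-in formulas and their invariants hold", {
  r2 <- r2_components(1, 1, 2)
  expect_equal(r2$r2_marginal, 0.25)
  expect_equal(r2$r2_conditional, 0.50)
  set.seed(3)
  for (i in 1:20) {
    v <- rexp(3)
    r <- r2_components(v[1], v[2], v[3])
    expect_true(r$r2_marginal <= r$r2_conditional)
    expect_true(r$r2_conditional <= 1 && r$r2_marginal >= 0)
  }
})

test_that("mixed-model fit recovers planted fixed effects with sane df and r2", {
  set.seed(21)
  d <- sim_lmm(n = 2000)
  fit <- fit_lmm(d, fixed = c("period", "x"), random = "(1 | year)",
                 response = "y")
  ct <- fit$coefficients
  expect_lt(abs(ct$estimate[ct$term == "period"] - 0.4), 0.1)
  expect_lt(ct$p[ct$term == "period"], 0.05)
  # Satterthwaite df never exceed the OLS residual df
  ols_df <- nrow(d) - 3
  expect_true(all(ct$df <= ols_df + 1e-9))
  # r2 from the fit equals the closed-form plug-in of its own components
  r2 <- r2_components(fit$var_f, fit$var_r, fit$var_e)
  expect_equal(fit$r2_marginal, r2$r2_marginal, tolerance = 1e-12)
  expect_true(fit$r2_marginal <= fit$r2_conditional)
})

test_that("single-level grouping degenerates gracefully to OLS", {
  set.seed(22)
  d <- sim_lmm(n = 300)
  d$year <- factor("2017")
  fit <- fit_lmm(d, fixed = c("period", "x"), random = "(1 | year)",
                 response = "y")
  ols <- lm(y ~ period + x, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(fit$var_r, 0)
  expect_equal(fit$r2_marginal, fit$r2_conditional, tolerance = 1e-6)
})

test_that("centring and scaling give exact z-scores and round-trip", {
  d <- data.frame(a = rnorm(50, 10, 3), b = runif(50), k = rep(1, 50))
  s <- centre_scale(d, c("a", "b"))
  expect_lt(abs(mean(s$a)), 1e-12)
  expect_lt(abs(sd(s$a) - 1), 1e-12)
  expect_lt(abs(mean(s$b)), 1e-12)
  expect_error(centre_scale(d, "k"), "constant")
  back <- uncentre_scale(s)
  expect_equal(back$a, d$a, tolerance = 1e-12)
  # scaling an already-scaled column leaves it unchanged
  s2 <- centre_scale(s, "a")
  expect_equal(s2$a, s$a, tolerance = 1e-12)
})

test_that("design tables have the contracted shape and flag missing temperature", {
  set.seed(23)
  bins <- label_bins(hour_bins("2017-04-01", 24))
  eggs <- data.frame(bin_start = bins$bin_start,
                     eggs = rexp(24, 1 / 100))
  bp <- rbind(
    data.frame(tag_code = "B1", bin_start = bins$bin_start[5:10], presence = 1),
    data.frame(tag_code = "B2", bin_start = bins$bin_start[8:9], presence = 0.5))
  temp <- data.frame(timestamp = bins$bin_start + 1800,
                     temp_c = 7 + rnorm(24, 0, 0.2))
  de <- build_design(eggs, bp, c("B1", "B2"), temp, bins, model = "eggs")
  expect_equal(nrow(de), 24L)
  expect_equal(de$bleak[5], 1)
  expect_equal(de$bleak[8], 1.5)
  expect_true(all(de$period %in% c(0, 1)))
  db <- build_design(eggs, bp, c("B1", "B2"), temp, bins, model = "bleak")
  expect_equal(nrow(db), 48L)
  expect_equal(sum(db$presence[db$bleak_id == "B2"]), 1)

  # drop bins whose nearest temperature sample is over 90 minutes away
  temp_gappy <- temp[-(12:14), ]
  de2 <- build_design(eggs, bp, c("B1", "B2"), temp_gappy, bins,
                      model = "eggs")
  expect_lt(nrow(de2), 24L)
  expect_gt(attr(de2, "n_dropped_temp"), 0L)
})

test_that("backward AIC selection keeps strong terms, is deterministic, and drops a null", {
  set.seed(24)
  d <- sim_lmm(n = 800, beta = c(period = 0.8, x = 0.8))
  sel <- stepwise_aic(d, fixed = c("period", "x", "z"), random = "(1 | year)",
                      response = "y")
  expect_true(all(c("period", "x") %in% sel$kept))
  expect_true(is.data.frame(sel$trace) && any(sel$trace$action == "candidate"))
  sel2 <- stepwise_aic(d, fixed = c("period", "x", "z"), random = "(1 | year)",
                       response = "y")
  expect_identical(sel$kept, sel2$kept)
  expect_equal(sel$model$aic, sel2$model$aic)
})

test_that("kendall tau handles perfect association and matches brute force", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(kendall_tau(x, x)$tau, 1)
  expect_equal(kendall_tau(x, -x)$tau, -1)
  set.seed(25)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    a <- sample(1:8, n, replace = TRUE)   # plenty of ties
    b <- a + sample(-2:2, n, replace = TRUE)
    got <- kendall_tau(a, b)
    expect_equal(got$tau, oracle_kendall(a, b), tolerance = 1e-12)
    expect_true(got$p >= 0 && got$p <= 1)
  }
  # large-n normal approximation p agrees with the base-R test
  set.seed(26)
  a <- rnorm(100); b <- 0.3 * a + rnorm(100)
  got <- kendall_tau(a, b)
  ref <- suppressWarnings(stats::cor.test(a, b, method = "kendall"))
  expect_equal(got$tau, unname(ref$estimate), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 0.02)
})

test_that("planted diel signs are recovered on synthetic seasons", {
  g <- generate_season(synth_config(seed = 31, n_asp_females = 120,
                                    n_asp_males = 0, n_asp_newly_tagged = 0,
                                    n_bleak = 15))
  ev <- dedupe_detections(
    g$detections[order(g$detections$tag_code, g$detections$timestamp), ], 1)
  season <- as.POSIXct(c("2017-04-01", "2017-04-15"), tz = "UTC")
  el <- apply_eligibility(segment_bouts(ev), g$registry,
                          eligibility_rules(), season = season)
  bins <- label_bins(make_bins(season[1], season[2]))
  fb <- el[el$species == "asp" & el$sex == "female", ]
  bb <- el[el$species == "bleak", ]
  eggs <- suppressWarnings(allocate_eggs(fb, g$truth$fecundity, bins))
  bp <- presence_matrix(bb, bins)
  temp <- g$temperature
  de <- centre_scale(build_design(eggs, bp, unique(bb$tag_code), temp, bins,
                                  model = "eggs"),
                     c("eggs", "period", "date", "bleak", "temp_c"))
  fe <- fit_lmm(de, c("period", "date", "bleak", "temp_c"), NULL, "eggs")
  cte <- fe$coefficients
  expect_gt(cte$estimate[cte$term == "period"], 0)  # night-coded 1: more eggs
  expect_lt(cte$estimate[cte$term == "date"], 0)    # arrivals decay in season
  db <- centre_scale(build_design(eggs, bp, unique(bb$tag_code), temp, bins,
                                  model = "bleak"),
                     c("presence", "period", "date", "eggs", "temp_c"))
  fbm <- fit_lmm(db, c("period", "date", "eggs"), "(1 | bleak_id)", "presence")
  ctb <- fbm$coefficients
  expect_lt(ctb$estimate[ctb$term == "period"], 0)  # bleak prefers daylight
  expect_gt(ctb$estimate[ctb$term == "date"], 0)    # bleak arrive later in season
})
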