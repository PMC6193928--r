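mk_bout <- function(tag, start_str, dur_h) {
  s <- as.POSIXct(start_str, tz = "UTC")
  data.frame(tag_code = tag, start = s, end = s + dur_h * 3600)
}

test_that("eggs spread uniformly over a single bout", {
  bins <- hour_bins("2017-04-01", 48)
  bouts <- mk_bout("F1", "2017-04-01 22:00:00", 4)
  fec <- data.frame(tag_code = "F1", eggs = 10000)
  es <- allocate_eggs(bouts, fec, bins)
  nz <- es[es$eggs > 0, ]
  expect_equal(nrow(nz), 4L)
  expect_equal(nz$eggs, rep(2500, 4))
  expect_equal(format(nz$bin_start, "%H"), c("22", "23", "00", "01"))
})

test_that("a single rate across the bout union splits eggs by duration", {
  bins <- hour_bins("2017-04-01", 48)
  bouts <- rbind(mk_bout("F1", "2017-04-01 02:00:00", 1),
                 mk_bout("F1", "2017-04-01 10:00:00", 3))
  fec <- data.frame(tag_code = "F1", eggs = 8000)
  es <- allocate_eggs(bouts, fec, bins)
  h <- as.POSIXlt(es$bin_start, tz = "UTC")$hour
  d <- as.POSIXlt(es$bin_start, tz = "UTC")$mday
  expect_equal(sum(es$eggs[h == 2 & d == 1]), 2000)
  expect_equal(sum(es$eggs[h %in% 10:12 & d == 1]), 6000)
})

test_that("zero-duration-only females deposit into their containing bins", {
  bins <- hour_bins("2017-04-01", 24)
  bouts <- rbind(mk_bout("F1", "2017-04-01 05:15:00", 0),
                 mk_bout("F1", "2017-04-01 09:40:00", 0))
  fec <- data.frame(tag_code = "F1", eggs = 600)
  es <- allocate_eggs(bouts, fec, bins)
  h <- as.POSIXlt(es$bin_start, tz = "UTC")$hour
  expect_equal(es$eggs[h == 5], 300)
  expect_equal(es$eggs[h == 9], 300)
  expect_equal(sum(es$eggs), 600)
})

test_that("allocation matches a fine-grid numerical oracle and conserves eggs", {
  set.seed(12)
  bins <- hour_bins("2017-04-01", 24 * 6)
  g0 <- as.numeric(bins$bin_start[1])
  for (rep in 1:5) {
    bouts <- do.call(rbind, lapply(1:6, function(i) {
      k <- sample(1:3, 1)
      s <- sort(g0 + round(runif(k, 0, 5 * 86400)))
      d <- round(runif(k, 900, 6 * 3600))
      # enforce disjoint bouts per female
      for (j in seq_len(k - 1)) s[j + 1] <- max(s[j + 1], s[j] + d[j] + 1)
      data.frame(tag_code = sprintf("F%d", i),
                 start = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
                 end = as.POSIXct(pmin(s + d, g0 + 6 * 86400 - 1),
                                  origin = "1970-01-01", tz = "UTC"))
    }))
    fec <- data.frame(tag_code = sprintf("F%d", 1:6),
                      eggs = runif(6, 1e3, 5e4))
    es <- allocate_eggs(bouts, fec, bins)
    expect_equal(sum(es$eggs), sum(fec$eggs), tolerance = 1e-9)
    oracle <- oracle_allocate(bouts, fec, bins)
    expect_equal(es$eggs, oracle, tolerance = 1e-9)
  }
})

test_that("a female with fecundity but no bouts is skipped with a warning", {
  bins <- hour_bins("2017-04-01", 24)
  bouts <- mk_bout("F1", "2017-04-01 05:00:00", 2)
  fec <- data.frame(tag_code = c("F1", "F2"), eggs = c(100, 200))
  expect_warning(es <- allocate_eggs(bouts, fec, bins), "skipped")
  expect_equal(sum(es$eggs), 100)
})

test_that("night share summarizes per group with fractional weights", {
  bins <- label_bins(hour_bins("2017-04-01", 24 * 4))
  h <- as.POSIXlt(bins$bin_start, tz = "UTC")$hour
  g <- as.Date(bins$bin_start, tz = "UTC")

  all_night <- as.numeric(bins$night_frac == 1)
  sh <- night_share(bins$bin_start, all_night, bins$night_frac, g)
  expect_equal(sh$mean_pct, 100)
  expect_equal(sh$sd_pct, 0)

  # equal mass in one full-night and one full-day bin each day
  v <- as.numeric(h == 0 | h == 12)
  sh2 <- night_share(bins$bin_start, v, bins$night_frac, g)
  expect_equal(sh2$mean_pct, 50)
  expect_equal(sh2$sd_pct, 0)

  sh3 <- night_share(bins$bin_start, rep(0, nrow(bins)), bins$night_frac, g)
  expect_true(is.na(sh3$mean_pct))
  expect_equal(sh3$n_zero_groups, 4L)
})

test_that("night share is scale invariant and diel-periodic", {
  set.seed(13)
  bins <- label_bins(hour_bins("2017-04-01", 24 * 8))
  v <- rexp(nrow(bins))
  g <- as.Date(bins$bin_start, tz = "UTC")
  a <- night_share(bins$bin_start, v, bins$night_frac, g)
  b <- night_share(bins$bin_start, 1000 * v, bins$night_frac, g)
  expect_equal(a$mean_pct, b$mean_pct, tolerance = 1e-12)
  expect_true(a$mean_pct >= 0 && a$mean_pct <= 100)

  # a +24 h shift preserves the share exactly when every day has the same
  # diel window (hour-of-day weights)
  h <- as.POSIXlt(bins$bin_start, tz = "UTC")$hour
  wk <- as.numeric(h < 5 | h >= 19)
  n <- length(v)
  v_shift <- v[((seq_len(n) - 1 - 24) %% n) + 1]
  a2 <- night_share(bins$bin_start, v, wk, g)
  b2 <- night_share(bins$bin_start, v_shift, wk, g)
  expect_equal(b2$mean_pct, a2$mean_pct, tolerance = 1e-9)
  expect_equal(b2$sd_pct, a2$sd_pct, tolerance = 1e-9)
})
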