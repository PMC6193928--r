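test_that("two-hour gap rule segments bouts with an inclusive boundary", {
  h <- 3600
  ev <- make_events(c(0, 1 * h, 4 * h))
  b <- segment_bouts(ev, gap_hours = 2)
  expect_equal(nrow(b), 2L)
  expect_equal(as.numeric(b$start), c(0, 4 * h))
  expect_equal(as.numeric(b$end), c(1 * h, 4 * h))
  expect_equal(b$n_detections, c(2L, 1L))

  # a gap of exactly the threshold still merges
  b2 <- segment_bouts(make_events(c(0, 2 * h)), gap_hours = 2)
  expect_equal(nrow(b2), 1L)
  expect_equal(as.numeric(b2$end) - as.numeric(b2$start), 2 * h)

  expect_error(segment_bouts(make_events(c(10, 5))), "sorted")
})

test_that("segmentation matches the pairwise-chaining oracle on random streams", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(c(5, 50, 500), 1)
    t <- sort(runif(n, 0, 30 * 86400))
    gap <- runif(1, 600, 4 * 3600)
    b <- segment_bouts(make_events(t), gap_hours = gap / 3600)
    o <- oracle_bouts(t, gap)
    expect_equal(as.numeric(b$start), o$start)
    expect_equal(as.numeric(b$end), o$end)
    expect_equal(b$n_detections, o$n_detections)
    # partition: every detection lies in exactly one bout
    expect_equal(sum(b$n_detections), n)
  }
})

test_that("enlarging the gap threshold never increases bout count", {
  set.seed(42)
  t <- sort(runif(400, 0, 20 * 86400))
  counts <- vapply(c(0.25, 0.5, 1, 2, 4, 8, 24),
                   function(g) nrow(segment_bouts(make_events(t), g)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("eligibility applies species lags, sex rule and orphan collection", {
  reg <- data.frame(
    tag_code = c("A1", "A2", "M1", "B1"),
    species = c("asp", "asp", "asp", "bleak"),
    sex = c("female", "female", "male", "unknown"),
    total_length_cm = c(49.5, 51, 47, 12),
    tagging_date = as.Date(c("2016-04-01", "2015-03-20", "2015-03-20",
                             "2016-03-31")),
    stringsAsFactors = FALSE)
  mk <- function(tag, start_str) {
    s <- as.POSIXct(start_str, tz = "UTC")
    data.frame(tag_code = tag, start = s, end = s + 3600,
               n_detections = 5L, antennas_seen = "1")
  }
  bouts <- rbind(mk("A1", "2016-04-05 01:00:00"),  # same season as tagging
                 mk("A2", "2016-04-05 01:00:00"),  # tagged a year before
                 mk("M1", "2016-04-05 01:00:00"),  # male
                 mk("B1", "2016-04-01 10:00:00"),  # bleak, day 1 after tagging
                 mk("X9", "2016-04-05 01:00:00")) # unknown tag
  out <- apply_eligibility(bouts, reg)
  expect_setequal(out$tag_code, c("A2", "B1"))
  expect_equal(attr(out, "orphans")$tag_code, "X9")
  ex <- attr(out, "n_excluded")
  expect_equal(unname(ex["male_asp"]), 1)
  expect_equal(unname(ex["tagging_lag"]), 1)

  # bleak detected the same day as tagging is excluded
  bouts2 <- mk("B1", "2016-03-31 23:00:00")
  expect_equal(nrow(apply_eligibility(bouts2, reg)), 0L)
})

test_that("season clipping truncates straddling bouts", {
  reg <- data.frame(tag_code = "A2", species = "asp", sex = "female",
                    total_length_cm = 50,
                    tagging_date = as.Date("2015-03-20"))
  s <- as.POSIXct("2016-04-01 00:00:00", tz = "UTC")
  bouts <- data.frame(tag_code = "A2", start = s - 3600, end = s + 3600,
                      n_detections = 10L, antennas_seen = "1,2")
  out <- apply_eligibility(bouts, reg, season = c(s, s + 14 * 86400))
  expect_equal(out$start, s)
  expect_equal(out$end, s + 3600)
})

test_that("presence fractions follow bout-bin geometry", {
  bins <- hour_bins("2017-04-01", 24)
  s <- as.POSIXct("2017-04-01 10:30:00", tz = "UTC")
  bouts <- data.frame(tag_code = "A1", start = s, end = s + 2 * 3600)
  pm <- presence_matrix(bouts, bins)
  expect_equal(pm$presence, c(0.5, 1, 0.5))
  expect_equal(format(pm$bin_start, "%H"), c("10", "11", "12"))

  # a zero-duration bout fills its containing bin
  zb <- data.frame(tag_code = "A1",
                   start = as.POSIXct("2017-04-01 10:15:00", tz = "UTC"),
                   end = as.POSIXct("2017-04-01 10:15:00", tz = "UTC"))
  pz <- presence_matrix(zb, bins)
  expect_equal(pz$presence, 1)
  expect_equal(format(pz$bin_start, "%H"), "10")
})

test_that("summed presence times bin width recovers total bout duration", {
  set.seed(7)
  bins <- hour_bins("2017-04-01", 24 * 5)
  g0 <- as.numeric(bins$bin_start[1])
  for (rep in 1:10) {
    s <- g0 + sort(runif(3, 0, 4 * 86400))
    d <- runif(3, 600, 8 * 3600)
    # keep bouts disjoint and inside the grid
    s <- s + cumsum(c(0, head(d, -1)))
    s <- pmin(s, g0 + 5 * 86400 - max(d) - 1)
    bouts <- data.frame(tag_code = "A1",
                        start = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
                        end = as.POSIXct(s + d, origin = "1970-01-01", tz = "UTC"))
    bouts <- bouts[order(bouts$start), ]
    bouts <- bouts[!duplicated(bouts$start), ]
    keep <- c(TRUE, bouts$start[-1] > bouts$end[-nrow(bouts)])
    bouts <- bouts[keep, ]
    pm <- presence_matrix(bouts, bins)
    expect_equal(sum(pm$presence) * 3600,
                 sum(as.numeric(bouts$end) - as.numeric(bouts$start)),
                 tolerance = 1e-9)
  }
})
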