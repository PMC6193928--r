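# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# Bout oracle: pairwise-chaining semantics via interval merging, processing
# detections in a randomized order (the package scans sorted times once).
oracle_bouts <- function(times, gap_s) {
  ord <- sample(seq_along(times))
  lo <- hi <- n <- numeric(0)
  for (t in times[ord]) {
    touch <- which(t >= lo - gap_s & t <= hi + gap_s)
    if (length(touch) == 0L) {
      lo <- c(lo, t); hi <- c(hi, t); n <- c(n, 1)
    } else {
      new_lo <- min(lo[touch], t); new_hi <- max(hi[touch], t)
      new_n <- sum(n[touch]) + 1
      lo <- c(lo[-touch], new_lo); hi <- c(hi[-touch], new_hi)
      n <- c(n[-touch], new_n)
    }
  }
  o <- order(lo)
  data.frame(start = lo[o], end = hi[o], n_detections = n[o])
}

# NOAA-spreadsheet solar oracle: the classic one-pass spreadsheet layout
# (all angles at noon UTC), coded independently of the package's refined
# two-pass implementation.
oracle_solar <- function(date, lat, lon, zenith = 90.833) {
  jd <- as.numeric(as.Date(date)) + 2440587.5 + 0.5
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  d2r <- pi / 180
  eqctr <- sin(gmas * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * d2r) * 0.000289
  truelong <- gmls + eqctr
  app <- truelong - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * d2r)
  obl0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obl <- obl0 + 0.00256 * cos((125.04 - 1934.136 * jc) * d2r)
  decl <- asin(sin(obl * d2r) * sin(app * d2r)) / d2r
  vary <- tan(obl / 2 * d2r)^2
  eqtime <- 4 / d2r * (vary * sin(2 * gmls * d2r) -
                         2 * ecc * sin(gmas * d2r) +
                         4 * ecc * vary * sin(gmas * d2r) * cos(2 * gmls * d2r) -
                         0.5 * vary^2 * sin(4 * gmls * d2r) -
                         1.25 * ecc^2 * sin(2 * gmas * d2r))
  cos_ha <- cos(zenith * d2r) / (cos(lat * d2r) * cos(decl * d2r)) -
    tan(lat * d2r) * tan(decl * d2r)
  ha <- acos(pmin(pmax(cos_ha, -1), 1)) / d2r
  midnight <- as.POSIXct(paste(as.Date(date)), tz = "UTC")
  list(sunrise = midnight + (720 - 4 * (lon + ha) - eqtime) * 60,
       sunset = midnight + (720 - 4 * (lon - ha) - eqtime) * 60)
}

# Fine-grid egg allocation oracle: chop each bout into one-second lattice
# pieces. Bouts with integer-second endpoints align exactly with the
# integer-second bin boundaries, so the discretization is exact.
oracle_allocate <- function(bouts, fec, bins) {
  g0 <- as.numeric(bins$bin_start[1])
  w <- as.numeric(bins$bin_end[1]) - g0
  out <- numeric(nrow(bins))
  for (tag in fec$tag_code) {
    b <- bouts[bouts$tag_code == tag, , drop = FALSE]
    if (nrow(b) == 0) next
    s <- round(as.numeric(b$start)); e <- round(as.numeric(b$end))
    total <- sum(e - s)
    eggs_i <- fec$eggs[fec$tag_code == tag]
    if (total == 0) next
    for (r in seq_along(s)) {
      if (e[r] == s[r]) next
      pieces <- seq(s[r], e[r] - 1)  # unit interval [t, t+1) per element
      idx <- pmin(pmax((pieces - g0) %/% w + 1, 1), nrow(bins))
      cnt <- tabulate(idx, nbins = nrow(bins))
      out <- out + eggs_i * cnt / total
    }
  }
  out
}

# Brute-force Kendall: explicit concordant/discordant/tie counting
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- (x[j] - x[i]) * (y[j] - y[i])
    if (p > 0) conc <- conc + 1 else if (p < 0) disc <- disc + 1
  }
  ties_x <- sum(table(x) * (table(x) - 1) / 2)
  ties_y <- sum(table(y) * (table(y) - 1) / 2)
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - ties_x) * (n0 - ties_y))
}

# Small well-formed detection fixture builders
make_events <- function(times, tag = "TAG000000001", antenna = 1L) {
  data.frame(timestamp = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
             antenna_id = as.integer(antenna), tag_code = tag,
             stringsAsFactors = FALSE)
}

hour_bins <- function(start, n) {
  s <- as.POSIXct(start, tz = "UTC")
  make_bins(s, s + n * 3600, 60)
}
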