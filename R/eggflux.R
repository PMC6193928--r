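#' Distribute each female's eggs evenly over her presence time
#'
#' The number of eggs a female produces is spread at a single uniform rate
#' over the union of her presence bouts within the season (rate = fecundity
#' / total bout duration), so a bin receives rate times the overlap of her
#' bouts with the bin. A female whose bouts are all zero-duration (single
#' detections) deposits her eggs in the containing bins, split equally.
#' Total allocated eggs equal total fecundity to within floating-point
#' round-off.
#'
#' @param bouts female bout table (`tag_code`, `start`, `end`), already
#'   eligibility-filtered and season-clipped.
#' @param fecundity_tbl data.frame `tag_code`, `eggs` (one row per female).
#' @param bins grid from [make_bins()].
#' @return a `data.frame` `bin_start`, `eggs` covering every bin of the
#'   grid (zeros included); attribute `per_female` holds the per-female
#'   per-bin allocation, attribute `skipped` the tag codes with fecundity
#'   but no bouts.
#' @export
allocate_eggs <- function(bouts, fecundity_tbl, bins) {
  .check_grid(bins)
  fec <- fecundity_tbl[, c("tag_code", "eggs")]
  if (any(fec$eggs < 0)) stop("fecundity must be non-negative")
  have_bout <- fec$tag_code %in% bouts$tag_code
  skipped <- fec$tag_code[!have_bout]
  if (length(skipped))
    warning(length(skipped), " female(s) with fecundity but no bouts skipped")
  b <- bouts[bouts$tag_code %in% fec$tag_code, , drop = FALSE]
  ov <- .bout_bin_overlap(b, bins)
  dur <- ov[, .(total_s = sum(overlap_s)), by = tag_code]
  ov <- dur[ov, on = "tag_code"]
  fdt <- data.table::as.data.table(fec)
  ov <- fdt[ov, on = "tag_code"]
  # positive-duration females: uniform rate over total presence time;
  # all-zero-duration females: equal split across containing bins
  ov[, n_zero := sum(zero_dur), by = tag_code]
  ov[, alloc := ifelse(total_s > 0,
                       eggs * overlap_s / total_s,
                       eggs * zero_dur / pmax(n_zero, 1L))]
  per_female <- ov[alloc > 0 | overlap_s > 0,
                   .(eggs = sum(alloc)), by = .(tag_code, bin_start)]
  series <- per_female[, .(eggs = sum(eggs)), by = bin_start]
  out <- data.frame(bin_start = bins$bin_start)
  out$eggs <- series$eggs[match(out$bin_start, series$bin_start)]
  out$eggs[is.na(out$eggs)] <- 0
  attr(out, "per_female") <- as.data.frame(per_female[order(tag_code, bin_start)])
  attr(out, "skipped") <- skipped
  out
}

#' Day/night share of a binned quantity, summarized over groups
#'
#' For each group (season day for the egg series, individual for predator
#' presence), the night percentage is
#' \eqn{100 \sum_b w^{night}_b v_b / \sum_b v_b} using the fractional night
#' weight of each bin (bins straddling sunrise or sunset contribute
#' proportionally, avoiding boundary bias). Groups with zero total are
#' excluded from the mean/SD and counted.
#'
#' @param bin_start,value the binned series (one row per bin, or per
#'   individual-bin when `group` is an individual id).
#' @param night_frac fractional night weight per bin (from [label_bins()],
#'   matched to `bin_start` by the caller).
#' @param group grouping vector, same length (e.g. UTC date, or tag code).
#' @return a list: `mean_pct`, `sd_pct` (over groups), `n_groups`,
#'   `n_zero_groups`, and `per_group` data.frame (`group`, `pct`).
#' @export
night_share <- function(bin_start, value, night_frac, group) {
  stopifnot(length(value) == length(night_frac),
            length(value) == length(group))
  if (any(value < 0)) stop("values must be non-negative")
  dt <- data.table::data.table(v = value, w = night_frac, g = group)
  per <- dt[, .(tot = sum(v), night = sum(v * w)), by = g]
  zero <- per$tot <= 0
  pg <- per[!zero]
  if (nrow(pg) == 0L) {
    return(list(mean_pct = NA_real_, sd_pct = NA_real_, n_groups = 0L,
                n_zero_groups = sum(zero),
                per_group = data.frame(group = character(0), pct = numeric(0))))
  }
  pct <- 100 * pg$night / pg$tot
  list(mean_pct = mean(pct),
       sd_pct = if (length(pct) > 1) sd(pct) else 0,
       n_groups = length(pct),
       n_zero_groups = sum(zero),
       per_group = data.frame(group = pg$g, pct = pct))
}
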