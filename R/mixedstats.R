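#' Build the hourly design table for the egg or the predator model
#'
#' Joins the binned egg series, the per-individual predator presence
#' matrix, the temperature logger series and the diel labels onto one
#' hourly grid. Temperature is matched to the nearest logger sample; bins
#' with no sample within 90 minutes are dropped (counted in the
#' `n_dropped_temp` attribute). The egg model has one row per bin with the
#' predator presence aggregated to an expected count; the predator model
#' expands to one row per individual x bin with a fractional presence
#' response.
#'
#' @param egg_series output of [allocate_eggs()].
#' @param bleak_presence output of [presence_matrix()] for the predator
#'   individuals.
#' @param bleak_ids character vector of all eligible predator tag codes
#'   (individuals never detected still contribute all-zero rows).
#' @param temperature data.frame from [read_temperature()].
#' @param bins_labeled labelled grid from [label_bins()].
#' @param model `"eggs"` or `"bleak"`.
#' @param max_temp_gap_min maximum bin-to-sample distance for the
#'   temperature join (default 90).
#' @return a `data.frame` with columns `bin_start`, `eggs`, `bleak`,
#'   `period` (night = 1, day = 0), `date` (day of year), `temp_c`, `year`
#'   (factor) and, for the predator model, `bleak_id` (factor) and
#'   `presence`.
#' @export
build_design <- function(egg_series, bleak_presence, bleak_ids, temperature,
                         bins_labeled, model = c("eggs", "bleak"),
                         max_temp_gap_min = 90) {
  model <- match.arg(model)
  bl <- data.table::as.data.table(bins_labeled)
  eg <- data.table::as.data.table(egg_series)
  tab <- eg[bl, on = "bin_start"]
  if (nrow(tab) == 0L) stop("empty intersection of bin grids")
  tab[is.na(eggs), eggs := 0]
  bp <- data.table::as.data.table(bleak_presence)
  agg <- bp[, .(bleak = sum(presence)), by = bin_start]
  tab <- agg[tab, on = "bin_start"]
  tab[is.na(bleak), bleak := 0]
  # nearest-sample temperature join
  tv <- data.table::as.data.table(temperature)
  mid <- as.numeric(tab$bin_start) +
    (as.numeric(bl$bin_end[1]) - as.numeric(bl$bin_start[1])) / 2
  ti <- as.numeric(tv$timestamp)
  j <- findInterval(mid, ti)
  lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(ti))
  pick <- ifelse(abs(mid - ti[lo]) <= abs(ti[hi] - mid), lo, hi)
  gap_min <- abs(mid - ti[pick]) / 60
  tab[, temp_c := tv$temp_c[pick]]
  ok <- gap_min <= max_temp_gap_min
  n_dropped <- sum(!ok)
  tab <- tab[ok]
  lt <- as.POSIXlt(tab$bin_start, tz = "UTC")
  tab[, `:=`(date = lt$yday + 1L,
             year = factor(lt$year + 1900L),
             period = as.numeric(period == "night"))]
  if (model == "eggs") {
    out <- as.data.frame(tab[, .(bin_start, eggs, bleak, period, date,
                                 temp_c, year)])
  } else {
    grid <- data.table::CJ(bleak_id = as.character(bleak_ids),
                           bin_start = tab$bin_start)
    long <- bp[grid, on = c(tag_code = "bleak_id", "bin_start")]
    data.table::setnames(long, "tag_code", "bleak_id")
    long[is.na(presence), presence := 0]
    out <- as.data.frame(
      long[tab, on = "bin_start",
           .(bin_start, bleak_id, presence, eggs, period, date, temp_c, year),
           allow.cartesian = TRUE])
    out$bleak_id <- factor(out$bleak_id)
  }
  attr(out, "n_dropped_temp") <- n_dropped
  out
}

#' Centre and scale model columns
#'
#' Z-scores the named columns (the binary day/night covariate, coded
#' night = 1, is z-scored like the rest) so coefficients are comparable
#' across covariates with dissimilar ranges. Scaling metadata is kept in
#' attributes so effects can be expressed back on original scales.
#'
#' @param tab design table.
#' @param cols columns to scale.
#' @return the table with scaled columns; attributes `scale_center` and
#'   `scale_scale` (named numeric vectors).
#' @export
centre_scale <- function(tab, cols) {
  ctr <- sc <- setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    x <- tab[[cl]]
    if (is.null(x)) stop("no such column: ", cl)
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("constant column cannot be scaled: ", cl)
    ctr[cl] <- mean(x); sc[cl] <- s
    tab[[cl]] <- (x - ctr[cl]) / s
  }
  attr(tab, "scale_center") <- ctr
  attr(tab, "scale_scale") <- sc
  tab
}

#' Undo [centre_scale()]
#' @param tab a scaled table carrying `scale_center`/`scale_scale`.
#' @return the table on original scales.
#' @export
uncentre_scale <- function(tab) {
  ctr <- attr(tab, "scale_center"); sc <- attr(tab, "scale_scale")
  for (cl in names(ctr)) tab[[cl]] <- tab[[cl]] * sc[cl] + ctr[cl]
  attr(tab, "scale_center") <- attr(tab, "scale_scale") <- NULL
  tab
}

#' Nakagawa-Schielzeth R-squared from variance components
#'
#' Marginal R2 is the fixed-effect share
#' \eqn{\sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)}; conditional R2
#' adds the random-effect variance to the numerator.
#'
#' @param var_f variance of the fixed-effect linear predictor.
#' @param var_r summed random-effect variance (for random slopes, the mean
#'   diagonal of the marginal random-effect covariance).
#' @param var_e residual variance.
#' @return list with `r2_marginal`, `r2_conditional`.
#' @export
r2_components <- function(var_f, var_r, var_e) {
  tot <- var_f + var_r + var_e
  list(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

# Variance components of a fitted model: var_f = var(X beta);
# var_r = mean(diag(Z G Z')) (Johnson's random-slope extension);
# var_e = residual variance.
.varcomp <- function(fit) {
  if (inherits(fit, "merMod")) {
    var_f <- var(as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
    zl <- lme4::getME(fit, "Z") %*% lme4::getME(fit, "Lambda")
    var_e <- lme4::getME(fit, "sigma")^2
    var_r <- var_e * mean(Matrix::rowSums(zl^2))
  } else {
    var_f <- var(fitted(fit))
    var_e <- summary(fit)$sigma^2
    var_r <- 0
  }
  list(var_f = var_f, var_r = var_r, var_e = var_e)
}

#' Fit a linear mixed model with Satterthwaite degrees of freedom
#'
#' REML fit of a Gaussian mixed model with per-term Satterthwaite
#' denominator degrees of freedom, Nakagawa-Schielzeth marginal/conditional
#' R2, and AIC. When every grouping factor in the random part has fewer
#' than two levels the model degenerates gracefully to OLS (zero random
#' variance, residual degrees of freedom).
#'
#' @param tab design table (typically [centre_scale()]d).
#' @param fixed character vector of fixed-effect terms (e.g.
#'   `c("period", "date")`).
#' @param random character vector of lme4 random terms (e.g. `"(1 | year)"`),
#'   or `NULL`/empty for a fixed-effects model.
#' @param response response column name.
#' @param reml fit by REML (default TRUE; stepwise uses ML internally).
#' @return an object of class `dw_lmm`: `coefficients` (term, estimate, se,
#'   df, t, p), `var_f`/`var_r`/`var_e`, `r2_marginal`, `r2_conditional`,
#'   `aic` (of the fit as fitted), `singular` flag, `fit`, plus the formula
#'   pieces.
#' @export
fit_lmm <- function(tab, fixed, random, response, reml = TRUE) {
  usable <- !is.null(random) && length(random) > 0
  if (usable) {
    grp_vars <- unique(unlist(lapply(random, function(r)
      all.vars(as.formula(paste("~", gsub("[()]", "", r)))))))
    grp_vars <- grp_vars[grp_vars %in% names(tab)]
    grp_fac <- grp_vars[vapply(grp_vars, function(v)
      is.factor(tab[[v]]) || is.character(tab[[v]]), logical(1))]
    if (length(grp_fac) &&
        all(vapply(grp_fac, function(v)
          length(unique(tab[[v]])) < 2, logical(1))))
      usable <- FALSE
  }
  rhs_fixed <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (usable) {
    form <- as.formula(paste(response, "~", rhs_fixed, "+",
                             paste(random, collapse = " + ")))
    fit <- lmerTest::lmer(form, data = tab, REML = reml)
    singular <- lme4::isSingular(fit)
    ct <- as.data.frame(summary(fit, ddf = "Satterthwaite")$coefficients)
    names(ct) <- c("estimate", "se", "df", "t", "p")
  } else {
    form <- as.formula(paste(response, "~", rhs_fixed))
    fit <- lm(form, data = tab)
    singular <- FALSE
    ct <- as.data.frame(summary(fit)$coefficients)
    names(ct) <- c("estimate", "se", "t", "p")
    ct$df <- fit$df.residual
    ct <- ct[, c("estimate", "se", "df", "t", "p")]
  }
  vc <- .varcomp(fit)
  r2 <- r2_components(vc$var_f, vc$var_r, vc$var_e)
  structure(list(coefficients = cbind(term = rownames(ct), ct),
                 var_f = vc$var_f, var_r = vc$var_r, var_e = vc$var_e,
                 r2_marginal = r2$r2_marginal,
                 r2_conditional = r2$r2_conditional,
                 aic = AIC(fit), singular = singular, fit = fit,
                 fixed = fixed, random = random, response = response),
            class = "dw_lmm")
}

#' @export
print.dw_lmm <- function(x, ...) {
  cat("Linear mixed model:", x$response, "~",
      paste(c(x$fixed, x$random), collapse = " + "), "\n")
  ct <- x$coefficients
  ct[-1] <- lapply(ct[-1], function(v) signif(v, 4))
  print(ct, row.names = FALSE)
  cat(sprintf("Marginal r2 = %.3f; conditional r2 = %.3f; AIC = %.1f%s\n",
              x$r2_marginal, x$r2_conditional, x$aic,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  invisible(x)
}

#' Backward stepwise selection of fixed effects by AIC
#'
#' Starting from the full fixed-effect set, repeatedly refits by maximum
#' likelihood with each remaining term dropped in turn (the random structure
#' held fixed) and removes the drop that lowers AIC most, stopping when no
#' single removal improves AIC. Every candidate AIC is logged in the trace.
#'
#' @inheritParams fit_lmm
#' @return list: `model` (final REML [fit_lmm()] refit), `kept`, `dropped`,
#'   `trace` (data.frame step/candidate/aic/action).
#' @export
stepwise_aic <- function(tab, fixed, random, response) {
  current <- fixed
  trace <- list()
  step_i <- 0L
  aic_of <- function(terms)
    fit_lmm(tab, terms, random, response, reml = FALSE)$aic
  cur_aic <- aic_of(current)
  trace[[length(trace) + 1L]] <-
    data.frame(step = step_i, candidate = "<full>", aic = cur_aic,
               action = "start")
  repeat {
    if (length(current) == 0L) break
    step_i <- step_i + 1L
    cand <- vapply(current, function(tm) aic_of(setdiff(current, tm)),
                   numeric(1))
    trace[[length(trace) + 1L]] <-
      data.frame(step = step_i, candidate = paste("-", current),
                 aic = unname(cand), action = "candidate")
    best <- which.min(cand)
    if (cand[best] < cur_aic) {
      dropped_term <- current[best]
      current <- setdiff(current, dropped_term)
      cur_aic <- cand[best]
      trace[[length(trace) + 1L]] <-
        data.frame(step = step_i, candidate = paste("-", dropped_term),
                   aic = cur_aic, action = "drop")
    } else break
  }
  list(model = fit_lmm(tab, current, random, response, reml = TRUE),
       kept = current, dropped = setdiff(fixed, current),
       trace = do.call(rbind, trace))
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Computes tau-b from concordant/discordant pair counts with the standard
#' tie corrections. For small samples (`n <= exact_n`) the p-value comes
#' from a seeded Monte Carlo permutation distribution of tau; above that,
#' from the normal approximation with tie-corrected variance of S.
#'
#' @param x,y paired numeric vectors.
#' @param exact_n largest n for the permutation p-value (default 30).
#' @param n_perm Monte Carlo permutations (default 10000).
#' @param perm_seed seed for the permutation draw (local RNG state; the
#'   global seed is untouched).
#' @return list with `tau`, `p`, `S` (concordant minus discordant), `n`,
#'   `method`.
#' @export
kendall_tau <- function(x, y, exact_n = 30, n_perm = 10000, perm_seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least two complete pairs")
  S <- .kendall_S(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) stop("tau undefined: a variable is constant")
  tau <- S / denom
  if (n <= exact_n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(perm_seed)
    perm <- vapply(seq_len(n_perm), function(i) .kendall_S(x, sample(y)),
                   numeric(1))
    p <- (1 + sum(abs(perm) >= abs(S) - 1e-12)) / (n_perm + 1)
    method <- "permutation"
  } else {
    t_i <- as.numeric(tx); u_i <- as.numeric(ty)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(t_i * (t_i - 1) * (2 * t_i + 5))
    vu <- sum(u_i * (u_i - 1) * (2 * u_i + 5))
    v1 <- sum(t_i * (t_i - 1)) * sum(u_i * (u_i - 1)) / (2 * n * (n - 1))
    v2 <- sum(t_i * (t_i - 1) * (t_i - 2)) * sum(u_i * (u_i - 1) * (u_i - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_S <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_S)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(tau = tau, p = p, S = S, n = n, method = method)
}

# concordant minus discordant pair count, O(n^2) vectorized per row
.kendall_S <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    s <- s + sum(sign(x[j] - x[i]) * sign(y[j] - y[i]))
  }
  s
}
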