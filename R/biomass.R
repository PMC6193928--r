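#' Fit a von Bertalanffy growth curve to age-length pairs
#'
#' Least-squares fit of \eqn{L(t) = L_\infty (1 - e^{-K (t - t_0)})} to
#' scale-read ages and total lengths at first capture. The initializer is
#' fixed (\eqn{L_\infty^{(0)} = 1.05 \max L}, \eqn{K^{(0)} = 0.2},
#' \eqn{t_0^{(0)} = 0}) so the fit is reproducible; Levenberg-Marquardt
#' handles the poorly conditioned surface typical of truncated age ranges.
#'
#' @param age_years numeric ages (years); at least 4 distinct values.
#' @param length_cm total lengths (cm), positive.
#' @return an object of class `dw_growth`: list with `l_inf`, `k`, `t0`,
#'   `resid_sd`, `n`, and the `fit` object.
#' @export
fit_growth <- function(age_years, length_cm) {
  ok <- is.finite(age_years) & is.finite(length_cm)
  age_years <- age_years[ok]; length_cm <- length_cm[ok]
  if (length(unique(age_years)) < 4)
    stop("insufficient data: need at least 4 distinct ages for a growth fit")
  if (any(length_cm <= 0)) stop("lengths must be positive")
  d <- data.frame(t = age_years, L = length_cm)
  start <- list(linf = 1.05 * max(d$L), k = 0.2, t0 = 0)
  fit <- minpack.lm::nlsLM(L ~ linf * (1 - exp(-k * (t - t0))),
                           data = d, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  if (cf[["linf"]] <= 0 || cf[["k"]] <= 0)
    stop("growth fit did not converge to a biologically valid curve: ",
         paste(names(cf), signif(cf, 4), sep = "=", collapse = ", "))
  structure(list(l_inf = cf[["linf"]], k = cf[["k"]], t0 = cf[["t0"]],
                 resid_sd = sd(residuals(fit)), n = nrow(d), fit = fit),
            class = "dw_growth")
}

#' @export
print.dw_growth <- function(x, ...) {
  cat(sprintf("von Bertalanffy growth fit (n = %d)\n", x$n))
  cat(sprintf("  L_inf = %.2f cm   K = %.4f /yr   t0 = %.3f yr   resid SD = %.2f cm\n",
              x$l_inf, x$k, x$t0, x$resid_sd))
  invisible(x)
}

#' Project an individual's length to a target date
#'
#' The population curve is individualized by rescaling \eqn{L_\infty} so the
#' curve passes exactly through the observed length at the scale-read
#' tagging age:
#' \eqn{L_{\infty,i} = TL_{tag} / (1 - e^{-K (a_{tag} - t_0)})}, then
#' evaluated at \eqn{a_{tag}} plus the elapsed time to the target date.
#' With zero elapsed time the tagging length is returned exactly. If the
#' individual was recaptured in the target year, the recapture length
#' replaces the model prediction outright (the true increment is known).
#'
#' @param record one tag-registry row (needs `total_length_cm`, `age_years`,
#'   `tagging_date`; optionally `recapture_length_cm`, `recapture_date`).
#' @param params a `dw_growth` fit (or list with `l_inf`, `k`, `t0`).
#' @param target_date `Date` to project to.
#' @return projected total length, cm.
#' @export
project_length <- function(record, params, target_date) {
  target_date <- as.Date(target_date)
  if (!is.na(record$recapture_length_cm) && !is.na(record$recapture_date) &&
      format(as.Date(record$recapture_date), "%Y") == format(target_date, "%Y"))
    return(as.numeric(record$recapture_length_cm))
  age_tag <- record$age_years
  if (is.na(age_tag)) stop("record has no age; cannot project length")
  if (age_tag <= params$t0)
    stop("invalid age: tagging age ", age_tag, " not above t0 = ", params$t0)
  elapsed <- as.numeric(target_date - as.Date(record$tagging_date)) / 365.25
  l_inf_i <- record$total_length_cm / (1 - exp(-params$k * (age_tag - params$t0)))
  l_inf_i * (1 - exp(-params$k * (age_tag + elapsed - params$t0)))
}

#' Length-weight conversion (allometric power law)
#'
#' \eqn{W = a \, TL^b} with `TL` in centimetres and `W` in grams. The
#' default coefficients (a = 0.00744, b = 3.046) are the female-asp values
#' estimated from non-ovulating females; with these coefficients the
#' centimetre/gram unit pairing is the only consistent one (millimetre input
#' would give tonne-scale fish).
#'
#' @param tl_cm total length, cm (> 0).
#' @param a,b coefficient and allometric exponent; `b` must lie in (2, 4).
#' @return weight in grams.
#' @export
length_to_weight <- function(tl_cm, a = 0.00744, b = 3.046) {
  if (a <= 0 || b <= 2 || b >= 4) stop("length-weight parameters out of range")
  if (any(tl_cm <= 0)) stop("total length must be positive")
  a * tl_cm^b
}

#' Fecundity from body weight via the gonadosomatic index
#'
#' Egg number is gonad mass over single-egg mass:
#' \eqn{E = GSI \cdot W / m_{egg}}. The defaults (GSI = 0.15, egg mass
#' 3.5 mg) are literature-scale cyprinid placeholders and should be treated
#' as configuration: every downstream proportion (diel shares, z-scored
#' model coefficients) is invariant to rescaling either one.
#'
#' @param weight_g body weight, g (> 0).
#' @param gsi gonad mass as a fraction of body mass, in (0, 1).
#' @param egg_mass_g mean mass of one egg, g (> 0).
#' @return expected egg count (non-negative real).
#' @export
fecundity <- function(weight_g, gsi = 0.15, egg_mass_g = 0.0035) {
  if (gsi <= 0 || gsi >= 1) stop("gsi must be in (0, 1)")
  if (egg_mass_g <= 0) stop("egg_mass_g must be positive")
  if (any(weight_g <= 0)) stop("weight must be positive")
  gsi * weight_g / egg_mass_g
}

#' Per-female fecundity table for a spawning season
#'
#' Convenience chain over the female asp rows of a registry: fit (or take) a
#' population growth curve, project each female's length to the season
#' reference date, convert to weight and fecundity.
#'
#' @param registry tag registry ([read_registry()]).
#' @param target_date reference date of the spawning season (used for growth
#'   projection and recapture matching).
#' @param growth optional `dw_growth`; fitted from the registry's female asp
#'   age-length pairs when `NULL`.
#' @param lw_a,lw_b length-weight coefficients ([length_to_weight()]).
#' @param gsi,egg_mass_g fecundity parameters ([fecundity()]).
#' @return a `data.frame`: `tag_code`, `tl_cm` (projected), `weight_g`,
#'   `eggs`; attribute `growth` holds the growth fit used.
#' @export
female_fecundity <- function(registry, target_date, growth = NULL,
                             lw_a = 0.00744, lw_b = 3.046,
                             gsi = 0.15, egg_mass_g = 0.0035) {
  fem <- registry[registry$species == "asp" & registry$sex == "female" &
                    !is.na(registry$age_years), , drop = FALSE]
  if (nrow(fem) == 0L) stop("no aged female asp in registry")
  if (is.null(growth))
    growth <- fit_growth(fem$age_years, fem$total_length_cm)
  tl <- vapply(seq_len(nrow(fem)), function(i)
    project_length(fem[i, ], growth, target_date), numeric(1))
  w <- length_to_weight(tl, lw_a, lw_b)
  out <- data.frame(tag_code = fem$tag_code, tl_cm = tl, weight_g = w,
                    eggs = fecundity(w, gsi, egg_mass_g))
  attr(out, "growth") <- growth
  out
}
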