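# Run code under a temporary RNG state so seeded draws do not disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a FAME profile by compositional (Dirichlet) noise
#'
#' Draws a composition from a Dirichlet distribution whose mean is the
#' template profile and whose dispersion is set by the `concentration`
#' parameter (alpha_i = concentration x template fraction), emulating
#' the replicate-to-replicate variation of GC-MS FAME quantification.
#' Because abundances are compositional (they must sum to 100%), noise
#' is applied on the simplex rather than per species, so renormalization
#' never distorts the template means.
#'
#' @param template A `fame_profile` (or object coercible via
#'   [fame_profile()]) giving the mean composition; defaults to the
#'   Tetraselmis sp. CTP4 reference profile ([ctp4_profile()]).
#' @param concentration Positive scalar; larger means less noise
#'   (variance of each fraction is p(1-p)/(concentration + 1)). Default
#'   500, which reproduces the few-percent relative scatter typical of
#'   triplicate GC-MS determinations. `Inf` returns the template
#'   exactly.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A normalized `fame_profile`.
#' @examples
#' gen_fame_profile(seed = 1)
#' @export
gen_fame_profile <- function(template = ctp4_profile(), concentration = 500,
                             seed = NULL) {
  if (!inherits(template, "fame_profile")) {
    template <- fame_profile(template)
  }
  template <- normalize_profile(template)
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration <= 0) {
    stop("`concentration` must be a positive scalar", call. = FALSE)
  }
  if (!is.finite(concentration)) {
    return(template)
  }
  frac <- template$percent / 100
  draw <- with_seed(seed, {
    g <- stats::rgamma(length(frac), shape = concentration * frac, rate = 1)
    if (sum(g) <= 0) g <- frac  # all-zero gamma draw; degenerate template
    g / sum(g)
  })
  out <- template
  out$percent <- draw * 100
  attr(out, "normalized") <- TRUE
  out
}

#' Parameters of the two-stage growth and lipid-induction model
#'
#' Describes the canonical two-stage microalgal lipid-production
#' experiment: a nutrient-replete growth stage (logistic biomass
#' accumulation at intrinsic rate `r` towards carrying capacity `K`)
#' until nutrients deplete at `t_switch`, followed by a second stage in
#' which cultures either receive fresh nutrients (`regime = "replete"`)
#' or are starved (`regime = "starved"`). The lipid fraction of dry
#' weight starts at `f_base`, dips to `f_dip` during the exponential
#' phase (fast-dividing cells invest in membranes, not storage lipids),
#' recovers to `f_base` by `t_switch`, and -- under starvation only --
#' ramps linearly from `f_base` to `f_max` between
#' `t_switch + induction_lag` and `t_max` (lipid induction needs ~48 h
#' of starvation before triacylglycerols accumulate).
#'
#' Defaults emulate a Tetraselmis-like strain: `r` 0.30/day, `K` 3 g
#' DW/L, 10-day first stage, baseline lipids 10% of DW dipping to 6.5%,
#' starvation plateau 33% of DW, two-day induction lag, 5%
#' multiplicative lognormal measurement noise, and 1e6 cells/mL per g
#' DW/L linking counts to dry weight.
#'
#' @param r Intrinsic growth rate, 1/day (> 0).
#' @param K Carrying capacity, g DW/L (> 0).
#' @param X0 Inoculum biomass, g DW/L (> 0).
#' @param t_switch Day the nutrients deplete / second stage starts.
#' @param f_base,f_dip,f_max Lipid fractions of DW: replete baseline,
#'   exponential-phase dip, starvation plateau; need
#'   `0 <= f_dip <= f_base <= f_max < 1`.
#' @param induction_lag Days of starvation before lipids start to rise
#'   (>= 0).
#' @param noise_sigma Standard deviation of multiplicative lognormal
#'   measurement noise (0 for noise-free series).
#' @param regime `"replete"` (nutrients re-added at `t_switch`) or
#'   `"starved"`.
#' @param cells_per_gram Cell count equivalent of 1 g DW/L (cells/mL).
#' @return A validated `two_stage_params` list.
#' @export
two_stage_params <- function(r = 0.30, K = 3.0, X0 = 0.1, t_switch = 10,
                             f_base = 0.10, f_dip = 0.065, f_max = 0.33,
                             induction_lag = 2, noise_sigma = 0.05,
                             regime = c("replete", "starved"),
                             cells_per_gram = 1e6) {
  regime <- match.arg(regime)
  if (r <= 0 || K <= 0 || X0 <= 0) {
    stop("`r`, `K` and `X0` must be positive", call. = FALSE)
  }
  if (!(0 <= f_dip && f_dip <= f_base && f_base <= f_max && f_max < 1)) {
    stop("need 0 <= f_dip <= f_base <= f_max < 1", call. = FALSE)
  }
  if (induction_lag < 0 || noise_sigma < 0 || t_switch <= 0 ||
      cells_per_gram <= 0) {
    stop("`t_switch`, `cells_per_gram` must be positive and ",
         "`induction_lag`, `noise_sigma` non-negative", call. = FALSE)
  }
  structure(list(r = r, K = K, X0 = X0, t_switch = t_switch,
                 f_base = f_base, f_dip = f_dip, f_max = f_max,
                 induction_lag = induction_lag, noise_sigma = noise_sigma,
                 regime = regime, cells_per_gram = cells_per_gram),
            class = "two_stage_params")
}

#' Logistic biomass curve (closed form)
#'
#' \deqn{X(t) = K / (1 + ((K - X_0)/X_0) e^{-rt})}
#'
#' @param t Time in days.
#' @param r Intrinsic growth rate, 1/day.
#' @param K Carrying capacity.
#' @param X0 Initial biomass.
#' @return Biomass at `t`, same units as `K`.
#' @export
logistic_biomass <- function(t, r, K, X0) {
  K / (1 + ((K - X0) / X0) * exp(-r * t))
}

#' Deterministic lipid-fraction trajectory of the two-stage model
#'
#' Piecewise-linear in time: `f_base` until 40% of the first stage, a
#' symmetric dip to `f_dip` centred at 60% of the first stage,
#' recovery to `f_base` at `t_switch`, then (starved regime only) a
#' linear ramp from `f_base` at `t_switch + induction_lag` to `f_max`
#' at `t_max`.
#'
#' @param t Time in days.
#' @param params A [two_stage_params()] object.
#' @param t_max End of the experiment (day the starvation ramp tops out).
#' @return Lipid fraction of DW at `t`.
#' @export
lipid_fraction_curve <- function(t, params, t_max) {
  stopifnot(inherits(params, "two_stage_params"))
  ts <- params$t_switch
  d1 <- 0.4 * ts; dmid <- 0.6 * ts
  f <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    f[i] <- if (ti <= d1) {
      params$f_base
    } else if (ti <= dmid) {
      params$f_base + (params$f_dip - params$f_base) * (ti - d1) / (dmid - d1)
    } else if (ti <= ts) {
      params$f_dip + (params$f_base - params$f_dip) * (ti - dmid) / (ts - dmid)
    } else {
      params$f_base
    }
    if (params$regime == "starved") {
      ramp_start <- ts + params$induction_lag
      if (ti > ramp_start && t_max > ramp_start) {
        prog <- min(1, (ti - ramp_start) / (t_max - ramp_start))
        f[i] <- params$f_base + (params$f_max - params$f_base) * prog
      }
    }
  }
  f
}

#' Simulate a two-stage culture growth series
#'
#' Generates a [growth_series()] from the two-stage model: logistic
#' biomass with multiplicative lognormal noise, cell concentration
#' proportional to biomass, and the piecewise lipid-fraction trajectory
#' of [lipid_fraction_curve()] (noisy lipid fractions are clamped to
#' `[0, 1]`).
#'
#' @param params A [two_stage_params()] object.
#' @param n_points Number of equally spaced observations (>= 3).
#' @param t_max Last sampling day; must exceed `t_switch` for the
#'   starved regime.
#' @param seed Optional integer seed.
#' @return A [growth_series()] with all columns populated.
#' @examples
#' gen_growth_series(two_stage_params(regime = "starved", noise_sigma = 0),
#'                   n_points = 18, t_max = 17)
#' @export
gen_growth_series <- function(params = two_stage_params(), n_points = 18,
                              t_max = 17, seed = NULL) {
  stopifnot(inherits(params, "two_stage_params"))
  if (n_points < 3) {
    stop("`n_points` must be at least 3", call. = FALSE)
  }
  if (params$regime == "starved" && t_max <= params$t_switch) {
    stop("`t_max` must exceed `t_switch` for the starved regime", call. = FALSE)
  }
  days <- seq(0, t_max, length.out = n_points)
  x_true <- logistic_biomass(days, params$r, params$K, params$X0)
  f_true <- lipid_fraction_curve(days, params, t_max)
  with_seed(seed, {
    noise <- function(n) {
      if (params$noise_sigma == 0) rep(1, n)
      else exp(stats::rnorm(n, 0, params$noise_sigma))
    }
    x_obs <- x_true * noise(n_points)
    f_obs <- pmin(1, pmax(0, f_true * noise(n_points)))
    cc_obs <- x_true * params$cells_per_gram * noise(n_points)
    growth_series(days, cell_conc = cc_obs, biomass = x_obs,
                  lipid_fraction = f_obs)
  })
}
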