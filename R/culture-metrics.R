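#' Construct a culture growth series
#'
#' Time-ordered culture observations: day, cell concentration
#' (cells/mL), biomass dry-weight concentration (g DW/L) and lipid
#' content as a fraction of DW. Any of the three measurement columns may
#' be missing (NA) at individual time points.
#'
#' @param day Numeric vector of sampling days, strictly increasing.
#' @param cell_conc Optional cells/mL, >= 0.
#' @param biomass Optional g DW/L, >= 0.
#' @param lipid_fraction Optional fraction of DW in `[0, 1]`.
#' @return A `growth_series` tibble.
#' @examples
#' growth_series(day = 0:3, cell_conc = 5e5 * 2^(0:3))
#' @export
growth_series <- function(day, cell_conc = NULL, biomass = NULL,
                          lipid_fraction = NULL) {
  day <- as.numeric(day)
  n <- length(day)
  if (n < 1 || any(!is.finite(day))) {
    stop("`day` must be finite numeric", call. = FALSE)
  }
  if (n > 1 && any(diff(day) <= 0)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  fill <- function(x, nm, lo = 0, hi = Inf) {
    if (is.null(x)) return(rep(NA_real_, n))
    x <- as.numeric(x)
    if (length(x) != n) stop("`", nm, "` must have length ", n, call. = FALSE)
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) {
      stop("`", nm, "` out of range [", lo, ", ", hi, "]", call. = FALSE)
    }
    x
  }
  out <- tibble::tibble(
    day = day,
    cell_conc = fill(cell_conc, "cell_conc"),
    biomass = fill(biomass, "biomass"),
    lipid_fraction = fill(lipid_fraction, "lipid_fraction", 0, 1)
  )
  structure(out, class = c("growth_series", class(out)))
}

#' Read a culture growth series from CSV
#'
#' Columns `day,cell_conc,biomass_gL,lipid_fraction` with header;
#' missing cells allowed.
#'
#' @param path Path to the CSV file.
#' @return A [growth_series()].
#' @export
read_growth_series <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE, blank.lines.skip = TRUE)
  if (!"day" %in% names(df)) {
    stop("growth CSV must have a `day` column: ", path, call. = FALSE)
  }
  pick <- function(nm) if (nm %in% names(df)) df[[nm]] else NULL
  growth_series(df$day,
                cell_conc = pick("cell_conc"),
                biomass = pick("biomass_gL"),
                lipid_fraction = pick("lipid_fraction"))
}

#' Write a growth series to CSV
#' @param series A [growth_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_series <- function(series, path) {
  stopifnot(inherits(series, "growth_series"))
  utils::write.csv(
    data.frame(day = series$day, cell_conc = series$cell_conc,
               biomass_gL = series$biomass,
               lipid_fraction = series$lipid_fraction),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

series_row <- function(series, day, caller) {
  i <- which(abs(series$day - day) < 1e-9)
  if (length(i) != 1) {
    stop(caller, "(): day ", day, " not present in the series", call. = FALSE)
  }
  series[i, ]
}

#' Specific growth rate over a window
#'
#' The exponential-phase specific growth rate
#' \deqn{\mu = \ln(N_{end}/N_{start}) / (end - start)}
#' in per-day units, computed from cell concentrations at the two window
#' endpoints. Invariant to rescaling N by any positive constant and to
#' shifting time.
#'
#' @param series A [growth_series()] with `cell_conc` at both endpoints.
#' @param start_day,end_day Window endpoints (days present in the
#'   series, `end_day > start_day`).
#' @return Growth rate in 1/day.
#' @examples
#' s <- growth_series(0:3, cell_conc = 1e5 * 2^(0:3))
#' specific_growth_rate(s, 0, 3) # ln(2)
#' @export
specific_growth_rate <- function(series, start_day, end_day) {
  stopifnot(inherits(series, "growth_series"))
  if (end_day <= start_day) {
    stop("`end_day` must be greater than `start_day`", call. = FALSE)
  }
  a <- series_row(series, start_day, "specific_growth_rate")
  b <- series_row(series, end_day, "specific_growth_rate")
  if (is.na(a$cell_conc) || is.na(b$cell_conc) ||
      a$cell_conc <= 0 || b$cell_conc <= 0) {
    stop("cell concentration missing or non-positive at a window endpoint",
         call. = FALSE)
  }
  log(b$cell_conc / a$cell_conc) / (end_day - start_day)
}

#' Volumetric biomass productivity over a window
#'
#' Linear rate `(X_end - X_start) / (end - start)` in g DW/L/day. A
#' negative rate (declining culture) is returned with a warning.
#'
#' @inheritParams specific_growth_rate
#' @return Productivity in g/L/day.
#' @examples
#' s <- growth_series(c(0, 10), biomass = c(0.2, 3.0))
#' biomass_productivity(s, 0, 10) # 0.28
#' @export
biomass_productivity <- function(series, start_day, end_day) {
  stopifnot(inherits(series, "growth_series"))
  if (end_day <= start_day) {
    stop("`end_day` must be greater than `start_day`", call. = FALSE)
  }
  a <- series_row(series, start_day, "biomass_productivity")
  b <- series_row(series, end_day, "biomass_productivity")
  if (is.na(a$biomass) || is.na(b$biomass)) {
    stop("biomass missing at a window endpoint", call. = FALSE)
  }
  rate <- (b$biomass - a$biomass) / (end_day - start_day)
  if (rate < 0) {
    warning("negative biomass productivity: culture declined over the window",
            call. = FALSE)
  }
  rate
}

#' Volumetric lipid productivity over a window
#'
#' Lipid mass balance over the window:
#' \deqn{P_{lipid} = (X_{end} f_{end} - X_{start} f_{start}) \cdot 1000
#'       / (end - start)}
#' where X is biomass (g DW/L) and f the lipid fraction of DW; result in
#' mg lipid/L/day.
#'
#' @inheritParams specific_growth_rate
#' @return Productivity in mg/L/day.
#' @examples
#' s <- growth_series(c(0, 14), biomass = c(0.5, 4.0),
#'                    lipid_fraction = c(0.10, 0.33))
#' lipid_productivity(s, 0, 14) # 90.71
#' @export
lipid_productivity <- function(series, start_day, end_day) {
  stopifnot(inherits(series, "growth_series"))
  if (end_day <= start_day) {
    stop("`end_day` must be greater than `start_day`", call. = FALSE)
  }
  a <- series_row(series, start_day, "lipid_productivity")
  b <- series_row(series, end_day, "lipid_productivity")
  if (is.na(a$biomass) || is.na(b$biomass) ||
      is.na(a$lipid_fraction) || is.na(b$lipid_fraction)) {
    stop("biomass and lipid_fraction required at both window endpoints",
         call. = FALSE)
  }
  (b$biomass * b$lipid_fraction - a$biomass * a$lipid_fraction) * 1000 /
    (end_day - start_day)
}

#' Suggest an exponential-phase window for growth-rate estimation
#'
#' Scans all windows of at least `min_points` consecutive observations
#' with positive cell concentrations, fits `log(N) ~ day` to each, and
#' returns the window with the steepest slope among those whose
#' coefficient of determination reaches `r2_min` (falling back to the
#' best-R2 window when none qualifies). Useful because the exponential
#' phase is rarely the whole series.
#'
#' @param series A [growth_series()] with cell counts.
#' @param min_points Minimum window length (default 3).
#' @param r2_min Minimum R2 for a window to qualify (default 0.98).
#' @return List with `start_day`, `end_day`, `mu` (log-linear slope,
#'   1/day) and `r_squared`.
#' @export
suggest_exponential_window <- function(series, min_points = 3, r2_min = 0.98) {
  stopifnot(inherits(series, "growth_series"), min_points >= 3)
  ok <- !is.na(series$cell_conc) & series$cell_conc > 0
  s <- series[ok, ]
  if (nrow(s) < min_points) {
    stop("need at least ", min_points, " positive cell counts", call. = FALSE)
  }
  best <- NULL
  for (i in seq_len(nrow(s) - min_points + 1)) {
    for (j in seq(i + min_points - 1, nrow(s))) {
      d <- s$day[i:j]
      y <- log(s$cell_conc[i:j])
      fit <- stats::lm(y ~ d)
      cand <- list(start_day = s$day[i], end_day = s$day[j],
                   mu = unname(stats::coef(fit)[2]),
                   r_squared = summary(fit)$r.squared)
      better <- is.null(best) ||
        (cand$r_squared >= r2_min && best$r_squared < r2_min) ||
        (cand$r_squared >= r2_min && best$r_squared >= r2_min &&
           cand$mu > best$mu) ||
        (cand$r_squared < r2_min && best$r_squared < r2_min &&
           cand$r_squared > best$r_squared)
      if (better) best <- cand
    }
  }
  best
}

#' Medium-removal efficiency from a sedimentation step
#'
#' After gravity settling (e.g. in an Imhoff cone), the culture
#' concentrates into a settled volume fraction v of the initial volume;
#' the supernatant medium that can be decanted is the removal efficiency
#' `1 - v`. A culture settling to 18% of its initial volume allows 82%
#' of the medium to be removed before centrifugation.
#'
#' @param settled_volume_fraction Settled volume as a fraction of the
#'   initial culture volume, in `[0, 1]`.
#' @return Removal efficiency as a fraction in `[0, 1]`.
#' @examples
#' medium_removal_efficiency(0.18) # 0.82
#' @export
medium_removal_efficiency <- function(settled_volume_fraction) {
  v <- settled_volume_fraction
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("`settled_volume_fraction` must lie in [0, 1]", call. = FALSE)
  }
  1 - v
}
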