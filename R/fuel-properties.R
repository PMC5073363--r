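#' Cetane number of a FAME mixture
#'
#' The cetane number of a biodiesel blend is estimated as the
#' abundance-weighted mean of the per-ester cetane numbers of its
#' components:
#' \deqn{CN_{mix} = \frac{\sum_c A_c \, CN_c}{\sum_c A_c}}
#' where \eqn{A_c} is the abundance of ester c (% of total FAME) and
#' \eqn{CN_c} its neat cetane number. The result is bounded by the
#' smallest and largest per-ester CN among the species present. Esters
#' absent from the coefficient table are resolved by the
#' structure-nearest fallback (see [fame_coefficients()]), with a warning.
#'
#' @param profile A normalized [fame_profile()].
#' @param coeffs A [fame_coefficients()] set.
#' @return Cetane number (dimensionless scalar).
#' @examples
#' p <- fame_profile(c("C16:0" = 50, "C18:1" = 50), normalized = TRUE)
#' cetane_number(p)
#' @export
cetane_number <- function(profile, coeffs = fame_coefficients()) {
  assert_normalized(profile, "cetane_number")
  present <- profile[profile$percent > 0, , drop = FALSE]
  if (nrow(present) == 0) {
    stop("profile has no species with positive abundance", call. = FALSE)
  }
  cn_c <- mapply(lookup_coef,
                 carbons = present$carbons,
                 double_bonds = present$double_bonds,
                 MoreArgs = list(table = coeffs$cn, what = "cetane number"))
  sum(present$percent * cn_c) / sum(present$percent)
}

#' Iodine value of a FAME mixture
#'
#' The iodine value (g I2 absorbed per 100 g of fuel, a proxy for total
#' unsaturation) is computed as
#' \deqn{IV = \sum_c A_c \, f_c}
#' where \eqn{A_c} is the abundance (% of total FAME) and \eqn{f_c} the
#' per-ester iodine factor. Saturated species contribute exactly zero.
#' The shipped factors follow the EN 14214 calculated-IV convention,
#' \eqn{f_c = 253.81 \cdot db / MW_c}: iodine adds across each double
#' bond (2 x 126.905 g/mol) of the methyl ester of mass \eqn{MW_c}.
#'
#' @inheritParams cetane_number
#' @return Iodine value in g I/100 g; zero iff the profile is fully
#'   saturated.
#' @examples
#' p <- fame_profile(c("C18:1" = 100), normalized = TRUE)
#' iodine_value(p) # ~85.6 for pure methyl oleate
#' @export
iodine_value <- function(profile, coeffs = fame_coefficients()) {
  assert_normalized(profile, "iodine_value")
  present <- profile[profile$percent > 0, , drop = FALSE]
  factors <- numeric(nrow(present))
  unsat <- present$double_bonds > 0
  if (any(unsat)) {
    factors[unsat] <- mapply(
      lookup_coef,
      carbons = present$carbons[unsat],
      double_bonds = present$double_bonds[unsat],
      MoreArgs = list(table = coeffs$iv, what = "iodine factor"))
  }
  sum(present$percent * factors)
}

#' Long-chain saturated factor (LCSF)
#'
#' A weighted sum of the long-chain saturated ester abundances that
#' predicts cold-flow behaviour:
#' \deqn{LCSF = 0.1\,\%C16{:}0 + 0.5\,\%C18{:}0 + 1\,\%C20{:}0 +
#'       1.5\,\%C22{:}0 + 2\,\%C24{:}0}
#' Unsaturated species contribute nothing; saturated species outside the
#' weight table (chains shorter than C16) contribute nothing, with a
#' warning.
#'
#' @inheritParams cetane_number
#' @return LCSF (dimensionless scalar, >= 0).
#' @examples
#' p <- fame_profile(c("C16:0" = 24.13, "C18:1" = 75.87), normalized = TRUE)
#' lcsf(p) # 0.1 * 24.13 = 2.413
#' @export
lcsf <- function(profile, coeffs = fame_coefficients()) {
  assert_normalized(profile, "lcsf")
  sat <- profile[profile$double_bonds == 0 & profile$percent > 0, , drop = FALSE]
  if (nrow(sat) == 0) {
    return(0)
  }
  key <- as.character(sat$carbons)
  known <- key %in% names(coeffs$lcsf_weights)
  if (any(!known)) {
    warning("saturated species outside the LCSF weight table contribute 0: ",
            paste(sQuote(sat$species[!known]), collapse = ", "), call. = FALSE)
  }
  sum(sat$percent[known] * coeffs$lcsf_weights[key[known]])
}

#' Cold filter plugging point from LCSF
#'
#' Affine prediction of the cold filter plugging point (the lowest
#' temperature at which the fuel still passes a standardized filter) from
#' the long-chain saturated factor, after Ramos et al. (2009):
#' \deqn{CFPP = 3.1417 \cdot LCSF - 16.477}
#'
#' @param lcsf_value LCSF (dimensionless, >= 0).
#' @return CFPP in degrees Celsius; strictly increasing in LCSF.
#' @examples
#' cfpp(2.413) # -8.90 C
#' @export
cfpp <- function(lcsf_value) {
  if (!is.numeric(lcsf_value) || any(!is.finite(lcsf_value))) {
    stop("`lcsf_value` must be finite numeric", call. = FALSE)
  }
  if (any(lcsf_value < 0)) {
    stop("LCSF cannot be negative", call. = FALSE)
  }
  3.1417 * lcsf_value - 16.477
}

#' Compute the full fuel-property set of a FAME profile
#'
#' Runs all composition-derived property predictions (cetane number,
#' iodine value, LCSF, CFPP, saturation class sums) and merges supplied
#' laboratory measurements (density, viscosity, oxidation stability,
#' glycerides, metals, phosphorus, FAME content) that cannot be derived
#' from composition, producing the unified property set consumed by
#' [evaluate_compliance()].
#'
#' @inheritParams cetane_number
#' @param measured Optional laboratory measurements: a named list/vector
#'   or a data frame with columns `property,value`. Values may be
#'   censored upper bounds written as strings like `"<0.1"` (common for
#'   below-quantification glyceride results). See [measured_properties()]
#'   for the recognised property names.
#' @return A `fuel_property_set`: list with `computed` (tibble
#'   `property,value,units`), `class_sums` (tibble, see [class_sums()]),
#'   `measured` (tibble `property,value,censored,units`), and
#'   `coefficients_version`.
#' @examples
#' props <- compute_fuel_properties(ctp4_profile(), measured = ctp4_measured())
#' props$computed
#' @export
compute_fuel_properties <- function(profile, coeffs = fame_coefficients(),
                                    measured = NULL) {
  assert_normalized(profile, "compute_fuel_properties")
  cs <- class_sums(profile)
  lcsf_val <- lcsf(profile, coeffs)
  computed <- tibble::tibble(
    property = c("cetane_number", "iodine_value", "lcsf", "cfpp",
                 "linolenic_acid", "pufa_ge4db"),
    value = c(cetane_number(profile, coeffs),
              iodine_value(profile, coeffs),
              lcsf_val,
              cfpp(lcsf_val),
              cs$linolenic_pct,
              cs$pufa_ge4db_pct),
    units = c("", "g I/100 g", "", "degC", "% (m/m)", "% (m/m)")
  )
  structure(
    list(
      computed = computed,
      class_sums = cs,
      measured = measured_properties(measured),
      coefficients_version = coeffs$version
    ),
    class = "fuel_property_set"
  )
}

#' Parse laboratory-measured fuel properties
#'
#' Normalises user-supplied measured properties into a tidy table.
#' Recognised names (with units): `fame_content` (% m/m), `density`
#' (kg/L at 15 degC), `viscosity` (mm2/s at 40 degC),
#' `oxidation_stability` (h), `monoglycerides`, `diglycerides`,
#' `triglycerides`, `free_glycerol`, `total_glycerol` (% m/m),
#' `group1_metals` (Na+K, mg/kg), `group2_metals` (Ca+Mg, mg/kg),
#' `phosphorus` (mg/kg). Unknown names are kept and reported as having
#' no specification limit. A value written `"<x"` is treated as a
#' censored upper bound (true value below the quantification limit x).
#'
#' @param measured Named list/vector, data frame with `property,value`
#'   columns, or `NULL`.
#' @return Tibble with columns `property`, `value` (numeric; the bound
#'   for censored entries), `censored` (logical), `units`.
#' @export
measured_properties <- function(measured = NULL) {
  units_map <- c(
    fame_content = "% (m/m)", density = "kg/L", viscosity = "mm2/s",
    oxidation_stability = "h", monoglycerides = "% (m/m)",
    diglycerides = "% (m/m)", triglycerides = "% (m/m)",
    free_glycerol = "% (m/m)", total_glycerol = "% (m/m)",
    group1_metals = "mg/kg", group2_metals = "mg/kg", phosphorus = "mg/kg"
  )
  if (is.null(measured) || (is.data.frame(measured) && nrow(measured) == 0) ||
      length(measured) == 0) {
    return(tibble::tibble(property = character(), value = numeric(),
                          censored = logical(), units = character()))
  }
  if (is.data.frame(measured) &&
      all(c("property", "value", "censored", "units") %in% names(measured))) {
    return(tibble::as_tibble(measured))  # already parsed
  }
  if (is.data.frame(measured)) {
    if (!all(c("property", "value") %in% names(measured))) {
      stop("measured data frame needs columns `property` and `value`",
           call. = FALSE)
    }
    prop <- as.character(measured$property)
    raw <- as.character(measured$value)
  } else {
    if (is.null(names(measured)) || any(names(measured) == "")) {
      stop("measured values must be named", call. = FALSE)
    }
    prop <- names(measured)
    raw <- as.character(unlist(measured))
  }
  raw <- trimws(raw)
  censored <- startsWith(raw, "<")
  num <- suppressWarnings(as.numeric(sub("^<", "", raw)))
  if (any(is.na(num))) {
    stop("non-numeric measured value(s) for: ",
         paste(sQuote(prop[is.na(num)]), collapse = ", "), call. = FALSE)
  }
  if (any(num < 0)) {
    stop("measured values must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    property = prop,
    value = num,
    censored = censored,
    units = unname(units_map[prop])
  )
}

#' Read measured fuel properties from CSV
#'
#' Two columns `property,value` with header; values may be censored
#' (`<0.1`). See [measured_properties()] for recognised names.
#'
#' @param path Path to the CSV file.
#' @return Tibble as returned by [measured_properties()].
#' @export
read_measured_properties <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE, blank.lines.skip = TRUE,
                        stringsAsFactors = FALSE, colClasses = "character")
  measured_properties(df)
}

#' @export
print.fuel_property_set <- function(x, ...) {
  cat("<fuel_property_set>\n")
  cat("Computed from composition:\n")
  for (i in seq_len(nrow(x$computed))) {
    cat(sprintf("  %-20s %8.2f %s\n", x$computed$property[i],
                x$computed$value[i], x$computed$units[i]))
  }
  cat(sprintf("Class sums: SFA %.2f%%  MUFA %.2f%%  PUFA %.2f%%\n",
              x$class_sums$sfa_pct, x$class_sums$mufa_pct,
              x$class_sums$pufa_pct))
  if (nrow(x$measured) > 0) {
    cat(sprintf("Measured: %d properties supplied\n", nrow(x$measured)))
  }
  cat("coefficient tables:", x$coefficients_version, "\n")
  invisible(x)
}

# Flat property -> (value, censored) view used by the compliance engine.
property_values <- function(props) {
  stopifnot(inherits(props, "fuel_property_set"))
  dplyr::bind_rows(
    tibble::tibble(property = props$computed$property,
                   value = props$computed$value,
                   censored = FALSE),
    tibble::tibble(property = props$measured$property,
                   value = props$measured$value,
                   censored = props$measured$censored)
  )
}
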