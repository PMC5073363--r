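#' Load the specification limit table for a biodiesel standard
#'
#' Returns the limit set for the European EN 14214 or American ASTM
#' D6751 B100 biodiesel specification (the rows relevant to
#' FAME-profile-derived and routinely measured properties). Bounds
#' printed as ">= x" / "<= x" in the standards are inclusive; the
#' oxidation-stability induction-period bounds are strict (">6 h" under
#' EN, ">3 h" under ASTM).
#'
#' CFPP carries no numeric limit here: EN 14214 delegates cold-flow
#' classes to national annexes (country-dependent), so CFPP is evaluated
#' only when the user supplies a national limit (see
#' [evaluate_compliance()]).
#'
#' @param standard `"EN14214"` or `"ASTM_D6751"` (case-insensitive;
#'   `"astm"` and `"en"` prefixes accepted).
#' @return Tibble with columns `property`, `standard`, `lower`, `upper`,
#'   `inclusive_lower`, `inclusive_upper`, `units`, `note`.
#' @examples
#' load_limits("EN14214")
#' @export
load_limits <- function(standard) {
  std <- normalize_standard(standard)
  all <- utils::read.csv(system.file("extdata", "spec_limits.csv",
                                     package = "fameprop"),
                         stringsAsFactors = FALSE,
                         colClasses = c(lower = "numeric", upper = "numeric",
                                        inclusive_lower = "logical",
                                        inclusive_upper = "logical"))
  out <- tibble::as_tibble(all[all$standard == std, , drop = FALSE])
  stopifnot(nrow(out) > 0)
  out
}

normalize_standard <- function(standard) {
  if (length(standard) != 1 || !is.character(standard)) {
    stop("`standard` must be a single string", call. = FALSE)
  }
  key <- gsub("[^a-z0-9]", "", tolower(standard))
  if (key %in% c("en14214", "en")) return("EN14214")
  if (key %in% c("astmd6751", "astm", "d6751")) return("ASTM_D6751")
  stop("unknown standard ", sQuote(standard),
       "; supported standards: EN14214, ASTM_D6751", call. = FALSE)
}

#' Evaluate a fuel-property set against a biodiesel specification
#'
#' Compares every property in a [compute_fuel_properties()] result
#' against the limits of the chosen standard and produces a per-property
#' pass/fail report. Verdicts are mechanical:
#'
#' * `pass` / `fail` -- the value was compared against the bound(s) with
#'   their stated inclusivity. A censored measurement `"<u"` passes an
#'   upper limit L when `u <= L` (the true value is below u).
#' * `not_evaluable` -- the standard limits the property but no usable
#'   value is available (missing measurement; a censored bound that does
#'   not settle the comparison; CFPP without a national limit).
#' * `no_limit` -- the property has no limit in this standard; it is
#'   never counted as a pass.
#'
#' The overall verdict is `"fail"` iff at least one property fails.
#'
#' @param props A `fuel_property_set`.
#' @param standard `"EN14214"` or `"ASTM_D6751"`.
#' @param country_cfpp_limit Optional national CFPP maximum (degC) for
#'   the season of interest; when supplied, CFPP is evaluated as
#'   `cfpp <= limit` (inclusive).
#' @return A `compliance_report`: list with `standard`, `entries`
#'   (tibble: `property,value,censored,lower,upper,verdict,note`),
#'   `overall` (`"pass"` or `"fail"`), `failing` (character vector).
#' @examples
#' props <- compute_fuel_properties(ctp4_profile(), measured = ctp4_measured())
#' evaluate_compliance(props, "EN14214")$failing
#' @export
evaluate_compliance <- function(props, standard,
                                country_cfpp_limit = NULL) {
  stopifnot(inherits(props, "fuel_property_set"))
  std <- normalize_standard(standard)
  limits <- load_limits(std)
  if (!is.null(country_cfpp_limit)) {
    limits <- dplyr::bind_rows(limits, tibble::tibble(
      property = "cfpp", standard = std,
      lower = NA_real_, upper = as.numeric(country_cfpp_limit),
      inclusive_lower = NA, inclusive_upper = TRUE,
      units = "degC", note = "user-supplied national limit"
    ))
  }
  vals <- property_values(props)
  # lcsf is an intermediate, not a specification property
  vals <- vals[vals$property != "lcsf", , drop = FALSE]

  entries <- dplyr::full_join(vals, limits, by = "property")
  entries$verdict <- vapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    has_limit <- !is.na(e$lower) || !is.na(e$upper)
    if (!has_limit) {
      if (e$property %in% "cfpp") return("not_evaluable")
      return("no_limit")
    }
    if (is.na(e$value)) return("not_evaluable")
    compare_to_limit(e$value, isTRUE(e$censored),
                     e$lower, e$upper,
                     isTRUE(e$inclusive_lower), isTRUE(e$inclusive_upper))
  }, character(1))
  entries$note[entries$property == "cfpp" & entries$verdict == "not_evaluable"] <-
    "country-dependent limit not included in EN 14214; supply country_cfpp_limit"
  entries <- entries[!(is.na(entries$value) & entries$verdict == "no_limit"), ]
  entries <- tibble::as_tibble(
    entries[, c("property", "value", "censored", "lower", "upper",
                "verdict", "note")])
  failing <- entries$property[entries$verdict == "fail"]
  structure(
    list(standard = std,
         entries = entries,
         overall = if (length(failing) > 0) "fail" else "pass",
         failing = failing),
    class = "compliance_report"
  )
}

# Pure bound comparison. Censored value u means true value < u.
compare_to_limit <- function(value, censored, lower, upper,
                             inclusive_lower, inclusive_upper) {
  if (censored) {
    # true value in [0, u): settles an upper bound when u <= upper;
    # fails a strictly positive lower bound only if u <= lower is
    # unknowable -> not evaluable otherwise
    ok_upper <- is.na(upper) || value <= upper
    if (!is.na(lower)) return("not_evaluable")
    return(if (ok_upper) "pass" else "not_evaluable")
  }
  ok_lower <- is.na(lower) ||
    (if (inclusive_lower) value >= lower else value > lower)
  ok_upper <- is.na(upper) ||
    (if (inclusive_upper) value <= upper else value < upper)
  if (ok_lower && ok_upper) "pass" else "fail"
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> standard: %s  overall: %s\n",
              x$standard, toupper(x$overall)))
  e <- x$entries
  for (i in seq_len(nrow(e))) {
    bounds <- paste0(
      if (!is.na(e$lower[i])) sprintf(">=%s", format(e$lower[i])) else "",
      if (!is.na(e$lower[i]) && !is.na(e$upper[i])) ", " else "",
      if (!is.na(e$upper[i])) sprintf("<=%s", format(e$upper[i])) else "")
    cat(sprintf("  %-20s %10s  [%s]  %s\n", e$property[i],
                ifelse(is.na(e$value[i]), "-",
                       paste0(ifelse(e$censored[i], "<", ""),
                              format(round(e$value[i], 3)))),
                bounds, e$verdict[i]))
  }
  if (length(x$failing) > 0) {
    cat("failing:", paste(x$failing, collapse = ", "), "\n")
  }
  invisible(x)
}
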