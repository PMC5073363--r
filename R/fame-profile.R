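#' Construct a FAME composition profile
#'
#' A FAME profile maps fatty acid species to their abundance as a
#' percentage of total FAME content, the convention in which GC-MS lipid
#' profiles of biodiesel feedstocks are reported. Species are identified
#' by `(carbons, double_bonds)`; duplicate species are rejected.
#'
#' @param x Either a named numeric vector (names in `Cx:y` notation) or a
#'   data frame with columns `species` and `percent`.
#' @param normalized Logical; mark the profile as normalized. When `TRUE`
#'   the abundances must already sum to 100 within `1e-9`.
#' @return A `fame_profile`: a tibble with columns `species`, `carbons`,
#'   `double_bonds`, `omega`, `percent` and a `normalized` attribute.
#' @examples
#' fame_profile(c("C16:0" = 50, "C18:1" = 50), normalized = TRUE)
#' @export
fame_profile <- function(x, normalized = FALSE) {
  if (is.data.frame(x)) {
    if (!all(c("species", "percent") %in% names(x))) {
      stop("profile data frame needs columns `species` and `percent`", call. = FALSE)
    }
    labels <- as.character(x$species)
    percent <- as.numeric(x$percent)
  } else if (is.numeric(x) && !is.null(names(x))) {
    labels <- names(x)
    percent <- as.numeric(x)
  } else {
    stop("`x` must be a named numeric vector or a data frame with ",
         "`species` and `percent` columns", call. = FALSE)
  }
  sp <- parse_fame_label(labels)
  if (anyDuplicated(sp$label)) {
    stop("duplicate FAME species after canonicalisation: ",
         paste(sQuote(unique(sp$label[duplicated(sp$label)])), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(percent)) || any(percent < 0)) {
    stop("abundances must be finite and >= 0", call. = FALSE)
  }
  out <- tibble::tibble(
    species = sp$label,
    carbons = sp$carbons,
    double_bonds = sp$double_bonds,
    omega = sp$omega,
    percent = percent
  )
  if (normalized && abs(sum(percent) - 100) > 1e-9) {
    stop("profile flagged normalized but abundances sum to ",
         format(sum(percent)), ", not 100", call. = FALSE)
  }
  structure(out, class = c("fame_profile", class(out)), normalized = normalized)
}

#' @export
print.fame_profile <- function(x, ...) {
  cat(sprintf("<fame_profile> %d species, %s (sum = %.4f%%)\n",
              nrow(x),
              if (is_normalized(x)) "normalized" else "unnormalized",
              sum(x$percent)))
  NextMethod()
}

#' Is a profile normalized?
#'
#' @param profile A `fame_profile`.
#' @return `TRUE` when the profile carries the normalized flag and its
#'   abundances sum to 100 within `1e-9`.
#' @export
is_normalized <- function(profile) {
  isTRUE(attr(profile, "normalized")) &&
    abs(sum(profile$percent) - 100) <= 1e-9
}

#' Normalize a FAME profile to percentages of total FAME
#'
#' Rescales abundances by `100 / sum` so that they sum to exactly 100,
#' preserving relative proportions. Idempotent: a profile that is already
#' normalized is returned unchanged.
#'
#' @param profile A `fame_profile`.
#' @return The normalized `fame_profile`.
#' @examples
#' p <- fame_profile(c("C16:0" = 1, "C18:1" = 3))
#' normalize_profile(p)
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  if (is_normalized(profile)) {
    return(profile)
  }
  s <- sum(profile$percent)
  if (nrow(profile) == 0 || s <= 0) {
    stop("cannot normalize: profile has no strictly positive abundance",
         call. = FALSE)
  }
  profile$percent <- profile$percent * (100 / s)
  attr(profile, "normalized") <- TRUE
  profile
}

assert_normalized <- function(profile, caller) {
  if (!inherits(profile, "fame_profile")) {
    stop("expected a `fame_profile` object", call. = FALSE)
  }
  if (!is_normalized(profile)) {
    stop(caller, "() requires a normalized profile; ",
         "call normalize_profile() first", call. = FALSE)
  }
  invisible(TRUE)
}

#' Saturation class sums of a FAME profile
#'
#' Buckets species by double-bond count: saturated (0), monounsaturated
#' (1) and polyunsaturated (>= 2) fatty acids, plus the two
#' specification-relevant subtotals: PUFA with >= 4 double bonds and
#' linolenic acid (C18:3). On a normalized profile the three class sums
#' partition 100%.
#'
#' @param profile A normalized `fame_profile`.
#' @return A one-row tibble with columns `sfa_pct`, `mufa_pct`,
#'   `pufa_pct`, `pufa_ge4db_pct`, `linolenic_pct` (each % of total FAME).
#' @examples
#' p <- fame_profile(c("C16:0" = 25, "C18:1" = 40, "C18:2" = 35),
#'                   normalized = TRUE)
#' class_sums(p)
#' @export
class_sums <- function(profile) {
  assert_normalized(profile, "class_sums")
  db <- profile$double_bonds
  pct <- profile$percent
  tibble::tibble(
    sfa_pct = sum(pct[db == 0]),
    mufa_pct = sum(pct[db == 1]),
    pufa_pct = sum(pct[db >= 2]),
    pufa_ge4db_pct = sum(pct[db >= 4]),
    linolenic_pct = sum(pct[profile$carbons == 18 & db == 3])
  )
}

#' Read a FAME profile from CSV
#'
#' Expects two columns `species,percent` with a header; species in
#' `Cx:y[n-z]` notation. Whitespace is stripped and blank lines ignored.
#' Rows whose species label is not parseable (e.g. an "unidentified"
#' remainder peak) are rejected unless `allow_remainder = TRUE`, in which
#' case they are dropped and the remaining abundances renormalize
#' proportionally.
#'
#' @param path Path to the CSV file.
#' @param allow_remainder Drop unparseable species rows and redistribute
#'   their mass proportionally during normalization (default `FALSE`).
#' @param normalize Normalize the profile after reading (default `TRUE`).
#' @return A `fame_profile`.
#' @export
read_fame_profile <- function(path, allow_remainder = FALSE, normalize = TRUE) {
  if (!file.exists(path)) {
    stop("profile CSV not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, strip.white = TRUE, blank.lines.skip = TRUE,
                        stringsAsFactors = FALSE)
  if (!all(c("species", "percent") %in% names(df))) {
    stop("profile CSV must have columns `species,percent`: ", path, call. = FALSE)
  }
  parseable <- grepl("^\\s*[Cc]\\s*[0-9]+\\s*:", df$species)
  if (any(!parseable)) {
    if (!allow_remainder) {
      stop("unparseable species in ", path, ": ",
           paste(sQuote(df$species[!parseable]), collapse = ", "),
           "; use allow_remainder = TRUE to drop and redistribute",
           call. = FALSE)
    }
    df <- df[parseable, , drop = FALSE]
  }
  p <- fame_profile(df)
  if (normalize) normalize_profile(p) else p
}

#' Write a FAME profile to CSV
#'
#' @param profile A `fame_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fame_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fame_profile"))
  utils::write.csv(
    data.frame(species = profile$species, percent = profile$percent),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
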