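#' Parse fatty acid shorthand notation
#'
#' Parses one or more fatty acid labels in the standard `Cx:y` shorthand
#' (x acyl carbons, y double bonds), optionally with an omega suffix `n-z`
#' giving the position of the double bond closest to the methyl end
#' (e.g. `"C20:5n-3"` for eicosapentaenoic acid, EPA). Parsing is
#' case-insensitive and whitespace-tolerant.
#'
#' Species identity is carried by `(carbons, double_bonds)`; the omega
#' position is retained as metadata only, so `"C18:3"` and `"C18:3n-3"`
#' canonicalise to the same species. This matches how the downstream
#' property equations work: per-ester cetane numbers, iodine factors and
#' cold-flow weights depend only on chain length and unsaturation.
#'
#' @param label Character vector of labels such as `"C16:0"`, `"c18:1"`,
#'   `" C20:5n-3 "`.
#' @return A tibble with one row per label and columns `label` (canonical
#'   form `C{carbons}:{double_bonds}`), `carbons`, `double_bonds`, `omega`
#'   (integer, `NA` when absent).
#' @examples
#' parse_fame_label(c("C16:0", "C18:1", "C20:5n-3"))
#' @export
parse_fame_label <- function(label) {
  if (!is.character(label) || length(label) == 0) {
    stop("`label` must be a non-empty character vector", call. = FALSE)
  }
  rx <- "^\\s*[Cc]\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*(?:[Nn]\\s*-\\s*([0-9]+))?\\s*$"
  m <- regmatches(label, regexec(rx, label))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed FAME label(s): ",
         paste(sQuote(trimws(label[bad])), collapse = ", "),
         " (expected Cx:y or Cx:yn-z notation)", call. = FALSE)
  }
  carbons      <- vapply(m, function(g) as.integer(g[2]), integer(1))
  double_bonds <- vapply(m, function(g) as.integer(g[3]), integer(1))
  omega        <- vapply(m, function(g) {
    if (g[4] == "") NA_integer_ else as.integer(g[4])
  }, integer(1))
  validate_fame_species(carbons, double_bonds, omega, label)
  tibble::tibble(
    label = fame_species_label(carbons, double_bonds),
    carbons = carbons,
    double_bonds = double_bonds,
    omega = omega
  )
}

#' Canonical label for a FAME species
#'
#' @param carbons Integer vector of acyl-chain carbon counts.
#' @param double_bonds Integer vector of double-bond counts.
#' @return Character vector `"C{carbons}:{double_bonds}"`.
#' @examples
#' fame_species_label(18, 1)
#' @export
fame_species_label <- function(carbons, double_bonds) {
  sprintf("C%d:%d", as.integer(carbons), as.integer(double_bonds))
}

# A chain of n carbons has at most (n - 2)/2 methylene-interrupted double
# bonds in an acyl chain; anything beyond that is chemically impossible.
validate_fame_species <- function(carbons, double_bonds, omega = NA_integer_,
                                  label = fame_species_label(carbons, double_bonds)) {
  if (any(carbons < 4)) {
    stop("acyl chains shorter than 4 carbons are not supported: ",
         paste(sQuote(label[carbons < 4]), collapse = ", "), call. = FALSE)
  }
  if (any(double_bonds < 0)) {
    stop("negative double-bond counts are not allowed", call. = FALSE)
  }
  impossible <- carbons < 2L * double_bonds + 2L
  if (any(impossible)) {
    stop("chemically impossible unsaturation (need carbons >= 2*double_bonds + 2): ",
         paste(sQuote(label[impossible]), collapse = ", "), call. = FALSE)
  }
  has_omega <- !is.na(omega)
  if (any(has_omega & omega < 1)) {
    stop("omega position must be a positive integer", call. = FALSE)
  }
  invisible(TRUE)
}

#' Molecular weight of a fatty acid methyl ester
#'
#' Computes the molecular weight of the methyl ester of a `Cx:y` fatty
#' acid from its molecular formula C(x+1) H(2x+2-2y) O2, using IUPAC 2021
#' standard atomic weights. Used by the theoretical iodine-value relation
#' `IV = 253.81 * db * 100 / MW` (halogen addition across each double
#' bond, 2 x atomic iodine = 253.81 g/mol).
#'
#' @param carbons Integer vector, acyl-chain carbons.
#' @param double_bonds Integer vector, double bonds.
#' @return Numeric vector of molecular weights in g/mol.
#' @examples
#' methyl_ester_mw(16, 0) # methyl palmitate, 270.46
#' @export
methyl_ester_mw <- function(carbons, double_bonds) {
  validate_fame_species(carbons, double_bonds)
  n_c <- carbons + 1
  n_h <- 2 * carbons + 2 - 2 * double_bonds
  12.011 * n_c + 1.008 * n_h + 15.999 * 2
}
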