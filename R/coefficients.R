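#' Per-ester property coefficient tables
#'
#' Assembles the coefficient tables used by the fuel-property equations:
#'
#' * `cn`: per-ester cetane numbers (dimensionless), shipped from the
#'   published compilations of measured methyl-ester cetane numbers.
#' * `iv`: per-ester iodine-value factors (g I2 contributed per 100 g of
#'   fuel per 1% abundance), calculated in the EN 14214 Annex B
#'   convention from the halogen-addition stoichiometry
#'   `253.81 * db / MW(methyl ester)`.
#' * `lcsf_weights`: the long-chain saturated factor weights of Ramos et
#'   al. (2009, Bioresour Technol 100:261): 0.1 for C16:0, 0.5 for C18:0,
#'   1.0 for C20:0, 1.5 for C22:0, 2.0 for C24:0.
#'
#' All property operations accept an injected coefficient set, so users
#' can substitute alternative tables; every report carries the table
#' version hash because the computed properties are table-dependent.
#'
#' @param cn Optional replacement cetane table: a data frame with columns
#'   `species,value,source` (species in `Cx:y` notation, `value` > 0).
#' @param iv Optional replacement iodine-factor table, same columns;
#'   factors must be exactly 0 for saturated species.
#' @param lcsf_weights Optional named numeric vector mapping saturated
#'   chain length (as character, e.g. `"16"`) to weight; must be strictly
#'   increasing in chain length.
#' @return A `fame_coefficients` object: list with elements `cn`, `iv`
#'   (tibbles with parsed `carbons`/`double_bonds` columns),
#'   `lcsf_weights`, and `version` (MD5 hash of the tables).
#' @examples
#' coeffs <- fame_coefficients()
#' coeffs$lcsf_weights
#' @export
fame_coefficients <- function(cn = NULL, iv = NULL, lcsf_weights = NULL) {
  if (is.null(cn)) {
    cn <- utils::read.csv(system.file("extdata", "cn_methyl_esters.csv",
                                      package = "fameprop"),
                          stringsAsFactors = FALSE)
  }
  if (is.null(iv)) {
    iv <- utils::read.csv(system.file("extdata", "iv_factors.csv",
                                      package = "fameprop"),
                          stringsAsFactors = FALSE)
  }
  if (is.null(lcsf_weights)) {
    lcsf_weights <- c("16" = 0.1, "18" = 0.5, "20" = 1.0,
                      "22" = 1.5, "24" = 2.0)
  }
  cn <- parse_coef_table(cn, "cn")
  iv <- parse_coef_table(iv, "iv")
  if (any(cn$value <= 0)) {
    stop("per-ester cetane numbers must be > 0", call. = FALSE)
  }
  sat <- iv$double_bonds == 0
  if (any(iv$value[sat] != 0)) {
    stop("iodine factors must be exactly 0 for saturated species", call. = FALSE)
  }
  if (any(iv$value < 0)) {
    stop("iodine factors must be >= 0", call. = FALSE)
  }
  w <- lcsf_weights[order(as.integer(names(lcsf_weights)))]
  if (length(w) > 1 && any(diff(w) <= 0)) {
    stop("LCSF weights must be strictly increasing in chain length", call. = FALSE)
  }
  obj <- list(cn = cn, iv = iv, lcsf_weights = w)
  obj$version <- coef_version_hash(obj)
  structure(obj, class = "fame_coefficients")
}

parse_coef_table <- function(df, what) {
  if (!all(c("species", "value") %in% names(df))) {
    stop("coefficient table `", what,
         "` needs columns `species` and `value`", call. = FALSE)
  }
  sp <- parse_fame_label(as.character(df$species))
  if (anyDuplicated(sp$label)) {
    stop("duplicate species in coefficient table `", what, "`", call. = FALSE)
  }
  tibble::tibble(
    species = sp$label,
    carbons = sp$carbons,
    double_bonds = sp$double_bonds,
    value = as.numeric(df$value),
    source = if ("source" %in% names(df)) as.character(df$source)
             else NA_character_
  )
}

coef_version_hash <- function(obj) {
  canon <- paste(
    paste(obj$cn$species, format(obj$cn$value, digits = 15), collapse = ";"),
    paste(obj$iv$species, format(obj$iv$value, digits = 15), collapse = ";"),
    paste(names(obj$lcsf_weights), format(obj$lcsf_weights, digits = 15),
          collapse = ";"),
    sep = "|"
  )
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.fame_coefficients <- function(x, ...) {
  cat(sprintf("<fame_coefficients> CN: %d esters; IV: %d esters; LCSF weights: %s\n",
              nrow(x$cn), nrow(x$iv),
              paste(sprintf("C%s:0=%.1f", names(x$lcsf_weights), x$lcsf_weights),
                    collapse = ", ")))
  cat("version:", x$version, "\n")
  invisible(x)
}

# Coefficient lookup with the structure-nearest fallback used for GC
# response factors: exact (carbons, db) match first, then the
# same-unsaturation species nearest in chain length, then the same-chain
# species nearest in unsaturation. Each fallback emits a warning so that
# substitutions are visible in logs.
lookup_coef <- function(table, carbons, double_bonds, what) {
  hit <- table$value[table$carbons == carbons &
                     table$double_bonds == double_bonds]
  if (length(hit) == 1) {
    return(hit)
  }
  same_db <- table[table$double_bonds == double_bonds, , drop = FALSE]
  if (nrow(same_db) > 0) {
    i <- which.min(abs(same_db$carbons - carbons))
    warning(sprintf("%s: no coefficient for %s; using structure-nearest %s",
                    what, fame_species_label(carbons, double_bonds),
                    same_db$species[i]), call. = FALSE)
    return(same_db$value[i])
  }
  same_chain <- table[table$carbons == carbons, , drop = FALSE]
  if (nrow(same_chain) > 0) {
    i <- which.min(abs(same_chain$double_bonds - double_bonds))
    warning(sprintf("%s: no coefficient for %s; using structure-nearest %s",
                    what, fame_species_label(carbons, double_bonds),
                    same_chain$species[i]), call. = FALSE)
    return(same_chain$value[i])
  }
  stop(sprintf("%s: no coefficient (and no structural neighbour) for %s",
               what, fame_species_label(carbons, double_bonds)), call. = FALSE)
}
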