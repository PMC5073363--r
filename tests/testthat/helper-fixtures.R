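# Random species/profile builders shared by the property-style tests.

random_species <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  carbons <- sample(seq(4, 24, by = 2), n, replace = TRUE)
  db <- vapply(carbons, function(cc) {
    sample(0:min(6, (cc - 2) %/% 2), 1)
  }, integer(1))
  labs <- fame_species_label(carbons, db)
  dup <- duplicated(labs)
  list(carbons = carbons[!dup], double_bonds = db[!dup], label = labs[!dup])
}

random_profile <- function(n = 6, seed = NULL, normalized = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sp <- random_species(n)
  x <- stats::runif(length(sp$label), 0.1, 10)
  names(x) <- sp$label
  p <- fame_profile(x)
  if (normalized) normalize_profile(p) else p
}

# Coefficient set that covers every generatable species, for property
# tests that must avoid fallback warnings.
full_coverage_coeffs <- function() {
  grid <- expand.grid(carbons = seq(4, 24, by = 2), db = 0:6)
  grid <- grid[grid$carbons >= 2 * grid$db + 2, ]
  cn <- data.frame(
    species = fame_species_label(grid$carbons, grid$db),
    value = 100 - 2 * grid$db * 10 / (1 + grid$db) + grid$carbons / 2,
    source = "synthetic test table"
  )
  iv <- data.frame(
    species = fame_species_label(grid$carbons, grid$db),
    value = 253.81 * grid$db / methyl_ester_mw(grid$carbons, grid$db),
    source = "halogen addition"
  )
  fame_coefficients(cn = cn, iv = iv)
}
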