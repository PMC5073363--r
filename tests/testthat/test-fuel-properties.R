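coeffs <- fame_coefficients()

test_that("cetane number is the abundance-weighted mean of per-ester values", {
  cn16 <- coeffs$cn$value[coeffs$cn$species == "C16:0"]
  cn181 <- coeffs$cn$value[coeffs$cn$species == "C18:1"]
  one <- fame_profile(c("C16:0" = 100), normalized = TRUE)
  expect_equal(cetane_number(one, coeffs), cn16)
  blend <- fame_profile(c("C16:0" = 50, "C18:1" = 50), normalized = TRUE)
  expect_equal(cetane_number(blend, coeffs), (cn16 + cn181) / 2)
})

test_that("cetane number is bounded by the per-ester extremes present", {
  cc <- full_coverage_coeffs()
  for (seed in 1:15) {
    p <- random_profile(5, seed = seed)
    cn_c <- vapply(seq_len(nrow(p)), function(i) {
      cc$cn$value[cc$cn$carbons == p$carbons[i] &
                  cc$cn$double_bonds == p$double_bonds[i]]
    }, numeric(1))
    cn <- cetane_number(p, cc)
    expect_gte(cn, min(cn_c) - 1e-12)
    expect_lte(cn, max(cn_c) + 1e-12)
  }
})

test_that("missing cetane coefficients fall back to the structure-nearest ester", {
  # same unsaturation, nearest chain first
  p <- fame_profile(c("C16:2" = 100), normalized = TRUE)
  expect_warning(cn <- cetane_number(p, coeffs), "C16:2.*C18:2")
  expect_equal(cn, coeffs$cn$value[coeffs$cn$species == "C18:2"])
  # no structural neighbour at all -> error naming the species
  tiny <- fame_coefficients(cn = data.frame(species = "C16:0", value = 74.5))
  p2 <- fame_profile(c("C18:2" = 100), normalized = TRUE)
  expect_error(suppressWarnings(
    cetane_number(p2, fame_coefficients(
      cn = data.frame(species = "C4:1", value = 20)))), "C18:2")
  # same chain, nearest unsaturation as second resort
  expect_warning(cn2 <- cetane_number(
    fame_profile(c("C16:1" = 100), normalized = TRUE), tiny), "C16:1.*C16:0")
  expect_equal(cn2, 74.5)
})

test_that("iodine value is zero iff saturated and matches the halogen-addition oracle", {
  expect_equal(iodine_value(fame_profile(c("C16:0" = 100), normalized = TRUE),
                            coeffs), 0)
  # every shipped unsaturated factor within 3% of 253.81*db*100/MW per 100%
  unsat <- coeffs$iv[coeffs$iv$double_bonds > 0, ]
  for (i in seq_len(nrow(unsat))) {
    theo <- 253.81 * unsat$double_bonds[i] /
      methyl_ester_mw(unsat$carbons[i], unsat$double_bonds[i])
    expect_equal(unsat$value[i], theo, tolerance = 0.03,
                 info = unsat$species[i])
  }
  # single-species check quoted for methyl oleate
  oleate <- fame_profile(c("C18:1" = 100), normalized = TRUE)
  expect_equal(iodine_value(oleate, coeffs),
               253.81 * 1 * 100 / methyl_ester_mw(18, 1),
               tolerance = 0.03)
})

test_that("LCSF weights saturated chains and ignores everything else", {
  p <- fame_profile(c("C16:0" = 10, "C18:0" = 10, "C20:0" = 10,
                      "C22:0" = 10, "C24:0" = 10, "C18:1" = 50),
                    normalized = TRUE)
  expect_equal(lcsf(p, coeffs), 10 * (0.1 + 0.5 + 1 + 1.5 + 2))
  none <- fame_profile(c("C18:1" = 60, "C18:2" = 40), normalized = TRUE)
  expect_equal(lcsf(none, coeffs), 0)
  short <- fame_profile(c("C14:0" = 20, "C16:0" = 80), normalized = TRUE)
  expect_warning(v <- lcsf(short, coeffs), "C14:0")
  expect_equal(v, 0.1 * 80)
})

test_that("CFPP is the stated affine map of LCSF", {
  expect_equal(cfpp(0), -16.477)
  expect_equal(cfpp(16.477 / 3.1417), 0)
  expect_equal(cfpp(2.413), 3.1417 * 2.413 - 16.477)
  expect_error(cfpp(-0.1), "negative")
  # strictly increasing
  x <- seq(0, 10, by = 0.5)
  expect_true(all(diff(cfpp(x)) > 0))
})

test_that("all four properties are linear in the profile", {
  cc <- full_coverage_coeffs()
  set.seed(42)
  for (rep in 1:8) {
    p <- random_profile(5)
    q <- random_profile(5)
    mix <- c(stats::setNames(p$percent / 2, p$species))
    for (i in seq_len(nrow(q))) {
      lab <- q$species[i]
      mix[lab] <- (if (lab %in% names(mix)) mix[[lab]] else 0) + q$percent[i] / 2
    }
    blend <- fame_profile(mix, normalized = TRUE)
    expect_equal(cetane_number(blend, cc),
                 (cetane_number(p, cc) + cetane_number(q, cc)) / 2,
                 tolerance = 1e-9)
    expect_equal(iodine_value(blend, cc),
                 (iodine_value(p, cc) + iodine_value(q, cc)) / 2,
                 tolerance = 1e-9)
    l_p <- suppressWarnings(lcsf(p, cc)); l_q <- suppressWarnings(lcsf(q, cc))
    l_b <- suppressWarnings(lcsf(blend, cc))
    expect_equal(l_b, (l_p + l_q) / 2, tolerance = 1e-9)
    expect_equal(cfpp(l_b) - (-16.477),
                 ((cfpp(l_p) + 16.477) + (cfpp(l_q) + 16.477)) / 2,
                 tolerance = 1e-9)
  }
})

test_that("compute_fuel_properties assembles computed and measured rows", {
  props <- suppressWarnings(
    compute_fuel_properties(ctp4_profile(), measured = ctp4_measured()))
  get <- function(nm) props$computed$value[props$computed$property == nm]
  expect_equal(get("lcsf"), 2.413, tolerance = 1e-12)
  expect_equal(get("cfpp"), cfpp(2.413))
  expect_equal(get("linolenic_acid"), 1.23)
  expect_equal(get("pufa_ge4db"), 0.77)
  expect_equal(props$measured$value[props$measured$property == "phosphorus"],
               24.02)
  expect_true(props$measured$censored[
    props$measured$property == "monoglycerides"])
  expect_match(props$coefficients_version, "^[0-9a-f]{32}$")

  # no measured values: computed present, measured empty
  bare <- suppressWarnings(compute_fuel_properties(ctp4_profile()))
  expect_equal(nrow(bare$measured), 0)
  expect_equal(bare$computed$value, props$computed$value)

  # saturated-only profile: IV 0, PUFA sums 0, CN = weighted saturated mean
  sat <- fame_profile(c("C16:0" = 60, "C18:0" = 40), normalized = TRUE)
  sp <- compute_fuel_properties(sat)
  expect_equal(sp$computed$value[sp$computed$property == "iodine_value"], 0)
  expect_equal(sp$class_sums$pufa_pct, 0)
  expect_equal(sp$computed$value[sp$computed$property == "cetane_number"],
               0.6 * 74.5 + 0.4 * 86.9)
})

test_that("coefficient tables validate their invariants", {
  expect_error(fame_coefficients(
    cn = data.frame(species = "C16:0", value = -1)), "> 0")
  expect_error(fame_coefficients(
    iv = data.frame(species = "C16:0", value = 0.5)), "saturated")
  expect_error(fame_coefficients(
    lcsf_weights = c("16" = 0.5, "18" = 0.1)), "increasing")
  # version hash tracks table content
  a <- fame_coefficients()
  b <- fame_coefficients(cn = data.frame(species = "C16:0", value = 74.5))
  expect_false(a$version == b$version)
  expect_equal(a$version, fame_coefficients()$version)
})
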