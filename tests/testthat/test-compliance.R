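ctp4_props <- suppressWarnings(
  compute_fuel_properties(ctp4_profile(), measured = ctp4_measured()))

test_that("limit tables carry the printed bounds of both standards", {
  en <- load_limits("EN14214")
  row <- function(tbl, p) tbl[tbl$property == p, ]
  expect_equal(row(en, "iodine_value")$upper, 120)
  expect_true(row(en, "iodine_value")$inclusive_upper)
  expect_equal(row(en, "oxidation_stability")$lower, 6)
  expect_false(row(en, "oxidation_stability")$inclusive_lower)
  expect_equal(row(en, "phosphorus")$upper, 4.0)
  expect_equal(row(en, "pufa_ge4db")$upper, 1.00)
  expect_equal(row(en, "fame_content")$lower, 96.50)
  expect_equal(c(row(en, "density")$lower, row(en, "density")$upper),
               c(0.86, 0.90))

  astm <- load_limits("astm")
  expect_equal(c(row(astm, "viscosity")$lower, row(astm, "viscosity")$upper),
               c(1.90, 6.00))
  expect_equal(row(astm, "oxidation_stability")$lower, 3)
  expect_equal(row(astm, "phosphorus")$upper, 10.0)
  expect_equal(row(astm, "cetane_number")$lower, 47)

  expect_error(load_limits("EN99999"), "EN14214.*ASTM_D6751")
})

test_that("CTP4 reproduces the published failure sets under both standards", {
  en <- evaluate_compliance(ctp4_props, "EN14214")
  verdict <- function(rep, p) rep$entries$verdict[rep$entries$property == p]
  # phosphorus 24.02 fails both; oxidation stability 4.74 fails EN (>6)
  # but passes ASTM (>3); PUFA>=4db 0.77 passes EN's <=1.00; density 0.85
  # sits below the EN band and fails mechanically
  expect_equal(verdict(en, "phosphorus"), "fail")
  expect_equal(verdict(en, "oxidation_stability"), "fail")
  expect_equal(verdict(en, "density"), "fail")
  expect_equal(verdict(en, "pufa_ge4db"), "pass")
  expect_equal(verdict(en, "iodine_value"), "pass")
  expect_equal(verdict(en, "cetane_number"), "pass")
  expect_equal(verdict(en, "linolenic_acid"), "pass")
  expect_equal(verdict(en, "fame_content"), "pass")
  expect_setequal(en$failing,
                  c("density", "oxidation_stability", "phosphorus"))
  expect_equal(en$overall, "fail")

  astm <- evaluate_compliance(ctp4_props, "ASTM_D6751")
  expect_equal(verdict(astm, "phosphorus"), "fail")
  expect_equal(verdict(astm, "oxidation_stability"), "pass")
  expect_equal(astm$failing, "phosphorus")
})

test_that("censored below-quantification values pass upper bounds they settle", {
  en <- evaluate_compliance(ctp4_props, "EN14214")
  verdict <- function(p) en$entries$verdict[en$entries$property == p]
  expect_equal(verdict("monoglycerides"), "pass")   # <0.1 vs <=0.80
  expect_equal(verdict("free_glycerol"), "pass")    # <0.001 vs <=0.02
  # a censored bound above the limit settles nothing
  loose <- suppressWarnings(compute_fuel_properties(
    ctp4_profile(), measured = list(monoglycerides = "<1.5")))
  rep <- evaluate_compliance(loose, "EN14214")
  expect_equal(rep$entries$verdict[rep$entries$property == "monoglycerides"],
               "not_evaluable")
})

test_that("inclusive bounds pass at the limit and strict bounds fail there", {
  at_limit <- suppressWarnings(compute_fuel_properties(
    ctp4_profile(),
    measured = list(fame_content = 96.50, density = 0.86, viscosity = 5.00,
                    oxidation_stability = 6, phosphorus = 4.0,
                    total_glycerol = 0.25)))
  rep <- evaluate_compliance(at_limit, "EN14214")
  verdict <- function(p) rep$entries$verdict[rep$entries$property == p]
  expect_equal(verdict("fame_content"), "pass")
  expect_equal(verdict("density"), "pass")
  expect_equal(verdict("viscosity"), "pass")
  expect_equal(verdict("phosphorus"), "pass")
  expect_equal(verdict("total_glycerol"), "pass")
  expect_equal(verdict("oxidation_stability"), "fail")  # strict >6
  # brute-force comparison oracle over all at-limit entries
  lim <- load_limits("EN14214")
  vals <- rbind(
    data.frame(property = at_limit$computed$property,
               value = at_limit$computed$value),
    data.frame(property = at_limit$measured$property,
               value = at_limit$measured$value))
  vals <- vals[!vals$property %in% c("lcsf", "cfpp"), ]
  merged <- merge(vals, lim, by = "property")
  merged <- merged[!merged$property %in%
                     rep$entries$property[rep$entries$censored], ]
  for (i in seq_len(nrow(merged))) {
    m <- merged[i, ]
    ok <- (is.na(m$lower) ||
             (if (isTRUE(m$inclusive_lower)) m$value >= m$lower
              else m$value > m$lower)) &&
          (is.na(m$upper) ||
             (if (isTRUE(m$inclusive_upper)) m$value <= m$upper
              else m$value < m$upper))
    expect_equal(verdict(m$property), if (ok) "pass" else "fail",
                 info = m$property)
  }
})

test_that("missing values, unknown properties and CFPP default handling", {
  bare <- suppressWarnings(compute_fuel_properties(ctp4_profile()))
  rep <- evaluate_compliance(bare, "EN14214")
  verdict <- function(p) rep$entries$verdict[rep$entries$property == p]
  expect_equal(verdict("density"), "not_evaluable")
  expect_equal(verdict("phosphorus"), "not_evaluable")
  expect_equal(verdict("cfpp"), "not_evaluable")
  expect_equal(verdict("iodine_value"), "pass")
  # never a fail from absent data: overall passes on composition alone
  expect_equal(rep$overall, "pass")

  # unknown property reported as no_limit, never pass
  odd <- suppressWarnings(compute_fuel_properties(
    ctp4_profile(), measured = list(cloud_point = 3)))
  rep2 <- evaluate_compliance(odd, "ASTM_D6751")
  expect_equal(rep2$entries$verdict[rep2$entries$property == "cloud_point"],
               "no_limit")

  # user-supplied national CFPP limit makes CFPP evaluable
  rep3 <- evaluate_compliance(bare, "EN14214", country_cfpp_limit = -5)
  expect_equal(rep3$entries$verdict[rep3$entries$property == "cfpp"], "pass")
  rep4 <- evaluate_compliance(bare, "EN14214", country_cfpp_limit = -12)
  expect_equal(rep4$entries$verdict[rep4$entries$property == "cfpp"], "fail")
})

test_that("evaluation is pure and verdicts are monotone toward the pass interval", {
  a <- evaluate_compliance(ctp4_props, "EN14214")
  b <- evaluate_compliance(ctp4_props, "EN14214")
  expect_identical(a$entries, b$entries)
  # moving phosphorus toward the limit flips fail -> pass exactly once
  verdicts <- vapply(c(24.02, 10, 4.0, 2, 0), function(v) {
    props <- suppressWarnings(compute_fuel_properties(
      ctp4_profile(), measured = list(phosphorus = v)))
    rep <- evaluate_compliance(props, "EN14214")
    rep$entries$verdict[rep$entries$property == "phosphorus"]
  }, character(1))
  expect_equal(verdicts, c("fail", "fail", "pass", "pass", "pass"))
})
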