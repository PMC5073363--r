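#' Reference FAME profile of Tetraselmis sp. CTP4 biodiesel
#'
#' The published fatty acid methyl ester composition of biodiesel
#' synthesised from the lipids of the euryhaline marine chlorophyte
#' *Tetraselmis* sp. CTP4, in % of total FAME. It is dominated by
#' palmitic (C16:0), oleic (C18:1) and linoleic (C18:2) acids (~75% of
#' total fatty acids) with only trace long-chain PUFA, which is what
#' makes it an unusually specification-friendly microalgal feedstock.
#' Ships as the worked example and as the default template of the
#' synthetic profile generator.
#'
#' @return A normalized `fame_profile` (8 species summing to 100%).
#' @examples
#' class_sums(ctp4_profile())
#' @export
ctp4_profile <- function() {
  fame_profile(c(
    "C16:0" = 24.13,  # palmitic
    "C16:1" = 14.70,  # palmitoleic
    "C18:1" = 25.67,  # oleic
    "C16:2" = 0.44,   # hexadecadienoic
    "C18:2" = 23.17,  # linoleic
    "C16:3" = 9.89,   # hexadecatrienoic
    "C18:3" = 1.23,   # linolenic
    "C20:5" = 0.77    # eicosapentaenoic (EPA)
  ), normalized = TRUE)
}

#' Laboratory-measured fuel properties of CTP4 biodiesel
#'
#' The measured (not composition-derivable) properties of the CTP4
#' biodiesel: FAME content (% m/m), density at 15 degC (kg/L), kinematic
#' viscosity at 40 degC (mm2/s), Rancimat oxidation stability (h),
#' glyceride and glycerol contents (% m/m; several below quantification,
#' recorded as censored `"<x"` bounds), group I/II metals and phosphorus
#' (mg/kg).
#'
#' @return A tibble as returned by [measured_properties()].
#' @examples
#' ctp4_measured()
#' @export
ctp4_measured <- function() {
  measured_properties(list(
    fame_content = 96.72,
    density = 0.85,
    viscosity = 3.64,
    oxidation_stability = 4.74,
    monoglycerides = "<0.1",
    diglycerides = "<0.05",
    triglycerides = "<0.05",
    free_glycerol = "<0.001",
    total_glycerol = "<0.05",
    group1_metals = 0.45,
    group2_metals = 0.05,
    phosphorus = 24.02
  ))
}
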