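# Default model parameterization.
#
# Rate laws are generic reversible-saturable (mm_rev), irreversible
# Michaelis-Menten (mm_irrev) and facilitated carrier forms with the
# allosteric modifiers and phospho-pairs of the liver scheme. Reference
# (fed-state) Vmax values were calibrated against the stationary physiology of
# the rat liver: glucose set points near 6.5 / 7.5 / 9 mM (fed / normal /
# fasted, half-filled store), reference exchange fluxes near -64 umol/g/h
# (fasted, 4 mM) and +81 umol/g/h (fed, 10 mM), and a gluconeogenic plateau of
# 60-70 umol/g/h on lactate titration.
#
# Units: concentrations mM, fluxes umol/g/h, time h.

# umol per g wet weight -> mM (cell-water fraction 0.46 mL/g, density 1.067 g/mL)
TISSUE_TO_MM <- 1.067 / 0.46

#' Default model parameterization
#'
#' Returns the bundled parameter set: species (with compartments, default
#' concentrations and clamp flags), the 32 reactions with rate laws, the
#' glycogen storage capacity and the tissue-unit conversion factor.
#'
#' @return A list with elements \code{species}, \code{reactions},
#'   \code{capacity}, \code{kappa}.
#' @export
default_parameters <- function() {
  sp <- function(id, compartment, conc, clamped = FALSE)
    list(id = id, compartment = compartment, conc = conc, clamped = clamped)

  species <- list(
    # external space (always clamped: plasma is an input, never a state)
    sp("Glc_ext", "external", 5,    TRUE),
    sp("Lac_ext", "external", 1,    TRUE),
    # cytosol, dynamic
    sp("Glc",     "cytosol",  4.5),
    sp("Glc6P",   "cytosol",  0.25),
    sp("Fru6P",   "cytosol",  0.08),
    sp("Fru16P2", "cytosol",  0.03),
    sp("Fru26P2", "cytosol",  0.008),
    sp("DHAP",    "cytosol",  0.15),
    sp("GAP",     "cytosol",  0.007),
    sp("13P2G",   "cytosol",  0.003),
    sp("3PG",     "cytosol",  0.4),
    sp("2PG",     "cytosol",  0.06),
    sp("PEP",     "cytosol",  0.15),
    sp("Pyr",     "cytosol",  0.1),
    sp("Lac",     "cytosol",  1),
    sp("OA",      "cytosol",  0.008),
    sp("Mal",     "cytosol",  0.4),
    sp("Glyc",    "cytosol",  450),
    # endoplasmic reticulum, dynamic
    sp("Glc6P_ER", "ER",      0.2),
    sp("Glc_ER",   "ER",      4.5),
    # mitochondrion, dynamic
    sp("Pyr_mito", "mitochondrion", 0.1),
    sp("OA_mito",  "mitochondrion", 0.005),
    sp("Mal_mito", "mitochondrion", 0.5),
    sp("PEP_mito", "mitochondrion", 0.1),
    # clamped cofactor pools
    sp("ATP",  "cytosol", 2.8,   TRUE),
    sp("ADP",  "cytosol", 0.8,   TRUE),
    sp("NAD",  "cytosol", 0.5,   TRUE),
    sp("NADH", "cytosol", 0.001, TRUE),
    sp("P",    "cytosol", 4,     TRUE),
    sp("GTP",  "cytosol", 0.3,   TRUE),
    sp("GDP",  "cytosol", 0.1,   TRUE),
    sp("UTP",  "cytosol", 0.3,   TRUE),
    sp("UDP",  "cytosol", 0.1,   TRUE),
    sp("GTP_mito", "mitochondrion", 0.3, TRUE),
    sp("GDP_mito", "mitochondrion", 0.1, TRUE),
    # rapid-equilibrium intermediates of the lumped glycogen branch
    sp("Glc1P",   "cytosol", 0.1,  TRUE),
    sp("UDP_Glc", "cytosol", 0.3,  TRUE),
    sp("PP",      "cytosol", 0.01, TRUE)
  )

  st <- function(...) {
    x <- c(...)
    stopifnot(!is.null(names(x)))
    x
  }
  b <- function(id, K, h = NULL) {
    out <- list(id = id, K = K)
    if (!is.null(h)) out$h <- h
    out
  }
  rxn <- function(id, stoich, form, vmax, subs = list(), prods = list(),
                  keq = NULL, allosteric = NULL, pair = NULL, store = NULL,
                  reversible = !(form == "mm_irrev")) {
    list(id = id, stoich = stoich, reversible = reversible,
         law = list(form = form, vmax = vmax, subs = subs, prods = prods,
                    keq = keq, allosteric = allosteric, pair = pair,
                    store = store))
  }

  reactions <- list(
    # -- plasma membrane / ER transport ------------------------------------
    rxn("GlcT", st(Glc_ext = -1, Glc = 1), "carrier", vmax = 600,
        subs = list(b("Glc_ext", 14)), prods = list(b("Glc", 14))),
    rxn("LacT", st(Lac_ext = -1, Lac = 1), "carrier", vmax = 515,
        subs = list(b("Lac_ext", 0.4)), prods = list(b("Lac", 0.4))),
    rxn("GlcT_ER", st(Glc_ER = -1, Glc = 1), "carrier", vmax = 3000,
        subs = list(b("Glc_ER", 30)), prods = list(b("Glc", 30))),
    rxn("G6PT_ER", st(Glc6P = -1, Glc6P_ER = 1), "carrier", vmax = 300,
        subs = list(b("Glc6P", 0.5)), prods = list(b("Glc6P_ER", 0.5))),

    # -- glucose phosphorylation / dephosphorylation -----------------------
    rxn("GK", st(Glc = -1, ATP = -1, Glc6P = 1, ADP = 1), "mm_irrev",
        vmax = 565,
        subs = list(b("Glc", 9, 1.7), b("ATP", 0.6)),
        allosteric = list(allosteric_term("Fru6P", p = 0.35, h = 1,
                                          mode = "inhibitor"))),
    rxn("G6P", st(Glc6P_ER = -1, Glc_ER = 1, P = 1), "mm_irrev", vmax = 67,
        subs = list(b("Glc6P_ER", 0.5))),

    # -- glycolysis / gluconeogenesis core ---------------------------------
    rxn("GPI", st(Glc6P = -1, Fru6P = 1), "mm_rev", vmax = 1500,
        subs = list(b("Glc6P", 0.4)), prods = list(b("Fru6P", 0.12)),
        keq = 0.3),
    rxn("PFK1", st(Fru6P = -1, ATP = -1, Fru16P2 = 1, ADP = 1), "mm_irrev",
        vmax = 300,
        subs = list(b("Fru6P", 0.6, 2), b("ATP", 0.35)),
        allosteric = list(allosteric_term("Fru26P2", p = 0.023, h = 3,
                                          mode = "activator", beta = 12))),
    rxn("FBP1", st(Fru16P2 = -1, Fru6P = 1, P = 1), "mm_irrev", vmax = 1784,
        subs = list(b("Fru16P2", 0.005)),
        allosteric = list(allosteric_term("Fru26P2", p = 0.023, h = 3,
                                          mode = "inhibitor"))),
    rxn("PFK2", st(Fru6P = -1, ATP = -1, Fru26P2 = 1, ADP = 1), "mm_irrev",
        vmax = 6.8,
        subs = list(b("Fru6P", 0.06), b("ATP", 0.3)),
        pair = list(phos = 0.1, dephos = 1)),
    rxn("FBP2", st(Fru26P2 = -1, Fru6P = 1, P = 1), "mm_irrev", vmax = 112,
        subs = list(b("Fru26P2", 0.5)),
        pair = list(phos = 1, dephos = 0.1)),
    rxn("ALD", st(Fru16P2 = -1, DHAP = 1, GAP = 1), "mm_rev", vmax = 1500,
        subs = list(b("Fru16P2", 0.01)),
        prods = list(b("DHAP", 0.3), b("GAP", 0.3)), keq = 0.1),
    rxn("TPI", st(DHAP = -1, GAP = 1), "mm_rev", vmax = 4000,
        subs = list(b("DHAP", 0.5)), prods = list(b("GAP", 0.5)), keq = 0.045),
    rxn("GAPDH", st(GAP = -1, P = -1, NAD = -1, `13P2G` = 1, NADH = 1),
        "mm_rev", vmax = 3000,
        subs = list(b("GAP", 0.1), b("P", 2), b("NAD", 0.05)),
        prods = list(b("13P2G", 0.01), b("NADH", 0.005)), keq = 2e-4),
    rxn("PGK", st(`13P2G` = -1, ADP = -1, `3PG` = 1, ATP = 1), "mm_rev",
        vmax = 3000,
        subs = list(b("13P2G", 0.02), b("ADP", 0.2)),
        prods = list(b("3PG", 0.6), b("ATP", 0.25)), keq = 350),
    rxn("PGM", st(`3PG` = -1, `2PG` = 1), "mm_rev", vmax = 2500,
        subs = list(b("3PG", 0.6)), prods = list(b("2PG", 0.1)), keq = 0.15),
    rxn("EN", st(`2PG` = -1, PEP = 1), "mm_rev", vmax = 2500,
        subs = list(b("2PG", 0.1)), prods = list(b("PEP", 0.3)), keq = 3),
    rxn("PK", st(PEP = -1, ADP = -1, Pyr = 1, ATP = 1), "mm_irrev", vmax = 800,
        subs = list(b("PEP", 0.6, 1.5), b("ADP", 0.3)),
        allosteric = list(allosteric_term("Fru16P2", p = 0.04, h = 1,
                                          mode = "activator", beta = 3)),
        pair = list(phos = 0.15, dephos = 1)),
    rxn("LDH", st(Pyr = -1, NADH = -1, Lac = 1, NAD = 1), "mm_rev",
        vmax = 15000,
        subs = list(b("Pyr", 0.3), b("NADH", 0.002)),
        prods = list(b("Lac", 3), b("NAD", 0.1)), keq = 1.6e3),

    # -- mitochondrial gluconeogenic limb ----------------------------------
    rxn("PyrT", st(Pyr = -1, Pyr_mito = 1), "carrier", vmax = 2000,
        subs = list(b("Pyr", 0.3)), prods = list(b("Pyr_mito", 0.3))),
    rxn("PC", st(Pyr_mito = -1, ATP = -1, OA_mito = 1, ADP = 1, P = 1),
        "mm_irrev", vmax = 176,
        subs = list(b("Pyr_mito", 0.08), b("ATP", 0.5))),
    rxn("MDH_mito", st(OA_mito = -1, NADH = -1, Mal_mito = 1, NAD = 1),
        "mm_rev", vmax = 2000,
        subs = list(b("OA_mito", 0.04), b("NADH", 0.005)),
        prods = list(b("Mal_mito", 1), b("NAD", 0.06)), keq = 5e4),
    rxn("PyrMalT", st(Mal_mito = -1, Pyr = -1, Mal = 1, Pyr_mito = 1),
        "antiport", vmax = 600,
        subs = list(b("Mal_mito", 1), b("Pyr", 0.3)),
        prods = list(b("Mal", 1), b("Pyr_mito", 0.3))),
    rxn("MDH", st(Mal = -1, NAD = -1, OA = 1, NADH = 1), "mm_rev",
        vmax = 2000,
        subs = list(b("Mal", 1), b("NAD", 0.06)),
        prods = list(b("OA", 0.04), b("NADH", 0.005)), keq = 2e-5),
    rxn("PEPCK", st(OA = -1, GTP = -1, PEP = 1, GDP = 1), "mm_irrev",
        vmax = 305,
        subs = list(b("OA", 0.01), b("GTP", 0.1))),
    rxn("PEPCK_mito",
        st(OA_mito = -1, GTP_mito = -1, PEP_mito = 1, GDP_mito = 1),
        "mm_irrev", vmax = 152.5,
        subs = list(b("OA_mito", 0.01), b("GTP_mito", 0.1))),
    rxn("PEPT", st(PEP_mito = -1, PEP = 1), "carrier", vmax = 400,
        subs = list(b("PEP_mito", 0.3)), prods = list(b("PEP", 0.3))),

    # -- glycogen turnover (lumped with the fast Glc1P/UDP-Glc steps) ------
    rxn("GP", st(Glyc = -1, P = -1, Glc6P = 1), "mm_irrev", vmax = 31,
        subs = list(b("P", 1)),
        allosteric = list(allosteric_term("Glc", p = 12, h = 2,
                                          mode = "inhibitor")),
        pair = list(phos = 1, dephos = 0.02),
        store = list(type = "phosphorolysis", Kf = 0.08)),
    rxn("GS", st(Glc6P = -1, UTP = -1, Glyc = 1, UDP = 1, PP = 1), "mm_irrev",
        vmax = 18,
        subs = list(b("Glc6P", 0.6), b("UTP", 0.2)),
        allosteric = list(allosteric_term("Glc6P", p = 0.45, h = 2,
                                          mode = "activator", beta = 6)),
        pair = list(phos = 0.05, dephos = 1),
        store = list(type = "synthesis")),

    # -- nucleoside-diphosphate kinase (clamped nucleotide pools) ----------
    rxn("NDK_GTP", st(ATP = -1, GDP = -1, ADP = 1, GTP = 1), "mm_rev",
        vmax = 100,
        subs = list(b("ATP", 1), b("GDP", 0.1)),
        prods = list(b("ADP", 1), b("GTP", 0.1)), keq = 1),
    rxn("NDK_UTP", st(ATP = -1, UDP = -1, ADP = 1, UTP = 1), "mm_rev",
        vmax = 100,
        subs = list(b("ATP", 1), b("UDP", 0.1)),
        prods = list(b("ADP", 1), b("UTP", 0.1)), keq = 1),
    rxn("NDK_mito_GTP",
        st(ATP = -1, GDP_mito = -1, ADP = 1, GTP_mito = 1), "mm_rev",
        vmax = 100,
        subs = list(b("ATP", 1), b("GDP_mito", 0.1)),
        prods = list(b("ADP", 1), b("GTP_mito", 0.1)), keq = 1)
  )
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")

  list(species = species, reactions = reactions,
       capacity = 900, kappa = TISSUE_TO_MM)
}
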