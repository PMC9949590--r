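## Bundled miniature compartmentalized yeast-like network.
##
## Two compartments (cytosol "c", mitochondrion "m") plus an extracellular
## space "e" and two membranes (plasma, mito). Lumped integer-valued
## stoichiometries are chosen so closed-form oracles exist: glycolysis
## yields 2 ATP + 2 cytosolic NADH per glucose via a DHAP branch point,
## respiration oxidizes mitochondrial NADH at a configurable P/O ratio, and
## the three NAD(H) shuttles (acetaldehyde-ethanol via Adh3,
## malate-oxaloacetate via OAA/H+ symport, glycerol-3-phosphate) are built
## with an explicit mitochondrial proton species so that exporting one
## symported proton costs exactly one ATP at the mitochondrial ATPase.

#' Toy network configuration
#'
#' Defaults define the study conditions of the bundled network; see the
#' methods vignette for the rationale behind each value.
#'
#' @param po_ratio ATP per mitochondrial NADH oxidized (FADH2 yields half).
#' @param gam,ngam maintenance energetics (mmol ATP gDW^-1, mmol ATP
#'   gDW^-1 h^-1).
#' @param protein_content g protein per gDW.
#' @param cap_cytosol,cap_mito compartment proteome caps, g (g protein)^-1.
#' @param membrane_area_plasma total plasma membrane transporter area
#'   (arbitrary units consistent with per-molecule `area` = 1).
#' @param kcat_default,kcat_floor turnover defaults (s^-1) for
#'   [assign_kcats()].
#' @param elongation_rate_aa_s ribosome elongation rate used by the toy's
#'   translation machinery (aa s^-1; toy-scale, slower than the
#'   physiological rate so that translation dominates the functional
#'   proteome budget at toy fluxes).
#' @param min_up_fraction minimal unspecified-protein mass fraction.
#' @param amino_acid_mito_burden mmol mitochondrial NADH produced per mmol
#'   amino acid synthesized (the biosynthetic redox surplus of
#'   mitochondria).
#' @param nadph_per_aa mmol mitochondrial NADPH consumed per mmol amino
#'   acid synthesized.
#' @param biomass_nadh mmol cytosolic NADH released per unit biomass
#'   (lumped anabolic surplus outside amino-acid synthesis).
#' @param ethanol_shuttle_h_leak protons co-imported into the mitochondrion
#'   per acetaldehyde-ethanol shuttle cycle (membrane permeabilization
#'   scenario; 0 = tight membrane).
#' @param include_gut2 include the mitochondrial glycerol-3-phosphate
#'   dehydrogenase (the cytosol-to-mitochondrion leg of the G3P shuttle).
#' @param include_gpd2_mito include the mito-coupled Gpd2 route (consumes
#'   mitochondrial NADH into glycerol; the respiration-independent shuttle
#'   that must be co-deleted with Adh3).
#' @param seed integer; the generator itself is deterministic, the seed is
#'   recorded and used by [make_synthetic_chemostat_data()].
#' @return list of class `toy_config`.
#' @export
toy_config <- function(po_ratio = 1.0, gam = 24, ngam = 1,
                       protein_content = 0.45,
                       cap_cytosol = 0.80, cap_mito = 0.15,
                       membrane_area_plasma = 1e-3,
                       kcat_default = 71, kcat_floor = 1,
                       elongation_rate_aa_s = 3.5,
                       min_up_fraction = 0.22,
                       amino_acid_mito_burden = 0.5,
                       nadph_per_aa = 0.25, biomass_nadh = 0.25,
                       ethanol_shuttle_h_leak = 0,
                       include_gut2 = TRUE, include_gpd2_mito = TRUE,
                       seed = 1L) {
  stopifnot(po_ratio > 0, gam >= 0, ngam >= 0, protein_content > 0,
            protein_content < 1, cap_cytosol > 0, cap_mito > 0,
            amino_acid_mito_burden >= 0, ethanol_shuttle_h_leak >= 0)
  structure(as.list(environment()), class = "toy_config")
}

## metabolite table with carbon and available-electron bookkeeping
toy_metabolites <- function() {
  m <- function(id, name, comp, C, e)
    data.frame(id = id, name = name, compartment = comp, C = C, e = e,
               is_boundary = FALSE, stringsAsFactors = FALSE)
  rbind(
    m("glc_e", "glucose", "e", 6, 24), m("o2_e", "oxygen", "e", 0, -4),
    m("co2_e", "carbon dioxide", "e", 1, 0),
    m("etoh_e", "ethanol", "e", 2, 12), m("glyc_e", "glycerol", "e", 3, 14),
    m("ac_e", "acetate", "e", 2, 8), m("aa_e", "amino acid", "e", 3, 9.5),
    m("erg_e", "ergosterol-like lipid", "e", 2, 8),
    m("ole_e", "oleate-like lipid", "e", 2, 8),
    m("pam_e", "palmitoleate-like lipid", "e", 2, 6),
    m("glc_c", "glucose", "c", 6, 24), m("dhap_c", "DHAP", "c", 3, 12),
    m("pyr_c", "pyruvate", "c", 3, 10),
    m("acald_c", "acetaldehyde", "c", 2, 10),
    m("etoh_c", "ethanol", "c", 2, 12), m("ac_c", "acetate", "c", 2, 8),
    m("accoa_c", "acetyl-CoA", "c", 2, 8), m("coa_c", "coenzyme A", "c", 0, 0),
    m("atp_c", "ATP", "c", 0, 0), m("adp_c", "ADP", "c", 0, 0),
    m("amp_c", "AMP", "c", 0, 0),
    m("nad_c", "NAD+", "c", 0, 0), m("nadh_c", "NADH", "c", 0, 2),
    m("oaa_c", "oxaloacetate", "c", 4, 10), m("mal_c", "malate", "c", 4, 12),
    m("g3p_c", "glycerol 3-phosphate", "c", 3, 14),
    m("glyc_c", "glycerol", "c", 3, 14), m("aa_c", "amino acid", "c", 3, 9.5),
    m("carb_c", "carbohydrate precursor", "c", 6, 24),
    m("lip_c", "lipid precursor", "c", 8, 30),
    m("erg_c", "ergosterol-like lipid", "c", 2, 8),
    m("ole_c", "oleate-like lipid", "c", 2, 8),
    m("pam_c", "palmitoleate-like lipid", "c", 2, 6),
    m("o2_c", "oxygen", "c", 0, -4), m("co2_c", "carbon dioxide", "c", 1, 0),
    m("h_c", "proton", "c", 0, 0),
    m("pyr_m", "pyruvate", "m", 3, 10),
    m("acald_m", "acetaldehyde", "m", 2, 10),
    m("etoh_m", "ethanol", "m", 2, 12), m("ac_m", "acetate", "m", 2, 8),
    m("accoa_m", "acetyl-CoA", "m", 2, 8),
    m("coa_m", "coenzyme A", "m", 0, 0),
    m("oaa_m", "oxaloacetate", "m", 4, 10), m("mal_m", "malate", "m", 4, 12),
    m("succ_m", "succinate", "m", 4, 14),
    m("succoa_m", "succinyl-CoA", "m", 4, 14),
    m("atp_m", "ATP", "m", 0, 0), m("adp_m", "ADP", "m", 0, 0),
    m("nad_m", "NAD+", "m", 0, 0), m("nadh_m", "NADH", "m", 0, 2),
    m("nadp_m", "NADP+", "m", 0, 0), m("nadph_m", "NADPH", "m", 0, 2),
    m("fad_m", "FAD", "m", 0, 0), m("fadh2_m", "FADH2", "m", 0, 2),
    m("o2_m", "oxygen", "m", 0, -4), m("co2_m", "carbon dioxide", "m", 1, 0),
    m("h_m", "proton", "m", 0, 0))
}

## protein roster: id, mw (kDa), compartment, kcat fwd (s^-1), transporter
## metadata. Lengths follow mw at 0.11 kDa per residue.
toy_proteins <- function() {
  p <- function(id, mw, comp, transporter = "", membrane = "")
    data.frame(id = id, length = round(mw / 0.11), mw = mw,
               compartment = comp, is_transporter = nzchar(transporter),
               membrane = membrane, transporter_class = transporter,
               area = 1, stringsAsFactors = FALSE)
  rbind(
    p("Hxt1", 60, "c", "carbon", "plasma"), p("Gap1", 65, "c", "nitrogen",
                                              "plasma"),
    p("Pfk1", 110, "c"), p("Pyk1", 55, "c"), p("Pdc1", 60, "c"),
    p("Adh1", 40, "c"), p("Ald6", 55, "c"), p("Acs1", 75, "c"),
    p("Adk1", 25, "c"), p("Pyc1", 130, "c"), p("Mdh2", 35, "c"),
    p("Gpd1", 45, "c"), p("Gpp1", 30, "c"), p("Psa1", 55, "c"),
    p("Fas1", 230, "c"), p("Are1", 70, "c"),
    p("Dic1", 35, "m", "", "mito"), p("Oac1", 35, "m", "", "mito"),
    p("Mpc1", 30, "m", "", "mito"), p("Aac2", 35, "m", "", "mito"),
    p("Cat2", 65, "m", "", "mito"),
    p("Mdh1", 35, "m"), p("Pda1", 100, "m"), p("Cit1", 160, "m"),
    p("Idp1", 120, "m"), p("Cox1", 400, "m"), p("Sdh1", 260, "m"),
    p("Atp1", 120, "m"), p("Adh3", 40, "m"), p("Ach1", 60, "m"),
    p("Lsc1", 70, "m"), p("Mae1", 75, "m"), p("Gut2", 70, "m"),
    p("Gpd2", 45, "m"), p("Aro1", 150, "m"), p("Pos5", 46, "m"))
}

#' Generate the bundled toy yeast-like model
#'
#' @param cfg a [toy_config()].
#' @return list of class `toy_model` with elements `gem` (the
#'   [gem_model()]), `proteins`, `rules` (kcats already resolved),
#'   `profiles` (named list of capacity/parameter profiles:
#'   `aerobic_minimal`, `aerobic_rich`, `anaerobic`), `elements`
#'   (per-metabolite carbon/electron table), `shuttles` (reaction-id sets
#'   per redox shuttle) and `config`.
#' @export
make_toy_yeast <- function(cfg = toy_config()) {
  met <- toy_metabolites()
  h <- cfg$ethanol_shuttle_h_leak

  rx <- list()
  add <- function(id, stoich, rev = FALSE, protein = NULL, kcat = NA,
                  kcat_rev = NA, exchange = FALSE, lb = NULL, ub = 1000) {
    rx[[id]] <<- list(id = id, stoich = stoich,
                      lb = if (!is.null(lb)) lb else if (rev) -1000 else 0,
                      ub = ub, is_exchange = exchange,
                      gene_association = if (is.null(protein)) character()
                        else paste0("cx_", id),
                      protein = protein, kcat = kcat, kcat_rev = kcat_rev)
  }
  st <- function(...) {
    v <- c(...)
    setNames(as.numeric(v), names(v))
  }

  ## transport and glycolysis
  add("HXT", st(glc_e = -1, glc_c = 1), protein = "Hxt1", kcat = 50)
  add("GLYC1", st(glc_c = -1, dhap_c = 2), protein = "Pfk1", kcat = 10)
  add("GLYC2", st(dhap_c = -1, adp_c = -1, nad_c = -1, pyr_c = 1,
                  atp_c = 1, nadh_c = 1), protein = "Pyk1", kcat = 10)
  ## fermentation and the PDH bypass
  add("PDC", st(pyr_c = -1, acald_c = 1, co2_c = 1), protein = "Pdc1",
      kcat = 10)
  add("ADH", st(acald_c = -1, nadh_c = -1, etoh_c = 1, nad_c = 1),
      rev = TRUE, protein = "Adh1", kcat = 12, kcat_rev = 12)
  add("ALD", st(acald_c = -1, nad_c = -1, ac_c = 1, nadh_c = 1),
      protein = "Ald6", kcat = 20)
  add("ACS", st(ac_c = -1, coa_c = -1, atp_c = -1, accoa_c = 1, amp_c = 1),
      protein = "Acs1", kcat = 15)
  add("ADK", st(amp_c = -1, atp_c = -1, adp_c = 2), rev = TRUE,
      protein = "Adk1", kcat = 100, kcat_rev = 100)
  ## anaplerosis and the malate-oxaloacetate shuttle
  add("PYC", st(pyr_c = -1, atp_c = -1, co2_c = -1, oaa_c = 1, adp_c = 1),
      protein = "Pyc1", kcat = 20)
  add("MDHc", st(oaa_c = -1, nadh_c = -1, mal_c = 1, nad_c = 1),
      rev = TRUE, protein = "Mdh2", kcat = 30, kcat_rev = 30)
  add("MALt", st(mal_c = -1, mal_m = 1), rev = TRUE, protein = "Dic1",
      kcat = 30, kcat_rev = 30)
  add("OAAt", st(oaa_c = -1, h_c = -1, oaa_m = 1, h_m = 1), rev = TRUE,
      protein = "Oac1", kcat = 30, kcat_rev = 30)
  add("MDHm", st(oaa_m = -1, nadh_m = -1, mal_m = 1, nad_m = 1),
      rev = TRUE, protein = "Mdh1", kcat = 30, kcat_rev = 30)
  ## mitochondrial carbon metabolism
  add("PYRt", st(pyr_c = -1, pyr_m = 1), rev = TRUE, protein = "Mpc1",
      kcat = 50, kcat_rev = 50)
  add("PDH", st(pyr_m = -1, coa_m = -1, nad_m = -1, accoa_m = 1,
                co2_m = 1, nadh_m = 1), protein = "Pda1", kcat = 15)
  add("TCA", st(accoa_m = -1, nad_m = -3, fad_m = -1, co2_m = 2,
                nadh_m = 3, fadh2_m = 1, coa_m = 1), protein = "Cit1",
      kcat = 6)
  add("IDP", st(accoa_m = -1, nad_m = -2, nadp_m = -1, fad_m = -1,
                co2_m = 2, nadh_m = 2, nadph_m = 1, fadh2_m = 1,
                coa_m = 1), protein = "Idp1", kcat = 6)
  add("OXPN", st(nadh_m = -1, o2_m = -0.5, adp_m = -cfg$po_ratio,
                 nad_m = 1, atp_m = cfg$po_ratio), protein = "Cox1",
      kcat = 20)
  add("OXPF", st(fadh2_m = -1, o2_m = -0.5, adp_m = -cfg$po_ratio / 2,
                 fad_m = 1, atp_m = cfg$po_ratio / 2), protein = "Sdh1",
      kcat = 20)
  add("ANT", st(atp_c = -1, adp_m = -1, atp_m = 1, adp_c = 1), rev = TRUE,
      protein = "Aac2", kcat = 80, kcat_rev = 80)
  ## proton export: one ATP per proton pumped out of the mitochondrion
  add("ATPASE", st(atp_m = -1, h_m = -1, adp_m = 1, h_c = 1),
      protein = "Atp1", kcat = 60)
  ## acetaldehyde-ethanol shuttle (Adh3), with optional proton leak
  adh3 <- st(acald_m = -1, nadh_m = -1, etoh_m = 1, nad_m = 1)
  if (h > 0) adh3 <- c(adh3, st(h_c = -h, h_m = h))
  add("ADH3", adh3, protein = "Adh3", kcat = 40)
  add("ACALDt", st(acald_c = -1, acald_m = 1), rev = TRUE)
  add("ETOHtm", st(etoh_c = -1, etoh_m = 1), rev = TRUE)
  ## carnitine shuttle + CoA transferase + succinyl-CoA ligase
  add("CARN", st(accoa_c = -1, coa_m = -1, accoa_m = 1, coa_c = 1),
      rev = TRUE, protein = "Cat2", kcat = 20, kcat_rev = 20)
  add("COAT", st(succ_m = -1, accoa_m = -1, succoa_m = 1, ac_m = 1),
      rev = TRUE, protein = "Ach1", kcat = 4, kcat_rev = 4)
  add("SCL", st(succoa_m = -1, adp_m = -1, succ_m = 1, coa_m = 1,
                atp_m = 1), rev = TRUE, protein = "Lsc1", kcat = 4,
      kcat_rev = 4)
  add("MAE", st(mal_m = -1, nadp_m = -1, pyr_m = 1, co2_m = 1,
                nadph_m = 1), protein = "Mae1", kcat = 15)
  add("POS5", st(nadh_m = -1, atp_m = -1, nadp_m = -1, nadph_m = 1,
                 nad_m = 1, adp_m = 1), protein = "Pos5", kcat = 2)
  ## glycerol shunt and G3P shuttle
  add("GPD1", st(dhap_c = -1, nadh_c = -1, g3p_c = 1, nad_c = 1),
      protein = "Gpd1", kcat = 30)
  if (cfg$include_gpd2_mito)
    add("GPD2M", st(dhap_c = -1, nadh_m = -1, g3p_c = 1, nad_m = 1),
        protein = "Gpd2", kcat = 30)
  if (cfg$include_gut2)
    add("GUT2", st(g3p_c = -1, fad_m = -1, dhap_c = 1, fadh2_m = 1),
        protein = "Gut2", kcat = 20)
  add("GPP", st(g3p_c = -1, glyc_c = 1), protein = "Gpp1", kcat = 40)
  add("ACtm", st(ac_c = -1, ac_m = 1), rev = TRUE)
  ## biosynthesis
  add("AAS", st(pyr_m = -1, nadph_m = -cfg$nadph_per_aa,
                nad_m = -cfg$amino_acid_mito_burden, atp_c = -2,
                aa_c = 1, nadh_m = cfg$amino_acid_mito_burden,
                nadp_m = cfg$nadph_per_aa, adp_c = 2),
      protein = "Aro1", kcat = 6)
  add("CARB", st(glc_c = -1, atp_c = -1, carb_c = 1, adp_c = 1),
      protein = "Psa1", kcat = 20)
  add("LIPS", st(accoa_c = -4, o2_c = -0.5, atp_c = -1, lip_c = 1,
                 coa_c = 4, adp_c = 1), protein = "Fas1", kcat = 5)
  add("LIPANA", st(erg_c = -1, ole_c = -1, pam_c = -1, accoa_c = -1,
                   atp_c = -1, lip_c = 1, coa_c = 1, adp_c = 1),
      protein = "Are1", kcat = 10)
  ## maintenance and biomass (GAM ATP is added at assembly)
  add("ATPM", st(atp_c = -1, adp_c = 1))
  add("BIOMASS", st(aa_c = -0.2, carb_c = -2, lip_c = -0.05,
                    nad_c = -cfg$biomass_nadh, nadh_c = cfg$biomass_nadh))
  ## small-molecule transport and exchanges
  add("O2t", st(o2_e = -1, o2_c = 1))
  add("O2tm", st(o2_c = -1, o2_m = 1), rev = TRUE)
  add("CO2tm", st(co2_m = -1, co2_c = 1), rev = TRUE)
  add("CO2t", st(co2_c = -1, co2_e = 1), rev = TRUE)
  add("ETOHt", st(etoh_c = -1, etoh_e = 1), rev = TRUE)
  add("GLYCt", st(glyc_c = -1, glyc_e = 1))
  add("ACt", st(ac_c = -1, ac_e = 1), rev = TRUE)
  add("AAt", st(aa_e = -1, aa_c = 1), protein = "Gap1", kcat = 30)
  add("ERGt", st(erg_e = -1, erg_c = 1))
  add("OLEt", st(ole_e = -1, ole_c = 1))
  add("PAMt", st(pam_e = -1, pam_c = 1))
  for (ex in c("glc", "o2", "co2", "etoh", "glyc", "ac", "aa", "erg",
               "ole", "pam"))
    add(paste0("EX_", ex), st(setNames(-1, paste0(ex, "_e"))),
        exchange = TRUE, lb = 0)

  proteins <- toy_proteins()
  rules <- list()
  for (r in rx) {
    if (!is.null(r$protein)) {
      rules[[length(rules) + 1L]] <- list(
        reaction_id = r$id, complex = setNames(1, r$protein),
        complex_id = paste0("cx_", r$id),
        kcat_fwd = r$kcat, kcat_rev = r$kcat_rev)
    }
  }
  rules <- assign_kcats(rules, cfg$kcat_default, cfg$kcat_floor)
  reactions <- lapply(rx, function(r)
    r[c("id", "stoich", "lb", "ub", "is_exchange", "gene_association")])

  compartments <- data.frame(
    id = c("e", "c", "m", "plasma", "mito"),
    name = c("extracellular", "cytosol", "mitochondrion",
             "plasma membrane", "mitochondrial membrane"),
    membrane = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)

  gem <- gem_model(met[, c("id", "name", "compartment", "is_boundary")],
                   reactions, compartments,
                   biomass_reaction_id = "BIOMASS",
                   protein_content = cfg$protein_content)

  profiles <- toy_profiles(cfg)
  shuttles <- list(
    acetaldehyde_ethanol = c("ADH3"),
    malate_oaa = c("MDHm", "MALt", "OAAt", "MDHc"),
    g3p = if (cfg$include_gut2) c("GPD1", "GUT2") else character())

  structure(list(gem = gem, proteins = proteins, rules = rules,
                 profiles = profiles,
                 elements = met[, c("id", "C", "e")],
                 shuttles = shuttles, config = cfg),
            class = "toy_model")
}

#' @export
print.toy_model <- function(x, ...) {
  cat("toy_model:", length(x$gem$reactions), "reactions,",
      nrow(x$gem$metabolites), "metabolites,", nrow(x$proteins),
      "proteins; profiles:", paste(names(x$profiles), collapse = ", "),
      "\n")
  invisible(x)
}

## plasma membrane transporter area caps per condition (percent of the
## membrane area available to carbon / nitrogen transporters), plus the
## per-condition maintenance and minimal-UP settings.
toy_profiles <- function(cfg) {
  prof <- function(carbon, nitrogen, gam, min_up) {
    list(membrane_caps = c(carbon = carbon / 100, nitrogen = nitrogen / 100),
         cap_cytosol = cfg$cap_cytosol, cap_mito = cfg$cap_mito,
         gam = gam, min_up = min_up)
  }
  list(aerobic_minimal = prof(11.0, 4.5, cfg$gam, cfg$min_up_fraction),
       aerobic_rich = prof(13.0, 5.5, cfg$gam, cfg$min_up_fraction),
       anaerobic = prof(13.0, 4.5, 40, 0.32))
}

#' Assemble a proteome-constrained model from a toy model
#'
#' Convenience wrapper wiring the toy network, its protein roster and a
#' named capacity profile into [build_pc_model()].
#'
#' @param toy a `toy_model` from [make_toy_yeast()].
#' @param profile profile name (`"aerobic_minimal"`, `"aerobic_rich"`,
#'   `"anaerobic"`).
#' @param gam,ngam,min_up optional overrides of the profile values.
#' @return a `pc_model`.
#' @export
toy_pc_model <- function(toy, profile = "aerobic_minimal", gam = NULL,
                         ngam = NULL, min_up = NULL) {
  pr <- toy$profiles[[profile]]
  if (is.null(pr)) stop("unknown profile '", profile, "'")
  cfg <- toy$config
  trn <- translation_params(elongation_rate_aa_s = cfg$elongation_rate_aa_s,
                            min_up_fraction = min_up %||% pr$min_up,
                            aa_metabolite = "aa_c",
                            atp_metabolite = "atp_c",
                            adp_metabolite = "adp_c")
  en <- energy_params(gam = gam %||% pr$gam, ngam = ngam %||% cfg$ngam)
  caps <- list(
    capacity_constraint("compartment_proteome", "c", pr$cap_cytosol),
    capacity_constraint("compartment_proteome", "m", pr$cap_mito),
    capacity_constraint("membrane_area", "plasma",
                        pr$membrane_caps[["carbon"]], "carbon"),
    capacity_constraint("membrane_area", "plasma",
                        pr$membrane_caps[["nitrogen"]], "nitrogen"))
  build_pc_model(toy$gem, toy$proteins, toy$rules, trn, en, caps,
                 membrane_area = c(plasma = cfg$membrane_area_plasma,
                                   mito = 1))
}

#' Standard toy media
#'
#' @param toy a `toy_model`.
#' @param condition `"aerobic_minimal"`, `"aerobic_rich"`, `"anaerobic"`
#'   (anaerobic is minimal medium with the oxygen exchange closed and trace
#'   lipids provided, see [set_anaerobic()]).
#' @param f_sat_glucose optional glucose transporter saturation factor.
#' @param aa_bound upper uptake bound (mmol gDW^-1 h^-1) for the lumped
#'   amino acid exchange in rich media.
#' @return a `medium_def`.
#' @export
toy_medium <- function(toy, condition = "aerobic_minimal",
                       f_sat_glucose = NULL, aa_bound = 5) {
  eb <- list(EX_glc = c(-1000, 1000), EX_o2 = c(-1000, 1000))
  if (condition == "aerobic_rich") eb$EX_aa <- c(-aa_bound, 0)
  fs <- numeric()
  if (!is.null(f_sat_glucose)) fs["Hxt1"] <- f_sat_glucose
  med <- medium(eb, fs, name = condition, limiting_exchange = "EX_glc")
  if (condition == "anaerobic") med <- set_anaerobic(med)
  med
}

#' Check elemental bookkeeping of the toy network
#'
#' Verifies that every non-exchange, non-biomass reaction conserves carbon
#' and available electrons according to the generator's element table.
#'
#' @param toy a `toy_model`.
#' @return data.frame of reaction, carbon imbalance, electron imbalance.
#' @export
check_element_balance <- function(toy) {
  el <- toy$elements
  C <- setNames(el$C, el$id); E <- setNames(el$e, el$id)
  rows <- lapply(toy$gem$reactions, function(r) {
    if (isTRUE(r$is_exchange) || r$id == toy$gem$biomass_reaction_id)
      return(NULL)
    data.frame(reaction = r$id,
               carbon = sum(r$stoich * C[names(r$stoich)]),
               electrons = sum(r$stoich * E[names(r$stoich)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the toy bundle to a directory
#'
#' Emits the model in both dialects, the protein table, the capacity
#' profiles (YAML) and the three standard media.
#'
#' @param toy a `toy_model`.
#' @param dir output directory (created if missing).
#' @export
write_toy_dir <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gem(toy$gem, file.path(dir, "toy_model.tsv"), "tabular")
  write_gem(toy$gem, file.path(dir, "toy_model.xml"), "sbml")
  write_protein_table(toy$proteins, toy$rules,
                      file.path(dir, "toy_proteins.tsv"))
  yaml::write_yaml(toy$profiles, file.path(dir, "toy_profiles.yaml"))
  for (cond in c("aerobic_minimal", "aerobic_rich", "anaerobic"))
    write_medium(toy_medium(toy, cond),
                 file.path(dir, paste0("medium_", cond, ".tsv")))
  invisible(dir)
}

#' Generate a synthetic chemostat dataset
#'
#' Sweeps the glucose transporter saturation factor at a known
#' (generating) GAM and perturbs each exchange flux with multiplicative
#' lognormal noise of the given coefficient of variation. With
#' `noise_cv = 0` the data reproduce the model curve exactly.
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param gam_true generating GAM value, mmol ATP gDW^-1.
#' @param f_sat_grid increasing saturation factors in (0, 1].
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @param path optional TSV output path.
#' @return data.frame with columns `D_h`, `q_glc`, `q_etoh`,
#'   `q_glycerol`, `q_o2`, `q_co2`.
#' @export
make_synthetic_chemostat_data <- function(pc, medium, gam_true,
                                          f_sat_grid, noise_cv = 0,
                                          seed = 1L, path = NULL) {
  stopifnot(noise_cv >= 0)
  curve <- chemostat_sweep(set_gam(pc, gam_true), medium, f_sat_grid)
  pts <- curve$points[!vapply(curve$points, is.null, TRUE)]
  tab <- do.call(rbind, lapply(pts, function(p) {
    data.frame(D_h = p$physiology$mu, q_glc = p$physiology$q_glc,
               q_etoh = p$physiology$q_etoh,
               q_glycerol = p$physiology$q_glycerol,
               q_o2 = p$physiology$q_o2, q_co2 = p$physiology$q_co2)
  }))
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    for (col in c("q_glc", "q_etoh", "q_glycerol", "q_o2", "q_co2")) {
      fac <- exp(stats::rnorm(nrow(tab), -sdlog^2 / 2, sdlog))
      tab[[col]] <- tab[[col]] * fac
    }
  }
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
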