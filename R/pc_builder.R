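## Assembly of the proteome-constrained model object: enzyme variables and
## synthesis/dilution balances, kcat capacity couplings, translation
## machinery, the unspecified protein (UP), compartment/membrane capacity
## constraints and maintenance energetics. The numerical LP is assembled
## per growth rate in lp_engine.R; this file owns the model description.

#' Resolve turnover numbers
#'
#' Applies the default-and-floor policy: an unset kcat becomes
#' `default_kcat` (71 s^-1); a measured value below `floor_kcat` (1 s^-1) is
#' raised to the floor when `apply_floor` is `TRUE`. Values at or above the
#' floor pass through unchanged. Deterministic and order-independent.
#'
#' The floor implements one reading of an ambiguous curation rule for
#' sub-1 s^-1 measurements; set `apply_floor = FALSE` to keep measured
#' values untouched instead.
#'
#' @param rules list of catalysis rules (see [read_protein_table()]).
#' @param default_kcat s^-1, used where no measurement exists.
#' @param floor_kcat s^-1, lower clamp for measured values.
#' @param apply_floor apply the clamp (default) or keep sub-floor values.
#' @return the rules with `kcat_fwd`/`kcat_rev` resolved (reverse defaults
#'   to forward when unset).
#' @export
assign_kcats <- function(rules, default_kcat = 71, floor_kcat = 1,
                         apply_floor = TRUE) {
  stopifnot(default_kcat > 0, floor_kcat > 0)
  resolve <- function(k) {
    if (is.na(k)) return(default_kcat)
    if (k <= 0) stop("assign_kcats: nonpositive measured kcat")
    if (apply_floor && k < floor_kcat) return(floor_kcat)
    k
  }
  lapply(rules, function(rule) {
    rule$kcat_fwd <- resolve(rule$kcat_fwd)
    rule$kcat_rev <- if (is.na(rule$kcat_rev)) rule$kcat_fwd
      else resolve(rule$kcat_rev)
    rule
  })
}

#' Translation machinery parameters
#'
#' @param elongation_rate_aa_s amino acids polymerized per second per
#'   ribosome.
#' @param ribosome_length,ribosome_mw length (aa) and mass (kDa) of the
#'   lumped ribosome pseudo-protein.
#' @param atp_per_peptide_bond mmol ATP hydrolyzed per mmol amino acid
#'   polymerized (charging + elongation, lumped).
#' @param up_length,up_mw length and mass of the unspecified protein (UP),
#'   an artificial near-average-composition protein representing
#'   metabolically inactive proteome. Its residues-per-mass ratio is set
#'   marginally below that of the real proteins so that slack proteome is
#'   always attributed to UP rather than to an arbitrary enzyme (a
#'   tie-break of the closure equality; see the methods vignette).
#' @param min_up_fraction minimal UP mass fraction, g UP (g protein)^-1.
#' @param aa_metabolite,atp_metabolite,adp_metabolite metabolite ids the
#'   translation drains act on (`NULL` disables a drain).
#' @return list of class `translation_params`.
#' @export
translation_params <- function(elongation_rate_aa_s = 10,
                               ribosome_length = 12000, ribosome_mw = 1320,
                               atp_per_peptide_bond = 4.3,
                               up_length = 396, up_mw = 44,
                               min_up_fraction = 0.22,
                               aa_metabolite = NULL, atp_metabolite = NULL,
                               adp_metabolite = NULL) {
  stopifnot(elongation_rate_aa_s > 0, ribosome_length > 0, ribosome_mw > 0,
            atp_per_peptide_bond > 0, up_length > 0, up_mw > 0,
            min_up_fraction >= 0, min_up_fraction < 1)
  structure(list(elongation_rate_aa_s = elongation_rate_aa_s,
                 ribosome_length = ribosome_length, ribosome_mw = ribosome_mw,
                 atp_per_peptide_bond = atp_per_peptide_bond,
                 up_length = up_length, up_mw = up_mw,
                 min_up_fraction = min_up_fraction,
                 aa_metabolite = aa_metabolite,
                 atp_metabolite = atp_metabolite,
                 adp_metabolite = adp_metabolite),
            class = "translation_params")
}

#' Maintenance energetics
#'
#' @param gam growth-associated maintenance, mmol ATP gDW^-1 hydrolyzed per
#'   unit biomass formed (added to the biomass reaction at assembly).
#' @param ngam non-growth-associated maintenance, mmol ATP gDW^-1 h^-1,
#'   enforced as the lower bound of the maintenance reaction.
#' @param atp_metabolite,adp_metabolite ids carrying the GAM drain.
#' @param ngam_reaction id of the ATP-hydrolysis maintenance reaction.
#' @return list of class `energy_params`.
#' @export
energy_params <- function(gam = 24, ngam = 1,
                          atp_metabolite = "atp_c", adp_metabolite = "adp_c",
                          ngam_reaction = "ATPM") {
  stopifnot(gam >= 0, ngam >= 0)
  structure(list(gam = gam, ngam = ngam, atp_metabolite = atp_metabolite,
                 adp_metabolite = adp_metabolite,
                 ngam_reaction = ngam_reaction),
            class = "energy_params")
}

#' Capacity constraint definition
#'
#' @param kind `"compartment_proteome"` (cap on the summed mass fraction of
#'   proteins located in a compartment) or `"membrane_area"` (cap on the
#'   summed per-molecule area of a transporter class in a membrane).
#' @param target compartment id (proteome cap) or membrane id (area cap).
#' @param cap fraction in (0, 1]: g (g protein)^-1 for proteome caps, or
#'   fraction of the membrane's total area for transporter caps.
#' @param member_filter for membrane caps, the `transporter_class` of the
#'   proteins the cap applies to (e.g. `"carbon"`); ignored for
#'   compartment caps.
#' @return list of class `capacity_def`.
#' @export
capacity_constraint <- function(kind = c("compartment_proteome",
                                         "membrane_area"),
                                target, cap, member_filter = NULL) {
  kind <- match.arg(kind)
  stopifnot(cap > 0, cap <= 1)
  structure(list(kind = kind, target = target, cap = cap,
                 member_filter = member_filter),
            class = "capacity_def")
}

capacity_name <- function(cc) {
  if (cc$kind == "compartment_proteome")
    sprintf("capacity_compartment_%s", cc$target)
  else sprintf("capacity_membrane_%s_%s", cc$target,
               cc$member_filter %||% "all")
}

#' Assemble a proteome-constrained model
#'
#' Combines a stoichiometric model with protein properties, catalysis rules
#' (turnover couplings), translation machinery, maintenance energetics and
#' capacity constraints into a single object that [feasible()],
#' [solve_at_mu()] and [maximize_growth()] consume. Two pseudo-proteins are
#' added: the ribosome (`RIBOSOME`) and the unspecified protein (`UP`).
#'
#' At a fixed growth rate mu the assembled system is linear: per protein an
#' abundance variable c_p (mmol gDW^-1) with balance
#' `synthesis - mu * c_p = 0`; per catalyzed reaction direction a capacity
#' coupling `v <= sum(kcat * 3600 * allocation)` with shared enzymes
#' allocatable across their reactions; a translation capacity
#' `sum(length_p * synthesis_p) <= elongation_rate * 3600 * c_ribosome`;
#' an ATP drain per peptide bond; proteome closure
#' `sum(mw_p c_p) = protein_content`; the UP minimum; compartment and
#' membrane capacity caps; GAM added to the biomass reaction and NGAM as a
#' fixed hydrolysis flux.
#'
#' @param gem a `gem_model`.
#' @param proteins protein data.frame (see [read_protein_table()]).
#' @param rules catalysis rules with resolved kcats ([assign_kcats()]).
#' @param translation a `translation_params`.
#' @param energy an `energy_params`.
#' @param capacities list of `capacity_def`.
#' @param membrane_area named numeric: total area per membrane id
#'   (arbitrary units consistent with the proteins' `area` column).
#' @return object of class `pc_model`.
#' @export
build_pc_model <- function(gem, proteins, rules, translation, energy,
                           capacities = list(),
                           membrane_area = c(plasma = 1, mito = 1)) {
  rxn_ids <- vapply(gem$reactions, `[[`, "", "id")
  for (rule in rules) {
    if (!rule$reaction_id %in% rxn_ids)
      stop("catalysis rule references missing reaction '",
           rule$reaction_id, "'")
    missing <- setdiff(names(rule$complex), proteins$id)
    if (length(missing))
      stop("catalysis rule for '", rule$reaction_id,
           "' references unknown protein '", missing[1], "'")
    if (!is.na(rule$kcat_fwd) && rule$kcat_fwd <= 0)
      stop("nonpositive kcat for reaction '", rule$reaction_id, "'")
  }
  ## pseudo-proteins: ribosome (cytosolic) and UP (no compartment cap
  ## membership: it is metabolically inactive)
  pseudo <- data.frame(
    id = c("RIBOSOME", "UP"),
    length = c(translation$ribosome_length, translation$up_length),
    mw = c(translation$ribosome_mw, translation$up_mw),
    compartment = c("c", ""),
    is_transporter = FALSE, membrane = "", transporter_class = "",
    area = 1, stringsAsFactors = FALSE)
  keep <- setdiff(names(proteins),
                  c("id", "length", "mw", "compartment", "is_transporter",
                    "membrane", "transporter_class", "area"))
  prot <- rbind(proteins[, names(pseudo)], pseudo)
  rownames(prot) <- NULL

  for (cc in capacities) {
    if (cc$kind == "membrane_area") {
      hits <- prot$is_transporter & prot$membrane == cc$target &
        (is.null(cc$member_filter) |
           prot$transporter_class == cc$member_filter)
      if (!any(hits))
        stop("membrane capacity '", capacity_name(cc),
             "' resolves to no protein")
    } else {
      if (!any(prot$compartment == cc$target & prot$id != "UP"))
        stop("compartment capacity '", capacity_name(cc),
             "' resolves to no protein")
    }
  }

  pc <- structure(list(gem = gem, proteins = prot, rules = rules,
                       translation = translation, energy = energy,
                       capacities = capacities,
                       membrane_area = membrane_area,
                       knockouts = character()),
                  class = "pc_model")
  pc$registry <- pc_registry(pc)
  pc
}

#' @export
print.pc_model <- function(x, ...) {
  cat("pc_model:", length(x$gem$reactions), "reactions,",
      nrow(x$proteins), "proteins (incl. RIBOSOME, UP),",
      length(x$rules), "catalysis rules\n")
  cat("  GAM", x$energy$gam, "mmol/gDW | NGAM", x$energy$ngam,
      "mmol/gDW/h | min UP", x$translation$min_up_fraction,
      "g/(g protein)\n")
  if (length(x$knockouts))
    cat("  knockouts:", paste(x$knockouts, collapse = ", "), "\n")
  invisible(x)
}

## Stable names for variables and constraints of the assembled system.
pc_registry <- function(pc) {
  rxn <- pc$gem$reactions
  rids <- vapply(rxn, `[[`, "", "id")
  rev <- vapply(rxn, function(r) r$lb < 0, TRUE)
  vars <- c(sprintf("v_%s_f", rids),
            sprintf("v_%s_r", rids[rev]),
            sprintf("c_%s", pc$proteins$id),
            sprintf("syn_%s", pc$proteins$id))
  cons <- c(sprintf("mass_%s",
                    pc$gem$metabolites$id[!pc$gem$metabolites$is_boundary]),
            sprintf("protein_balance_%s", pc$proteins$id),
            "translation_capacity", "proteome_closure", "up_minimum",
            vapply(pc$capacities, capacity_name, ""))
  list(variables = vars, constraints = cons)
}

#' Update global model parameters
#'
#' `set_gam()`, `set_ngam()` and `set_min_up()` return an updated copy of
#' the model with all other coefficients untouched; repeated calls are
#' last-write-wins.
#'
#' @param pc a `pc_model`.
#' @param gam,ngam,fraction new parameter value (see [energy_params()],
#'   [translation_params()]).
#' @return the updated `pc_model`.
#' @export
set_gam <- function(pc, gam) {
  stopifnot(gam >= 0)
  pc$energy$gam <- gam
  pc
}

#' @rdname set_gam
#' @export
set_ngam <- function(pc, ngam) {
  stopifnot(ngam >= 0)
  pc$energy$ngam <- ngam
  pc
}

#' @rdname set_gam
#' @export
set_min_up <- function(pc, fraction) {
  if (fraction < 0 || fraction >= 1)
    stop("min UP fraction must lie in [0, 1): a value of 1 would exclude ",
         "the whole functional proteome")
  pc$translation$min_up_fraction <- fraction
  pc
}
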