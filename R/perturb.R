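## Genotype and environment perturbations: knockouts, compartment capacity
## scaling (the Hap4 overexpression/deletion surrogate), anaerobic medium
## setup, and amino-acid uptake bounds from depletion series.

#' Delete proteins from the model
#'
#' Fixes the abundance variables of the listed proteins to zero, so every
#' reaction they catalyze carries zero flux. Composable: repeated calls
#' accumulate.
#'
#' @param pc a `pc_model`.
#' @param protein_ids character vector of protein ids.
#' @return the updated `pc_model`.
#' @export
knockout <- function(pc, protein_ids) {
  unknown <- setdiff(protein_ids, pc$proteins$id)
  if (length(unknown))
    stop("unknown protein id(s): ", paste(unknown, collapse = ", "))
  pc$knockouts <- union(pc$knockouts, protein_ids)
  pc
}

#' Expand a genotype string into protein knockouts
#'
#' `"adh3"` expands to Adh3 plus Gpd2 (the glycerol-3-phosphate route is
#' respiration-independent and must be co-deleted for the mutant phenotype
#' to emerge; disable with `pair_gpd2 = FALSE`); `"mae1"` deletes Mae1;
#' `"hap4oe:FACTOR"` / `"hap4del:FACTOR"` scale the mitochondrial proteome
#' capacity instead of deleting a protein.
#'
#' @param pc a `pc_model`.
#' @param genotype genotype string.
#' @param pair_gpd2 co-delete Gpd2 with Adh3.
#' @return the perturbed `pc_model`.
#' @export
apply_genotype <- function(pc, genotype, pair_gpd2 = TRUE) {
  g <- tolower(genotype)
  if (g == "wt") return(pc)
  if (g == "adh3")
    return(knockout(pc, c("Adh3", if (pair_gpd2) "Gpd2")))
  if (g == "mae1") return(knockout(pc, "Mae1"))
  if (grepl("^hap4(oe|del):", g)) {
    factor <- as.numeric(sub("^hap4(oe|del):", "", g))
    return(scale_compartment_capacity(pc, "m", factor))
  }
  stop("unknown genotype '", genotype, "'")
}

#' Switch a medium to anaerobiosis
#'
#' Closes the oxygen uptake bound and opens the three trace lipid
#' exchanges (sterol and unsaturated fatty acid surrogates) at a small
#' uptake bound, mimicking ergosterol/Tween supplementation of anaerobic
#' cultures. Idempotent.
#'
#' @param med a `medium_def`.
#' @param oxygen_exchange oxygen exchange reaction id.
#' @param lipid_exchanges trace lipid exchange ids.
#' @param trace_bound uptake bound for each trace lipid,
#'   mmol gDW^-1 h^-1; the default is chosen to be non-limiting for the
#'   bundled toy network (lipid demand 0.05 per unit biomass).
#' @return the updated `medium_def`.
#' @export
set_anaerobic <- function(med, oxygen_exchange = "EX_o2",
                          lipid_exchanges = c("EX_erg", "EX_ole", "EX_pam"),
                          trace_bound = 0.05) {
  ob <- med$exchange_bounds[[oxygen_exchange]]
  if (is.null(ob))
    stop("medium does not name the oxygen exchange '", oxygen_exchange, "'")
  med$exchange_bounds[[oxygen_exchange]] <- c(0, max(0, ob[2]))
  for (id in lipid_exchanges)
    med$exchange_bounds[[id]] <- c(-trace_bound, 0)
  if (!grepl("anaerobic", med$name)) med$name <- "anaerobic"
  med
}

#' Scale a compartment proteome capacity
#'
#' Multiplies the proteome cap of the named compartment by `factor`
#' (clipped at 1), the surrogate used to mimic over- and under-expression
#' of the mitochondrial biogenesis program.
#'
#' @param pc a `pc_model`.
#' @param compartment compartment id carrying a proteome cap.
#' @param factor positive scaling factor.
#' @return the updated `pc_model`.
#' @export
scale_compartment_capacity <- function(pc, compartment, factor) {
  stopifnot(factor > 0)
  hit <- FALSE
  for (i in seq_along(pc$capacities)) {
    cc <- pc$capacities[[i]]
    if (cc$kind == "compartment_proteome" && cc$target == compartment) {
      pc$capacities[[i]]$cap <- min(1, factor * cc$cap)
      hit <- TRUE
    }
  }
  if (!hit)
    stop("no compartment proteome capacity defined for '", compartment, "'")
  pc
}

#' Amino-acid depletion series
#'
#' Observations of medium amino-acid concentration against culture biomass
#' concentration, with the culture's specific growth rate.
#'
#' @param data data.frame with columns `amino_acid`, `biomass_gdw_per_l`,
#'   `conc_um`.
#' @param mu culture specific growth rate, h^-1.
#' @return list of class `aa_depletion_series`.
#' @export
aa_depletion_series <- function(data, mu) {
  stopifnot(all(c("amino_acid", "biomass_gdw_per_l", "conc_um")
                %in% names(data)), mu > 0)
  for (aa in unique(data$amino_acid)) {
    b <- data$biomass_gdw_per_l[data$amino_acid == aa]
    if (length(b) < 2)
      stop("amino acid '", aa, "': need at least two points")
    if (is.unsorted(b, strictly = TRUE))
      stop("amino acid '", aa, "': biomass concentrations must be ",
           "strictly increasing")
  }
  structure(list(data = data, mu = mu), class = "aa_depletion_series")
}

#' Amino-acid uptake bounds from a depletion series
#'
#' For each amino acid, the least-squares slope of concentration (uM)
#' against biomass concentration (gDW L^-1) gives the specific
#' consumption (umol gDW^-1); the uptake bound is `-slope * mu`,
#' converted to mmol gDW^-1 h^-1. A nonnegative slope (no net uptake)
#' gives a bound of zero.
#'
#' @param series an [aa_depletion_series()].
#' @return named numeric of upper uptake bounds, mmol gDW^-1 h^-1.
#' @export
aa_uptake_bounds <- function(series) {
  stopifnot(inherits(series, "aa_depletion_series"))
  d <- series$data
  out <- vapply(unique(d$amino_acid), function(aa) {
    sub <- d[d$amino_acid == aa, ]
    slope <- unname(coef(lm(conc_um ~ biomass_gdw_per_l, data = sub))[2])
    if (slope < 0) -slope * series$mu / 1000 else 0
  }, 0)
  setNames(out, unique(d$amino_acid))
}
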