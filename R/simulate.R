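## Batch and chemostat simulation, physiological readouts, critical
## dilution rate, proteome-fraction aggregation, flux comparison and
## redox-shuttle cost analysis.

GLUCOSE_MW_G_PER_MMOL <- 0.18015

#' Physiological readout of a solved state
#'
#' Extracts specific exchange rates by reaction id: uptake rates
#' (`q_glc`, `q_o2`) are positive when the compound is consumed, excretion
#' rates (`q_etoh`, `q_glycerol`, `q_co2`, `q_acetate`) positive when
#' produced. The respiratory quotient `rq = q_co2 / q_o2` is defined only
#' when oxygen is consumed; the biomass yield is
#' `yield_xs = mu / (q_glc * 0.18015)` (gDW per g glucose).
#'
#' @param result a solved `sim_result`.
#' @param gem the `gem_model` the result was solved on (id check).
#' @param exchanges named map of physiological quantity to exchange
#'   reaction id.
#' @return list of class `physiology_readout`.
#' @export
physiology <- function(result, gem,
                       exchanges = c(glc = "EX_glc", etoh = "EX_etoh",
                                     glycerol = "EX_glyc", o2 = "EX_o2",
                                     co2 = "EX_co2", acetate = "EX_ac")) {
  stopifnot(identical(result$status, "optimal"))
  missing <- setdiff(exchanges, names(result$fluxes))
  if (length(missing))
    stop("exchange reaction(s) absent from result: ",
         paste(missing, collapse = ", "))
  fl <- result$fluxes[exchanges]
  tol <- 1e-9
  q_glc <- max(0, -fl[["EX_glc"]]); q_o2 <- max(0, -fl[["EX_o2"]])
  out <- list(mu = result$mu, q_glc = q_glc,
              q_etoh = max(0, fl[["EX_etoh"]]),
              q_glycerol = max(0, fl[["EX_glyc"]]),
              q_o2 = q_o2, q_co2 = max(0, fl[["EX_co2"]]),
              q_acetate = max(0, fl[["EX_ac"]]))
  out$rq <- if (q_o2 > tol) out$q_co2 / q_o2 else NA_real_
  out$yield_xs <- if (q_glc > tol)
    result$mu / (q_glc * GLUCOSE_MW_G_PER_MMOL) else NA_real_
  structure(out, class = "physiology_readout")
}

#' @export
print.physiology_readout <- function(x, ...) {
  cat(sprintf(
    "mu=%.4f q_glc=%.3f q_etoh=%.3f q_glyc=%.3f q_o2=%.3f q_co2=%.3f RQ=%s Yxs=%s\n",
    x$mu, x$q_glc, x$q_etoh, x$q_glycerol, x$q_o2, x$q_co2,
    ifelse(is.na(x$rq), "undef", sprintf("%.3f", x$rq)),
    ifelse(is.na(x$yield_xs), "undef", sprintf("%.3f", x$yield_xs))))
  invisible(x)
}

#' Glucose-limited chemostat sweep
#'
#' Emulates glucose limitation by scaling the glucose transporter's
#' effective turnover (`kcat* = f_sat * kcat`); each grid point maximizes
#' growth at that saturation, and the resulting growth rate is the
#' dilution rate D of the point.
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param f_sat_grid strictly increasing values in (0, 1].
#' @param transporter glucose transporter protein id.
#' @param cfg a [solve_config()]; chemostat points are substrate-limited
#'   steady states, so the default inner objective here minimizes uptake
#'   first (batch solves keep the protein-first default).
#' @return object of class `chemostat_curve`: `points` is a list of
#'   `list(f_sat, physiology, result)` (infeasible points recorded with
#'   `result = NULL`), `d_crit` is filled by [detect_dcrit()].
#' @export
chemostat_sweep <- function(pc, medium, f_sat_grid, transporter = "Hxt1",
                            cfg = solve_config(
                              tie_break = "min_uptake_then_min_protein")) {
  stopifnot(all(f_sat_grid > 0), all(f_sat_grid <= 1),
            !is.unsorted(f_sat_grid, strictly = TRUE))
  points <- vector("list", length(f_sat_grid))
  for (i in seq_along(f_sat_grid)) {
    med <- medium
    med$f_sat[transporter] <- f_sat_grid[i]
    pt <- tryCatch({
      res <- maximize_growth(pc, med, cfg)
      list(f_sat = f_sat_grid[i], physiology = physiology(res, pc$gem),
           result = res)
    }, error = function(e) {
      warning("chemostat point f_sat = ", f_sat_grid[i], " failed: ",
              conditionMessage(e), call. = FALSE)
      list(f_sat = f_sat_grid[i], physiology = NULL, result = NULL)
    })
    points[[i]] <- pt
  }
  structure(list(points = points, d_crit = NA_real_),
            class = "chemostat_curve")
}

#' @export
print.chemostat_curve <- function(x, ...) {
  ok <- !vapply(x$points, function(p) is.null(p$result), TRUE)
  cat("chemostat_curve:", sum(ok), "solved points")
  if (!is.na(x$d_crit)) cat("; d_crit =", signif(x$d_crit, 4), "h^-1")
  cat("\n")
  for (p in x$points[ok])
    cat(sprintf("  f_sat=%.3f  D=%.4f  q_glc=%.3f  q_etoh=%.3f  q_o2=%.3f\n",
                p$f_sat, p$physiology$mu, p$physiology$q_glc,
                p$physiology$q_etoh, p$physiology$q_o2))
  invisible(x)
}

#' Critical dilution rate from a chemostat curve
#'
#' The critical dilution rate is the onset of fermentative ethanol
#' excretion: the smallest growth rate on the curve at which
#' `q_etoh > epsilon`, linearly interpolated between the bracketing
#' points.
#'
#' @param curve a `chemostat_curve`.
#' @param epsilon ethanol-onset threshold, mmol gDW^-1 h^-1.
#' @return the critical dilution rate (h^-1), or `NA` with a warning when
#'   no onset lies within the curve.
#' @export
detect_dcrit <- function(curve, epsilon = 1e-3) {
  pts <- curve$points[!vapply(curve$points,
                              function(p) is.null(p$result), TRUE)]
  if (length(pts) < 2) stop("need at least two solved chemostat points")
  mu <- vapply(pts, function(p) p$physiology$mu, 0)
  qe <- vapply(pts, function(p) p$physiology$q_etoh, 0)
  ord <- order(mu)
  mu <- mu[ord]; qe <- qe[ord]
  i <- which(qe > epsilon)[1]
  if (is.na(i)) {
    warning("no ethanol onset within the curve; d_crit unset")
    return(NA_real_)
  }
  if (i == 1) {
    warning("first chemostat point already excretes ethanol; ",
            "d_crit reported at the lowest growth rate")
    return(mu[1])
  }
  mu[i - 1] + (epsilon - qe[i - 1]) * (mu[i] - mu[i - 1]) /
    (qe[i] - qe[i - 1])
}

#' Proteome fractions by pathway group
#'
#' Aggregates per-protein mass fractions into pathway groups; the
#' unspecified protein is reported as `"UP"` and proteins absent from the
#' mapping as `"unassigned"`. Fractions sum to 1.
#'
#' @param result a solved `sim_result`.
#' @param groups named character vector mapping protein id to group label
#'   (see [read_annotation_groups()]).
#' @return named numeric of group mass fractions, g (g protein)^-1.
#' @export
proteome_fractions <- function(result, groups) {
  stopifnot(identical(result$status, "optimal"))
  frac <- result$proteome_fraction
  lab <- ifelse(names(frac) == "UP", "UP",
                ifelse(names(frac) %in% names(groups),
                       groups[names(frac)], "unassigned"))
  out <- tapply(frac, lab, sum)
  setNames(as.numeric(out), names(out))
}

#' Compare two flux distributions
#'
#' @param wt,mut solved `sim_result`s over the same reaction id space.
#' @param threshold relative-change flag threshold (0.30 flags fluxes that
#'   differ by at least 30 percent from the reference value).
#' @param tol flux magnitude below which a reaction counts as inactive.
#' @return data.frame with columns `reaction`, `wt`, `mut`, `ratio`
#'   (mut/wt where the reference flux is nonzero) and `flag`
#'   (`"up"`, `"down"`, `"inactive"` or `""`).
#' @export
flux_comparison <- function(wt, mut, threshold = 0.30, tol = 1e-9) {
  stopifnot(identical(sort(names(wt$fluxes)), sort(names(mut$fluxes))))
  m <- mut$fluxes[names(wt$fluxes)]
  ratio <- ifelse(abs(wt$fluxes) > tol, m / wt$fluxes, NA_real_)
  flag <- rep("", length(ratio))
  flag[!is.na(ratio) & ratio - 1 >= threshold] <- "up"
  flag[!is.na(ratio) & 1 - ratio >= threshold] <- "down"
  flag[abs(m) <= tol & abs(wt$fluxes) > tol] <- "inactive"
  data.frame(reaction = names(wt$fluxes), wt = unname(wt$fluxes),
             mut = unname(m), ratio = unname(ratio), flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---------------------------------------------------------------------
## auxiliary flux-only LPs (shuttle energetics)
## ---------------------------------------------------------------------

## pseudo-reactions forcing a unit of redox transfer for each shuttle
shuttle_demand <- function(shuttle) {
  switch(shuttle,
    acetaldehyde_ethanol = ,
    malate_oaa = list(
      nadh_source_m = c(nad_m = -1, nadh_m = 1),   # mito surplus
      nadh_sink_c = c(nadh_c = -1, nad_c = 1)),    # cytosolic oxidation
    g3p = list(
      nadh_source_c = c(nad_c = -1, nadh_c = 1),   # cytosolic surplus
      fadh_sink_m = c(fadh2_m = -1, fad_m = 1)),   # mito FAD reoxidation
    stop("unknown shuttle '", shuttle, "'"))
}

#' ATP cost of a mitochondrial redox shuttle
#'
#' Solves an auxiliary flux LP at zero growth: one unit of net NAD(H)
#' transfer is forced through the named shuttle (mitochondrion to cytosol
#' for the acetaldehyde-ethanol and malate-oxaloacetate shuttles; cytosol
#' to the mitochondrial FAD pool for the glycerol-3-phosphate shuttle,
#' its physiological direction) while all other shuttle routes are
#' blocked, and the minimal ATP regeneration required to sustain the cycle
#' is returned. The malate-oxaloacetate shuttle imports one proton per
#' cycle by oxaloacetate-proton symport, and pumping that proton back out
#' through the mitochondrial ATPase costs one ATP; the
#' acetaldehyde-ethanol shuttle moves no protons and costs nothing
#' (unless a proton leak is configured, which costs exactly the leak
#' stoichiometry).
#'
#' @param pc a `pc_model` or `toy_model` containing the shuttle reactions.
#' @param shuttle one of `"acetaldehyde_ethanol"`, `"malate_oaa"`,
#'   `"g3p"`.
#' @param shuttles named list of reaction-id sets per shuttle; defaults to
#'   the toy network's sets when `pc` is a `toy_model`.
#' @return ATP consumed per NADH equivalent shuttled (mmol/mmol).
#' @export
shuttle_cost <- function(pc, shuttle = c("acetaldehyde_ethanol",
                                         "malate_oaa", "g3p"),
                         shuttles = NULL) {
  shuttle <- match.arg(shuttle)
  if (inherits(pc, "toy_model")) {
    shuttles <- shuttles %||% pc$shuttles
    gem <- pc$gem
  } else {
    gem <- pc$gem
    if (is.null(shuttles))
      stop("supply the shuttle reaction sets for non-toy models")
  }
  sel <- shuttles[[shuttle]]
  if (!length(sel) || !all(sel %in% names(gem$reactions)))
    stop("shuttle '", shuttle, "' reactions absent from the model")
  other <- setdiff(unique(c(unlist(shuttles), "GPD1", "GPD2M", "GUT2")),
                   sel)
  extra <- c(shuttle_demand(shuttle),
             list(atp_drive = c(adp_c = -1, atp_c = 1)))
  force <- setNames(c(1, 1), names(extra)[1:2])
  res <- gem_aux_lp_forced(gem, block = other, extra = extra,
                           forced_extra = force)
  if (res$status != "optimal")
    stop("shuttle '", shuttle, "' cannot carry the forced transfer (",
         res$status, ")")
  res$cost
}

## variant of gem_aux_lp where named extra pseudo-columns are fixed to a
## forced value instead of 0
gem_aux_lp_forced <- function(gem, block, extra, forced_extra,
                              force_rxn = numeric()) {
  rxns <- gem$reactions
  rids <- vapply(rxns, `[[`, "", "id")
  lbs <- setNames(vapply(rxns, `[[`, 0, "lb"), rids)
  ubs <- setNames(vapply(rxns, `[[`, 0, "ub"), rids)
  for (r in rxns) if (isTRUE(r$is_exchange)) {
    lbs[r$id] <- 0; ubs[r$id] <- 0
  }
  lbs[gem$biomass_reaction_id] <- 0; ubs[gem$biomass_reaction_id] <- 0
  for (id in block) if (id %in% rids) { lbs[id] <- 0; ubs[id] <- 0 }
  for (id in names(force_rxn)) {
    lbs[id] <- force_rxn[[id]]; ubs[id] <- force_rxn[[id]]
  }
  S <- stoich_matrix(gem)
  for (nm in names(extra)) {
    col <- numeric(nrow(S)); names(col) <- rownames(S)
    col[names(extra[[nm]])] <- extra[[nm]]
    S <- cbind(S, col); colnames(S)[ncol(S)] <- nm
    if (nm %in% names(forced_extra)) {
      lbs[nm] <- forced_extra[[nm]]; ubs[nm] <- forced_extra[[nm]]
    } else { lbs[nm] <- 0; ubs[nm] <- 1000 }
  }
  n <- ncol(S)
  has_rev <- lbs < 0
  Sfull <- cbind(S, -S[, has_rev, drop = FALSE])
  lb <- c(pmax(0, lbs), pmax(0, -ubs[has_rev]))
  ub <- c(pmax(0, ubs), pmax(0, -lbs[has_rev]))
  obj <- numeric(ncol(Sfull))
  obj[match("atp_drive", colnames(S))] <- 1
  res <- solve_lp(obj, Sfull, rep("=", nrow(Sfull)), numeric(nrow(Sfull)),
                  lb, ub)
  if (res$status != "optimal")
    return(list(status = res$status, flux = NULL, cost = NA_real_))
  flux <- res$x[seq_len(n)]
  flux[has_rev] <- flux[has_rev] - res$x[n + seq_len(sum(has_rev))]
  names(flux) <- colnames(S)
  list(status = "optimal", flux = flux, cost = res$obj)
}

#' Cytosolic ATP cost of the carnitine-shuttle ATP bypass
#'
#' Forces one unit of flux through the mitochondrial succinyl-CoA ligase
#' supplied exclusively by cytosolic acetyl-CoA through the carnitine
#' shuttle (pyruvate dehydrogenase blocked), at zero growth, and returns
#' the cytosolic ATP-equivalent consumption per mitochondrial ATP
#' generated. ATP-to-AMP hydrolysis (acetyl-CoA synthetase) counts as two
#' equivalents, so the route costs 2 cytosolic ATP equivalents per
#' mitochondrial ATP.
#'
#' @param pc a `toy_model` (or `pc_model` whose gem carries the route).
#' @return ATP equivalents consumed in the cytosol per mitochondrial ATP.
#' @export
bypass_cost <- function(pc) {
  gem <- if (inherits(pc, "toy_model")) pc$gem else pc$gem
  need <- c("SCL", "COAT", "CARN", "ACS", "ACtm")
  if (!all(need %in% names(gem$reactions)))
    stop("carnitine-shuttle bypass reactions absent from the model")
  extra <- list(atp_drive = c(adp_c = -1, atp_c = 1),
                atp_m_sink = c(atp_m = -1, adp_m = 1))
  res <- gem_aux_lp_forced(gem, block = "PDH", extra = extra,
                           forced_extra = c(atp_m_sink = 1),
                           force_rxn = c(SCL = 1))
  if (res$status != "optimal")
    stop("bypass route cannot carry the forced flux (", res$status, ")")
  ## cytosolic ATP equivalents (ATP = 2, ADP = 1, AMP = 0) consumed per
  ## reaction, excluding the regeneration pseudo-flux
  equiv <- vapply(gem$reactions, function(r) {
    q <- 0
    if ("atp_c" %in% names(r$stoich)) q <- q + 2 * r$stoich[["atp_c"]]
    if ("adp_c" %in% names(r$stoich)) q <- q + r$stoich[["adp_c"]]
    q
  }, 0)
  v <- res$flux[names(equiv)]
  consumed <- sum(pmax(0, -equiv * v))
  consumed / res$flux[["SCL"]]
}
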