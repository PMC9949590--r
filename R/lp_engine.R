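## Numerical engine: assemble the proteome-constrained LP at fixed growth
## rate, test feasibility, maximize growth by bisection, and report
## constraint utilizations. The growth rate enters the constraint matrix
## only through the protein dilution terms (-mu on each abundance in its
## synthesis balance) and the biomass flux bounds, so the assembled
## structure is built once per (model, medium) and patched per mu.

#' Solver configuration
#'
#' @param feasibility_tolerance accepted phase-1 residual when declaring a
#'   fixed-mu system feasible.
#' @param bisection_tolerance_mu termination width (h^-1) of the growth-rate
#'   bisection.
#' @param mu_upper_seed initial upper bracket for the bisection; doubled
#'   until infeasible.
#' @param mu_hard_cap growth rate above which continued feasibility is
#'   treated as a modeling defect (unbounded growth).
#' @param tie_break inner objective at the optimum.
#'   `"min_protein_then_min_uptake"` (default) first minimizes total
#'   functional enzyme mass (the minimal-required-proteome reading), then
#'   minimizes limiting-substrate uptake among proteome-minimal solutions;
#'   `"min_uptake_then_min_protein"` reverses the order. The default
#'   reproduces the glucose-excess pattern in which respiration is not
#'   expanded to fill the mitochondrial capacity merely to save substrate
#'   (see the methods vignette).
#' @param precision_refine re-solve the final LP with tightened pivot and
#'   feasibility tolerances.
#' @return list of class `solve_config`.
#' @export
solve_config <- function(feasibility_tolerance = 1e-9,
                         bisection_tolerance_mu = 1e-4,
                         mu_upper_seed = 1.0, mu_hard_cap = 64,
                         tie_break = "min_protein_then_min_uptake",
                         precision_refine = FALSE) {
  stopifnot(feasibility_tolerance > 0, bisection_tolerance_mu > 0,
            mu_upper_seed > 0)
  tie_break <- match.arg(tie_break, c("min_protein_then_min_uptake",
                                      "min_uptake_then_min_protein"))
  structure(list(feasibility_tolerance = feasibility_tolerance,
                 bisection_tolerance_mu = bisection_tolerance_mu,
                 mu_upper_seed = mu_upper_seed, mu_hard_cap = mu_hard_cap,
                 tie_break = tie_break,
                 precision_refine = precision_refine),
            class = "solve_config")
}

## ---------------------------------------------------------------------
## assembly
## ---------------------------------------------------------------------

## Build the mu-independent LP skeleton for (pc, medium). Returns a list
## with the dense matrix A (dilution entries left at 0), senses, rhs,
## bounds, variable/constraint names, patch indices and objective vectors.
assemble_pc_lp <- function(pc, medium) {
  gem <- pc$gem
  prot <- pc$proteins
  trn <- pc$translation
  rxns <- gem$reactions
  rids <- vapply(rxns, `[[`, "", "id")
  np <- nrow(prot)

  ## effective reaction bounds (medium overrides exchanges)
  lbs <- vapply(rxns, `[[`, 0, "lb")
  ubs <- vapply(rxns, `[[`, 0, "ub")
  for (id in names(medium$exchange_bounds)) {
    i <- match(id, rids)
    if (is.na(i)) stop("medium references unknown exchange '", id, "'")
    lbs[i] <- medium$exchange_bounds[[id]][1]
    ubs[i] <- medium$exchange_bounds[[id]][2]
  }
  i_ngam <- match(pc$energy$ngam_reaction, rids)
  if (!is.na(i_ngam)) lbs[i_ngam] <- max(lbs[i_ngam], pc$energy$ngam)

  has_rev <- lbs < 0
  ## variable layout
  nvf <- length(rids); nvr <- sum(has_rev)
  v_f <- seq_len(nvf)
  v_r <- integer(nvf); v_r[has_rev] <- nvf + seq_len(nvr)
  c_ix <- nvf + nvr + seq_len(np)
  s_ix <- nvf + nvr + np + seq_len(np)
  nrule <- length(pc$rules)
  a_f <- if (nrule) nvf + nvr + 2 * np + seq_len(nrule) else integer()
  rule_rxn <- match(vapply(pc$rules, `[[`, "", "reaction_id"), rids)
  rule_rev <- has_rev[rule_rxn]
  a_r <- integer(nrule)
  a_r[rule_rev] <- nvf + nvr + 2 * np + nrule + seq_len(sum(rule_rev))
  nv <- nvf + nvr + 2 * np + nrule + sum(rule_rev)

  vnames <- character(nv)
  vnames[v_f] <- sprintf("v_%s_f", rids)
  vnames[v_r[has_rev]] <- sprintf("v_%s_r", rids[has_rev])
  vnames[c_ix] <- sprintf("c_%s", prot$id)
  vnames[s_ix] <- sprintf("syn_%s", prot$id)
  if (nrule) {
    vnames[a_f] <- sprintf("alloc_%d_f", seq_len(nrule))
    vnames[a_r[rule_rev]] <- sprintf("alloc_%d_r", which(rule_rev))
  }

  ## constraint layout
  met <- gem$metabolites[!gem$metabolites$is_boundary, , drop = FALSE]
  nm <- nrow(met)
  cat_prot <- sort(unique(unlist(lapply(pc$rules, function(r)
    names(r$complex)))))
  catalyzed_f <- sort(unique(rule_rxn))
  catalyzed_r <- sort(unique(rule_rxn[rule_rev]))
  ncons <- nm + np + 3L + length(cat_prot) + length(catalyzed_f) +
    length(catalyzed_r) + length(pc$capacities)
  A <- matrix(0, ncons, nv)
  sense <- character(ncons); rhs <- numeric(ncons)
  cnames <- character(ncons)

  row <- 0L
  met_row <- setNames(seq_len(nm), met$id)

  ## mass balances
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$stoich
    keep <- names(st)[names(st) %in% met$id]
    if (j == match(gem$biomass_reaction_id, rids) && pc$energy$gam > 0) {
      st <- add_gam(st, pc$energy)
      keep <- names(st)[names(st) %in% met$id]
    }
    A[met_row[keep], v_f[j]] <- st[keep]
    if (has_rev[j]) A[met_row[keep], v_r[j]] <- -st[keep]
  }
  ## translation drains on synthesis fluxes
  drain <- function(metid, coefs) {
    if (!is.null(metid) && metid %in% met$id)
      A[met_row[metid], s_ix] <<- A[met_row[metid], s_ix] + coefs
  }
  drain(trn$aa_metabolite, -prot$length)
  drain(trn$atp_metabolite, -trn$atp_per_peptide_bond * prot$length)
  drain(trn$adp_metabolite, trn$atp_per_peptide_bond * prot$length)
  sense[seq_len(nm)] <- "="; rhs[seq_len(nm)] <- 0
  cnames[seq_len(nm)] <- sprintf("mass_%s", met$id)
  row <- nm

  ## protein synthesis-dilution balances: syn_p - mu * c_p = 0
  pbal <- row + seq_len(np)
  A[cbind(pbal, s_ix)] <- 1
  ## the -mu coefficients on c_ix are patched per mu
  sense[pbal] <- "="; rhs[pbal] <- 0
  cnames[pbal] <- sprintf("protein_balance_%s", prot$id)
  row <- row + np

  ## translation capacity
  row <- row + 1L
  tr_row <- row
  A[tr_row, s_ix] <- prot$length
  A[tr_row, c_ix[match("RIBOSOME", prot$id)]] <-
    -trn$elongation_rate_aa_s * 3600
  sense[row] <- "<="; rhs[row] <- 0
  cnames[row] <- "translation_capacity"

  ## proteome closure and UP minimum
  P <- gem$protein_content
  row <- row + 1L
  A[row, c_ix] <- prot$mw
  sense[row] <- "="; rhs[row] <- P
  cnames[row] <- "proteome_closure"
  row <- row + 1L
  up_c <- c_ix[match("UP", prot$id)]
  A[row, up_c] <- trn$up_mw
  sense[row] <- ">="; rhs[row] <- trn$min_up_fraction * P
  cnames[row] <- "up_minimum"

  ## enzyme usage: sum_k n_pk (a_f + a_r) <= c_p
  use_row <- setNames(row + seq_along(cat_prot), cat_prot)
  for (k in seq_len(nrule)) {
    cx <- pc$rules[[k]]$complex
    r <- use_row[names(cx)]
    A[cbind(r, rep(a_f[k], length(r)))] <- cx
    if (rule_rev[k]) A[cbind(r, rep(a_r[k], length(r)))] <-
        A[cbind(r, rep(a_r[k], length(r)))] + cx
  }
  A[cbind(use_row, c_ix[match(cat_prot, prot$id)])] <- -1
  sense[use_row] <- "<="; rhs[use_row] <- 0
  cnames[use_row] <- sprintf("enzyme_usage_%s", cat_prot)
  row <- row + length(cat_prot)

  ## f_sat: effective turnover kcat* = f_sat * kcat for complexes that
  ## contain a transporter listed in the medium
  fs <- medium$f_sat
  rule_fsat <- vapply(pc$rules, function(rule) {
    hit <- intersect(names(rule$complex), names(fs))
    if (length(hit)) min(fs[hit]) else 1
  }, 0)

  ## capacity couplings per catalyzed reaction direction
  cap_f_row <- setNames(row + seq_along(catalyzed_f), rids[catalyzed_f])
  for (k in seq_len(nrule)) {
    r <- cap_f_row[[rids[rule_rxn[k]]]]
    A[r, a_f[k]] <- -3600 * pc$rules[[k]]$kcat_fwd * rule_fsat[k]
  }
  A[cbind(cap_f_row, v_f[catalyzed_f])] <- 1
  sense[cap_f_row] <- "<="; rhs[cap_f_row] <- 0
  cnames[cap_f_row] <- sprintf("enzyme_capacity_%s_f", rids[catalyzed_f])
  row <- row + length(catalyzed_f)

  cap_r_row <- setNames(row + seq_along(catalyzed_r), rids[catalyzed_r])
  for (k in which(rule_rev)) {
    r <- cap_r_row[[rids[rule_rxn[k]]]]
    A[r, a_r[k]] <- -3600 * pc$rules[[k]]$kcat_rev * rule_fsat[k]
  }
  if (length(catalyzed_r))
    A[cbind(cap_r_row, v_r[catalyzed_r])] <- 1
  sense[cap_r_row] <- "<="; rhs[cap_r_row] <- 0
  cnames[cap_r_row] <- sprintf("enzyme_capacity_%s_r", rids[catalyzed_r])
  row <- row + length(catalyzed_r)

  ## compartment proteome and membrane area caps
  cap_meta <- list()
  for (cc in pc$capacities) {
    row <- row + 1L
    nm_c <- capacity_name(cc)
    if (cc$kind == "compartment_proteome") {
      members <- which(prot$compartment == cc$target & prot$id != "UP")
      A[row, c_ix[members]] <- prot$mw[members]
      rhs[row] <- cc$cap * P
    } else {
      members <- which(prot$is_transporter & prot$membrane == cc$target &
                         (if (is.null(cc$member_filter)) TRUE
                          else prot$transporter_class == cc$member_filter))
      A[row, c_ix[members]] <- prot$area[members]
      area_tot <- pc$membrane_area[[cc$target]] %||% 1
      rhs[row] <- cc$cap * area_tot
    }
    sense[row] <- "<="
    cnames[row] <- nm_c
    cap_meta[[nm_c]] <- list(row = row, bound = rhs[row])
  }

  ## bounds
  lb <- numeric(nv); ub <- rep(Inf, nv)
  ub[v_f] <- pmax(0, ubs); lb[v_f] <- pmax(0, lbs)
  ub[v_r[has_rev]] <- pmax(0, -lbs[has_rev])
  lb[v_r[has_rev]] <- pmax(0, -ubs[has_rev])
  if (length(pc$knockouts))
    ub[c_ix[match(pc$knockouts, prot$id)]] <- 0

  i_bio <- match(gem$biomass_reaction_id, rids)

  ## lexicographic objectives
  obj_uptake <- numeric(nv)
  lim <- medium$limiting_exchange
  if (!is.null(lim)) {
    i <- match(lim, rids)
    if (!is.na(i) && has_rev[i]) obj_uptake[v_r[i]] <- 1
  }
  obj_mass <- numeric(nv)
  fun <- prot$id != "UP"
  obj_mass[c_ix[fun]] <- prot$mw[fun]

  list(A = A, sense = sense, rhs = rhs, lb = lb, ub = ub,
       vnames = vnames, cnames = cnames,
       v_f = v_f, v_r = v_r, has_rev = has_rev, c_ix = c_ix, s_ix = s_ix,
       rids = rids, prot = prot, pbal = pbal, i_bio = i_bio,
       tr_row = tr_row, up_c = up_c, cap_meta = cap_meta,
       obj_uptake = obj_uptake, obj_mass = obj_mass,
       P = P, trn = trn)
}

add_gam <- function(st, energy) {
  for (m in c(energy$atp_metabolite, energy$adp_metabolite))
    if (!m %in% names(st)) st[m] <- 0
  st[energy$atp_metabolite] <- st[energy$atp_metabolite] - energy$gam
  st[energy$adp_metabolite] <- st[energy$adp_metabolite] + energy$gam
  st
}

## patch the dilution terms and biomass bounds for a given mu
lp_at_mu <- function(asm, mu) {
  asm$A[cbind(asm$pbal, asm$c_ix)] <- -mu
  asm$lb[asm$v_f[asm$i_bio]] <- mu
  asm$ub[asm$v_f[asm$i_bio]] <- mu
  asm
}

## ---------------------------------------------------------------------
## feasibility / optimization
## ---------------------------------------------------------------------

#' Fixed-growth-rate feasibility
#'
#' Tests whether the proteome-constrained system admits a solution at growth
#' rate `mu` under the given medium. Feasibility is monotone: a system
#' feasible at `mu` is feasible at any smaller growth rate.
#'
#' @param pc a `pc_model`.
#' @param mu growth rate, h^-1.
#' @param medium a `medium_def`.
#' @param cfg a [solve_config()].
#' @param .asm pre-assembled LP skeleton (internal reuse).
#' @return logical.
#' @export
feasible <- function(pc, mu, medium, cfg = solve_config(), .asm = NULL) {
  stopifnot(mu >= 0)
  asm <- .asm %||% assemble_pc_lp(pc, medium)
  l <- lp_at_mu(asm, mu)
  res <- solve_lp(numeric(ncol(l$A)), l$A, l$sense, l$rhs, l$lb, l$ub,
                  feas_tol = max(cfg$feasibility_tolerance, 1e-9))
  if (res$status %in% c("unbounded", "iteration_limit"))
    stop("LP solver failure at mu = ", mu, ": ", res$status)
  res$status == "optimal"
}

#' Solve the model at a fixed growth rate
#'
#' Lexicographic objective (default policy): (1) minimize total functional
#' enzyme mass (pushing slack proteome into the unspecified protein — the
#' minimal-required-proteome reading), (2) among proteome-minimal
#' solutions, minimize uptake of the medium's limiting substrate. Returns
#' the solved state.
#'
#' @inheritParams feasible
#' @return object of class `sim_result` with growth rate, net fluxes,
#'   enzyme abundances (mmol gDW^-1), proteome mass fractions, capacity
#'   constraint utilizations and the active-constraint list.
#' @export
solve_at_mu <- function(pc, mu, medium, cfg = solve_config(), .asm = NULL,
                        active_tol = 1e-6) {
  asm <- .asm %||% assemble_pc_lp(pc, medium)
  l <- lp_at_mu(asm, mu)
  tol <- max(cfg$feasibility_tolerance, 1e-9)
  ptol <- if (isTRUE(cfg$precision_refine)) 1e-12 else 1e-9

  objs <- if (identical(cfg$tie_break, "min_uptake_then_min_protein"))
    list(l$obj_uptake, l$obj_mass) else list(l$obj_mass, l$obj_uptake)
  r1 <- solve_lp(objs[[1]], l$A, l$sense, l$rhs, l$lb, l$ub,
                 tol = ptol, feas_tol = tol)
  if (r1$status != "optimal")
    stop("model ", r1$status, " at mu = ", mu)
  x <- r1$x
  if (any(objs[[2]] != 0)) {
    ## pin the first optimum, then optimize the second objective
    l$A <- rbind(l$A, objs[[1]])
    l$sense <- c(l$sense, "<=")
    l$rhs <- c(l$rhs, r1$obj + 1e-9 * (1 + abs(r1$obj)))
    r2 <- solve_lp(objs[[2]], l$A, l$sense, l$rhs, l$lb, l$ub,
                   tol = ptol, feas_tol = tol)
    if (r2$status == "optimal") x <- r2$x
  }
  build_sim_result(asm, x, mu, medium, pc, active_tol)
}

build_sim_result <- function(asm, x, mu, medium, pc, active_tol = 1e-6) {
  flux <- x[asm$v_f]
  flux[asm$has_rev] <- flux[asm$has_rev] - x[asm$v_r[asm$has_rev]]
  names(flux) <- asm$rids
  cvals <- setNames(x[asm$c_ix], asm$prot$id)
  svals <- setNames(x[asm$s_ix], asm$prot$id)
  frac <- setNames(asm$prot$mw * cvals / asm$P, asm$prot$id)

  util <- c()
  trn <- asm$trn
  denom <- trn$elongation_rate_aa_s * 3600 * cvals[["RIBOSOME"]]
  util["translation_capacity"] <-
    if (denom > 0) sum(asm$prot$length * svals) / denom else 0
  util["proteome_closure"] <- sum(asm$prot$mw * cvals) / asm$P
  up_mass <- trn$up_mw * cvals[["UP"]]
  util["up_minimum"] <- if (up_mass > 0)
    (trn$min_up_fraction * asm$P) / up_mass
  else if (trn$min_up_fraction == 0) 0 else Inf
  for (nm in names(asm$cap_meta)) {
    cm <- asm$cap_meta[[nm]]
    util[nm] <- sum(asm$A[cm$row, ] * x) / cm$bound
  }
  active <- names(util)[util >= 1 - active_tol & is.finite(util)]

  structure(list(mu = mu, fluxes = flux, enzyme_abundances = cvals,
                 synthesis_fluxes = svals, proteome_fraction = frac,
                 constraint_utilization = util,
                 active_constraints = active, status = "optimal",
                 medium = medium$name,
                 biomass_reaction = pc$gem$biomass_reaction_id),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: status", x$status, "| mu =", signif(x$mu, 6), "h^-1\n")
  nz <- x$fluxes[abs(x$fluxes) > 1e-9]
  cat(" ", length(nz), "nonzero fluxes; active constraints:",
      if (length(x$active_constraints))
        paste(x$active_constraints, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Maximal growth rate by feasibility bisection
#'
#' Doubles `mu_upper_seed` until infeasible, then bisects the bracket down
#' to `bisection_tolerance_mu` and returns the solved state at the largest
#' certified-feasible growth rate.
#'
#' @inheritParams feasible
#' @return a `sim_result` at the maximal growth rate.
#' @export
maximize_growth <- function(pc, medium, cfg = solve_config()) {
  asm <- assemble_pc_lp(pc, medium)
  if (!feasible(pc, 0, medium, cfg, .asm = asm))
    stop("model infeasible at zero growth under medium '", medium$name, "'")
  lo <- 0; hi <- cfg$mu_upper_seed
  while (feasible(pc, hi, medium, cfg, .asm = asm)) {
    lo <- hi; hi <- 2 * hi
    if (hi > cfg$mu_hard_cap)
      stop("growth rate still feasible at mu = ", hi,
           " h^-1; unbounded growth indicates a modeling defect")
  }
  while (hi - lo > cfg$bisection_tolerance_mu) {
    mid <- (lo + hi) / 2
    if (feasible(pc, mid, medium, cfg, .asm = asm)) lo <- mid else hi <- mid
  }
  ## the certified growth rate sits up to tol_mu below the true maximum,
  ## so the binding capacity is attained only to ~tol_mu/mu relative
  ## accuracy; scale the activity threshold accordingly
  atol <- max(1e-6, 8 * cfg$bisection_tolerance_mu / max(lo, 1e-3))
  solve_at_mu(pc, lo, medium, cfg, .asm = asm, active_tol = atol)
}

#' Constraint utilizations and active constraints
#'
#' Utilization of a named capacity constraint is its attained left-hand
#' side over its bound; a constraint with utilization at 1 (within 1e-6)
#' is active, i.e. it currently limits growth.
#'
#' @param result a solved `sim_result`.
#' @return list with `utilization` (named numeric in `[0, 1]`) and
#'   `active` (character).
#' @export
constraint_utilization <- function(result) {
  stopifnot(inherits(result, "sim_result"),
            identical(result$status, "optimal"))
  list(utilization = result$constraint_utilization,
       active = result$active_constraints)
}

## precedence used to label a solved state by its growth-limiting regime
#' Growth-limiting regime label
#'
#' Classifies a state by the most downstream capacity constraint, in the
#' precedence cytosolic proteome > mitochondrial proteome > transporter
#' membrane area (the order in which the regimes appear as glucose
#' availability rises). Pass the output of [limiting_constraints()] for
#' the growth-limitation semantics, or a solved `sim_result` to use its
#' saturation-based active list.
#'
#' @param result a solved `sim_result`, or a character vector of
#'   constraint names.
#' @param cytosol,mitochondrion compartment ids.
#' @param transporter_constraint name of the carbon transporter membrane
#'   cap.
#' @return one of `"cytosolic"`, `"mitochondrial"`, `"transporter"`,
#'   `"other"`.
#' @export
regime_label <- function(result, cytosol = "c", mitochondrion = "m",
                         transporter_constraint =
                           "capacity_membrane_plasma_carbon") {
  act <- if (is.character(result)) result else result$active_constraints
  ## the minimal-UP constraint is the operative proxy for total cytosolic
  ## proteome capacity: when UP sits at its floor, investment in any
  ## functional protein comes at the expense of another
  if (any(c(sprintf("capacity_compartment_%s", cytosol), "up_minimum",
            "translation_capacity") %in% act)) return("cytosolic")
  if (sprintf("capacity_compartment_%s", mitochondrion) %in% act)
    return("mitochondrial")
  if (transporter_constraint %in% act) return("transporter")
  "other"
}

#' Growth-limiting capacity constraints
#'
#' A saturated capacity is not necessarily growth-limiting: with the
#' proteome closure, ballast proteome is synthesized either way, so the
#' uptake-minimizing solution can saturate a capacity (e.g. respire to the
#' mitochondrial cap at glucose excess) without that capacity restricting
#' the maximal growth rate. This probe relaxes each named capacity by a
#' small factor and tests whether a growth rate just above the certified
#' maximum becomes feasible; only then does the constraint limit growth.
#' Probed constraints: every compartment/membrane capacity, the UP
#' minimum, and the translation capacity.
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param cfg a [solve_config()].
#' @param relax relaxation factor per probe.
#' @param mumax optional precomputed maximal growth rate (h^-1); computed
#'   by bisection when missing.
#' @return character vector of growth-limiting constraint names (same
#'   naming as the utilization map).
#' @export
limiting_constraints <- function(pc, medium, cfg = solve_config(),
                                 relax = 1.05, mumax = NULL) {
  if (is.null(mumax)) mumax <- maximize_growth(pc, medium, cfg)$mu
  probe_mu <- mumax + 4 * cfg$bisection_tolerance_mu
  lim <- character()
  for (i in seq_along(pc$capacities)) {
    pc2 <- pc
    pc2$capacities[[i]]$cap <- min(1, relax * pc$capacities[[i]]$cap)
    if (feasible(pc2, probe_mu, medium, cfg))
      lim <- c(lim, capacity_name(pc$capacities[[i]]))
  }
  pc2 <- set_min_up(pc, pc$translation$min_up_fraction / relax)
  if (feasible(pc2, probe_mu, medium, cfg)) lim <- c(lim, "up_minimum")
  pc2 <- pc
  pc2$translation$elongation_rate_aa_s <-
    relax * pc$translation$elongation_rate_aa_s
  if (feasible(pc2, probe_mu, medium, cfg))
    lim <- c(lim, "translation_capacity")
  lim
}
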