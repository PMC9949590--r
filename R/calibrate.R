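## Calibration procedures: compartment capacity to the critical dilution
## rate, GAM to observed chemostat exchange fluxes, and the minimal
## unspecified-protein fraction to the maximal growth rate. All three are
## deterministic given their inputs.

calibration_result <- function(parameter_name, fitted_value, residuals,
                               iterations, bracket, details = list()) {
  structure(list(parameter_name = parameter_name,
                 fitted_value = fitted_value, residuals = residuals,
                 iterations = iterations, bracket = bracket,
                 details = details),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result:", x$parameter_name, "=",
      signif(x$fitted_value, 6), "\n  bracket [",
      x$bracket[1], ",", x$bracket[2], "],", x$iterations, "iterations\n")
  invisible(x)
}

#' Fit a compartment capacity scaling to a target critical dilution rate
#'
#' Bisects the capacity scaling factor of the named compartment until the
#' critical dilution rate of the swept chemostat curve matches the target.
#' The critical dilution rate increases with mitochondrial capacity, so
#' the bracket endpoints must straddle the target.
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param compartment compartment id whose proteome cap is scaled.
#' @param target_dcrit target critical dilution rate, h^-1.
#' @param bracket `c(lo, hi)` scaling factors.
#' @param f_sat_grid saturation grid for the chemostat sweeps; the onset
#'   bracket is re-swept at finer resolution before each estimate.
#' @param tol_d acceptance tolerance on the critical dilution rate, h^-1.
#' @param cfg a [solve_config()].
#' @return a `calibration_result`; `details$dcrit` holds the achieved
#'   value.
#' @export
fit_capacity_to_dcrit <- function(pc, medium, compartment, target_dcrit,
                                  bracket = c(0.2, 2),
                                  f_sat_grid = c(0.02, 0.04, 0.06, 0.08,
                                                 0.1, 0.13, 0.16, 0.2,
                                                 0.28, 0.4, 0.65, 1.0),
                                  tol_d = 5e-3, cfg = solve_config()) {
  eval_d <- function(factor) {
    m <- scale_compartment_capacity(pc, compartment, factor)
    dcrit_refined(m, medium, f_sat_grid, cfg = cfg)
  }
  d_lo <- eval_d(bracket[1]); d_hi <- eval_d(bracket[2])
  if (is.na(d_lo) || is.na(d_hi) || target_dcrit < d_lo ||
      target_dcrit > d_hi)
    stop("target d_crit ", target_dcrit, " outside bracket range [",
         signif(d_lo, 4), ", ", signif(d_hi, 4), "]")
  lo <- bracket[1]; hi <- bracket[2]; it <- 0L; d_mid <- NA_real_
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    d_mid <- eval_d(mid)
    if (!is.na(d_mid) && abs(d_mid - target_dcrit) <= tol_d &&
        hi - lo <= 0.02) break
    if (is.na(d_mid) || d_mid < target_dcrit) lo <- mid else hi <- mid
    if (hi - lo < 2e-3 || it >= 18L) break
  }
  calibration_result("capacity_scaling", (lo + hi) / 2,
                     residuals = d_mid - target_dcrit, iterations = it,
                     bracket = bracket,
                     details = list(dcrit = d_mid, target = target_dcrit,
                                    compartment = compartment))
}

#' Fit the growth-associated maintenance to chemostat exchange fluxes
#'
#' For each candidate GAM the model is solved at every observed dilution
#' rate (chemostat mode: fixed growth rate, minimal uptake) and scored by
#' the sum of squared relative residuals over the measured fluxes. The
#' grid argmin is returned with the full score profile; `refine = TRUE`
#' adds a quadratic refinement between the argmin's neighbors.
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param data data.frame with column `D_h` and any of `q_glc`, `q_etoh`,
#'   `q_glycerol`, `q_o2`, `q_co2` (NA = not measured, excluded from
#'   scoring).
#' @param grid candidate GAM values, mmol ATP gDW^-1.
#' @param refine continuous refinement around the grid argmin.
#' @param cfg a [solve_config()].
#' @return a `calibration_result`; `details$profile` holds the score per
#'   grid value, `details$excluded` any infeasible dilution rates.
#' @export
fit_gam_to_fluxes <- function(pc, medium, data, grid = c(24, 32, 40, 48),
                              refine = FALSE,
                              cfg = solve_config(
                                tie_break = "min_uptake_then_min_protein")) {
  if (is.null(data) || nrow(data) == 0) stop("empty chemostat data")
  cols <- intersect(c("q_glc", "q_etoh", "q_glycerol", "q_o2", "q_co2"),
                    names(data))
  score_gam <- function(gam) {
    m <- set_gam(pc, gam)
    asm <- assemble_pc_lp(m, medium)
    total <- 0; excluded <- numeric(); resid <- list()
    for (i in seq_len(nrow(data))) {
      D <- data$D_h[i]
      res <- tryCatch(solve_at_mu(m, D, medium, cfg, .asm = asm),
                      error = function(e) NULL)
      if (is.null(res)) { excluded <- c(excluded, D); next }
      ph <- physiology(res, m$gem)
      key <- c(q_glc = "q_glc", q_etoh = "q_etoh",
               q_glycerol = "q_glycerol", q_o2 = "q_o2", q_co2 = "q_co2")
      for (col in cols) {
        obs <- data[[col]][i]
        if (is.na(obs)) next
        pred <- ph[[key[[col]]]]
        rr <- (pred - obs) / max(abs(obs), 0.01)
        total <- total + rr^2
        resid[[length(resid) + 1L]] <- data.frame(
          D_h = D, quantity = col, observed = obs, predicted = pred,
          stringsAsFactors = FALSE)
      }
    }
    list(score = total, excluded = excluded,
         residuals = do.call(rbind, resid))
  }
  prof <- lapply(grid, score_gam)
  scores <- vapply(prof, `[[`, 0, "score")
  excluded <- unique(unlist(lapply(prof, `[[`, "excluded")))
  if (length(excluded))
    warning("dilution rate(s) infeasible and excluded from scoring: ",
            paste(signif(excluded, 4), collapse = ", "))
  best <- which.min(scores)
  fitted <- grid[best]
  it <- length(grid)
  if (refine && length(grid) >= 3 && best > 1 && best < length(grid)) {
    opt <- stats::optimize(function(g) score_gam(g)$score,
                           lower = grid[best - 1], upper = grid[best + 1],
                           tol = 0.5)
    it <- it + 10L
    if (opt$objective < scores[best]) fitted <- opt$minimum
  }
  calibration_result("gam", fitted,
                     residuals = prof[[best]]$residuals,
                     iterations = it, bracket = range(grid),
                     details = list(profile = setNames(scores, grid),
                                    excluded = excluded))
}

#' Fit the minimal unspecified-protein fraction to a target maximal
#' growth rate
#'
#' The maximal growth rate is non-increasing in the minimal UP fraction
#' (a larger metabolically inactive reserve leaves less usable proteome);
#' the fraction is bisected until the predicted maximal growth rate
#' matches the target.
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param target_mumax target maximal growth rate, h^-1.
#' @param bracket `c(lo, hi)` UP fractions straddling the target.
#' @param tol_mu acceptance tolerance on the growth rate, h^-1.
#' @param cfg a [solve_config()].
#' @return a `calibration_result`; `details$mumax` holds the achieved
#'   value.
#' @export
fit_min_up <- function(pc, medium, target_mumax, bracket = c(0.0, 0.9),
                       tol_mu = 1e-3, cfg = solve_config()) {
  mu_at <- function(f) maximize_growth(set_min_up(pc, f), medium, cfg)$mu
  mu_lo <- mu_at(bracket[1]); mu_hi <- mu_at(bracket[2])
  if (mu_lo < mu_hi - 1e-9)
    stop("maximal growth rate failed to decrease across the bracket; ",
         "the UP minimum is not limiting here")
  if (target_mumax > mu_lo + tol_mu || target_mumax < mu_hi - tol_mu)
    stop("target mumax ", target_mumax, " outside achievable range [",
         signif(mu_hi, 4), ", ", signif(mu_lo, 4), "]")
  lo <- bracket[1]; hi <- bracket[2]; it <- 0L; mu_mid <- mu_lo
  if (abs(mu_lo - target_mumax) <= tol_mu) {
    lo <- hi <- bracket[1]; mu_mid <- mu_lo
  } else if (abs(mu_hi - target_mumax) <= tol_mu) {
    lo <- hi <- bracket[2]; mu_mid <- mu_hi
  } else {
    repeat {
      it <- it + 1L
      mid <- (lo + hi) / 2
      mu_mid <- mu_at(mid)
      if (abs(mu_mid - target_mumax) <= tol_mu) { lo <- hi <- mid; break }
      if (mu_mid > target_mumax) lo <- mid else hi <- mid
      if (hi - lo < 1e-4 || it >= 30L) break
    }
  }
  calibration_result("min_up_fraction", (lo + hi) / 2,
                     residuals = mu_mid - target_mumax, iterations = it,
                     bracket = bracket,
                     details = list(mumax = mu_mid, target = target_mumax))
}

#' Sequential capacity/GAM recalibration protocol
#'
#' Reproduces the two-stage loop used for respiration-deficient strains:
#' fit the mitochondrial capacity scaling to the critical dilution rate at
#' the naive GAM, refit GAM against the observed exchange fluxes, then
#' readjust the capacity at the fitted GAM. Also reports the
#' ethanol-per-glucose ratio at the naive and fitted GAM as a diagnostic
#' (the ratio is expected to be largely insensitive to GAM).
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param target_dcrit target critical dilution rate, h^-1.
#' @param data chemostat flux data for the GAM stage
#'   (see [fit_gam_to_fluxes()]).
#' @param gam_grid candidate GAM values.
#' @param naive_gam starting GAM.
#' @param bracket capacity scaling bracket.
#' @param ... passed to [fit_capacity_to_dcrit()].
#' @return list with `capacity_stage1`, `gam_stage`, `capacity_stage2`,
#'   `qratio_diagnostic`.
#' @export
hap4_protocol <- function(pc, medium, target_dcrit, data,
                          gam_grid = c(24, 32, 40, 48), naive_gam = 24,
                          bracket = c(0.2, 2), ...) {
  s1 <- fit_capacity_to_dcrit(set_gam(pc, naive_gam), medium, "m",
                              target_dcrit, bracket, ...)
  pc1 <- scale_compartment_capacity(pc, "m", s1$fitted_value)
  s2 <- fit_gam_to_fluxes(pc1, medium, data, gam_grid)
  s3 <- fit_capacity_to_dcrit(set_gam(pc, s2$fitted_value), medium, "m",
                              target_dcrit, bracket, ...)
  qr <- function(gam) {
    m <- set_gam(scale_compartment_capacity(pc, "m", s3$fitted_value), gam)
    ph <- physiology(maximize_growth(m, medium), m$gem)
    if (ph$q_glc > 0) ph$q_etoh / ph$q_glc else NA_real_
  }
  list(capacity_stage1 = s1, gam_stage = s2, capacity_stage2 = s3,
       qratio_diagnostic = c(naive = qr(naive_gam),
                             fitted = qr(s2$fitted_value)))
}


#' Two-stage critical-dilution-rate estimate
#'
#' Sweeps the saturation grid, then re-sweeps the ethanol-onset bracket at
#' finer resolution before interpolating the critical dilution rate; this
#' is the estimator the capacity calibration uses.
#'
#' @param pc a `pc_model`.
#' @param medium a `medium_def`.
#' @param f_sat_grid coarse saturation grid.
#' @param cfg a [solve_config()].
#' @return critical dilution rate, h^-1 (NA when no onset).
#' @export
dcrit_refined <- function(pc, medium,
                          f_sat_grid = c(0.02, 0.04, 0.06, 0.08, 0.1,
                                         0.13, 0.16, 0.2, 0.28, 0.4,
                                         0.65, 1.0),
                          cfg = solve_config(
                            tie_break = "min_uptake_then_min_protein")) {
  curve <- chemostat_sweep(pc, medium, f_sat_grid, cfg = cfg)
  pts <- curve$points[!vapply(curve$points, function(p) is.null(p$result),
                              TRUE)]
  if (length(pts) < 2) return(NA_real_)
  qe <- vapply(pts, function(p) p$physiology$q_etoh, 0)
  fs <- vapply(pts, `[[`, 0, "f_sat")
  i <- which(qe > 1e-3)[1]
  if (!is.na(i) && i > 1) {
    fine <- seq(fs[i - 1], fs[i], length.out = 6)[2:5]
    curve <- chemostat_sweep(pc, medium, sort(unique(c(fs, fine))),
                             cfg = cfg)
  }
  suppressWarnings(detect_dcrit(curve))
}
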