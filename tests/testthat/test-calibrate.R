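test_that("GAM refits recover the generating value from synthetic
          chemostat data", {
  pc <- pc_aerobic(); med <- med_aerobic()
  fgrid <- c(0.03, 0.05, 0.08, 0.12, 0.16)
  dat <- make_synthetic_chemostat_data(pc, med, gam_true = 40, fgrid,
                                       noise_cv = 0, seed = 7)
  fit <- fit_gam_to_fluxes(pc, med, dat, grid = c(24, 32, 40, 48))
  expect_equal(fit$fitted_value, 40)
  expect_lt(fit$details$profile[["40"]], 1e-6)      # noiseless: exact
  ## 5 percent multiplicative noise, fixed seed
  dat5 <- make_synthetic_chemostat_data(pc, med, gam_true = 40, fgrid,
                                        noise_cv = 0.05, seed = 7)
  fit5 <- fit_gam_to_fluxes(pc, med, dat5, grid = c(24, 32, 40, 48))
  expect_equal(fit5$fitted_value, 40)
  expect_error(fit_gam_to_fluxes(pc, med, dat[0, ]), "empty")
  ## an unreachable dilution rate is excluded with a warning
  bad <- rbind(dat, data.frame(D_h = 2, q_glc = 1, q_etoh = 0,
                               q_glycerol = 0, q_o2 = 1, q_co2 = 1))
  expect_warning(fit_gam_to_fluxes(pc, med, bad, grid = c(24, 40)),
                 "excluded")
})

test_that("synthetic chemostat data are deterministic and exact at zero
          noise", {
  pc <- pc_aerobic(); med <- med_aerobic()
  fgrid <- c(0.04, 0.1)
  a <- make_synthetic_chemostat_data(pc, med, 24, fgrid, 0.05, seed = 3)
  b <- make_synthetic_chemostat_data(pc, med, 24, fgrid, 0.05, seed = 3)
  expect_identical(a, b)
  z <- make_synthetic_chemostat_data(pc, med, 24, fgrid, 0, seed = 3)
  curve <- chemostat_sweep(pc, med, fgrid)
  expect_equal(z$q_glc,
               vapply(curve$points, function(p) p$physiology$q_glc, 0),
               tolerance = 1e-9)
})

test_that("capacity calibration recovers a planted scaling factor", {
  pc <- pc_aerobic(); med <- med_aerobic()
  planted <- scale_compartment_capacity(pc, "m", 0.5)
  d_true <- dcrit_refined(planted, med)
  fit <- fit_capacity_to_dcrit(pc, med, "m", d_true, bracket = c(0.2, 2))
  expect_equal(fit$fitted_value, 0.5, tolerance = 0.02)
  expect_lte(abs(fit$details$dcrit - d_true), 5e-3)
  ## a target below the bracket's reachable range is rejected
  expect_error(
    fit_capacity_to_dcrit(pc, med, "m", 0.001, bracket = c(0.5, 1.5)),
    "outside bracket")
})

test_that("minimal-UP calibration matches a target growth rate and
          respects the bracket", {
  pc <- pc_aerobic(); med <- med_aerobic()
  planted <- 0.32
  target <- maximize_growth(set_min_up(pc, planted), med)$mu
  fit <- fit_min_up(pc, med, target, bracket = c(0.22, 0.6))
  expect_equal(fit$fitted_value, planted, tolerance = 0.005)
  expect_lte(abs(fit$details$mumax - target), 1e-3)
  ## endpoint identity: target equal to the low-endpoint optimum
  mu22 <- maximize_growth(set_min_up(pc, 0.22), med)$mu
  fit22 <- fit_min_up(pc, med, mu22, bracket = c(0.22, 0.6))
  expect_equal(fit22$fitted_value, 0.22, tolerance = 1e-9)
  ## unreachable target
  expect_error(fit_min_up(pc, med, mu22 + 0.1, bracket = c(0.22, 0.6)),
               "outside achievable")
})

test_that("the sequential capacity/GAM protocol runs both stages and
          keeps the ethanol-to-glucose ratio stable", {
  pc <- pc_aerobic(); med <- med_aerobic()
  ## synthesize the scenario: a strain with reduced mitochondrial
  ## capacity observed at its shifted critical dilution rate
  strain <- scale_compartment_capacity(set_gam(pc, 40), "m", 0.6)
  d_target <- dcrit_refined(strain, med)
  ## sub-critical dilution rates: there the respiratory state does not
  ## touch the capacity cap, so the maintenance parameter is identified
  ## independently of the (still mis-set) capacity
  dat <- make_synthetic_chemostat_data(strain, med, gam_true = 40,
                                       c(0.008, 0.012, 0.018), 0,
                                       seed = 1)
  out <- hap4_protocol(pc, med, d_target, dat, gam_grid = c(24, 40),
                       bracket = c(0.3, 1.5))
  expect_s3_class(out$capacity_stage2, "calibration_result")
  expect_equal(out$gam_stage$fitted_value, 40)
  expect_equal(out$capacity_stage2$fitted_value, 0.6, tolerance = 0.1)
  ## the qEtOH/qGlc diagnostic is insensitive to the GAM choice
  expect_equal(out$qratio_diagnostic[["naive"]],
               out$qratio_diagnostic[["fitted"]], tolerance = 0.25)
})
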