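test_that("feasibility behaves at the growth-rate boundaries", {
  pc <- pc_aerobic(); med <- med_aerobic()
  expect_true(feasible(pc, 0, med))
  ## no carbon + maintenance demand: infeasible even at zero growth
  closed <- med
  closed$exchange_bounds$EX_glc <- c(0, 0)
  expect_false(feasible(pc, 0, closed))
  expect_true(feasible(set_ngam(pc, 0), 0, closed))
  ## growth with all carbon closed is impossible
  expect_false(feasible(set_ngam(pc, 0), 0.05, closed))
})

test_that("growth is infeasible beyond the hand-computed yield ceiling", {
  ## anaerobic: <= 2 ATP per glucose, uptake capped by the carbon
  ## transporter area (0.13 * area * kcat * 3600 = 23.4 mmol/gDW/h), and
  ## >= 69 mmol ATP per gDW at GAM 40 - so mu < 2*23.4/69 = 0.68
  pc <- pc_anaerobic()
  expect_false(feasible(pc, 0.7, med_anaerobic()))
  expect_true(feasible(pc, 0.1, med_anaerobic()))
})

test_that("feasibility is monotone in the growth rate", {
  pc <- pc_aerobic(); med <- med_aerobic()
  mu_star <- batch_aerobic()$mu
  feas <- vapply(c(0.2, 0.6, 0.9, 1.2) * mu_star,
                 function(m) feasible(pc, m, med), TRUE)
  expect_equal(feas, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("fixed-growth solutions satisfy balances and closure", {
  pc <- pc_aerobic(); med <- med_aerobic()
  for (mu in c(0.05, 0.25, 0.4)) {
    res <- solve_at_mu(pc, mu, med)
    expect_equal(sum(res$proteome_fraction), 1, tolerance = 1e-6)
    ## mass balance: S v plus the translation drains vanishes row-wise
    S <- stoich_matrix(pc$gem)
    resid <- as.numeric(S %*% res$fluxes[colnames(S)])
    names(resid) <- rownames(S)
    prot <- pc$proteins
    syn <- res$synthesis_fluxes[prot$id]
    resid["aa_c"] <- resid["aa_c"] - sum(prot$length * syn)
    apb <- pc$translation$atp_per_peptide_bond
    resid["atp_c"] <- resid["atp_c"] - apb * sum(prot$length * syn) -
      pc$energy$gam * res$fluxes[["BIOMASS"]]
    resid["adp_c"] <- resid["adp_c"] + apb * sum(prot$length * syn) +
      pc$energy$gam * res$fluxes[["BIOMASS"]]
    expect_lt(max(abs(resid)), 1e-6)
    expect_true(all(res$constraint_utilization <=
                      1 + 1e-6 | !is.finite(res$constraint_utilization)))
  }
})

test_that("anaerobic maintenance at zero growth draws the fermentative
          minimum of half a millimole glucose", {
  pc <- set_ngam(pc_anaerobic(), 1)
  res <- solve_at_mu(pc, 0, med_anaerobic())
  ## 2 ATP per glucose fermented -> q_glc = ngam / 2
  expect_equal(-res$fluxes[["EX_glc"]], 0.5, tolerance = 1e-6)
  expect_equal(res$fluxes[["EX_etoh"]], 1.0, tolerance = 1e-6)
})

test_that("bisection certifies the maximum and reports active limits", {
  res <- batch_aerobic()
  pc <- pc_aerobic(); med <- med_aerobic()
  expect_true(feasible(pc, res$mu, med))
  expect_false(feasible(pc, res$mu + 5e-4, med))
  expect_gt(length(res$active_constraints), 0)
  expect_error(solve_at_mu(pc, res$mu + 0.05, med), "infeasible")
})

test_that("the upper-seed doubling guard flags unbounded growth", {
  cfg <- solve_config(mu_upper_seed = 0.05, mu_hard_cap = 0.15)
  expect_error(maximize_growth(pc_aerobic(), med_aerobic(), cfg),
               "unbounded")
})

test_that("precision refinement reproduces the default solution", {
  pc <- pc_aerobic(); med <- med_aerobic()
  a <- solve_at_mu(pc, 0.2, med)
  b <- solve_at_mu(pc, 0.2, med, solve_config(precision_refine = TRUE))
  expect_equal(b$fluxes, a$fluxes, tolerance = 1e-6)
})

test_that("constraint utilization flags the saturated capacities", {
  res <- batch_aerobic()
  cu <- constraint_utilization(res)
  expect_true(all(cu$utilization[cu$active] >= 1 - 2e-3))
  ## a capacity with a generous cap stays below saturation
  expect_lt(cu$utilization[["capacity_membrane_plasma_nitrogen"]], 0.5)
  expect_false("capacity_membrane_plasma_nitrogen" %in% cu$active)
})
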