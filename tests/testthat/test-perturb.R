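test_that("knockouts compose, validate ids and never increase growth", {
  pc <- pc_aerobic()
  expect_error(knockout(pc, "Nope1"), "Nope1")
  k <- knockout(knockout(pc, "Adh3"), "Gpd2")
  expect_setequal(k$knockouts, c("Adh3", "Gpd2"))
  mu_wt <- batch_aerobic()$mu
  for (g in c("adh3", "mae1")) {
    mu_ko <- maximize_growth(apply_genotype(pc, g), med_aerobic())$mu
    expect_lte(mu_ko, mu_wt + 1e-9)
  }
})

test_that("the paired Adh3/Gpd2 deletion reroutes mitochondrial redox
          through the malate-oxaloacetate shuttle", {
  pc <- apply_genotype(pc_anaerobic(), "adh3")
  res <- maximize_growth(pc, med_anaerobic())
  expect_lt(res$mu, batch_anaerobic()$mu)
  ## the shuttle carries flux: oxaloacetate-proton symport plus the
  ## ATP-driven proton export are both engaged
  expect_gt(abs(res$fluxes[["OAAt"]]), 1e-4)
  expect_gt(res$fluxes[["ATPASE"]], 1e-4)
  expect_lt(abs(res$fluxes[["ADH3"]]), 1e-8)
})

test_that("anaerobic medium setup closes oxygen, opens trace lipids and
          is idempotent", {
  med <- set_anaerobic(toy_medium(toy_default(), "aerobic_minimal"))
  expect_equal(med$exchange_bounds$EX_o2[1], 0)
  expect_equal(med$exchange_bounds$EX_erg[1], -0.05)
  expect_identical(set_anaerobic(med), med)
  expect_error(set_anaerobic(medium(list(EX_glc = c(-10, 0)))), "oxygen")
  ## without the trace lipids the lipid precursor cannot be made
  ## anaerobically, so growth is impossible
  med_bare <- toy_medium(toy_default(), "aerobic_minimal")
  med_bare$exchange_bounds$EX_o2 <- c(0, 0)
  expect_false(feasible(pc_anaerobic(), 0.05, med_bare))
  expect_true(feasible(pc_anaerobic(), 0.05, med_anaerobic()))
})

test_that("compartment capacity scaling shifts the critical dilution
          rate in the expected directions", {
  pc <- pc_aerobic(); med <- med_aerobic()
  expect_error(scale_compartment_capacity(pc, "vacuole", 1.2), "vacuole")
  ## identity
  same <- scale_compartment_capacity(pc, "m", 1.0)
  expect_equal(same$capacities, pc$capacities)
  grid <- c(0.02, 0.04, 0.06, 0.08, 0.1, 0.13, 0.16, 0.2, 0.28, 0.4, 1.0)
  d_wt <- dcrit_refined(pc, med, grid)
  d_oe <- dcrit_refined(scale_compartment_capacity(pc, "m", 1.25), med,
                        grid)
  d_del <- dcrit_refined(scale_compartment_capacity(pc, "m", 0.28), med,
                         grid)
  expect_gt(d_oe, d_wt + 5e-3)
  expect_lt(d_del, d_wt - 5e-3)
})

test_that("depletion slopes convert to uptake bounds by the stated rule", {
  d <- data.frame(
    amino_acid = rep(c("leu", "ala", "gly"), each = 3),
    biomass_gdw_per_l = rep(c(0.5, 1.0, 1.5), 3),
    conc_um = c(250, 150, 50,          # slope -200 uM per gDW/L
                100, 102.5, 105,       # positive slope: no uptake
                80, 60.5, 40))         # slope -40
  s <- aa_depletion_series(d, mu = 0.35)
  b <- aa_uptake_bounds(s)
  expect_equal(b[["leu"]], 200 * 0.35 / 1000)
  expect_equal(b[["ala"]], 0)
  expect_equal(b[["gly"]], 40 * 0.35 / 1000)
  ## two points: slope equals the finite difference
  d2 <- data.frame(amino_acid = "leu", biomass_gdw_per_l = c(1, 2),
                   conc_um = c(300, 200))
  expect_equal(aa_uptake_bounds(aa_depletion_series(d2, 0.35))[["leu"]],
               100 * 0.35 / 1000)
  expect_error(aa_depletion_series(
    data.frame(amino_acid = "x", biomass_gdw_per_l = 1, conc_um = 5), 0.3),
    "two points")
})

test_that("amino-acid supplementation relaxes, never restricts, growth", {
  pc <- pc_anaerobic()
  mu_min <- batch_anaerobic()$mu
  med_rich <- set_anaerobic(toy_medium(toy_default(), "aerobic_rich"))
  mu_rich <- maximize_growth(pc, med_rich)$mu
  expect_gt(mu_rich, mu_min)   # the mitochondrial synthesis burden lifts
})
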