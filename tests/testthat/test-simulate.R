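chemostat_cfg <- solve_config(tie_break = "min_uptake_then_min_protein")

test_that("physiological readouts follow exchange stoichiometry", {
  pc <- set_ngam(pc_aerobic(), 1)
  ## starvation state under uptake minimization: complete combustion
  res <- solve_at_mu(pc, 0, med_aerobic(), chemostat_cfg)
  ph <- physiology(res, toy_default()$gem)
  expect_equal(ph$rq, 1, tolerance = 1e-6)        # C6H12O6 + 6 O2 -> 6 CO2
  expect_equal(ph$q_co2, 6 * ph$q_glc, tolerance = 1e-6)
  ## fermentation state: oxygen-free, RQ undefined
  res2 <- solve_at_mu(set_ngam(pc_anaerobic(), 1), 0, med_anaerobic(),
                      chemostat_cfg)
  ph2 <- physiology(res2, toy_default()$gem)
  expect_true(is.na(ph2$rq))
  expect_equal(ph2$q_etoh, 2 * ph2$q_glc, tolerance = 1e-6)
  ## yield arithmetic
  res3 <- batch_aerobic()
  ph3 <- physiology(res3, toy_default()$gem)
  expect_equal(ph3$yield_xs, res3$mu / (ph3$q_glc * 0.18015))
  expect_error(physiology(res3, toy_default()$gem,
                          exchanges = c(glc = "EX_nope")), "EX_nope")
})

test_that("chemostat sweep is monotone and matches batch at full
          saturation", {
  pc <- pc_aerobic(); med <- med_aerobic()
  curve <- chemostat_sweep(pc, med, c(0.03, 0.08, 0.15, 0.4, 1.0))
  mus <- vapply(curve$points, function(p) p$physiology$mu, 0)
  expect_true(all(diff(mus) >= -1e-9))
  expect_equal(mus[5], batch_aerobic()$mu, tolerance = 2e-4)
  ## below the critical dilution rate the toy respires without overflow
  expect_equal(curve$points[[1]]$physiology$q_etoh, 0, tolerance = 1e-6)
  expect_gt(curve$points[[1]]$physiology$q_o2, 0)
})

test_that("critical dilution rate detection interpolates the onset", {
  fake_curve <- function(mu, qe) {
    pts <- Map(function(m, q)
      list(f_sat = m, physiology = list(mu = m, q_etoh = q), result = TRUE),
      mu, qe)
    structure(list(points = pts, d_crit = NA_real_),
              class = "chemostat_curve")
  }
  ## onset between mu 0.2 (q 0) and 0.3 (q 2): at eps 1e-3 the crossing
  ## sits at 0.2 + (1e-3/2) * 0.1
  d <- detect_dcrit(fake_curve(c(0.1, 0.2, 0.3), c(0, 0, 2)))
  expect_equal(d, 0.2 + 1e-3 / 2 * 0.1 / 1, tolerance = 1e-12)
  expect_warning(d0 <- detect_dcrit(fake_curve(c(0.1, 0.2), c(0, 0))),
                 "no ethanol onset")
  expect_true(is.na(d0))
  ## threshold above the maximum excretion: no onset
  expect_warning(
    dna <- detect_dcrit(fake_curve(c(0.1, 0.3), c(0, 2)), epsilon = 5),
    "no ethanol onset")
  expect_true(is.na(dna))
})

test_that("proteome fractions aggregate to unity by group", {
  res <- batch_aerobic()
  groups <- c(Pfk1 = "glycolysis", Pyk1 = "glycolysis", Cox1 = "oxphos",
              RIBOSOME = "ribosome")
  fr <- proteome_fractions(res, groups)
  expect_equal(sum(fr), 1, tolerance = 1e-6)
  expect_true(all(c("UP", "unassigned", "glycolysis", "ribosome")
                  %in% names(fr)))
  ## one group swallowing every protein leaves only UP beside it
  all_groups <- setNames(rep("all", nrow(pc_aerobic()$proteins)),
                         pc_aerobic()$proteins$id)
  fr2 <- proteome_fractions(res, all_groups[names(all_groups) != "UP"])
  expect_equal(unname(fr2[["all"]] + fr2[["UP"]]), 1, tolerance = 1e-6)
  ## an elevated UP floor is respected
  res_up <- maximize_growth(set_min_up(pc_aerobic(), 0.32), med_aerobic())
  expect_gte(proteome_fractions(res_up, groups)[["UP"]], 0.32 - 1e-6)
})

test_that("flux comparison flags rerouted and silenced reactions", {
  res <- batch_aerobic()
  cmp0 <- flux_comparison(res, res)
  expect_true(all(cmp0$flag == ""))
  mut <- res
  mut$fluxes[["SCL"]] <- res$fluxes[["SCL"]] + 1   # force a visible change
  mut$fluxes[["PDC"]] <- 20 * res$fluxes[["PDC"]]
  mut$fluxes[["ADH"]] <- 0
  cmp <- flux_comparison(res, mut)
  expect_equal(cmp$flag[cmp$reaction == "PDC"], "up")
  expect_equal(cmp$flag[cmp$reaction == "ADH"], "inactive")
  expect_equal(cmp$flag[cmp$reaction == "HXT"], "")
})

test_that("redox shuttle costs follow the proton bookkeeping", {
  toy <- toy_default()
  expect_equal(shuttle_cost(toy, "malate_oaa"), 1, tolerance = 1e-9)
  expect_equal(shuttle_cost(toy, "acetaldehyde_ethanol"), 0,
               tolerance = 1e-9)
  expect_equal(shuttle_cost(toy, "g3p"), 0, tolerance = 1e-9)
  ## proton leak: cost rises by exactly the leak stoichiometry
  for (h in c(1.5, 3)) {
    leaky <- make_toy_yeast(toy_config(ethanol_shuttle_h_leak = h))
    expect_equal(shuttle_cost(leaky, "acetaldehyde_ethanol"), h,
                 tolerance = 1e-9)
  }
})

test_that("the carnitine-shuttle ATP bypass spills two cytosolic
          equivalents per mitochondrial ATP", {
  expect_equal(bypass_cost(toy_default()), 2, tolerance = 1e-9)
})
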