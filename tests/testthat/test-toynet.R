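test_that("the toy network has no orphan metabolites", {
  gem <- toy_default()$gem
  uses <- table(unlist(lapply(gem$reactions, function(r) names(r$stoich))))
  internal <- gem$metabolites$id[!gem$metabolites$is_boundary]
  expect_true(all(internal %in% names(uses)))
  expect_true(all(uses[internal] >= 2))
})

test_that("the toy generator is deterministic", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_toy_dir(make_toy_yeast(), d1)
  write_toy_dir(make_toy_yeast(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("every internal reaction conserves carbon and electrons", {
  bal <- check_element_balance(toy_default())
  expect_lt(max(abs(bal$carbon)), 1e-9)
  expect_lt(max(abs(bal$electrons)), 1e-9)
})

test_that("capacity profiles carry the per-condition transporter areas", {
  pr <- toy_default()$profiles
  expect_equal(pr$aerobic_minimal$membrane_caps,
               c(carbon = 0.110, nitrogen = 0.045))
  expect_equal(pr$aerobic_rich$membrane_caps,
               c(carbon = 0.130, nitrogen = 0.055))
  expect_equal(pr$anaerobic$membrane_caps,
               c(carbon = 0.130, nitrogen = 0.045))
  expect_equal(pr$anaerobic$gam, 40)
  expect_equal(pr$anaerobic$min_up, 0.32)
})

test_that("anaerobic wild type outgrows the shuttle-deficient mutant", {
  mu_wt <- batch_anaerobic()$mu
  mu_mut <- maximize_growth(apply_genotype(pc_anaerobic(), "adh3"),
                            med_anaerobic())$mu
  expect_gte(mu_wt, mu_mut)
  expect_gt(mu_wt, mu_mut + 1e-3)   # strictly, at the bundled defaults
})

test_that("anaerobic glycerol excretion closes the cytosolic redox
          balance in closed form", {
  toy <- toy_default()
  cfgv <- toy$config
  res <- batch_anaerobic()
  ## zero growth, zero maintenance: no glycerol required
  res0 <- solve_at_mu(set_ngam(pc_anaerobic(), 0), 0, med_anaerobic())
  expect_lt(res0$fluxes[["EX_glyc"]], 1e-8)
  ## growing: every NADH source outside the glycerol shunt must drain
  ## through it. Per unit biomass: biomass_nadh; per amino acid: +1 from
  ## the withdrawn glycolytic pyruvate, +burden re-exported through the
  ## shuttle, -nadph_per_aa consumed by the malate/malic-enzyme cycle;
  ## per lipid (anaerobic route): +2 from acetyl activation.
  mu <- res$mu
  v_aas <- res$fluxes[["AAS"]]
  v_lip <- res$fluxes[["LIPANA"]]
  expected <- cfgv$biomass_nadh * mu +
    (1 + cfgv$amino_acid_mito_burden - cfgv$nadph_per_aa) * v_aas +
    2 * v_lip
  expect_equal(res$fluxes[["EX_glyc"]], expected, tolerance = 1e-6)
})

test_that("shuttle energetics are asymmetric by construction", {
  toy <- toy_default()
  expect_equal(shuttle_cost(toy, "malate_oaa") -
                 shuttle_cost(toy, "acetaldehyde_ethanol"), 1)
})
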