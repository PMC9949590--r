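## rebuild the aerobic model with altered rules
toy_pc_model_with_rules <- function(toy, rules) {
  toy$rules <- rules
  toy_pc_model(toy, "aerobic_minimal")
}

rule <- function(kf = NA_real_, kr = NA_real_)
  list(reaction_id = "R1", complex = c(P1 = 1), complex_id = "cx",
       kcat_fwd = kf, kcat_rev = kr)

test_that("turnover assignment applies default and floor", {
  out <- assign_kcats(list(rule(), rule(0.5), rule(250)))
  expect_equal(vapply(out, `[[`, 0, "kcat_fwd"), c(71, 1, 250))
  ## reverse defaults to forward
  expect_equal(out[[3]]$kcat_rev, 250)
  ## switchable floor keeps the measured value
  out2 <- assign_kcats(list(rule(0.5)), apply_floor = FALSE)
  expect_equal(out2[[1]]$kcat_fwd, 0.5)
  expect_error(assign_kcats(list(rule(-2))), "nonpositive")
  ## order independence
  a <- assign_kcats(list(rule(), rule(0.5)))
  b <- rev(assign_kcats(list(rule(0.5), rule())))
  expect_equal(vapply(a, `[[`, 0, "kcat_fwd"),
               vapply(b, `[[`, 0, "kcat_fwd"))
})

test_that("assembled registry has one synthesis balance per protein", {
  pc <- pc_aerobic()
  bal <- grep("^protein_balance_", pc$registry$constraints, value = TRUE)
  ## every table protein plus the two pseudo-proteins (ribosome, UP)
  expect_length(bal, nrow(toy_default()$proteins) + 2L)
  expect_true("protein_balance_UP" %in% bal)
  expect_false(anyDuplicated(pc$registry$constraints) > 0)
})

test_that("GAM enters the biomass column and is last-write-wins", {
  pc <- pc_aerobic()
  med <- med_aerobic()
  coef_at <- function(p) {
    asm <- pcfba:::assemble_pc_lp(p, med)
    i <- match("mass_atp_c", asm$cnames)
    asm$A[i, match("v_BIOMASS_f", asm$vnames)]
  }
  c24 <- coef_at(set_gam(pc, 24))
  c0 <- coef_at(set_gam(pc, 0))
  expect_equal(c0 - c24, 24)
  ## setting 40 then 24 equals never having set 40
  expect_equal(coef_at(set_gam(set_gam(pc, 40), 24)), c24)
})

test_that("UP minimum and NGAM parameters propagate to the system", {
  pc <- set_min_up(pc_aerobic(), 0.32)
  asm <- pcfba:::assemble_pc_lp(pc, med_aerobic())
  i <- match("up_minimum", asm$cnames)
  expect_equal(asm$rhs[i], 0.32 * 0.45)
  expect_error(set_min_up(pc, 1.0), "functional proteome")

  asm0 <- pcfba:::assemble_pc_lp(set_ngam(pc, 0), med_aerobic())
  expect_equal(asm0$lb[match("v_ATPM_f", asm0$vnames)], 0)
  asm2 <- pcfba:::assemble_pc_lp(set_ngam(pc, 2.5), med_aerobic())
  expect_equal(asm2$lb[match("v_ATPM_f", asm2$vnames)], 2.5)
})

test_that("growth rate enters only dilution terms and biomass bounds", {
  pc <- pc_aerobic(); med <- med_aerobic()
  asm <- pcfba:::assemble_pc_lp(pc, med)
  l1 <- pcfba:::lp_at_mu(asm, 0.1)
  l2 <- pcfba:::lp_at_mu(asm, 0.3)
  diff <- which(l1$A != l2$A, arr.ind = TRUE)
  expect_true(all(diff[, "row"] %in% asm$pbal))
  expect_true(all(diff[, "col"] %in% asm$c_ix))
  bdiff <- which(l1$lb != l2$lb | l1$ub != l2$ub)
  expect_equal(bdiff, asm$v_f[asm$i_bio])
})

test_that("zero enzyme abundance forces zero catalyzed flux", {
  pc <- knockout(pc_aerobic(), "Pdc1")
  res <- solve_at_mu(pc, 0.1, med_aerobic())
  expect_lt(abs(res$fluxes[["PDC"]]), 1e-8)
  expect_equal(res$enzyme_abundances[["Pdc1"]], 0)
})

test_that("doubling all turnover numbers weakly increases growth", {
  toy <- toy_default()
  toy2 <- toy
  toy2$rules <- lapply(toy$rules, function(r) {
    r$kcat_fwd <- 2 * r$kcat_fwd; r$kcat_rev <- 2 * r$kcat_rev; r
  })
  mu1 <- batch_aerobic()$mu
  mu2 <- maximize_growth(toy_pc_model(toy2, "aerobic_minimal"),
                         med_aerobic())$mu
  expect_gte(mu2, mu1 - 1e-9)
})

test_that("a rule-free model degenerates to FBA with proteome closure", {
  toy <- toy_default()
  pc <- build_pc_model(toy$gem, toy$proteins, list(),
                       translation_params(elongation_rate_aa_s = 3.5,
                                          aa_metabolite = "aa_c",
                                          atp_metabolite = "atp_c",
                                          adp_metabolite = "adp_c"),
                       energy_params(),
                       list(capacity_constraint("compartment_proteome",
                                                "c", 0.8)))
  res <- maximize_growth(pc, med_aerobic())
  expect_gt(res$mu, batch_aerobic()$mu)  # no kinetic limits left
  expect_equal(sum(res$proteome_fraction), 1, tolerance = 1e-6)
})

test_that("builder rejects dangling references and empty cap filters", {
  toy <- toy_default()
  bad <- toy$rules
  bad[[1]]$reaction_id <- "NOPE"
  expect_error(toy_pc_model_with_rules(toy, bad), "missing reaction")
  expect_error(
    build_pc_model(toy$gem, toy$proteins, toy$rules,
                   translation_params(), energy_params(),
                   list(capacity_constraint("membrane_area", "vacuole",
                                            0.1, "carbon"))),
    "resolves to no protein")
})

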