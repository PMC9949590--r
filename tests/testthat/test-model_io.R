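test_that("tabular model reader preserves records and counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mini_gem(path)
  gem <- read_gem(path, "tabular")
  expect_equal(length(gem$reactions), 10L)
  expect_equal(nrow(gem$metabolites), 12L)
  expect_equal(gem$biomass_reaction_id, "BIOMASS")
  expect_equal(gem$reactions$GLY$stoich[["pyr_c"]], 2)
  expect_equal(gem$reactions$EX_glc$lb, -10)
  expect_true(gem$reactions$EX_glc$is_exchange)
  expect_equal(gem$reactions$GLY$gene_association, "cx1")
})

test_that("model round-trips through both dialects", {
  gem <- toy_default()$gem
  for (dialect in c("tabular", "sbml")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_gem(gem, path, dialect)
    back <- read_gem(path, dialect)
    expect_equal(sort(names(back$reactions)), sort(names(gem$reactions)))
    expect_equal(back$metabolites$id, gem$metabolites$id)
    expect_equal(back$protein_content, gem$protein_content)
    for (id in names(gem$reactions)) {
      a <- gem$reactions[[id]]; b <- back$reactions[[id]]
      expect_equal(sort(names(a$stoich)), sort(names(b$stoich)), info = id)
      expect_equal(b$stoich[names(a$stoich)], a$stoich, info = id)
      expect_equal(c(b$lb, b$ub), c(a$lb, a$ub), info = id)
      expect_equal(b$gene_association, a$gene_association, info = id)
    }
  }
})

test_that("parsing is order-independent", {
  path <- withr::local_tempfile(); path2 <- withr::local_tempfile()
  write_mini_gem(path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  set.seed(42)
  writeLines(sample(body), path2)
  a <- read_gem(path); b <- read_gem(path2)
  expect_equal(sort(names(a$reactions)), sort(names(b$reactions)))
  expect_equal(sort(a$metabolites$id), sort(b$metabolites$id))
  expect_equal(a$reactions$GLY$stoich, b$reactions$GLY$stoich)
})

test_that("model validation names the offending record", {
  path <- withr::local_tempfile()
  write_mini_gem(path)
  lines <- readLines(path)
  lines <- sub("pyr_c:-1 nadh_c:-1", "xyz:-1 nadh_c:-1", lines)
  writeLines(lines, path)
  expect_error(read_gem(path), "xyz")

  lines <- readLines(write_mini_gem(path))
  lines <- c(lines, "metabolite\tglc_c\tdup\tc\t0")
  writeLines(lines, path)
  expect_error(read_gem(path), "duplicate")

  lines <- readLines(write_mini_gem(path))
  lines <- sub("model\tBIOMASS", "model\tNOPE", lines)
  writeLines(lines, path)
  expect_error(read_gem(path), "NOPE")
})

test_that("protein table aggregation, defaults and errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- paste(
    "protein_id\tlength_aa\tmw_kda\tcompartment\tcomplex_id\tcomplex_stoich\treaction_ids\tkcat_s",
    "P1\t500\t55\tc\tcxA\t2\tR1,R2\t",
    "P2\t300\t33\tc\tcxA\t1\t\t",
    "P3\t400\t44\tm\tcxB\t1\tR3\t12.5",
    sep = "\n")
  writeLines(tab, path)
  pt <- read_protein_table(path, compartments = c("c", "m"))
  expect_equal(nrow(pt$proteins), 3L)
  ## complex cxA: two subunits 2:1, catalyzing two reactions
  cxA <- Filter(function(r) r$complex_id == "cxA", pt$rules)
  expect_length(cxA, 2L)
  expect_equal(cxA[[1]]$complex, c(P1 = 2, P2 = 1))
  expect_true(is.na(cxA[[1]]$kcat_fwd))          # blank kcat stays unset
  cxB <- Filter(function(r) r$complex_id == "cxB", pt$rules)
  expect_equal(cxB[[1]]$kcat_fwd, 12.5)

  writeLines(sub("P3\t400\t44\tm", "P3\t400\t44\tnucleolus2", tab), path)
  expect_error(read_protein_table(path, compartments = c("c", "m")),
               "nucleolus2")
  writeLines(sub("P2\t300", "P2\t-1", tab), path)
  expect_error(read_protein_table(path, compartments = c("c", "m")),
               "length")
})

test_that("protein table round-trips", {
  toy <- toy_default()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(toy$proteins, toy$rules, path)
  back <- read_protein_table(path, compartments = c("c", "m"))
  expect_setequal(back$proteins$id, toy$proteins$id)
  expect_length(back$rules, length(toy$rules))
  ors <- setNames(toy$rules, vapply(toy$rules, `[[`, "", "reaction_id"))
  for (r in back$rules)
    expect_equal(r$kcat_fwd, ors[[r$reaction_id]]$kcat_fwd,
                 info = r$reaction_id)
})

test_that("medium and annotation tables read and write", {
  med <- medium(list(EX_glc = c(-10, 0), EX_o2 = c(-1000, 1000)),
                f_sat = c(Hxt1 = 0.25), name = "chemostat_point",
                limiting_exchange = "EX_glc")
  path <- withr::local_tempfile()
  write_medium(med, path)
  back <- read_medium(path)
  expect_equal(back$exchange_bounds, med$exchange_bounds)
  expect_equal(back$f_sat, med$f_sat)
  expect_equal(back$limiting_exchange, "EX_glc")
  expect_error(medium(f_sat = c(Hxt1 = 1.5)), "f_sat")

  apath <- withr::local_tempfile()
  writeLines("protein_id\tgroup\nPfk1\tglycolysis\nCox1\toxphos", apath)
  g <- read_annotation_groups(apath)
  expect_equal(g[["Cox1"]], "oxphos")
  writeLines("protein_id\tgroup\nPfk1\t", apath)
  expect_error(read_annotation_groups(apath), "empty")
})

test_that("solution tables round-trip to full precision", {
  res <- batch_aerobic()
  prefix <- file.path(withr::local_tempdir(), "run1")
  write_solution(res, prefix)
  back <- read_solution(prefix)
  expect_equal(back$mu, res$mu, tolerance = 1e-12)
  expect_equal(back$fluxes, res$fluxes, tolerance = 1e-12)
  expect_equal(back$enzyme_abundances, res$enzyme_abundances,
               tolerance = 1e-12)
  expect_setequal(back$active_constraints, res$active_constraints)
  ## refuse to write an unsolved placeholder
  bad <- res; bad$status <- "infeasible"
  expect_error(write_solution(bad, prefix), "solved")
})
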