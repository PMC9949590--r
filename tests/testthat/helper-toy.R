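## Shared fixtures: the default toy model and its standard media, built
## once per test run. All expensive solved states are cached lazily.

.toy_env <- new.env(parent = emptyenv())

toy_default <- function() {
  if (is.null(.toy_env$toy)) .toy_env$toy <- make_toy_yeast()
  .toy_env$toy
}

pc_aerobic <- function() {
  if (is.null(.toy_env$pc_aer))
    .toy_env$pc_aer <- toy_pc_model(toy_default(), "aerobic_minimal")
  .toy_env$pc_aer
}

pc_anaerobic <- function() {
  if (is.null(.toy_env$pc_ana))
    .toy_env$pc_ana <- toy_pc_model(toy_default(), "anaerobic")
  .toy_env$pc_ana
}

med_aerobic <- function() toy_medium(toy_default(), "aerobic_minimal")
med_anaerobic <- function() toy_medium(toy_default(), "anaerobic")

batch_aerobic <- function() {
  if (is.null(.toy_env$batch_aer))
    .toy_env$batch_aer <- maximize_growth(pc_aerobic(), med_aerobic())
  .toy_env$batch_aer
}

batch_anaerobic <- function() {
  if (is.null(.toy_env$batch_ana))
    .toy_env$batch_ana <- maximize_growth(pc_anaerobic(), med_anaerobic())
  .toy_env$batch_ana
}

## a tiny hand-written tabular model fixture: 12 metabolites, 10 reactions
write_mini_gem <- function(path) {
  lines <- c(
    "compartment\te\textracellular\t0",
    "compartment\tc\tcytosol\t0",
    "metabolite\tglc_e\tglucose\te\t0",
    "metabolite\tglc_c\tglucose\tc\t0",
    "metabolite\tpyr_c\tpyruvate\tc\t0",
    "metabolite\tetoh_c\tethanol\tc\t0",
    "metabolite\tetoh_e\tethanol\te\t0",
    "metabolite\tco2_c\tCO2\tc\t0",
    "metabolite\tco2_e\tCO2\te\t0",
    "metabolite\tatp_c\tATP\tc\t0",
    "metabolite\tadp_c\tADP\tc\t0",
    "metabolite\tnadh_c\tNADH\tc\t0",
    "metabolite\tnad_c\tNAD\tc\t0",
    "metabolite\tbm_c\tbiomass precursor\tc\t0",
    "reaction\tGLCt\tglc_e:-1 glc_c:1\t0\t1000\t0\t",
    "reaction\tGLY\tglc_c:-1 adp_c:-2 nad_c:-2 pyr_c:2 atp_c:2 nadh_c:2\t0\t1000\t0\tcx1",
    paste0("reaction\tFERM\tpyr_c:-1 nadh_c:-1 etoh_c:1 co2_c:1 nad_c:1",
           "\t0\t1000\t0\t"),
    "reaction\tETOHt\tetoh_c:-1 etoh_e:1\t-1000\t1000\t0\t",
    "reaction\tCO2t\tco2_c:-1 co2_e:1\t-1000\t1000\t0\t",
    "reaction\tBMS\tglc_c:-1 atp_c:-1 bm_c:1 adp_c:1\t0\t1000\t0\t",
    "reaction\tBIOMASS\tbm_c:-1\t0\t1000\t0\t",
    "reaction\tEX_glc\tglc_e:-1\t-10\t0\t1\t",
    "reaction\tEX_etoh\tetoh_e:-1\t0\t1000\t1\t",
    "reaction\tEX_co2\tco2_e:-1\t0\t1000\t1\t",
    "model\tBIOMASS\t0.45")
  writeLines(lines, path)
  path
}
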