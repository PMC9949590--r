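## Stoichiometric model container and readers/writers.
##
## A `gem_model` is a plain list: metabolite and compartment tables
## (data.frames), a named list of reactions (each with a sparse stoichiometry
## vector), the biomass reaction id and the total protein content of biomass.
## Two on-disk dialects are supported: a tab-separated text dialect (one
## record per line, human-diffable) and an SBML Level 3 + fbc subset.

#' Construct a stoichiometric model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `is_boundary`.
#' @param reactions named list; each element a list with `id`, `stoich`
#'   (named numeric, negative = consumed), `lb`, `ub` (mmol gDW^-1 h^-1),
#'   `is_exchange`, `gene_association` (character vector of complex ids,
#'   empty = spontaneous).
#' @param compartments data.frame with columns `id`, `name`, `membrane`
#'   (logical: does this compartment id denote a membrane that can carry
#'   transporter-area constraints).
#' @param biomass_reaction_id id of the biomass reaction.
#' @param protein_content total protein mass per dry weight, g gDW^-1,
#'   in (0, 1).
#' @return object of class `gem_model`.
#' @export
gem_model <- function(metabolites, reactions, compartments,
                      biomass_reaction_id, protein_content = 0.45) {
  gem <- structure(list(metabolites = metabolites, reactions = reactions,
                        compartments = compartments,
                        biomass_reaction_id = biomass_reaction_id,
                        protein_content = protein_content),
                   class = "gem_model")
  validate_gem(gem)
  gem
}

#' @export
print.gem_model <- function(x, ...) {
  cat("gem_model:", length(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,",
      nrow(x$compartments), "compartments\n")
  cat("  biomass:", x$biomass_reaction_id,
      " protein content:", x$protein_content, "g/gDW\n")
  invisible(x)
}

validate_gem <- function(gem) {
  met <- gem$metabolites
  if (anyDuplicated(met$id))
    stop("duplicate metabolite id: ", met$id[duplicated(met$id)][1])
  rid <- vapply(gem$reactions, `[[`, "", "id")
  if (anyDuplicated(rid))
    stop("duplicate reaction id: ", rid[duplicated(rid)][1])
  bad_comp <- setdiff(met$compartment, gem$compartments$id)
  if (length(bad_comp))
    stop("metabolite compartment not declared: ", bad_comp[1])
  for (r in gem$reactions) {
    missing <- setdiff(names(r$stoich), met$id)
    if (length(missing))
      stop("reaction '", r$id, "' references undeclared metabolite '",
           missing[1], "'")
    if (r$lb > r$ub)
      stop("reaction '", r$id, "': lower bound exceeds upper bound")
    if (isTRUE(r$is_exchange)) {
      nb <- sum(!met$is_boundary[match(names(r$stoich), met$id)])
      if (nb != 1L)
        stop("exchange reaction '", r$id,
             "' must touch exactly one non-boundary metabolite")
    }
  }
  if (!gem$biomass_reaction_id %in% rid)
    stop("biomass reaction '", gem$biomass_reaction_id, "' not present")
  if (!(gem$protein_content > 0 && gem$protein_content < 1))
    stop("protein_content must lie in (0, 1)")
  invisible(TRUE)
}

#' Stoichiometric matrix of a model
#'
#' @param gem a `gem_model`.
#' @param drop_boundary drop rows of boundary metabolites.
#' @return dense numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(gem, drop_boundary = TRUE) {
  met <- gem$metabolites
  if (drop_boundary) met <- met[!met$is_boundary, , drop = FALSE]
  rid <- vapply(gem$reactions, `[[`, "", "id")
  S <- matrix(0, nrow(met), length(rid), dimnames = list(met$id, rid))
  for (r in gem$reactions) {
    keep <- intersect(names(r$stoich), met$id)
    S[keep, r$id] <- r$stoich[keep]
  }
  S
}

## ---------------------------------------------------------------------
## tabular dialect
## ---------------------------------------------------------------------

DEFAULT_BOUND <- 1000

fmt_num <- function(x) sprintf("%.15g", x)

#' Read a stoichiometric model
#'
#' @param path file path.
#' @param dialect `"tabular"` (tab-separated record lines) or `"sbml"`
#'   (SBML Level 3 + fbc subset).
#' @return a `gem_model`.
#' @export
read_gem <- function(path, dialect = c("tabular", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "sbml") return(read_gem_sbml(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(fields, `[[`, "", 1L)
  pick <- function(k) fields[kind == k]

  comp <- pick("compartment")
  compartments <- data.frame(
    id = vapply(comp, `[[`, "", 2L),
    name = vapply(comp, `[[`, "", 3L),
    membrane = vapply(comp, `[[`, "", 4L) == "1",
    stringsAsFactors = FALSE)

  metl <- pick("metabolite")
  metabolites <- data.frame(
    id = vapply(metl, `[[`, "", 2L),
    name = vapply(metl, `[[`, "", 3L),
    compartment = vapply(metl, `[[`, "", 4L),
    is_boundary = vapply(metl, `[[`, "", 5L) == "1",
    stringsAsFactors = FALSE)

  reactions <- list()
  for (f in pick("reaction")) {
    id <- f[[2L]]
    stoich <- parse_stoich(f[[3L]], id)
    lb <- if (f[[4L]] == "") -DEFAULT_BOUND else as.numeric(f[[4L]])
    ub <- if (f[[5L]] == "") DEFAULT_BOUND else as.numeric(f[[5L]])
    genes <- if (length(f) >= 7L && nzchar(f[[7L]]))
      strsplit(f[[7L]], ",", fixed = TRUE)[[1L]] else character()
    reactions[[id]] <- list(id = id, stoich = stoich, lb = lb, ub = ub,
                            is_exchange = f[[6L]] == "1",
                            gene_association = genes)
  }

  mod <- pick("model")
  if (length(mod) != 1L) stop("model record missing or duplicated")
  gem_model(metabolites, reactions, compartments,
            biomass_reaction_id = mod[[1L]][[2L]],
            protein_content = as.numeric(mod[[1L]][[3L]]))
}

parse_stoich <- function(txt, rid) {
  if (!nzchar(txt)) stop("reaction '", rid, "': empty stoichiometry")
  parts <- strsplit(trimws(txt), " ", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("reaction '", rid, "': malformed stoichiometry term '",
         parts[bad][1], "'")
  setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
           vapply(kv, `[[`, "", 1L))
}

#' Write a stoichiometric model
#'
#' @inheritParams read_gem
#' @param gem a `gem_model`.
#' @export
write_gem <- function(gem, path, dialect = c("tabular", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "sbml") return(write_gem_sbml(gem, path))
  out <- c("# pcfba tabular model",
           "# compartment\tid\tname\tmembrane")
  out <- c(out, sprintf("compartment\t%s\t%s\t%d", gem$compartments$id,
                        gem$compartments$name,
                        as.integer(gem$compartments$membrane)))
  out <- c(out, "# metabolite\tid\tname\tcompartment\tboundary",
           sprintf("metabolite\t%s\t%s\t%s\t%d", gem$metabolites$id,
                   gem$metabolites$name, gem$metabolites$compartment,
                   as.integer(gem$metabolites$is_boundary)))
  out <- c(out, "# reaction\tid\tstoich\tlb\tub\texchange\tgenes")
  for (r in gem$reactions) {
    st <- paste(sprintf("%s:%s", names(r$stoich), fmt_num(r$stoich)),
                collapse = " ")
    out <- c(out, sprintf("reaction\t%s\t%s\t%s\t%s\t%d\t%s", r$id, st,
                          fmt_num(r$lb), fmt_num(r$ub),
                          as.integer(isTRUE(r$is_exchange)),
                          paste(r$gene_association, collapse = ",")))
  }
  out <- c(out, sprintf("model\t%s\t%s", gem$biomass_reaction_id,
                        fmt_num(gem$protein_content)))
  writeLines(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------
## SBML L3 + fbc subset
## ---------------------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_gem_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)

  cn <- xml2::xml_find_all(model, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- data.frame(
    id = xml2::xml_attr(cn, "id"),
    name = ifelse(is.na(xml2::xml_attr(cn, "name")), xml2::xml_attr(cn, "id"),
                  xml2::xml_attr(cn, "name")),
    membrane = !is.na(xml2::xml_attr(cn, "membrane")) &
      xml2::xml_attr(cn, "membrane") == "true",
    stringsAsFactors = FALSE)

  sp <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), xml2::xml_attr(sp, "id"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    is_boundary = xml2::xml_attr(sp, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))

  reactions <- list()
  for (rn in xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)) {
    id <- xml2::xml_attr(rn, "id")
    sto <- numeric()
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      m <- xml2::xml_attr(sr, "species")
      sto[m] <- (if (is.na(sto[m])) 0 else sto[m]) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      m <- xml2::xml_attr(sr, "species")
      sto[m] <- (if (is.na(sto[m])) 0 else sto[m]) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbp <- xml2::xml_attr(rn, "fbc:lowerFluxBound")
    if (is.na(lbp)) lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    if (is.na(ubp)) ubp <- xml2::xml_attr(rn, "fbc:upperFluxBound")
    lb <- if (is.na(lbp)) -DEFAULT_BOUND else unname(parval[lbp])
    ub <- if (is.na(ubp)) DEFAULT_BOUND else unname(parval[ubp])
    genes <- xml2::xml_attr(rn, "genes")
    genes <- if (is.na(genes) || !nzchar(genes)) character()
      else strsplit(genes, ",", fixed = TRUE)[[1L]]
    reactions[[id]] <- list(id = id, stoich = sto, lb = lb, ub = ub,
                            is_exchange = grepl("^EX_", id),
                            gene_association = genes)
  }

  biomass <- xml2::xml_attr(model, "biomassReaction")
  pc <- xml2::xml_attr(model, "proteinContent")
  gem_model(metabolites, reactions, compartments,
            biomass_reaction_id = biomass,
            protein_content = as.numeric(pc))
}

write_gem_sbml <- function(gem, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
           sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
                   SBML_NS, FBC_NS),
           sprintf('<model id="pcfba_model" biomassReaction="%s" proteinContent="%s" fbc:strict="false">',
                   gem$biomass_reaction_id, fmt_num(gem$protein_content)),
           "<listOfCompartments>",
           sprintf('<compartment id="%s" name="%s" membrane="%s" constant="true"/>',
                   gem$compartments$id, esc(gem$compartments$name),
                   tolower(gem$compartments$membrane)),
           "</listOfCompartments>", "<listOfSpecies>",
           sprintf('<species id="%s" name="%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
                   gem$metabolites$id, esc(gem$metabolites$name),
                   gem$metabolites$compartment,
                   tolower(gem$metabolites$is_boundary)),
           "</listOfSpecies>")
  bounds <- unique(unlist(lapply(gem$reactions, function(r) c(r$lb, r$ub))))
  bid <- function(v) sprintf("b_%s", gsub("[^0-9A-Za-z]", "_", fmt_num(v)))
  out <- c(out, "<listOfParameters>",
           sprintf('<parameter id="%s" value="%s" constant="true"/>',
                   bid(bounds), fmt_num(bounds)),
           "</listOfParameters>", "<listOfReactions>")
  for (r in gem$reactions) {
    out <- c(out, sprintf('<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s" genes="%s">',
                          r$id, tolower(r$lb < 0), bid(r$lb), bid(r$ub),
                          paste(r$gene_association, collapse = ",")))
    cons <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(cons))
      out <- c(out, "<listOfReactants>",
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       names(cons), fmt_num(-cons)),
               "</listOfReactants>")
    if (length(prod))
      out <- c(out, "<listOfProducts>",
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       names(prod), fmt_num(prod)),
               "</listOfProducts>")
    out <- c(out, "</reaction>")
  }
  out <- c(out, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------
## protein table
## ---------------------------------------------------------------------

#' Read a protein table
#'
#' Tab-separated with columns `protein_id`, `length_aa`, `mw_kda`,
#' `compartment`, `complex_id`, `complex_stoich`, `reaction_ids`
#' (comma-separated), `kcat_s` (blank = unset, resolved later by
#' [assign_kcats()]). Optional columns: `kcat_rev_s`, `is_transporter`,
#' `membrane`, `transporter_class`, `area`.
#'
#' Rows sharing a `complex_id` are aggregated into one catalytic complex;
#' the complex's reaction set is the union over its rows.
#'
#' @param path file path.
#' @param compartments character vector of valid compartment ids (or a
#'   `gem_model`); `NULL` skips the check.
#' @return list with `proteins` (data.frame) and `rules` (list of catalysis
#'   rules: `reaction_id`, `complex` named numeric of subunit stoichiometry,
#'   `kcat_fwd`, `kcat_rev`, possibly `NA` = unset).
#' @export
read_protein_table <- function(path, compartments = NULL) {
  if (inherits(compartments, "gem_model"))
    compartments <- compartments$compartments$id
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("protein_id", "length_aa", "mw_kda", "compartment",
            "complex_id", "complex_stoich", "reaction_ids", "kcat_s")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("protein table lacks column(s): ",
                            paste(missing, collapse = ", "))
  numcol <- function(x) suppressWarnings(as.numeric(x))
  for (i in seq_len(nrow(tab))) {
    len <- numcol(tab$length_aa[i]); mw <- numcol(tab$mw_kda[i])
    if (is.na(len) || len < 1)
      stop("protein table row ", i, " ('", tab$protein_id[i],
           "'): nonpositive or missing length")
    if (is.na(mw) || mw <= 0)
      stop("protein table row ", i, " ('", tab$protein_id[i],
           "'): nonpositive or missing molecular weight")
    if (!is.null(compartments) && !tab$compartment[i] %in% compartments)
      stop("protein table row ", i, " ('", tab$protein_id[i],
           "'): unknown compartment '", tab$compartment[i], "'")
  }
  opt <- function(col, default) if (col %in% names(tab)) tab[[col]]
    else rep(default, nrow(tab))
  proteins <- data.frame(
    id = tab$protein_id,
    length = numcol(tab$length_aa),
    mw = numcol(tab$mw_kda),
    compartment = tab$compartment,
    is_transporter = opt("is_transporter", "0") %in% c("1", "TRUE", "true"),
    membrane = opt("membrane", ""),
    transporter_class = opt("transporter_class", ""),
    area = ifelse(is.na(numcol(opt("area", "1"))), 1,
                  numcol(opt("area", "1"))),
    stringsAsFactors = FALSE)
  proteins <- proteins[!duplicated(proteins$id), , drop = FALSE]
  rownames(proteins) <- NULL

  rules <- list()
  for (cx in unique(tab$complex_id[nzchar(tab$complex_id)])) {
    rows <- tab[tab$complex_id == cx, , drop = FALSE]
    complex <- setNames(numcol(rows$complex_stoich), rows$protein_id)
    complex[is.na(complex)] <- 1
    rxns <- unique(unlist(strsplit(rows$reaction_ids[nzchar(rows$reaction_ids)],
                                   ",", fixed = TRUE)))
    kf <- numcol(rows$kcat_s); kf <- kf[!is.na(kf)]
    kr <- numcol(opt("kcat_rev_s", "")[tab$complex_id == cx])
    kr <- kr[!is.na(kr)]
    if (length(kf) && any(kf <= 0))
      stop("complex '", cx, "': nonpositive measured kcat")
    for (r in rxns) {
      rules[[length(rules) + 1L]] <- list(
        reaction_id = r, complex = complex, complex_id = cx,
        kcat_fwd = if (length(kf)) kf[1] else NA_real_,
        kcat_rev = if (length(kr)) kr[1] else NA_real_)
    }
  }
  list(proteins = proteins, rules = rules)
}

#' Write a protein table
#'
#' Inverse of [read_protein_table()]; one row per (complex, subunit) with the
#' complex's first reaction list repeated on its first row.
#' @param proteins,rules as returned by [read_protein_table()].
#' @param path output file.
#' @export
write_protein_table <- function(proteins, rules, path) {
  ## group rules back per complex
  cxs <- split(rules, vapply(rules, `[[`, "", "complex_id"))
  rows <- list()
  seen <- character()
  for (cx in names(cxs)) {
    rl <- cxs[[cx]]
    complex <- rl[[1L]]$complex
    rxns <- paste(unique(vapply(rl, `[[`, "", "reaction_id")), collapse = ",")
    for (j in seq_along(complex)) {
      p <- proteins[proteins$id == names(complex)[j], , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p$id, length_aa = p$length, mw_kda = p$mw,
        compartment = p$compartment, complex_id = cx,
        complex_stoich = unname(complex[j]),
        reaction_ids = if (j == 1L) rxns else "",
        kcat_s = ifelse(is.na(rl[[1L]]$kcat_fwd), "",
                        fmt_num(rl[[1L]]$kcat_fwd)),
        kcat_rev_s = ifelse(is.na(rl[[1L]]$kcat_rev), "",
                            fmt_num(rl[[1L]]$kcat_rev)),
        is_transporter = as.integer(p$is_transporter),
        membrane = p$membrane, transporter_class = p$transporter_class,
        area = p$area, stringsAsFactors = FALSE)
      seen <- c(seen, p$id)
    }
  }
  ## proteins with no catalytic role still get a row
  for (i in which(!proteins$id %in% seen)) {
    p <- proteins[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = p$id, length_aa = p$length, mw_kda = p$mw,
      compartment = p$compartment, complex_id = "", complex_stoich = "",
      reaction_ids = "", kcat_s = "", kcat_rev_s = "",
      is_transporter = as.integer(p$is_transporter), membrane = p$membrane,
      transporter_class = p$transporter_class, area = p$area,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------
## medium, annotation groups
## ---------------------------------------------------------------------

#' Define a growth medium
#'
#' @param exchange_bounds named list (or 2-column matrix with rownames) of
#'   `c(lower, upper)` flux bounds per exchange reaction, mmol gDW^-1 h^-1;
#'   uptake is the negative direction, so a closed nutrient has lower
#'   bound 0.
#' @param f_sat named numeric in (0, 1]: saturation factor per
#'   transporter protein id; scales the transporter's effective turnover
#'   (`kcat* = f_sat * kcat`) to emulate substrate limitation.
#' @param name medium label.
#' @param limiting_exchange exchange id whose uptake the solver's first
#'   lexicographic objective minimizes (the limiting substrate).
#' @return object of class `medium_def`.
#' @export
medium <- function(exchange_bounds = list(), f_sat = numeric(),
                   name = "medium", limiting_exchange = NULL) {
  if (is.matrix(exchange_bounds))
    exchange_bounds <- setNames(split(exchange_bounds, row(exchange_bounds)),
                                rownames(exchange_bounds))
  if (length(f_sat) && (any(f_sat <= 0) || any(f_sat > 1)))
    stop("f_sat entries must lie in (0, 1]")
  structure(list(exchange_bounds = exchange_bounds, f_sat = f_sat,
                 name = name, limiting_exchange = limiting_exchange),
            class = "medium_def")
}

#' @export
print.medium_def <- function(x, ...) {
  cat("medium_def '", x$name, "': ", length(x$exchange_bounds),
      " exchange bounds, ", length(x$f_sat), " saturation factors\n",
      sep = "")
  invisible(x)
}

#' Read / write a medium definition (TSV record lines)
#' @param path file path.
#' @export
read_medium <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(fields, `[[`, "", 1L)
  eb <- list(); fs <- numeric(); nm <- "medium"; lim <- NULL
  for (f in fields) {
    switch(f[[1L]],
      exchange = { eb[[f[[2L]]]] <- as.numeric(c(f[[3L]], f[[4L]])) },
      fsat = { fs[f[[2L]]] <- as.numeric(f[[3L]]) },
      name = { nm <- f[[2L]] },
      limiting = { lim <- f[[2L]] },
      stop("unknown medium record '", f[[1L]], "'"))
  }
  medium(eb, fs, nm, lim)
}

#' @rdname read_medium
#' @param med a `medium_def`.
#' @export
write_medium <- function(med, path) {
  out <- c(sprintf("name\t%s", med$name))
  if (!is.null(med$limiting_exchange))
    out <- c(out, sprintf("limiting\t%s", med$limiting_exchange))
  for (id in names(med$exchange_bounds)) {
    b <- med$exchange_bounds[[id]]
    out <- c(out, sprintf("exchange\t%s\t%s\t%s", id, fmt_num(b[1]),
                          fmt_num(b[2])))
  }
  for (p in names(med$f_sat))
    out <- c(out, sprintf("fsat\t%s\t%s", p, fmt_num(med$f_sat[[p]])))
  writeLines(out, path)
  invisible(path)
}

#' Read annotation groups (protein id to pathway-group label)
#'
#' @param path TSV with columns `protein_id`, `group`.
#' @return named character vector.
#' @export
read_annotation_groups <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "group") %in% names(tab)))
    stop("annotation table needs columns protein_id, group")
  if (any(is.na(tab$group) | !nzchar(tab$group)))
    stop("empty group label")
  setNames(tab$group, tab$protein_id)
}

## ---------------------------------------------------------------------
## solution tables
## ---------------------------------------------------------------------

#' Write a solved simulation result as delimited text tables
#'
#' Emits `<prefix>_fluxes.tsv`, `<prefix>_enzymes.tsv`,
#' `<prefix>_constraints.tsv` and a short `<prefix>_summary.txt`.
#' Values are written with 15 significant digits so a round trip through
#' [read_solution()] reproduces them to at least 12.
#'
#' @param result a solved `sim_result` (see [solve_at_mu()]).
#' @param prefix output path prefix.
#' @export
write_solution <- function(result, prefix) {
  if (!inherits(result, "sim_result") || !identical(result$status, "optimal"))
    stop("write_solution: result is not a solved sim_result")
  wr <- function(df, what) {
    p <- paste0(prefix, "_", what, ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  wr(data.frame(reaction = names(result$fluxes),
                flux = fmt_num(result$fluxes)), "fluxes")
  wr(data.frame(protein = names(result$enzyme_abundances),
                abundance = fmt_num(result$enzyme_abundances),
                proteome_fraction = fmt_num(result$proteome_fraction)),
     "enzymes")
  wr(data.frame(constraint = names(result$constraint_utilization),
                utilization = fmt_num(result$constraint_utilization),
                active = as.integer(names(result$constraint_utilization)
                                    %in% result$active_constraints)),
     "constraints")
  writeLines(c(sprintf("status\t%s", result$status),
               sprintf("mu_per_h\t%s", fmt_num(result$mu)),
               sprintf("medium\t%s", result$medium %||% "")),
             paste0(prefix, "_summary.txt"))
  invisible(prefix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_solution
#' @export
read_solution <- function(prefix) {
  fl <- read.delim(paste0(prefix, "_fluxes.tsv"), stringsAsFactors = FALSE)
  en <- read.delim(paste0(prefix, "_enzymes.tsv"), stringsAsFactors = FALSE)
  co <- read.delim(paste0(prefix, "_constraints.tsv"),
                   stringsAsFactors = FALSE)
  su <- strsplit(readLines(paste0(prefix, "_summary.txt")), "\t")
  suv <- setNames(vapply(su, `[[`, "", 2L), vapply(su, `[[`, "", 1L))
  structure(list(
    mu = as.numeric(suv[["mu_per_h"]]),
    fluxes = setNames(as.numeric(fl$flux), fl$reaction),
    enzyme_abundances = setNames(as.numeric(en$abundance), en$protein),
    proteome_fraction = setNames(as.numeric(en$proteome_fraction),
                                 en$protein),
    constraint_utilization = setNames(as.numeric(co$utilization),
                                      co$constraint),
    active_constraints = co$constraint[co$active == 1L],
    status = suv[["status"]], medium = suv[["medium"]]),
    class = "sim_result")
}
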