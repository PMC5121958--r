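# Model readers and writers.
#
# Two dialects:
#   * tabular_json — a flat, diff-able fixture format:
#       {metabolites: [{id, compartment}],
#        reactions:   [{id, stoich: {met: coef}, lb, ub, gpr, subsystem, external_id}],
#        biomass:     id}
#   * sbml — SBML Level 3 with the fbc extension (explicit flux-bound
#     parameters and geneProductAssociation trees). The reader also tolerates
#     legacy documents that encode reversibility only through the reaction's
#     "reversible" attribute and carry GPR/subsystem in COBRA-style notes.

#' Read a metabolic model
#'
#' @param path Path to a model file.
#' @param dialect `"tabular_json"` or `"sbml"`; guessed from the file
#'   extension when omitted (`.json` vs `.xml`/`.sbml`).
#' @return A validated [metabolic_model()].
#' @export
read_model <- function(path, dialect = c("auto", "tabular_json", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular_json"
  }
  switch(dialect,
    tabular_json = .read_model_json(path),
    sbml = .read_model_sbml(path)
  )
}

#' Write a metabolic model
#'
#' @param model A [metabolic_model()].
#' @param path Output file.
#' @param dialect `"tabular_json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("tabular_json", "sbml")) {
  dialect <- match.arg(dialect)
  validate_metabolic_model(model)
  switch(dialect,
    tabular_json = .write_model_json(model, path),
    sbml = .write_model_sbml(model, path)
  )
  invisible(path)
}

.read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed model JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (field in c("reactions", "biomass")) {
    if (is.null(doc[[field]])) {
      stop("model JSON '", path, "' lacks required element '", field, "'", call. = FALSE)
    }
  }
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoich)) {
      stop("malformed reaction entry (missing id or stoich) in '", path, "'", call. = FALSE)
    }
    reaction(
      id = r$id,
      stoich = unlist(r$stoich),
      lb = if (is.null(r$lb)) -1000 else r$lb,
      ub = if (is.null(r$ub)) 1000 else r$ub,
      gpr = if (is.null(r$gpr)) "" else r$gpr,
      subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
      external_id = if (is.null(r$external_id)) NA_character_ else r$external_id
    )
  })
  mets <- NULL
  if (!is.null(doc$metabolites)) {
    mets <- data.frame(
      id = vapply(doc$metabolites, `[[`, "", "id"),
      compartment = vapply(doc$metabolites, function(m) {
        if (is.null(m$compartment)) "" else m$compartment
      }, ""),
      stringsAsFactors = FALSE
    )
  }
  metabolic_model(rxns, biomass = doc$biomass, metabolites = mets,
                  id = if (is.null(doc$id)) "model" else doc$id)
}

.write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i], compartment = model$metabolites$compartment[i])
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(id = r$id, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub,
                  gpr = r$gpr, subsystem = r$subsystem)
      if (!is.na(r$external_id)) out$external_id <- r$external_id
      out
    }),
    biomass = model$biomass
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---------------------------------------------------------------------------
# SBML L3 + fbc

.xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.gpr_to_fbc <- function(gpr, indent) {
  tree <- .gpr_parse(.gpr_tokenize(gpr))
  render <- function(node, ind) {
    pad <- strrep(" ", ind)
    if (!is.null(node$gene)) {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     pad, .sbml_id(node$gene)))
    }
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    paste(
      c(sprintf("%s<%s>", pad, tag),
        vapply(node$args, render, "", ind + 2L),
        sprintf("%s</%s>", pad, tag)),
      collapse = "\n"
    )
  }
  render(tree, indent)
}

.write_model_sbml <- function(model, path) {
  bnd <- model_bounds(model)
  params <- unique(c(bnd$lb, bnd$ub))
  pid <- function(v) {
    sprintf("fb_%s", gsub("[^0-9A-Za-z]", "_",
                          vapply(v, format, "", scientific = FALSE, trim = TRUE)))
  }
  comps <- unique(model$metabolites$compartment)
  if (!length(comps)) comps <- "c"
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', .sbml_id(model$id)),
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>', .sbml_id(comps)),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf('      <species id="M_%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            .sbml_id(model$metabolites$id),
            .sbml_id(ifelse(nzchar(model$metabolites$compartment),
                            model$metabolites$compartment, comps[1]))),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            pid(params), format(params, scientific = FALSE)),
    "    </listOfParameters>",
    "    <listOfReactions>"
  )
  genes <- model_genes(model)
  for (r in model$reactions) {
    notes <- sprintf(
      paste0('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
             "<p>SUBSYSTEM: %s</p><p>EXTERNAL_ID: %s</p></body></notes>"),
      .xml_esc(r$subsystem), .xml_esc(ifelse(is.na(r$external_id), "", r$external_id))
    )
    lines <- c(lines, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      .sbml_id(r$id), tolower(r$lb < 0), pid(r$lb), pid(r$ub)
    ), notes)
    if (nzchar(trimws(r$gpr))) {
      lines <- c(lines,
                 "        <fbc:geneProductAssociation>",
                 .gpr_to_fbc(r$gpr, 10L),
                 "        </fbc:geneProductAssociation>")
    }
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         .sbml_id(names(subs)), format(-unname(subs), scientific = FALSE)),
                 "        </listOfReactants>")
    }
    if (length(prods)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         .sbml_id(names(prods)), format(unname(prods), scientific = FALSE)),
                 "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines,
    "    </listOfReactions>",
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            .sbml_id(model$biomass)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>"
  )
  if (length(genes)) {
    lines <- c(lines,
      "    <fbc:listOfGeneProducts>",
      sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              .sbml_id(genes), .xml_esc(genes)),
      "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
}

.fbc_to_gpr <- function(node, labels) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lab <- labels[[gid]]
    return(if (is.null(lab) || is.na(lab)) sub("^G_", "", gid) else lab)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .fbc_to_gpr, "", labels = labels)
  op <- if (name == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  find_all <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  # flux-bound parameters
  pars <- find_all(doc, "parameter")
  par_val <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id")
  )
  # gene product labels
  gps <- find_all(doc, "geneProduct")
  labels <- stats::setNames(
    as.list(xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id")
  )
  species <- find_all(doc, "species")
  met_ids <- sub("^M_", "", xml2::xml_attr(species, "id"))
  mets <- data.frame(
    id = met_ids,
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE
  )
  rxn_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rxn_nodes)) stop("SBML '", path, "' contains no reactions", call. = FALSE)
  fbc_lb <- function(n) xml2::xml_attr(n, "lowerFluxBound")
  fbc_ub <- function(n) xml2::xml_attr(n, "upperFluxBound")
  note_field <- function(n, key) {
    ps <- find_all(n, "p")
    txt <- xml2::xml_text(ps)
    hit <- grep(paste0("^", key, ":"), txt, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1])) else ""
  }
  rxns <- lapply(rxn_nodes, function(n) {
    rid <- sub("^R_", "", xml2::xml_attr(n, "id"))
    if (is.na(rid) || !nzchar(rid)) stop("SBML reaction without id in '", path, "'", call. = FALSE)
    reac <- xml2::xml_find_all(
      n, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prod <- xml2::xml_find_all(
      n, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      sub("^M_", "", xml2::xml_attr(reac, "species"))),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      sub("^M_", "", xml2::xml_attr(prod, "species")))
    )
    lbp <- fbc_lb(n)
    ubp <- fbc_ub(n)
    if (!is.na(lbp) && lbp %in% names(par_val)) {
      lb <- par_val[[lbp]]
      ub <- par_val[[ubp]]
    } else {
      # legacy dialect: reversibility flag only
      rev <- identical(tolower(xml2::xml_attr(n, "reversible")), "true")
      lb <- if (rev) -1000 else 0
      ub <- 1000
    }
    gpa <- xml2::xml_find_first(n, ".//*[local-name()='geneProductAssociation']")
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpr <- .fbc_to_gpr(kids[[1]], labels)
    } else {
      gpr <- note_field(n, "GENE_ASSOCIATION")
    }
    ext <- note_field(n, "EXTERNAL_ID")
    reaction(id = rid, stoich = st, lb = lb, ub = ub, gpr = gpr,
             subsystem = note_field(n, "SUBSYSTEM"),
             external_id = if (nzchar(ext)) ext else NA_character_)
  })
  obj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(obj, "xml_missing")) {
    biomass <- sub("^R_", "", xml2::xml_attr(obj, "reaction"))
  } else {
    rids <- vapply(rxns, `[[`, "", "id")
    hit <- grep("biomass", rids, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) {
      stop("SBML '", path, "' declares no biomass objective and no reaction id ",
           "matches 'biomass'", call. = FALSE)
    }
    biomass <- hit[1]
  }
  mdl_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  mid <- xml2::xml_attr(mdl_node, "id")
  metabolic_model(rxns, biomass = biomass,
                  metabolites = if (nrow(mets)) mets else NULL,
                  id = if (is.na(mid)) "model" else mid)
}
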