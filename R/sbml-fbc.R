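#' SBML (fbc) input/output for metabolic models
#'
#' Reads and writes constraint-based models in SBML Level 3 with the flux
#' balance constraints (fbc) version 2 extension — the dialect MitoCore and
#' other curated models are distributed in. Flux bounds are resolved through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameter references, chemical
#' formulas through `fbc:chemicalFormula`, and exchange reactions through the
#' SBO term 0000627.
#'
#' @name sbml-fbc
NULL

NS_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBO_EXCHANGE <- "SBO:0000627"

#' Parse an SBML/fbc metabolic model
#'
#' @param path SBML file path.
#' @return A [metabolic_model()].
#' @export
parse_sbml_metabolic <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed SBML file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ns <- c(s = NS_SBML, f = NS_FBC)
  get_attr <- function(nodes, name, qname) {
    v <- xml2::xml_attr(nodes, name)
    v2 <- xml2::xml_attr(nodes, qname)
    v[is.na(v)] <- v2[is.na(v)]
    v
  }
  comp <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- xml2::xml_attr(comp, "id")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = get_attr(sp, "chemicalFormula", "fbc:chemicalFormula"),
    stringsAsFactors = FALSE
  )
  metabolites$name[is.na(metabolites$name)] <- metabolites$id[is.na(metabolites$name)]
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L) stop("no reactions found in '", path, "'", call. = FALSE)
  ids <- xml2::xml_attr(rx, "id")
  lbref <- get_attr(rx, "lowerFluxBound", "fbc:lowerFluxBound")
  ubref <- get_attr(rx, "upperFluxBound", "fbc:upperFluxBound")
  missing_b <- is.na(lbref) | is.na(ubref)
  if (any(missing_b)) {
    stop("reaction(s) without flux bounds: ",
         paste(ids[missing_b], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(c(lbref, ubref), names(par_val))
  if (length(unknown) > 0L) {
    stop("flux bound parameter(s) not declared: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  sbo <- xml2::xml_attr(rx, "sboTerm")
  reactions <- data.frame(
    id = ids,
    name = {
      nm <- xml2::xml_attr(rx, "name"); nm[is.na(nm)] <- ids[is.na(nm)]; nm
    },
    lb = unname(par_val[lbref]),
    ub = unname(par_val[ubref]),
    exchange = !is.na(sbo) & sbo == SBO_EXCHANGE,
    stringsAsFactors = FALSE
  )
  st_rows <- list()
  for (k in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      sr <- xml2::xml_find_all(rx[[k]], paste0("./s:", side, "/s:speciesReference"), ns)
      if (length(sr) == 0L) next
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      st_rows[[length(st_rows) + 1L]] <- data.frame(
        reaction = ids[k],
        metabolite = xml2::xml_attr(sr, "species"),
        coefficient = coef,
        stringsAsFactors = FALSE
      )
    }
  }
  stoichiometry <- do.call(rbind, st_rows)
  # collapse duplicated (reaction, metabolite) pairs, as in species appearing
  # on both sides
  key <- paste(stoichiometry$reaction, stoichiometry$metabolite, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(coefficient ~ reaction + metabolite,
                            data = stoichiometry, FUN = sum)
    stoichiometry <- agg[abs(agg$coefficient) > 0, ]
  }
  metabolic_model(metabolites, reactions, stoichiometry, compartments)
}

#' Write a metabolic model as SBML/fbc
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @param objective Optional [objective_spec()]; if given, an active fbc
#'   objective (unweighted maximization over its reactions) is embedded so
#'   external tools optimize the same quantity.
#' @return `path`, invisibly.
#' @export
write_sbml_metabolic <- function(model, path, objective = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", NS_SBML, "\" level=\"3\" version=\"1\" ",
           "xmlns:fbc=\"", NS_FBC, "\" fbc:required=\"false\">"),
    "  <model id=\"metabolic_model\" fbc:strict=\"true\">",
    "    <listOfCompartments>"
  )
  for (cp in model$compartments) {
    lines <- c(lines, paste0("      <compartment id=\"", cp,
                             "\" constant=\"true\"/>"))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (k in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[k, ]
    fm <- if (!is.na(m$formula)) paste0(" fbc:chemicalFormula=\"", m$formula, "\"") else ""
    lines <- c(lines, paste0(
      "      <species id=\"", m$id, "\" name=\"", m$name,
      "\" compartment=\"", m$compartment,
      "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
      " constant=\"false\"", fm, "/>"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  bvals <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bid <- stats::setNames(paste0("bound_", seq_along(bvals)), num(bvals))
  for (v in bvals) {
    lines <- c(lines, paste0("      <parameter id=\"", bid[[num(v)]],
                             "\" value=\"", num(v),
                             "\" constant=\"true\" sboTerm=\"SBO:0000626\"/>"))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  st <- model$stoichiometry
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    sbo <- if (isTRUE(r$exchange)) paste0(" sboTerm=\"", SBO_EXCHANGE, "\"") else ""
    lines <- c(lines, paste0(
      "      <reaction id=\"", r$id, "\" name=\"", r$name,
      "\" reversible=\"", tolower(r$lb < 0), "\" fast=\"false\"",
      " fbc:lowerFluxBound=\"", bid[[num(r$lb)]],
      "\" fbc:upperFluxBound=\"", bid[[num(r$ub)]], "\"", sbo, ">"))
    rows <- st[st$reaction == r$id, ]
    for (side in c(-1, 1)) {
      sel <- rows[sign(rows$coefficient) == side, ]
      if (nrow(sel) == 0L) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, paste0("        <", tag, ">"))
      for (j in seq_len(nrow(sel))) {
        lines <- c(lines, paste0(
          "          <speciesReference species=\"", sel$metabolite[j],
          "\" stoichiometry=\"", num(abs(sel$coefficient[j])),
          "\" constant=\"true\"/>"))
      }
      lines <- c(lines, paste0("        </", tag, ">"))
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (!is.null(objective)) {
    lines <- c(lines,
      "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "        <fbc:listOfFluxObjectives>")
    for (rid in objective$reaction) {
      lines <- c(lines, paste0(
        "          <fbc:fluxObjective fbc:reaction=\"", rid,
        "\" fbc:coefficient=\"1\"/>"))
    }
    lines <- c(lines,
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
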