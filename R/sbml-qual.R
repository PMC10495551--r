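#' SBML-qual input/output
#'
#' Reads and writes logical models in the SBML Level 3 qualitative-models
#' dialect produced by map-to-model tools such as CaSQ: one qualitative
#' species per node (`maxLevel` 1), one transition per regulated node whose
#' level-1 function term carries the Boolean rule in MathML
#' (`and`/`or`/`not` over `eq(species, level)` comparisons). Species without
#' an incoming transition become inputs. Multi-valued species (maxLevel > 1)
#' are rejected: the modelling framework here is strictly Boolean.
#'
#' @name sbml-qual
NULL

NS_SBML <- "http://www.sbml.org/sbml/level3/version1/core"
NS_QUAL <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
NS_MATH <- "http://www.w3.org/1998/Math/MathML"

#' Parse an SBML-qual file into a Boolean network
#'
#' @param path Path to an SBML Level 3 file using the qual extension.
#' @return A [boolean_network()]; species `name` attributes are kept as the
#'   `name` annotation of each node.
#' @export
parse_sbml_qual <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed SBML file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ns <- c(s = NS_SBML, q = NS_QUAL, m = NS_MATH)
  sp <- xml2::xml_find_all(doc, ".//q:qualitativeSpecies", ns)
  if (length(sp) == 0L) {
    stop("no qualitative species found; is '", path, "' an SBML-qual file?",
         call. = FALSE)
  }
  # attributes may be namespaced (qual:id) or plain depending on the writer;
  # xml2 resolves both through the prefix-free name first
  qattr <- function(nodes, name) {
    v <- xml2::xml_attr(nodes, name)
    v2 <- xml2::xml_attr(nodes, paste0("q:", name), ns = ns)
    v[is.na(v)] <- v2[is.na(v)]
    v
  }
  ids <- qattr(sp, "id")
  if (anyNA(ids)) stop("qualitative species without id", call. = FALSE)
  maxlev <- qattr(sp, "maxLevel")
  multi <- !is.na(maxlev) & suppressWarnings(as.numeric(maxlev)) > 1
  if (any(multi)) {
    stop("unsupported multi-valued species (maxLevel > 1): ",
         paste(ids[multi], collapse = ", "), call. = FALSE)
  }
  nm <- qattr(sp, "name")

  functions <- stats::setNames(vector("list", length(ids)), ids)
  transitions <- xml2::xml_find_all(doc, ".//q:transition", ns)
  for (tr in transitions) {
    out <- xml2::xml_find_first(tr, ".//q:output", ns)
    target <- xml2::xml_attr(out, "qualitativeSpecies")
    if (is.na(target)) target <- xml2::xml_attr(out, "q:qualitativeSpecies", ns = ns)
    if (is.na(target) || !(target %in% ids)) {
      stop("transition output references unknown species", call. = FALSE)
    }
    terms <- xml2::xml_find_all(tr, ".//q:functionTerm", ns)
    expr <- FALSE
    for (ft in terms) {
      lev <- xml2::xml_attr(ft, "resultLevel")
      if (is.na(lev)) lev <- xml2::xml_attr(ft, "q:resultLevel", ns = ns)
      math <- xml2::xml_find_first(ft, "./m:math/*", ns)
      if (is.na(lev) || inherits(math, "xml_missing")) next
      if (as.integer(lev) == 1L) {
        expr <- mathml_to_expr(math, ids)
      } else if (as.integer(lev) != 0L) {
        stop("unsupported multi-valued function term (resultLevel ", lev,
             ") for species ", target, call. = FALSE)
      }
    }
    functions[[target]] <- expr
  }
  for (id in ids) {
    if (is.null(functions[[id]])) functions[id] <- list(NULL) # input
  }
  ann <- list()
  for (j in seq_along(ids)) {
    if (!is.na(nm[j])) ann[[ids[j]]] <- list(name = nm[j])
  }
  boolean_network(functions, annotations = ann)
}

mathml_to_expr <- function(node, ids) {
  tag <- xml2::xml_name(node)
  if (tag == "true") return(TRUE)
  if (tag == "false") return(FALSE)
  if (tag == "ci") {
    ref <- trimws(xml2::xml_text(node))
    if (!(ref %in% ids)) stop("MathML references unknown species '", ref, "'",
                              call. = FALSE)
    return(as.symbol(ref))
  }
  if (tag != "apply") stop("unsupported MathML element <", tag, ">", call. = FALSE)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1L]])
  args <- kids[-1L]
  if (op %in% c("eq", "geq")) {
    ci <- args[[1L]]
    cn <- args[[2L]]
    if (xml2::xml_name(ci) != "ci" || xml2::xml_name(cn) != "cn") {
      stop("unsupported comparison form in MathML", call. = FALSE)
    }
    ref <- trimws(xml2::xml_text(ci))
    if (!(ref %in% ids)) stop("MathML references unknown species '", ref, "'",
                              call. = FALSE)
    lev <- as.numeric(trimws(xml2::xml_text(cn)))
    if (!(lev %in% c(0, 1))) {
      stop("unsupported multi-valued comparison level ", lev, " for species ",
           ref, call. = FALSE)
    }
    if (op == "geq" && lev == 0) return(TRUE)
    if (lev == 1) return(as.symbol(ref))
    return(call("!", as.symbol(ref)))
  }
  sub <- lapply(args, mathml_to_expr, ids = ids)
  if (op == "not") {
    if (length(sub) != 1L) stop("MathML <not> takes one argument", call. = FALSE)
    return(call("!", sub[[1L]]))
  }
  if (op %in% c("and", "or")) {
    rop <- if (op == "and") "&" else "|"
    out <- sub[[1L]]
    for (k in seq_along(sub)[-1L]) out <- call(rop, out, sub[[k]])
    return(out)
  }
  stop("unsupported MathML operator <", op, ">", call. = FALSE)
}

expr_to_mathml <- function(expr) {
  if (is.symbol(expr)) {
    return(paste0("<apply><eq/><ci> ", as.character(expr),
                  " </ci><cn type=\"integer\"> 1 </cn></apply>"))
  }
  if (is.logical(expr)) return(if (expr) "<true/>" else "<false/>")
  op <- as.character(expr[[1L]])
  if (op == "(") return(expr_to_mathml(expr[[2L]]))
  if (op == "!") {
    inner <- expr[[2L]]
    if (is.symbol(inner)) {
      return(paste0("<apply><eq/><ci> ", as.character(inner),
                    " </ci><cn type=\"integer\"> 0 </cn></apply>"))
    }
    return(paste0("<apply><not/>", expr_to_mathml(inner), "</apply>"))
  }
  tag <- if (op %in% c("&", "&&")) "and" else "or"
  paste0("<apply><", tag, "/>", expr_to_mathml(expr[[2L]]),
         expr_to_mathml(expr[[3L]]), "</apply>")
}

#' Write a Boolean network as SBML-qual
#'
#' @param net A [boolean_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_qual <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", NS_SBML, "\" level=\"3\" version=\"1\" ",
           "xmlns:qual=\"", NS_QUAL, "\" qual:required=\"true\">"),
    "  <model id=\"logical_model\">",
    "    <listOfCompartments>",
    "      <compartment id=\"default\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <qual:listOfQualitativeSpecies>"
  )
  for (nm in net$nodes) {
    ann <- net$annotations[[nm]]
    namestr <- if (!is.null(ann$name)) paste0(" qual:name=\"", esc(ann$name), "\"") else ""
    lines <- c(lines, paste0(
      "      <qual:qualitativeSpecies qual:id=\"", nm,
      "\" qual:compartment=\"default\" qual:constant=\"false\" qual:maxLevel=\"1\"",
      namestr, "/>"))
  }
  lines <- c(lines, "    </qual:listOfQualitativeSpecies>",
             "    <qual:listOfTransitions>")
  for (nm in setdiff(net$nodes, net$inputs)) {
    expr <- net$functions[[nm]]
    regs <- expr_vars(expr)
    lines <- c(lines, paste0("      <qual:transition qual:id=\"tr_", nm, "\">"))
    if (length(regs) > 0L) {
      lines <- c(lines, "        <qual:listOfInputs>")
      for (rg in regs) {
        lines <- c(lines, paste0(
          "          <qual:input qual:qualitativeSpecies=\"", rg,
          "\" qual:transitionEffect=\"none\"/>"))
      }
      lines <- c(lines, "        </qual:listOfInputs>")
    }
    lines <- c(lines,
      "        <qual:listOfOutputs>",
      paste0("          <qual:output qual:qualitativeSpecies=\"", nm,
             "\" qual:transitionEffect=\"assignmentLevel\"/>"),
      "        </qual:listOfOutputs>",
      "        <qual:listOfFunctionTerms>",
      "          <qual:defaultTerm qual:resultLevel=\"0\"/>",
      "          <qual:functionTerm qual:resultLevel=\"1\">",
      paste0("            <math xmlns=\"", NS_MATH, "\">"),
      paste0("              ", expr_to_mathml(expr)),
      "            </math>",
      "          </qual:functionTerm>",
      "        </qual:listOfFunctionTerms>",
      "      </qual:transition>")
  }
  lines <- c(lines, "    </qual:listOfTransitions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
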