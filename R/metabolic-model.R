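#' Construct a constraint-based metabolic model
#'
#' Container for a stoichiometric model: metabolites (with compartment and
#' chemical formula), reactions (with flux bounds and an exchange flag) and a
#' stoichiometry table. Exchange reactions must touch exactly one metabolite
#' and follow the usual constraint-based sign convention (`met ->` with
#' negative flux meaning uptake).
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (`NA` allowed for formula-free species).
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `exchange` (logical).
#' @param stoichiometry data.frame with columns `reaction`, `metabolite`,
#'   `coefficient` (signed; negative = consumed).
#' @param compartments Optional character vector of compartment ids.
#' @return Object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            compartments = NULL) {
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L) {
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  req(metabolites, c("id", "compartment"), "metabolites")
  req(reactions, c("id", "lb", "ub"), "reactions")
  req(stoichiometry, c("reaction", "metabolite", "coefficient"), "stoichiometry")
  if (!("name" %in% names(metabolites))) metabolites$name <- metabolites$id
  if (!("formula" %in% names(metabolites))) metabolites$formula <- NA_character_
  if (!("name" %in% names(reactions))) reactions$name <- reactions$id
  if (!("exchange" %in% names(reactions))) reactions$exchange <- FALSE
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids", call. = FALSE)
  bad <- setdiff(stoichiometry$metabolite, metabolites$id)
  if (length(bad) > 0L) {
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(stoichiometry$reaction, reactions$id)
  if (length(bad) > 0L) {
    stop("stoichiometry references undeclared reaction(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (any(reactions$lb > reactions$ub)) {
    bad <- reactions$id[reactions$lb > reactions$ub]
    stop("lower bound above upper bound for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_mets_per_rxn <- table(stoichiometry$reaction)
  exch <- reactions$id[reactions$exchange]
  bad <- exch[exch %in% names(n_mets_per_rxn)[n_mets_per_rxn > 1L]]
  if (length(bad) > 0L) {
    stop("exchange reaction(s) touching more than one metabolite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)
  structure(
    list(metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
         reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
         stoichiometry = as.data.frame(stoichiometry, stringsAsFactors = FALSE),
         compartments = compartments),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions (", sum(x$reactions$exchange),
      "exchanges )\n")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#' @param model A `metabolic_model`.
#' @return Matrix (metabolites x reactions).
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite, model$metabolites$id),
          match(st$reaction, model$reactions$id))] <- st$coefficient
  S
}

#' Count atoms of an element in a chemical formula
#'
#' Parses formulas like `"C6H12O6"`; two-letter element symbols (`Cl`, `Ca`)
#' are handled correctly. Generic residue formulas containing `R` or `X`
#' groups are rejected as uncountable.
#'
#' @param formula Character vector of formulas.
#' @param element Element symbol, default `"C"`.
#' @return Integer vector of counts (`NA` for `NA` input).
#' @export
formula_element_count <- function(formula, element = "C") {
  vapply(formula, function(f) {
    if (is.na(f)) return(NA_integer_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1L]]
    toks <- regmatches(f, list(m))[[1L]]
    if (length(toks) == 0L || paste(toks, collapse = "") != f) {
      stop("cannot parse chemical formula '", f, "'", call. = FALSE)
    }
    total <- 0L
    for (tk in toks) {
      el <- sub("[0-9]*$", "", tk)
      if (el %in% c("R", "X")) {
        stop("generic residue formula '", f, "' is not countable", call. = FALSE)
      }
      if (el == element) {
        cnt <- sub("^[A-Za-z]+", "", tk)
        total <- total + if (cnt == "") 1L else as.integer(cnt)
      }
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

#' The single metabolite of each exchange reaction
#' @param model A `metabolic_model`.
#' @return data.frame with `reaction`, `metabolite`, `coefficient`.
#' @keywords internal
exchange_metabolites <- function(model) {
  ex <- model$reactions$id[model$reactions$exchange]
  st <- model$stoichiometry
  st[st$reaction %in% ex, c("reaction", "metabolite", "coefficient")]
}
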