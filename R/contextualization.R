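#' Expression contrast tables
#'
#' A contrast table holds one row per gene with a fold change and an adjusted
#' p-value, plus an explicit fold-change convention: `"linear"` (signed
#' linear ratio; down-regulation is negative, so |FC| > 1.5 means FC > 1.5 or
#' FC < -1.5) or `"log2"` (log2 ratio; |FC| > threshold applies to the log
#' value against `log2(threshold)`). Differential-expression statistics are
#' out of scope here: the table is the precomputed output of an upstream DEA.
#'
#' @param genes Character vector of unique gene symbols.
#' @param fc Numeric fold changes.
#' @param adj_p Adjusted p-values in \[0, 1\].
#' @param fc_convention `"linear"` or `"log2"`.
#' @return Object of class `expression_contrast` (data.frame with attribute
#'   `fc_convention`).
#' @export
expression_contrast <- function(genes, fc, adj_p, fc_convention = c("linear", "log2")) {
  fc_convention <- match.arg(fc_convention)
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  if (any(adj_p < 0 | adj_p > 1, na.rm = TRUE)) {
    stop("adjusted p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(gene = as.character(genes), fc = as.numeric(fc),
                    adj_p = as.numeric(adj_p), stringsAsFactors = FALSE)
  attr(out, "fc_convention") <- fc_convention
  class(out) <- c("expression_contrast", "data.frame")
  out
}

#' Read/write a contrast table as TSV
#'
#' The file carries a metadata comment line `# fc_convention: linear|log2`
#' followed by a header `gene fc adj_p`.
#'
#' @param path TSV path.
#' @return [expression_contrast()] (reading) or `path` invisibly (writing).
#' @export
read_contrast_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  conv <- sub(".*fc_convention:\\s*", "", meta[grepl("fc_convention", meta)])
  if (length(conv) != 1L || !(conv %in% c("linear", "log2"))) {
    stop("contrast table must declare its fold-change convention ",
         "('# fc_convention: linear' or 'log2')", call. = FALSE)
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  expression_contrast(df$gene, df$fc, df$adj_p, conv)
}

#' @rdname read_contrast_tsv
#' @param contrast An [expression_contrast()].
#' @export
write_contrast_tsv <- function(contrast, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fc_convention: ", attr(contrast, "fc_convention")), con)
  utils::write.table(as.data.frame(contrast), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call differentially expressed genes from a contrast table
#'
#' A gene is up-regulated when its adjusted p-value is strictly below
#' `p_threshold` and its fold change strictly exceeds `fc_threshold` in the
#' declared convention; down-regulated symmetrically. Strict inequalities
#' throughout, so a gene exactly at a threshold is not called.
#'
#' @param contrast An [expression_contrast()].
#' @param p_threshold Adjusted p-value cutoff (default 0.05).
#' @param fc_threshold Linear fold-change cutoff (default 1.5); applied on
#'   the log2 scale as `log2(fc_threshold)` when the table uses the log2
#'   convention.
#' @return List with character vectors `up` and `down` (always disjoint).
#' @export
call_degs <- function(contrast, p_threshold = 0.05, fc_threshold = 1.5) {
  stopifnot(inherits(contrast, "expression_contrast"))
  if (p_threshold <= 0 || fc_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  conv <- attr(contrast, "fc_convention")
  if (is.null(conv)) stop("contrast table lacks a fold-change convention", call. = FALSE)
  cut <- if (conv == "log2") log2(fc_threshold) else fc_threshold
  sig <- !is.na(contrast$adj_p) & contrast$adj_p < p_threshold
  # signed conventions in both cases: down-regulation is negative (linear
  # tables encode the reciprocal as -FC, log2 tables are symmetric around 0)
  up <- sig & contrast$fc > cut
  down <- sig & contrast$fc < -cut
  list(up = contrast$gene[up], down = contrast$gene[down])
}

#' Initial-condition sets
#'
#' Maps model nodes to fixed 0/1 initial values, each tagged with its
#' provenance: `"data-driven"` (from the expression contrast) or `"curated"`
#' (from literature).
#'
#' @param values Named 0/1 vector over node identifiers.
#' @param provenance Per-node tag, recycled if scalar.
#' @return Object of class `initial_conditions`.
#' @export
initial_conditions <- function(values = integer(), provenance = character()) {
  values <- unlist(values)
  if (length(values) > 0L) {
    if (is.null(names(values)) || any(names(values) == "") ||
        anyDuplicated(names(values))) {
      stop("initial-condition values must have unique names", call. = FALSE)
    }
    if (!all(values %in% c(0, 1))) stop("initial values must be 0 or 1", call. = FALSE)
  }
  provenance <- rep_len(as.character(provenance), length(values))
  if (length(values) > 0L && !all(provenance %in% c("data-driven", "curated"))) {
    stop("provenance must be 'data-driven' or 'curated'", call. = FALSE)
  }
  structure(
    list(values = stats::setNames(as.integer(values), names(values)),
         provenance = stats::setNames(provenance, names(values))),
    class = "initial_conditions"
  )
}

#' @export
print.initial_conditions <- function(x, ...) {
  cat("Initial conditions for", length(x$values), "node(s):",
      sum(x$values == 1L), "at 1,", sum(x$values == 0L), "at 0\n")
  invisible(x)
}

#' Map called DEGs onto network nodes and discretize
#'
#' Up-regulated genes matching a node set it to 1, down-regulated to 0
#' (provenance `"data-driven"`). Matching is case-insensitive exact matching
#' against node identifiers and `name` annotations, optionally extended by an
#' alias table; there is no fuzzy matching. Genes matching no node are
#' reported in the `unmapped` attribute rather than silently dropped. Two
#' genes of opposite direction mapping to the same node is an error.
#'
#' @param up,down Character vectors of gene symbols from [call_degs()].
#' @param net A [boolean_network()] whose annotations carry gene symbols.
#' @param aliases Optional named character vector mapping gene symbol ->
#'   node identifier.
#' @return An [initial_conditions()] with attribute `unmapped`.
#' @export
map_and_discretize <- function(up, down, net, aliases = character()) {
  stopifnot(inherits(net, "boolean_network"))
  both <- intersect(up, down)
  if (length(both) > 0L) {
    stop("gene(s) both up- and down-regulated: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  alias_map <- node_aliases(net)
  lookup <- function(gene) {
    g <- toupper(gene)
    hits <- names(alias_map)[vapply(alias_map, function(a) g %in% a, logical(1))]
    if (g %in% toupper(names(aliases))) {
      hits <- union(hits, aliases[[which(toupper(names(aliases)) == g)[1L]]])
    }
    intersect(hits, net$nodes)
  }
  values <- integer()
  by_gene <- list()
  unmapped <- character()
  for (spec in list(list(genes = up, value = 1L), list(genes = down, value = 0L))) {
    for (g in spec$genes) {
      nodes <- lookup(g)
      if (length(nodes) == 0L) {
        unmapped <- c(unmapped, g)
        next
      }
      for (nd in nodes) {
        if (nd %in% names(values) && values[[nd]] != spec$value) {
          stop("node '", nd, "' receives contradictory initial values from genes ",
               paste(unique(c(unlist(by_gene[[nd]]), g)), collapse = ", "),
               call. = FALSE)
        }
        values[nd] <- spec$value
        by_gene[[nd]] <- union(by_gene[[nd]], g)
      }
    }
  }
  out <- initial_conditions(values, "data-driven")
  attr(out, "unmapped") <- unmapped
  out
}

#' Merge data-driven and curated initial conditions
#'
#' Union with data-driven precedence: a curated value fills a node only if
#' the expression contrast left it unfixed (curation is used for inputs the
#' DEA could not fix). Overridden curated values are reported in the
#' `conflicts` attribute; input nodes still unfixed after merging in the
#' `unfixed_inputs` attribute.
#'
#' @param data_driven,curated [initial_conditions()] objects.
#' @param net A [boolean_network()]; curated nodes must exist in it.
#' @return Merged [initial_conditions()] with attributes `conflicts` and
#'   `unfixed_inputs`.
#' @export
merge_with_curation <- function(data_driven, curated, net) {
  stopifnot(inherits(data_driven, "initial_conditions"),
            inherits(curated, "initial_conditions"),
            inherits(net, "boolean_network"))
  bad <- setdiff(names(curated$values), net$nodes)
  if (length(bad) > 0L) {
    stop("curated condition(s) for unknown node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  values <- data_driven$values
  prov <- data_driven$provenance
  conflicts <- character()
  for (nd in names(curated$values)) {
    if (nd %in% names(values)) {
      if (values[[nd]] != curated$values[[nd]]) conflicts <- c(conflicts, nd)
      next # data-driven precedence
    }
    values[nd] <- curated$values[[nd]]
    prov[nd] <- "curated"
  }
  out <- initial_conditions(values, prov)
  attr(out, "conflicts") <- conflicts
  attr(out, "unfixed_inputs") <- setdiff(net$inputs, names(values))
  out
}

#' Read/write initial conditions as TSV (`node value provenance`)
#'
#' @param path TSV path.
#' @return [initial_conditions()] (reading) or `path` invisibly (writing).
#' @export
read_conditions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  initial_conditions(stats::setNames(df$value, df$node), df$provenance)
}

#' @rdname read_conditions_tsv
#' @param conditions An [initial_conditions()].
#' @export
write_conditions_tsv <- function(conditions, path) {
  df <- data.frame(node = names(conditions$values),
                   value = unname(conditions$values),
                   provenance = unname(conditions$provenance),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Turn initial conditions into a user clamping
#'
#' Following the contextualization semantics used throughout: every node with
#' a fixed initial value is clamped as a constant.
#'
#' @param conditions An [initial_conditions()].
#' @return A [clamping()] with origin `"user"`.
#' @export
conditions_to_clamping <- function(conditions) {
  clamping(conditions$values, "user")
}
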