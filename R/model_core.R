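# Constraint-based metabolic model container, GPR handling and validation.

#' Create a reaction
#'
#' @param id Reaction identifier.
#' @param stoich Named numeric vector mapping metabolite ids to stoichiometric
#'   coefficients (negative = consumed, positive = produced).
#' @param lb,ub Lower and upper flux bounds (mmol gDW^-1 h^-1). Reversibility
#'   is encoded solely by the bounds: a reaction is reversible iff
#'   `lb < 0 < ub`.
#' @param gpr Gene-protein-reaction rule: a boolean expression over gene ids
#'   using `and` / `or` and parentheses, or `""` for spontaneous/unassigned
#'   reactions. `and` binds tighter than `or`.
#' @param subsystem Pathway label (e.g. "TCA cycle"); may be `""`.
#' @param external_id Optional cross-reference (e.g. a KEGG reaction id).
#'
#' @return A list of class `"reaction"`.
#' @export
reaction <- function(id, stoich, lb = -1000, ub = 1000, gpr = "",
                     subsystem = "", external_id = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.list(stoich)) stoich <- unlist(stoich)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "': stoichiometry must be a named numeric vector", call. = FALSE)
  }
  structure(
    list(id = id, stoich = stoich, lb = as.numeric(lb), ub = as.numeric(ub),
         gpr = as.character(gpr), subsystem = as.character(subsystem),
         external_id = external_id),
    class = "reaction"
  )
}

#' Assemble a metabolic model
#'
#' @param reactions List of [reaction()] objects.
#' @param biomass Identifier of the biomass reaction (the default FBA
#'   objective). Must exist and consume at least one metabolite.
#' @param metabolites Optional data frame with columns `id` and `compartment`;
#'   derived from the reactions when omitted (compartment = trailing `_<tag>`
#'   of the metabolite id, if any).
#' @param id Model identifier.
#'
#' @return A validated object of class `"metabolic_model"` with fields
#'   `metabolites`, `reactions`, `biomass` and `exchanges` (ids of boundary
#'   reactions, auto-detected as reactions touching exactly one metabolite).
#'   On an exchange written as `met_external <->`, uptake is a negative flux;
#'   an uptake rate r is imposed as lower bound -r.
#' @export
metabolic_model <- function(reactions, biomass, metabolites = NULL, id = "model") {
  stopifnot(is.list(reactions), length(reactions) > 0L)
  reactions <- lapply(reactions, function(r) {
    if (!inherits(r, "reaction")) do.call(reaction, r) else r
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(names(reactions))) {
    stop("duplicated reaction ids: ",
         paste(unique(names(reactions)[duplicated(names(reactions))]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(metabolites)) {
    met_ids <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoich)))))
    metabolites <- data.frame(
      id = met_ids,
      compartment = sub("^.*_([A-Za-z0-9]+)$", "\\1", met_ids),
      stringsAsFactors = FALSE
    )
  }
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         biomass = biomass, exchanges = character(0)),
    class = "metabolic_model"
  )
  model$exchanges <- names(reactions)[vapply(reactions, function(r) length(r$stoich) == 1L, TRUE)]
  validate_metabolic_model(model)
}

#' Validate a metabolic model
#'
#' Checks that every stoichiometric coefficient references a declared
#' metabolite, that `lb <= ub` for each reaction, that the biomass reaction
#' exists and has at least one substrate, and that every GPR parses.
#'
#' @param model A `"metabolic_model"`.
#' @return The model, invisibly unchanged, or an error naming the offending
#'   element.
#' @export
validate_metabolic_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  declared <- model$metabolites$id
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), declared)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (is.na(r$lb) || is.na(r$ub) || r$lb > r$ub) {
      stop("reaction '", r$id, "': lower bound (", r$lb,
           ") exceeds upper bound (", r$ub, ")", call. = FALSE)
    }
    tryCatch(gpr_genes(r$gpr), error = function(e) {
      stop("reaction '", r$id, "': invalid GPR '", r$gpr, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  if (!model$biomass %in% names(model$reactions)) {
    stop("biomass reaction '", model$biomass, "' not found in model", call. = FALSE)
  }
  if (!any(model$reactions[[model$biomass]]$stoich < 0)) {
    stop("biomass reaction '", model$biomass, "' has no substrate", call. = FALSE)
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "': ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", length(x$exchanges),
      " exchanges), biomass = '", x$biomass, "'\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `"metabolic_model"`.
#' @return A dense metabolites x reactions matrix with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Bounds of all reactions
#' @param model A `"metabolic_model"`.
#' @return List with named numeric vectors `lb` and `ub`.
#' @export
model_bounds <- function(model) {
  list(
    lb = vapply(model$reactions, `[[`, 0, "lb"),
    ub = vapply(model$reactions, `[[`, 0, "ub")
  )
}

# ---------------------------------------------------------------------------
# GPR rules

.gpr_tokenize <- function(gpr) {
  s <- gsub("\\(", " ( ", gsub("\\)", " ) ", gpr))
  s <- gsub("&&|&", " and ", s)
  s <- gsub("\\|\\||\\|", " or ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parser; grammar: or := and ("or" and)*;
# and := atom ("and" atom)*; atom := gene | "(" or ")".
.gpr_parse <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      node <- list(op = "or", args = list(node, parse_and()))
    }
    node
  }
  parse_and <- function() {
    node <- parse_atom()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      node <- list(op = "and", args = list(node, parse_atom()))
    }
    node
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR expression", call. = FALSE)
    if (t == "(") {
      node <- parse_or()
      if (is.na(peek()) || take() != ")") stop("unbalanced parentheses in GPR", call. = FALSE)
      return(node)
    }
    if (t %in% c(")", "and", "or") || tolower(t) %in% c("and", "or")) {
      stop("unexpected token '", t, "' in GPR", call. = FALSE)
    }
    list(gene = t)
  }
  tree <- parse_or()
  if (!is.na(peek())) stop("trailing token '", peek(), "' in GPR", call. = FALSE)
  tree
}

#' Genes appearing in a GPR expression
#'
#' Parses the boolean gene-protein-reaction rule (validating its syntax) and
#' returns the unique gene identifiers it mentions. An empty rule yields an
#' empty character vector.
#'
#' @param gpr GPR string, e.g. `"(gA and gB) or gC"`.
#' @return Character vector of gene ids.
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  tree <- .gpr_parse(.gpr_tokenize(gpr))
  leaves <- function(node) {
    if (!is.null(node$gene)) return(node$gene)
    unlist(lapply(node$args, leaves))
  }
  unique(leaves(tree))
}

#' Union of genes encoding a set of reactions
#'
#' Resolves each reaction's GPR and returns the union of gene ids; reactions
#' with an empty GPR contribute nothing.
#'
#' @param model A `"metabolic_model"`.
#' @param reaction_ids Character vector (or set) of reaction ids.
#' @return Character vector of unique gene ids.
#' @export
genes_for_reactions <- function(model, reaction_ids) {
  reaction_ids <- unique(as.character(reaction_ids))
  unknown <- setdiff(reaction_ids, names(model$reactions))
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unique(c(character(0),
           unlist(lapply(model$reactions[reaction_ids],
                         function(r) gpr_genes(r$gpr)))))
}

#' All genes of a model
#' @param model A `"metabolic_model"`.
#' @return Character vector of unique gene ids over all GPRs.
#' @export
model_genes <- function(model) {
  genes_for_reactions(model, names(model$reactions))
}
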