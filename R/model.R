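#' Construct a constraint-based metabolic model
#'
#' The central container used throughout the package: a stoichiometric matrix
#' together with reaction bounds, gene-protein-reaction (GPR) rules, EC number
#' annotations and subsystem labels. Flux units are mmol gDW^-1 h^-1
#' throughout; on exchange reactions uptake is encoded as negative flux
#' (the boundary metabolite has coefficient -1).
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`, `charge`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` and optionally `subsystem`, `gpr` (rule strings; `""` or
#'   `NA` for none), `ec` (list column of EC number character vectors).
#' @param S stoichiometry, metabolites x reactions; any matrix coercible to a
#'   sparse `Matrix`. Rows must follow `metabolites$id`, columns
#'   `reactions$id`.
#' @param biomass_reaction_id id of the biomass reaction, or `NA`.
#' @param compartments character vector of compartment ids; defaults to the
#'   compartments referenced by the metabolites.
#' @param biomass_composition optional data.frame describing the biomass
#'   precursors (columns `metabolite`, `class`, `mw`; `mw` in g mmol^-1, class
#'   `"protein"` marks the protein component) used by [rescale_biomass()].
#' @param sink_prefix id prefixes identifying sink/demand reactions.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, S,
                            biomass_reaction_id = NA_character_,
                            compartments = NULL,
                            biomass_composition = NULL,
                            sink_prefix = c("sink_", "DM_")) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$ec)) {
    reactions$ec <- replicate(nrow(reactions), character(0), simplify = FALSE)
  }
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id

  S <- as(as(as(S, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)

  gprs <- lapply(reactions$gpr, function(g) {
    if (!nzchar(g)) NULL else parse_gpr(g)
  })
  names(gprs) <- reactions$id

  model <- structure(
    list(id = id,
         metabolites = metabolites,
         reactions = reactions,
         S = S,
         gprs = gprs,
         genes = sort(unique(unlist(lapply(gprs, gpr_genes)))),
         biomass_reaction_id = biomass_reaction_id,
         compartments = compartments %||% unique(metabolites$compartment),
         biomass_composition = biomass_composition,
         sink_prefix = sink_prefix,
         split_map = NULL),
    class = "metabolic_model")
  model <- flag_boundary_reactions(model)
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate model invariants
#'
#' Checks id uniqueness, compartment declarations, bound ordering, dimension
#' agreement of the stoichiometric matrix, and resolvability of the biomass
#' reaction. Called by the constructor; exported for use after manual edits.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violated invariant.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicated metabolite ids")
  if (anyDuplicated(rxns$id)) stop("duplicated reaction ids")
  if (!all(mets$compartment %in% model$compartments)) {
    stop("metabolite compartment not among declared compartments")
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
    stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "))
  }
  if (nrow(model$S) != nrow(mets) || ncol(model$S) != nrow(rxns)) {
    stop("stoichiometric matrix dimensions do not match metabolites/reactions")
  }
  if (!is.na(model$biomass_reaction_id) &&
      !model$biomass_reaction_id %in% rxns$id) {
    stop("biomass reaction '", model$biomass_reaction_id, "' not in model")
  }
  empty <- Matrix::colSums(model$S != 0) == 0
  if (any(empty & !(rxns$is_exchange | rxns$is_sink))) {
    stop("empty stoichiometry in non-boundary reaction(s): ",
         paste(rxns$id[empty & !(rxns$is_exchange | rxns$is_sink)],
               collapse = ", "))
  }
  invisible(model)
}

# Boundary reactions are single-metabolite reactions. Exchanges are those
# whose metabolite lives in the extracellular compartment ("e" when
# declared, otherwise the most common compartment among boundary
# metabolites); the rest are sinks/demands, as are reactions carrying a
# configured sink id prefix. Transport reactions involve more than one
# compartment.
flag_boundary_reactions <- function(model) {
  nmet <- Matrix::colSums(model$S != 0)
  comp <- model$metabolites$compartment
  single <- nmet == 1
  single_comp <- rep(NA_character_, length(single))
  single_comp[single] <- vapply(which(single), function(j) {
    comp[which(model$S[, j] != 0)[1]]
  }, character(1))
  extracellular <- if ("e" %in% model$compartments) "e" else {
    names(sort(table(single_comp), decreasing = TRUE))[1]
  }
  has_prefix <- Reduce(`|`, lapply(model$sink_prefix, function(p) {
    startsWith(model$reactions$id, p)
  }))
  model$reactions$is_exchange <- single & !has_prefix &
    !is.na(single_comp) & single_comp == extracellular
  model$reactions$is_sink <- single & !model$reactions$is_exchange
  model$reactions$is_transport <- vapply(seq_len(ncol(model$S)), function(j) {
    idx <- which(model$S[, j] != 0)
    length(unique(comp[idx])) > 1
  }, logical(1))
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("metabolic_model '%s': %d reactions, %d metabolites, %d genes\n",
              x$id, s$n_reactions, s$n_metabolites, s$n_genes))
  cat(sprintf("  compartments: %s\n", paste(x$compartments, collapse = ", ")))
  cat(sprintf("  GPR coverage: %.1f%%; exchanges: %d; biomass: %s\n",
              100 * s$gpr_coverage, s$n_exchanges,
              x$biomass_reaction_id))
  if (!is.null(x$split_map)) cat("  (reversible reactions split)\n")
  invisible(x)
}

#' Summarize a model
#'
#' @param model a `metabolic_model`.
#' @return list of counts: reactions, metabolites, genes, exchanges, and the
#'   fraction of reactions carrying a GPR rule.
#' @export
model_summary <- function(model) {
  list(n_reactions = nrow(model$reactions),
       n_metabolites = nrow(model$metabolites),
       n_genes = length(model$genes),
       n_exchanges = sum(model$reactions$is_exchange),
       gpr_coverage = mean(nzchar(model$reactions$gpr)))
}

#' Set reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction ids.
#' @param lower,upper replacement bounds (recycled); `NULL` leaves a side
#'   unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  idx <- match(reaction_id, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction(s): ",
         paste(reaction_id[is.na(idx)], collapse = ", "))
  }
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- upper
  validate_model(model)
  model
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound is replaced by a forward copy
#' with bounds `[0, ub]` and a reverse copy (id suffix `_rev`, negated
#' stoichiometry) with bounds `[0, |lb|]`. GPR, EC and subsystem annotations
#' are copied to both members. Exchange reactions additionally always receive
#' a reverse (uptake) copy, even when currently closed, so that media can be
#' re-applied to an already split model; a closed reverse copy has bounds
#' `[0, 0]` and leaves the feasible flux set unchanged.
#'
#' The mapping between original and split reactions is retained in
#' `$split_map` and used by [merge_irreversible_fluxes()].
#'
#' @param model a `metabolic_model` (not yet split).
#' @return the split model.
#' @export
split_reversible <- function(model) {
  if (!is.null(model$split_map)) return(model)
  rxns <- model$reactions
  needs_rev <- rxns$lower_bound < 0 | rxns$is_exchange
  if (!any(needs_rev)) {
    model$split_map <- data.frame(orig = rxns$id, fwd = rxns$id,
                                  rev = NA_character_,
                                  stringsAsFactors = FALSE)
    return(model)
  }
  fwd <- rxns
  fwd$lower_bound <- pmax(fwd$lower_bound, 0)
  rev <- rxns[needs_rev, , drop = FALSE]
  rev$upper_bound <- pmax(-rxns$lower_bound[needs_rev], 0)
  rev$lower_bound <- 0
  rev$id <- paste0(rev$id, "_rev")
  rev$name <- paste(rev$name, "(reverse)")
  new_rxns <- rbind(fwd, rev)
  S_new <- cbind(model$S, -model$S[, needs_rev, drop = FALSE])
  colnames(S_new) <- new_rxns$id
  out <- metabolic_model(
    id = model$id,
    metabolites = model$metabolites,
    reactions = new_rxns,
    S = S_new,
    biomass_reaction_id = model$biomass_reaction_id,
    compartments = model$compartments,
    biomass_composition = model$biomass_composition,
    sink_prefix = model$sink_prefix)
  out$split_map <- data.frame(
    orig = rxns$id,
    fwd = rxns$id,
    rev = ifelse(needs_rev, paste0(rxns$id, "_rev"), NA_character_),
    stringsAsFactors = FALSE)
  out
}

#' Recombine fluxes of a split model into net fluxes
#'
#' @param model a split `metabolic_model` (see [split_reversible()]).
#' @param fluxes named flux vector over the split reactions.
#' @return named net flux vector (forward minus reverse) over the original
#'   reaction ids.
#' @export
merge_irreversible_fluxes <- function(model, fluxes) {
  sm <- model$split_map
  if (is.null(sm)) stop("model carries no split mapping")
  missing_ids <- setdiff(c(sm$fwd, sm$rev[!is.na(sm$rev)]), names(fluxes))
  if (length(missing_ids)) {
    stop("flux vector is missing split members: ",
         paste(missing_ids, collapse = ", "))
  }
  net <- fluxes[sm$fwd]
  has_rev <- !is.na(sm$rev)
  net[has_rev] <- net[has_rev] - fluxes[sm$rev[has_rev]]
  setNames(as.numeric(net), sm$orig)
}

#' Apply a growth medium to a model
#'
#' A medium maps boundary metabolites to maximum uptake fluxes
#' (mmol gDW^-1 h^-1, all nonnegative). Uptake bounds of the corresponding
#' exchange reactions are set accordingly and uptake through every other
#' exchange is closed; secretion bounds are left untouched. Works on both
#' unsplit models (uptake = negative lower bound) and split models (uptake =
#' upper bound of the reverse exchange copy).
#'
#' @param model a `metabolic_model`.
#' @param medium named numeric vector or two-column data.frame
#'   (`metabolite`/`max_uptake`) keyed by boundary metabolite id.
#' @return the model with medium bounds applied.
#' @export
apply_medium <- function(model, medium) {
  if (is.data.frame(medium)) {
    medium <- setNames(medium[[2]], medium[[1]])
  }
  if (any(medium < 0)) stop("medium uptake fluxes must be nonnegative")
  split <- !is.null(model$split_map)
  ex_idx <- which(model$reactions$is_exchange &
                    !grepl("_rev$", model$reactions$id))
  # boundary metabolite of each exchange reaction
  ex_met <- vapply(ex_idx, function(j) {
    model$metabolites$id[which(model$S[, j] != 0)[1]]
  }, character(1))
  unresolved <- setdiff(names(medium), ex_met)
  if (length(unresolved)) {
    stop("medium components without exchange reaction: ",
         paste(unresolved, collapse = ", "))
  }
  uptake <- setNames(rep(0, length(ex_idx)), ex_met)
  uptake[names(medium)] <- medium
  for (k in seq_along(ex_idx)) {
    rid <- model$reactions$id[ex_idx[k]]
    if (split) {
      rev_id <- model$split_map$rev[match(rid, model$split_map$orig)]
      if (is.na(rev_id)) stop("split model lacks uptake copy for ", rid)
      model <- set_bounds(model, rev_id, lower = 0, upper = uptake[k])
    } else {
      model <- set_bounds(model, rid, lower = -uptake[k])
    }
  }
  model
}

#' Read a medium definition from a TSV file
#'
#' Expected columns: `metabolite_id`, `max_uptake` (mmol gDW^-1 h^-1).
#'
#' @param path file path.
#' @return named numeric vector suitable for [apply_medium()].
#' @export
read_medium <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab[[2]], tab[[1]])
}

#' Attach subsystem labels from a sidecar TSV
#'
#' Expected columns: `reaction_id`, `subsystem`. Reactions not listed keep
#' their current label.
#'
#' @param model a `metabolic_model`.
#' @param path file path.
#' @return the model with updated subsystem labels.
#' @export
read_subsystems <- function(model, path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  idx <- match(tab[[1]], model$reactions$id)
  if (anyNA(idx)) {
    stop("subsystem table references unknown reactions: ",
         paste(tab[[1]][is.na(idx)], collapse = ", "))
  }
  model$reactions$subsystem[idx] <- tab[[2]]
  model
}
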