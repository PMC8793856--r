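# Shared LP scaffolding: decision variables are the reaction fluxes; rows are
# metabolite steady-state balances (S v = 0) plus optional extra rows.

model_lp <- function(model, obj, maximize = TRUE, extra_rows = NULL,
                     lb = NULL, ub = NULL) {
  S <- model$S
  m <- nrow(S); n <- ncol(S)
  Tm <- as(as(S, "generalMatrix"), "TsparseMatrix")
  ai <- Tm@i + 1L; aj <- Tm@j + 1L; ax <- Tm@x
  rlb <- rep(0, m); rub <- rep(0, m)
  if (!is.null(extra_rows)) {
    for (k in seq_along(extra_rows)) {
      row <- extra_rows[[k]]
      nz <- which(row$coef != 0)
      ai <- c(ai, rep(m + k, length(nz)))
      aj <- c(aj, nz)
      ax <- c(ax, row$coef[nz])
      rlb <- c(rlb, row$lb); rub <- c(rub, row$ub)
    }
    m <- m + length(extra_rows)
  }
  solve_lp(obj, list(i = ai, j = aj, x = ax, nrow = m), rlb, rub,
           lb %||% model$reactions$lower_bound,
           ub %||% model$reactions$upper_bound,
           maximize = maximize)
}

growth_floor_row <- function(model, objective_reaction, floor) {
  coef <- numeric(nrow(model$reactions))
  coef[match(objective_reaction, model$reactions$id)] <- 1
  list(coef = coef, lb = floor, ub = Inf)
}

new_flux_solution <- function(model, lp, tol = 1e-6) {
  if (lp$status != "optimal") {
    return(structure(list(objective_value = NA_real_, fluxes = NULL,
                          status = lp$status), class = "flux_solution"))
  }
  fluxes <- setNames(lp$x, model$reactions$id)
  resid <- max(abs(as.numeric(model$S %*% fluxes)))
  if (resid > tol) {
    stop(sprintf("steady-state residual %.3g exceeds tolerance %.1g",
                 resid, tol))
  }
  if (any(fluxes < model$reactions$lower_bound - tol) ||
      any(fluxes > model$reactions$upper_bound + tol)) {
    stop("flux solution violates reaction bounds beyond tolerance")
  }
  structure(list(objective_value = lp$objective, fluxes = fluxes,
                 status = "optimal"), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status %s, objective %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the flux through the objective (biomass) reaction subject to the
#' steady-state constraint `S v = 0` and the reaction bounds. The returned
#' solution is audited post hoc: the steady-state residual and every bound
#' must hold within `tol`.
#'
#' @param model a `metabolic_model`.
#' @param objective_reaction reaction id to maximize; defaults to the model's
#'   biomass reaction.
#' @param tol feasibility tolerance for the post-solve audit.
#' @return a `flux_solution`: `objective_value`, named `fluxes`, `status`.
#' @export
fba <- function(model, objective_reaction = model$biomass_reaction_id,
                tol = 1e-6) {
  j <- match(objective_reaction, model$reactions$id)
  if (is.na(j)) stop("objective reaction '", objective_reaction,
                     "' not in model")
  obj <- numeric(nrow(model$reactions)); obj[j] <- 1
  new_flux_solution(model, model_lp(model, obj), tol)
}

#' Parsimonious flux balance analysis (pFBA)
#'
#' Two-step lexicographic LP: the FBA optimum is computed first, growth is
#' then fixed at that optimum and the total absolute flux -- the sum of
#' fluxes over the split irreversible reactions -- is minimized.
#'
#' @inheritParams fba
#' @return a `flux_solution` with net fluxes on the original reactions and an
#'   additional element `total_flux` (the minimized sum over split fluxes).
#' @export
pfba <- function(model, objective_reaction = model$biomass_reaction_id,
                 tol = 1e-6) {
  was_split <- !is.null(model$split_map)
  smodel <- split_reversible(model)
  sol <- fba(smodel, objective_reaction, tol)
  if (sol$status != "optimal") return(sol)
  floor_row <- growth_floor_row(smodel, objective_reaction,
                                sol$objective_value * (1 - 1e-9))
  lp <- model_lp(smodel, rep(1, nrow(smodel$reactions)), maximize = FALSE,
                 extra_rows = list(floor_row))
  psol <- new_flux_solution(smodel, lp, tol)
  if (psol$status != "optimal") return(psol)
  fluxes <- if (was_split) psol$fluxes else {
    merge_irreversible_fluxes(smodel, psol$fluxes)
  }
  structure(list(objective_value = sol$objective_value, fluxes = fluxes,
                 total_flux = lp$objective, status = "optimal"),
            class = "flux_solution")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to retaining at least
#' `fraction` of the optimal objective value.
#'
#' @inheritParams fba
#' @param fraction fraction of the optimum to guarantee, in `[0, 1]`.
#' @param reactions reaction ids to analyze (default: all).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, fraction = 0.9,
                objective_reaction = model$biomass_reaction_id,
                reactions = NULL, tol = 1e-6) {
  stopifnot(fraction >= 0, fraction <= 1)
  sol <- fba(model, objective_reaction, tol)
  if (sol$status != "optimal") stop("FVA requires an optimal FBA solution")
  floor <- fraction * sol$objective_value
  extra <- list(growth_floor_row(model, objective_reaction, floor))
  reactions <- reactions %||% model$reactions$id
  idx <- match(reactions, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction(s) in FVA request")
  n <- nrow(model$reactions)
  res <- vapply(idx, function(j) {
    obj <- numeric(n); obj[j] <- 1
    lo <- model_lp(model, obj, maximize = FALSE, extra_rows = extra)
    hi <- model_lp(model, obj, maximize = TRUE, extra_rows = extra)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for reaction ",
           model$reactions$id[j])
    }
    c(lo$objective, hi$objective)
  }, numeric(2))
  data.frame(reaction = reactions, min = res[1, ], max = res[2, ],
             stringsAsFactors = FALSE)
}

#' Blocked reactions
#'
#' Reactions unable to carry flux in any steady state under the current
#' bounds: both FVA endpoints at fraction 0 are within `tol` of zero.
#'
#' @inheritParams fba
#' @param tol zero tolerance on the FVA endpoints.
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model,
                              objective_reaction = model$biomass_reaction_id,
                              tol = 1e-9) {
  rng <- fva(model, fraction = 0, objective_reaction = objective_reaction)
  rng$reaction[abs(rng$min) <= tol & abs(rng$max) <= tol]
}

#' Detect stoichiometrically balanced cycles (SBCs)
#'
#' Closes every exchange and sink reaction (both directions) and reports the
#' internal reactions that can still carry flux: members of internal loops
#' able to sustain flux with no exchange with the environment. Detection
#' only; no automatic correction is attempted.
#'
#' @param model a `metabolic_model`.
#' @param tol flux threshold above which a closed-exchange FVA range counts
#'   as nonzero.
#' @return character vector of reaction ids participating in SBCs.
#' @export
detect_sbc <- function(model, tol = 1e-9) {
  boundary <- model$reactions$id[model$reactions$is_exchange |
                                   model$reactions$is_sink]
  closed <- model
  if (length(boundary)) {
    closed <- set_bounds(closed, boundary, lower = 0, upper = 0)
  }
  internal <- setdiff(model$reactions$id, boundary)
  # objective is irrelevant at fraction 0; reuse any internal reaction
  rng <- fva(closed, fraction = 0, objective_reaction = internal[1],
             reactions = internal)
  rng$reaction[abs(rng$min) > tol | abs(rng$max) > tol]
}

#' Subsystem flux-sum range
#'
#' Minimum and maximum of the summed fluxes of a subsystem's reactions while
#' guaranteeing a fraction of optimal growth. The model must have its
#' reversible reactions split so that all fluxes are nonnegative and the sum
#' measures total pathway activity.
#'
#' @inheritParams fva
#' @param subsystem subsystem label.
#' @return named numeric vector `c(min_sum, max_sum)`.
#' @export
subsystem_flux_range <- function(model, subsystem, fraction = 0.9,
                                 objective_reaction =
                                   model$biomass_reaction_id) {
  if (any(model$reactions$lower_bound < 0)) {
    stop("split reversible reactions before computing subsystem flux sums")
  }
  members <- model$reactions$subsystem == subsystem
  members[is.na(members)] <- FALSE
  if (!any(members)) stop("unknown subsystem: ", subsystem)
  sol <- fba(model, objective_reaction)
  extra <- list(growth_floor_row(model, objective_reaction,
                                 fraction * sol$objective_value))
  obj <- as.numeric(members)
  lo <- model_lp(model, obj, maximize = FALSE, extra_rows = extra)
  hi <- model_lp(model, obj, maximize = TRUE, extra_rows = extra)
  c(min_sum = lo$objective, max_sum = hi$objective)
}

#' Classify reaction coupling to the objective
#'
#' Compares each flux-carrying reaction's FVA range width with the biomass
#' reaction's range width at the same growth fraction: equal width (within
#' `tol`) is `hard` coupling, smaller is `soft`, strictly between the biomass
#' width and the default bound magnitude `vmax` is `partial`, and width equal
#' to `vmax` (within `tol`) is `uncoupled`. Reactions whose range is `[0, 0]`
#' (within `tol`) are `non-carrying`. The classes partition the reactions.
#'
#' @inheritParams fva
#' @param tol classification tolerance.
#' @param vmax default bound magnitude (mmol gDW^-1 h^-1).
#' @return data.frame with columns `reaction`, `width`, `class`.
#' @export
classify_coupling <- function(model, fraction = 0.9, tol = 1e-3, vmax = 2000,
                              objective_reaction =
                                model$biomass_reaction_id) {
  rng <- fva(model, fraction = fraction,
             objective_reaction = objective_reaction)
  width <- rng$max - rng$min
  bio_width <- width[match(objective_reaction, rng$reaction)]
  cls <- ifelse(abs(rng$min) <= tol & abs(rng$max) <= tol, "non-carrying",
         ifelse(width >= vmax - tol, "uncoupled",
         ifelse(abs(width - bio_width) <= tol, "hard",
         ifelse(width < bio_width, "soft", "partial"))))
  data.frame(reaction = rng$reaction, width = width, class = cls,
             stringsAsFactors = FALSE)
}

#' ATP production capacity and yield on a carbon source
#'
#' Maximizes the flux through an ATP sink/maintenance reaction while
#' guaranteeing a fraction of optimal growth; the yield divides the ATP flux
#' by the uptake flux of the given carbon source (mmol ATP per mmol carbon
#' source).
#'
#' @param model a `metabolic_model` with the medium applied.
#' @param carbon_source boundary metabolite id of the carbon source.
#' @param atp_sink reaction id of the ATP sink/demand reaction.
#' @param growth_fraction fraction of optimal growth to retain (0 or 0.5 in
#'   typical scans).
#' @param objective_reaction growth objective; defaults to biomass.
#' @return list with `max_atp_flux`, `atp_yield` and `carbon_uptake`.
#' @export
atp_production <- function(model, carbon_source, atp_sink,
                           growth_fraction = 0,
                           objective_reaction = model$biomass_reaction_id) {
  if (!atp_sink %in% model$reactions$id) {
    stop("ATP sink reaction '", atp_sink, "' not in model")
  }
  ex_idx <- which(model$reactions$is_exchange &
                    !grepl("_rev$", model$reactions$id))
  ex_met <- vapply(ex_idx, function(j) {
    model$metabolites$id[which(model$S[, j] != 0)[1]]
  }, character(1))
  src <- ex_idx[match(carbon_source, ex_met)]
  if (is.na(src)) stop("no exchange reaction for metabolite ", carbon_source)
  sol <- fba(model, objective_reaction)
  extra <- list(growth_floor_row(model, objective_reaction,
                                 growth_fraction * sol$objective_value))
  obj <- numeric(nrow(model$reactions))
  obj[match(atp_sink, model$reactions$id)] <- 1
  lp <- model_lp(model, obj, maximize = TRUE, extra_rows = extra)
  if (lp$status != "optimal") stop("ATP maximization not optimal")
  fluxes <- setNames(lp$x, model$reactions$id)
  uptake <- -fluxes[[model$reactions$id[src]]]
  if (!is.null(model$split_map)) {
    rev_id <- model$split_map$rev[match(model$reactions$id[src],
                                        model$split_map$orig)]
    if (!is.na(rev_id)) uptake <- fluxes[[rev_id]] - fluxes[[
      model$reactions$id[src]]]
  }
  atp <- lp$objective
  list(max_atp_flux = atp,
       atp_yield = if (uptake > 1e-9) atp / uptake else 0,
       carbon_uptake = uptake)
}

#' Jaccard index of EC number overlap between two models
#'
#' For every subsystem present in at least one model, computes the Jaccard
#' index of the EC number sets annotated to that subsystem's reactions.
#'
#' @param model_a,model_b `metabolic_model`s with EC annotations.
#' @param subsystem_map optional named character vector remapping subsystem
#'   labels (old name -> common name) before comparison.
#' @return data.frame with columns `subsystem`, `jaccard`, `n_union`.
#' @export
jaccard_ec_overlap <- function(model_a, model_b, subsystem_map = NULL) {
  ec_sets <- function(model) {
    sub <- model$reactions$subsystem
    if (!is.null(subsystem_map)) {
      hit <- sub %in% names(subsystem_map)
      sub[hit] <- subsystem_map[sub[hit]]
    }
    keep <- !is.na(sub)
    tapply(model$reactions$ec[keep], sub[keep],
           function(e) unique(unlist(e)), simplify = FALSE)
  }
  a <- ec_sets(model_a); b <- ec_sets(model_b)
  subs <- union(names(a), names(b))
  res <- lapply(subs, function(s) {
    ua <- a[[s]] %||% character(0)
    ub <- b[[s]] %||% character(0)
    un <- union(ua, ub)
    if (length(un) == 0) return(NULL)
    data.frame(subsystem = s,
               jaccard = length(intersect(ua, ub)) / length(un),
               n_union = length(un), stringsAsFactors = FALSE)
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}
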