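#' Michaelis-Menten transporter uptake bound
#'
#' Converts an external substrate concentration into a maximum transporter
#' flux, \eqn{v = V_{max} [S] / (K_m + [S])}.
#'
#' @param vmax maximal transport rate (mmol gDW^-1 h^-1), > 0.
#' @param km half-saturation constant (mM), > 0.
#' @param conc substrate concentration (mM), >= 0.
#' @return the uptake flux bound (mmol gDW^-1 h^-1).
#' @examples
#' uptake_bound(10, 5, 5)   # half saturation: 5
#' uptake_bound(10, 5, 10)  # 20/3
#' @export
uptake_bound <- function(vmax, km, conc) {
  stopifnot(vmax > 0, km > 0)
  if (any(conc < 0)) stop("substrate concentration must be nonnegative")
  vmax * conc / (km + conc)
}

#' Rescale the biomass reaction to a measured protein content
#'
#' Sets the mass fraction of the protein component of biomass to `C`
#' (g gDW^-1) and scales the remaining components by a common factor so that
#' their mass totals `1 - C`; after rescaling the sum of biomass
#' coefficients times precursor molecular weights equals 1 g gDW^-1. The
#' model must carry a `biomass_composition` table (columns `metabolite`,
#' `class`, `mw`) identifying the protein component and the precursor
#' molecular weights; precursors with zero molecular weight (e.g. the ATP
#' hydrolysis of growth-associated maintenance) are untouched.
#'
#' @param model a `metabolic_model` with `biomass_composition`.
#' @param C target protein content, in (0, 1) g gDW^-1.
#' @return the model with rescaled biomass coefficients.
#' @export
rescale_biomass <- function(model, C) {
  if (C <= 0 || C >= 1) stop("protein content C must lie in (0, 1)")
  comp <- model$biomass_composition
  if (is.null(comp)) stop("model carries no biomass_composition table")
  j <- match(model$biomass_reaction_id, model$reactions$id)
  if (is.na(j)) stop("model has no biomass reaction")
  idx <- match(comp$metabolite, model$metabolites$id)
  if (anyNA(idx)) stop("biomass composition references unknown metabolites")
  coef <- model$S[idx, j]
  mass <- abs(coef) * comp$mw
  is_prot <- comp$class == "protein" & comp$mw > 0
  has_mass <- comp$mw > 0
  P_old <- sum(mass[is_prot])
  O_old <- sum(mass[has_mass & !is_prot])
  if (P_old <= 0 || O_old <= 0) {
    stop("biomass must contain protein and non-protein mass components")
  }
  scale <- rep(1, nrow(comp))
  scale[is_prot] <- C / P_old
  scale[has_mass & !is_prot] <- (1 - C) / O_old
  model$S[cbind(idx, j)] <- coef * scale
  total <- sum(abs(model$S[idx, j]) * comp$mw)
  stopifnot(abs(total - 1) < 1e-9)
  model
}

#' Bundle enzyme constraint parameters
#'
#' @param kcats a `kcat_assignment` (from [assign_kcats()]) or a named vector
#'   of turnover numbers in h^-1 keyed by reaction id.
#' @param mw named vector of molecular weights in g mmol^-1, keyed by gene.
#' @param C total protein content (g gDW^-1).
#' @param alpha minimum abundance of an expressed gene (mmol gDW^-1).
#' @param beta maximum abundance of any gene (mmol gDW^-1).
#' @return an `enzyme_constraint_set` list.
#' @export
enzyme_constraint_set <- function(kcats, mw, C, alpha = 1e-10, beta = 1) {
  if (inherits(kcats, "kcat_assignment") || is.data.frame(kcats)) {
    kcats <- setNames(kcats$kcat_per_h, kcats$reaction)
  }
  stopifnot(all(kcats > 0), all(mw > 0), alpha < beta, C >= 0)
  structure(list(kcat = kcats, mw = mw, C = C, alpha = alpha, beta = beta),
            class = "enzyme_constraint_set")
}

#' Build the enzyme-allocation MILP
#'
#' Encodes the mixed-integer program that maximizes growth under enzyme
#' capacity and molecular crowding constraints:
#' \itemize{
#'   \item steady state, \eqn{S v = 0}, with \eqn{0 \le v \le ub} on the
#'     split-irreversible model;
#'   \item per enzymatic reaction \eqn{i}: \eqn{v_i \le E^r_i\,k_{cat,i}},
#'     where the reaction-level enzyme capacity \eqn{E^r_i} follows the GPR
#'     rule recursively -- for complexes (`and`) the capacity is bounded by
#'     each operand, for isozymes (`or`) by the sum of the operands;
#'   \item promiscuity: each gene's abundance \eqn{E^g_k} is split across the
#'     reactions it catalyzes through per-(gene, reaction) allocation
#'     variables that sum to \eqn{E^g_k};
#'   \item molecular crowding: \eqn{\sum_k E^g_k \cdot MW_k \le C};
#'   \item expression indicators: \eqn{\alpha y_k \le E^g_k \le \beta y_k}
#'     with \eqn{y_k \in \{0, 1\}}, enforcing a small minimum abundance for
#'     expressed genes.
#' }
#' Reactions without GPR (or without an assigned kcat) keep their plain flux
#' bounds.
#'
#' @param model a split-irreversible `metabolic_model`.
#' @param enz an [enzyme_constraint_set()].
#' @param crowding_groups optional list of `list(genes =, C =)` imposing one
#'   crowding constraint per gene pool instead of a single global one (used
#'   by [protein_pool_split()]). Genes in no group fall under no crowding
#'   constraint.
#' @return an `emoment_problem` (constraint triplets, bounds, and variable
#'   index maps), ready for [solve_emoment()].
#' @export
build_emoment <- function(model, enz, crowding_groups = NULL) {
  if (any(model$reactions$lower_bound < 0)) {
    stop("eMOMENT requires a split-irreversible model")
  }
  n_v <- nrow(model$reactions)
  constrained <- model$reactions$id[nzchar(model$reactions$gpr) &
                                      model$reactions$id %in%
                                        names(enz$kcat)]
  genes <- sort(unique(unlist(lapply(model$gprs[constrained], gpr_genes))))
  missing_mw <- setdiff(genes, names(enz$mw))
  if (length(missing_mw)) {
    stop("missing molecular weights for gene(s): ",
         paste(missing_mw, collapse = ", "))
  }

  env <- new.env(parent = emptyenv())
  env$nvar <- n_v
  env$nrow <- nrow(model$S)
  env$ai <- list(); env$aj <- list(); env$ax <- list()
  env$rlb <- list(); env$rub <- list()
  add_var <- function() (env$nvar <- env$nvar + 1L)
  add_row <- function(j, x, lb, ub) {
    env$nrow <- env$nrow + 1L
    env$ai[[length(env$ai) + 1L]] <- rep(env$nrow, length(j))
    env$aj[[length(env$aj) + 1L]] <- j
    env$ax[[length(env$ax) + 1L]] <- x
    env$rlb[[length(env$rlb) + 1L]] <- lb
    env$rub[[length(env$rub) + 1L]] <- ub
  }

  # Allocation and GPR-node variables, one allocation per (gene, reaction)
  # pair. To keep the constraint matrix well conditioned despite turnover
  # numbers spanning several orders of magnitude, these variables are held
  # in flux-capacity units (kcat_i times the allocated abundance): the
  # enzyme capacity rows then carry unit coefficients and kcat only enters
  # the gene-total rows as 1/kcat.
  alloc <- list()
  add_gpr <- function(expr, rid) {
    if (expr$op == "gene") {
      key <- paste(expr$gene, rid, sep = "\r")
      if (is.null(alloc[[key]])) alloc[[key]] <<- add_var()
      return(alloc[[key]])
    }
    children <- vapply(expr$args, add_gpr, integer(1), rid = rid)
    node <- add_var()
    if (expr$op == "and") {
      for (ch in children) add_row(c(node, ch), c(1, -1), -Inf, 0)
    } else {
      add_row(c(node, children), c(1, rep(-1, length(children))), -Inf, 0)
    }
    node
  }

  root_idx <- setNames(integer(length(constrained)), constrained)
  alloc_kcat <- list()  # capacity scale of each allocation variable
  for (rid in constrained) {
    n_before <- length(alloc)
    root_idx[[rid]] <- add_gpr(model$gprs[[rid]], rid)
    new_keys <- names(alloc)[seq_len(length(alloc) - n_before) + n_before]
    for (key in new_keys) alloc_kcat[[key]] <- enz$kcat[[rid]]
    j <- match(rid, model$reactions$id)
    add_row(c(j, root_idx[[rid]]), c(1, -1), -Inf, 0)
  }

  # When alpha sits orders of magnitude below the feasibility tolerance,
  # the indicator layer cannot move any abundance or flux by more than
  # alpha itself (1e-10 mmol gDW^-1 at the default), while its 1e-10-scale
  # matrix coefficients destabilize both the simplex and the
  # branch-and-cut. The indicators are then kept out of the matrix and
  # recovered from the abundance support after solving; for larger alpha
  # the binary layer is built and solved exactly.
  indicator_mode <- if (enz$alpha <= 1e-8) "support" else "milp"
  Eg_idx <- setNames(vapply(genes, function(g) add_var(), integer(1)), genes)
  y_idx <- if (indicator_mode == "milp") {
    setNames(vapply(genes, function(g) add_var(), integer(1)), genes)
  } else {
    setNames(integer(0), character(0))
  }

  alloc_keys <- strsplit(names(alloc), "\r", fixed = TRUE)
  alloc_gene <- vapply(alloc_keys, `[[`, character(1), 1)
  alloc_col <- unlist(alloc)
  alloc_scale <- unlist(alloc_kcat)[names(alloc)]
  for (g in genes) {
    sel <- alloc_gene == g
    # capacity-unit allocations divided by their kcat sum to the gene's
    # abundance (the promiscuity constraint)
    add_row(c(alloc_col[sel], Eg_idx[[g]]),
            c(1 / alloc_scale[sel], -1), 0, 0)
  }

  if (is.null(crowding_groups)) {
    crowding_groups <- list(list(genes = genes, C = enz$C))
  }
  for (grp in crowding_groups) {
    gg <- intersect(grp$genes, genes)
    if (length(gg) == 0) next
    add_row(Eg_idx[gg], enz$mw[gg], -Inf, grp$C)
  }

  if (indicator_mode == "milp") {
    # implied tightening: crowding already caps E_k at C/MW_k, so the
    # indicator coupling can use min(beta, C/MW_k) without changing the
    # feasible set -- this keeps the big-M coefficient on the scale of the
    # abundances and the branch-and-cut numerically clean
    gene_cap <- setNames(rep(enz$beta, length(genes)), genes)
    for (grp in crowding_groups) {
      gg <- intersect(grp$genes, genes)
      gene_cap[gg] <- pmin(gene_cap[gg], grp$C / enz$mw[gg])
    }
    for (g in genes) {
      add_row(c(y_idx[[g]], Eg_idx[[g]]), c(enz$alpha, -1), -Inf, 0)
      add_row(c(Eg_idx[[g]], y_idx[[g]]), c(1, -gene_cap[[g]]), -Inf, 0)
    }
  }

  Tm <- as(as(model$S, "generalMatrix"), "TsparseMatrix")
  nvar <- env$nvar
  clb <- c(model$reactions$lower_bound, rep(0, nvar - n_v))
  cub <- c(model$reactions$upper_bound, rep(Inf, nvar - n_v))
  cub[Eg_idx] <- enz$beta
  if (length(y_idx)) { clb[y_idx] <- 0; cub[y_idx] <- 1 }

  structure(list(
    model = model, enz = enz,
    nvar = nvar, nrow = env$nrow,
    ai = c(Tm@i + 1L, unlist(env$ai)),
    aj = c(Tm@j + 1L, unlist(env$aj)),
    ax = c(Tm@x, unlist(env$ax)),
    rlb = c(rep(0, nrow(model$S)), unlist(env$rlb)),
    rub = c(rep(0, nrow(model$S)), unlist(env$rub)),
    clb = clb, cub = cub,
    v_idx = setNames(seq_len(n_v), model$reactions$id),
    root_idx = root_idx,
    Eg_idx = Eg_idx, y_idx = y_idx,
    indicator_mode = indicator_mode,
    constrained = constrained, genes = genes),
    class = "emoment_problem")
}

# Solve the (MI)LP with a custom objective and optional extra rows
# (each list(j =, x =, lb =, ub =)) appended to the constraint set.
# In "support" indicator mode the problem carries no binary columns and
# this is a plain LP.
emoment_lp <- function(problem, obj, maximize = TRUE, extra_rows = NULL,
                       clb = NULL, cub = NULL, relax_binary = FALSE) {
  ai <- problem$ai; aj <- problem$aj; ax <- problem$ax
  rlb <- problem$rlb; rub <- problem$rub
  m <- problem$nrow
  for (row in extra_rows) {
    m <- m + 1L
    ai <- c(ai, rep(m, length(row$j))); aj <- c(aj, row$j)
    ax <- c(ax, row$x); rlb <- c(rlb, row$lb); rub <- c(rub, row$ub)
  }
  nvar <- length(obj)
  solve_lp(obj, list(i = ai, j = aj, x = ax, nrow = m), rlb, rub,
           clb %||% c(problem$clb, rep(0, nvar - problem$nvar)),
           cub %||% c(problem$cub, rep(Inf, nvar - problem$nvar)),
           maximize = maximize,
           binary = if (relax_binary) integer(0)
                    else unname(problem$y_idx))
}

#' Solve the enzyme-allocation MILP for maximal growth
#'
#' @param problem an `emoment_problem` from [build_emoment()].
#' @param objective_reaction reaction to maximize (default: the model's
#'   biomass reaction).
#' @param tol feasibility tolerance for the post-solve audit of the enzyme
#'   capacity, crowding and indicator constraints.
#' @return an `emoment_solution`: `growth`, named `fluxes`, `gene_abundance`
#'   (E^g, mmol gDW^-1), reaction-level capacities `reaction_enzyme` (E^r),
#'   indicators `y`, `status`.
#' @export
solve_emoment <- function(problem,
                          objective_reaction =
                            problem$model$biomass_reaction_id,
                          tol = 1e-6) {
  obj <- numeric(problem$nvar)
  obj[problem$v_idx[[objective_reaction]]] <- 1
  lp <- emoment_lp(problem, obj, maximize = TRUE)
  if (lp$status != "optimal") {
    return(structure(list(growth = NA_real_, status = lp$status),
                     class = "emoment_solution"))
  }
  sol <- emoment_extract(problem, lp, tol)
  sol$growth <- lp$objective
  sol
}

emoment_extract <- function(problem, lp, tol = 1e-6) {
  x <- lp$x
  fluxes <- setNames(x[problem$v_idx], names(problem$v_idx))
  Eg <- setNames(x[problem$Eg_idx], names(problem$Eg_idx))
  y <- if (problem$indicator_mode == "milp") {
    setNames(round(x[problem$y_idx]), names(problem$y_idx))
  } else {
    setNames(as.numeric(Eg > problem$enz$alpha), names(Eg))
  }
  enz <- problem$enz
  # root variables live in capacity units; reported E^r is an abundance
  capacity <- setNames(x[problem$root_idx], names(problem$root_idx))
  Er <- capacity / enz$kcat[names(capacity)]
  stopifnot(max(abs(as.numeric(problem$model$S %*% fluxes))) <= tol)
  stopifnot(all(fluxes[problem$constrained] <=
                  capacity[problem$constrained] + tol))
  stopifnot(sum(Eg * enz$mw[names(Eg)]) <= enz$C + tol)
  stopifnot(all(Eg >= enz$alpha * y - tol), all(Eg <= enz$beta * y + tol))
  structure(list(growth = NA_real_, fluxes = fluxes, gene_abundance = Eg,
                 reaction_enzyme = Er, y = y, status = "optimal"),
            class = "emoment_solution")
}

#' @export
print.emoment_solution <- function(x, ...) {
  cat(sprintf("emoment_solution: status %s, growth %s\n", x$status,
              format(x$growth)))
  invisible(x)
}

#' Brute-force reference for the enzyme-allocation MILP
#'
#' Enumerates all assignments of the binary expression indicators and solves
#' the remaining linear program for each, returning the best objective.
#' Exponential in the number of genes; intended as an independent check of
#' the branch-and-cut solution on small instances.
#'
#' @inheritParams solve_emoment
#' @param max_genes guard against accidental exponential blow-up.
#' @return list with `growth` (best objective over all indicator
#'   assignments) and `y` (the best assignment).
#' @export
emoment_enumerate <- function(problem,
                              objective_reaction =
                                problem$model$biomass_reaction_id,
                              max_genes = 16) {
  g <- length(problem$genes)
  if (g > max_genes) stop("too many genes for enumeration (", g, ")")
  if (problem$indicator_mode != "milp") {
    stop("problem carries no explicit indicator variables (alpha below ",
         "numerical relevance); rebuild with a larger alpha to enumerate")
  }
  obj <- numeric(problem$nvar)
  obj[problem$v_idx[[objective_reaction]]] <- 1
  best <- -Inf; best_y <- NULL
  for (mask in 0:(2^g - 1)) {
    yy <- as.numeric(bitwAnd(bitwShiftR(mask, seq_len(g) - 1L), 1L))
    clb <- problem$clb; cub <- problem$cub
    clb[problem$y_idx] <- yy; cub[problem$y_idx] <- yy
    lp <- emoment_lp(problem, obj, maximize = TRUE, clb = clb, cub = cub,
                     relax_binary = TRUE)
    if (lp$status == "optimal" && lp$objective > best) {
      best <- lp$objective
      best_y <- setNames(yy, problem$genes)
    }
  }
  list(growth = best, y = best_y)
}

#' Feasible abundance range per gene at near-optimal growth
#'
#' Minimizes and maximizes each gene's abundance E^g subject to all
#' enzyme-allocation constraints plus a growth floor, analogous to flux
#' variability analysis.
#'
#' @inheritParams solve_emoment
#' @param fraction fraction of the optimal growth to guarantee.
#' @param optimum optionally, a precomputed optimal growth value.
#' @return data.frame with columns `gene`, `min`, `max`.
#' @export
abundance_variability <- function(problem, fraction = 0.99,
                                  objective_reaction =
                                    problem$model$biomass_reaction_id,
                                  optimum = NULL) {
  if (is.null(optimum)) {
    optimum <- solve_emoment(problem, objective_reaction)$growth
  }
  floor_row <- list(j = problem$v_idx[[objective_reaction]], x = 1,
                    lb = fraction * optimum, ub = Inf)
  res <- vapply(problem$genes, function(g) {
    obj <- numeric(problem$nvar)
    obj[problem$Eg_idx[[g]]] <- 1
    lo <- emoment_lp(problem, obj, FALSE, extra_rows = list(floor_row))
    hi <- emoment_lp(problem, obj, TRUE, extra_rows = list(floor_row))
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("abundance variability subproblem not optimal for gene ", g)
    }
    c(lo$objective, hi$objective)
  }, numeric(2))
  data.frame(gene = problem$genes, min = res[1, ], max = res[2, ],
             stringsAsFactors = FALSE)
}

#' Sample feasible enzyme abundance vectors at near-optimal growth
#'
#' For each sample a reference abundance vector is drawn uniformly within
#' the per-gene feasible ranges and the closest feasible abundance vector
#' (L1 norm, keeping each step a linear MILP) satisfying all
#' enzyme-allocation constraints and the growth floor is returned.
#' Reproducible via `seed`.
#'
#' @inheritParams abundance_variability
#' @param n number of samples.
#' @param seed integer seed controlling the reference draws.
#' @param ranges optionally, precomputed [abundance_variability()] output.
#' @return an `abundance_samples` list: `samples` (n x genes matrix of E^g),
#'   `seed`, `fraction`, `n_failed`.
#' @export
sample_abundances <- function(problem, n = 1000, fraction = 0.99, seed = 1,
                              objective_reaction =
                                problem$model$biomass_reaction_id,
                              ranges = NULL) {
  optimum <- solve_emoment(problem, objective_reaction)$growth
  if (is.null(ranges)) {
    ranges <- abundance_variability(problem, fraction, objective_reaction,
                                    optimum = optimum)
  }
  genes <- problem$genes
  ng <- length(genes)
  # distance variables t_g appended after the problem's own columns:
  #   E_g - t_g <= ref_g   and   -E_g - t_g <= -ref_g
  t_idx <- problem$nvar + seq_len(ng)
  rows_template <- c(
    lapply(seq_len(ng), function(k) {
      list(j = c(problem$Eg_idx[[genes[k]]], t_idx[k]), x = c(1, -1),
           lb = -Inf, ub = NA_real_)
    }),
    lapply(seq_len(ng), function(k) {
      list(j = c(problem$Eg_idx[[genes[k]]], t_idx[k]), x = c(-1, -1),
           lb = -Inf, ub = NA_real_)
    }),
    list(list(j = problem$v_idx[[objective_reaction]], x = 1,
              lb = fraction * optimum, ub = Inf)))
  obj <- c(numeric(problem$nvar), rep(1, ng))
  set.seed(seed)
  # solver jitter can leave min infinitesimally above max on point ranges
  hi <- pmax(ranges$max, ranges$min)
  refs <- matrix(runif(n * ng, min = rep(ranges$min, each = n),
                       max = rep(hi, each = n)), nrow = n)
  samples <- matrix(NA_real_, n, ng, dimnames = list(NULL, genes))
  n_failed <- 0L
  for (s in seq_len(n)) {
    rows <- rows_template
    for (k in seq_len(ng)) {
      rows[[k]]$ub <- refs[s, k]
      rows[[ng + k]]$ub <- -refs[s, k]
    }
    lp <- emoment_lp(problem, obj, maximize = FALSE, extra_rows = rows)
    if (lp$status == "optimal") {
      samples[s, ] <- lp$x[problem$Eg_idx]
    } else {
      n_failed <- n_failed + 1L
    }
  }
  structure(list(samples = samples[!is.na(samples[, 1]), , drop = FALSE],
                 seed = seed, fraction = fraction, n_failed = n_failed),
            class = "abundance_samples")
}

#' Predict growth across carbon source / concentration conditions
#'
#' For each condition the model is restricted to a single carbon source
#' whose uptake bound follows Michaelis-Menten transporter kinetics at the
#' condition's concentration, the lipid (palmitate-like) uptake is capped at
#' its FBA-optimal value, the biomass reaction is rescaled to the measured
#' protein content, the crowding bound is set to the same content, and
#' growth is predicted with the enzyme-allocation MILP. Plain FBA growth
#' under identical bounds is reported for contrast.
#'
#' @param model a split-irreversible `metabolic_model` with a
#'   `biomass_composition` table.
#' @param enz an [enzyme_constraint_set()].
#' @param conditions data.frame with columns `condition`, `carbon_source`
#'   (boundary metabolite id), `concentration_mM`, `vmax`, `km`,
#'   `protein_content`.
#' @param base_medium named uptake vector of the always-present medium
#'   components (including the capped lipid source).
#' @return the `conditions` data.frame extended with `uptake_bound`,
#'   `growth_emoment` and `growth_fba`.
#' @export
simulate_condition_panel <- function(model, enz, conditions, base_medium) {
  res <- conditions
  res$uptake_bound <- NA_real_
  res$growth_emoment <- NA_real_
  res$growth_fba <- NA_real_
  for (k in seq_len(nrow(conditions))) {
    cond <- conditions[k, ]
    ub <- uptake_bound(cond$vmax, cond$km, cond$concentration_mM)
    medium <- base_medium
    medium[[cond$carbon_source]] <- ub
    m <- apply_medium(model, medium)
    m <- rescale_biomass(m, cond$protein_content)
    enz_k <- enz
    enz_k$C <- cond$protein_content
    prob <- build_emoment(m, enz_k)
    res$uptake_bound[k] <- ub
    res$growth_emoment[k] <- solve_emoment(prob)$growth
    res$growth_fba[k] <- fba(m)$objective_value
  }
  res
}

#' Effect of splitting the protein pool on growth with an extra fatty acid
#'
#' Splits the total protein content into a peroxisomal pool (bounded by
#' `alpha_pool * C`) and a pool of remaining enzymes (bounded by
#' `(1 - alpha_pool) * C`), then compares predicted growth with the
#' myristate-like uptake closed (reference) and open. The ratio
#' `Z = growth_with / growth_without` exceeds 1 where dedicating protein to
#' peroxisomal beta-oxidation pays off.
#'
#' @param model a split-irreversible `metabolic_model` with medium applied
#'   (myristate closed).
#' @param enz an [enzyme_constraint_set()].
#' @param peroxisomal_genes genes assigned to the peroxisomal pool.
#' @param alpha_grid pool ratios to scan, each in `[0, 1]`.
#' @param myristate boundary metabolite id of the myristate-like source.
#' @param myristate_uptake uptake bound granted when the source is open.
#' @return data.frame with columns `alpha_pool`, `growth_without`,
#'   `growth_with`, `Z`.
#' @export
protein_pool_split <- function(model, enz, peroxisomal_genes,
                               alpha_grid = seq(0, 0.5, by = 0.1),
                               myristate, myristate_uptake = 10) {
  if (length(peroxisomal_genes) == 0) {
    stop("peroxisomal gene set must be nonempty")
  }
  model_open <- apply_medium_delta(model, myristate, myristate_uptake)
  res <- data.frame(alpha_pool = alpha_grid, growth_without = NA_real_,
                    growth_with = NA_real_)
  for (k in seq_along(alpha_grid)) {
    a <- alpha_grid[k]
    groups <- function(m, genes_all) list(
      list(genes = intersect(peroxisomal_genes, genes_all), C = a * enz$C),
      list(genes = setdiff(genes_all, peroxisomal_genes),
           C = (1 - a) * enz$C))
    all_genes <- model$genes
    res$growth_without[k] <- solve_emoment(
      build_emoment(model, enz, crowding_groups = groups(model, all_genes))
    )$growth
    res$growth_with[k] <- solve_emoment(
      build_emoment(model_open, enz,
                    crowding_groups = groups(model_open, all_genes))
    )$growth
  }
  res$Z <- ifelse(res$growth_without > 0,
                  res$growth_with / res$growth_without, NA_real_)
  res
}

# set a single boundary metabolite's uptake without touching the rest
apply_medium_delta <- function(model, metabolite, max_uptake) {
  ex_idx <- which(model$reactions$is_exchange &
                    !grepl("_rev$", model$reactions$id))
  ex_met <- vapply(ex_idx, function(j) {
    model$metabolites$id[which(model$S[, j] != 0)[1]]
  }, character(1))
  j <- ex_idx[match(metabolite, ex_met)]
  if (is.na(j)) stop("no exchange reaction for metabolite ", metabolite)
  rid <- model$reactions$id[j]
  if (!is.null(model$split_map)) {
    rev_id <- model$split_map$rev[match(rid, model$split_map$orig)]
    if (is.na(rev_id)) stop("split model lacks uptake copy for ", rid)
    set_bounds(model, rev_id, lower = 0, upper = max_uptake)
  } else {
    set_bounds(model, rid, lower = -max_uptake)
  }
}

#' Plasticity of abundances or fluxes across conditions
#'
#' Coefficient of variation (sample standard deviation divided by mean) of
#' the per-condition mean value of each entity (gene or reaction) across
#' simulated conditions. Entities with zero mean across all conditions are
#' reported as `NA`.
#'
#' @param sample_sets named list (one element per condition) of sample
#'   matrices (samples x entities) or `abundance_samples` objects, all with
#'   identical column sets.
#' @return named numeric vector of CVs per entity.
#' @export
plasticity_cv <- function(sample_sets) {
  if (length(sample_sets) < 2) {
    stop("plasticity requires at least two conditions")
  }
  mats <- lapply(sample_sets, function(s) {
    if (inherits(s, "abundance_samples")) s$samples else s
  })
  cols <- colnames(mats[[1]])
  if (!all(vapply(mats, function(m) identical(colnames(m), cols),
                  logical(1)))) {
    stop("sample sets have mismatched entity columns")
  }
  means <- do.call(rbind, lapply(mats, colMeans))
  cv <- apply(means, 2, function(x) {
    if (mean(x) == 0) NA_real_ else sd(x) / mean(x)
  })
  setNames(cv, cols)
}
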