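#' Convert transcript counts to protein-equivalent abundances
#'
#' Counts are normalized to relative abundances summing to 1 and converted
#' to protein equivalents by distributing the total protein content `C`
#' according to relative abundance:
#' \eqn{tc'_k = tc_k / \sum_k tc_k}, \eqn{tc^p_k = tc'_k \, C / MW_k}
#' (mmol gDW^-1). The identity \eqn{\sum_k tc^p_k MW_k = C} holds by
#' construction.
#'
#' @param counts named nonnegative numeric vector of transcript counts per
#'   gene (replicates already averaged).
#' @param C total protein content (g gDW^-1).
#' @param mw named molecular weights (g mmol^-1) covering all genes.
#' @param structure optional structure label (e.g. `"ERM"`).
#' @return a `transcript_profile`: `counts`, `normalized`, `protein`
#'   (tc^p), `C`, `structure`.
#' @export
transcript_to_protein <- function(counts, C, mw, structure = NA_character_) {
  if (sum(counts) <= 0) stop("total transcript count must be positive")
  missing_mw <- setdiff(names(counts), names(mw))
  if (length(missing_mw)) {
    stop("missing molecular weights for gene(s): ",
         paste(missing_mw, collapse = ", "))
  }
  normalized <- counts / sum(counts)
  protein <- normalized * C / mw[names(counts)]
  structure(list(counts = counts, normalized = normalized,
                 protein = setNames(as.numeric(protein), names(counts)),
                 C = C, structure = structure),
            class = "transcript_profile")
}

#' Transcript-derived upper flux bounds per reaction
#'
#' Maps protein-equivalent abundances onto reactions through the GPR rules
#' in transcript mode (minimum over complex subunits, maximum over
#' isozymes) and multiplies by the reaction's turnover number:
#' \eqn{v_i \le k_{cat,i} \, tc^r_i}. Reactions without a GPR (or without an
#' assigned kcat) are not bounded.
#'
#' @param model a split-irreversible `metabolic_model`.
#' @param profile a [transcript_to_protein()] profile covering the model's
#'   genes.
#' @param kcats named turnover numbers in h^-1 (or a `kcat_assignment`).
#' @return named numeric vector of upper bounds for the constrained
#'   reactions.
#' @export
transcript_reaction_bounds <- function(model, profile, kcats) {
  if (inherits(kcats, "kcat_assignment") || is.data.frame(kcats)) {
    kcats <- setNames(kcats$kcat_per_h, kcats$reaction)
  }
  ids <- model$reactions$id[nzchar(model$reactions$gpr) &
                              model$reactions$id %in% names(kcats)]
  vapply(setNames(ids, ids), function(rid) {
    tcr <- evaluate_gpr(model$gprs[[rid]], profile$protein, "transcript")
    kcats[[rid]] * tcr
  }, numeric(1))
}

#' Apply transcript-derived bounds to a model
#'
#' Upper bounds of the constrained reactions are tightened to
#' `min(current, bound)`; all other reactions are untouched.
#'
#' @param model a split-irreversible `metabolic_model`.
#' @param bounds named vector from [transcript_reaction_bounds()].
#' @return the bounded model.
#' @export
apply_structure_bounds <- function(model, bounds) {
  idx <- match(names(bounds), model$reactions$id)
  if (anyNA(idx)) stop("bounds reference unknown reactions")
  model$reactions$upper_bound[idx] <-
    pmin(model$reactions$upper_bound[idx], bounds)
  validate_model(model)
  model
}

#' Growth of a transcript-bounded model
#'
#' FBA growth under structure-specific bounds. When `sigma` is given, growth
#' is additionally evaluated with all transcript bounds scaled to protein
#' contents `C - sigma` and `C + sigma` (bounds are proportional to `C`),
#' yielding error bars reflecting the measurement uncertainty of the protein
#' content.
#'
#' @inheritParams apply_structure_bounds
#' @param C protein content the bounds were computed at (g gDW^-1); only
#'   needed with `sigma`.
#' @param sigma standard deviation of the measured protein content.
#' @return list with `growth` and, when `sigma` is given, `growth_low` and
#'   `growth_high`.
#' @export
structure_growth <- function(model, bounds, C = NULL, sigma = NULL) {
  out <- list(growth = fba(apply_structure_bounds(model, bounds))$
                objective_value)
  if (!is.null(sigma)) {
    stopifnot(!is.null(C), sigma >= 0, sigma < C)
    out$growth_low <- fba(apply_structure_bounds(
      model, bounds * (C - sigma) / C))$objective_value
    out$growth_high <- fba(apply_structure_bounds(
      model, bounds * (C + sigma) / C))$objective_value
  }
  out
}

#' Flux variability at 99% of the transcript-bounded optimum
#'
#' Convenience wrapper around [fva()] at fraction 0.99 on the bounded
#' model; the resulting per-reaction ranges define the box for
#' [sample_fluxes()].
#'
#' @inheritParams apply_structure_bounds
#' @param fraction growth fraction to guarantee.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability_99 <- function(model, bounds, fraction = 0.99) {
  fva(apply_structure_bounds(model, bounds), fraction = fraction)
}

#' Sample steady-state flux distributions at near-optimal growth
#'
#' For each sample a target flux vector is drawn uniformly within the
#' per-reaction ranges at `fraction` of the optimum, and the closest
#' feasible flux vector (L1 norm) satisfying steady state, the structure
#' bounds and the growth floor is recorded. Reproducible via `seed`.
#'
#' @inheritParams apply_structure_bounds
#' @param n number of samples.
#' @param seed integer seed for the target draws.
#' @param fraction growth-floor fraction of the optimum.
#' @param ranges optionally, precomputed [flux_variability_99()] output.
#' @return a `flux_samples` list: `samples` (n x reactions matrix),
#'   `structure`, `seed`, `fraction`, `n_failed`.
#' @export
sample_fluxes <- function(model, bounds, n = 5000, seed = 1,
                          fraction = 0.99, ranges = NULL,
                          structure = NA_character_) {
  bounded <- apply_structure_bounds(model, bounds)
  sol <- fba(bounded)
  if (sol$status != "optimal") stop("transcript-bounded FBA not optimal")
  if (is.null(ranges)) ranges <- fva(bounded, fraction = fraction)
  nr <- nrow(bounded$reactions)
  stopifnot(identical(ranges$reaction, bounded$reactions$id))
  # variables: v (nr), then distance slacks t (nr);
  # rows: S v = 0, v_bio floor, v - t <= ref, -v - t <= -ref
  Tm <- as(as(bounded$S, "generalMatrix"), "TsparseMatrix")
  m0 <- nrow(bounded$S)
  bio <- match(bounded$biomass_reaction_id, bounded$reactions$id)
  ai <- c(Tm@i + 1L, m0 + 1L,
          m0 + 1L + seq_len(nr), m0 + 1L + seq_len(nr),
          m0 + 1L + nr + seq_len(nr), m0 + 1L + nr + seq_len(nr))
  aj <- c(Tm@j + 1L, bio,
          seq_len(nr), nr + seq_len(nr),
          seq_len(nr), nr + seq_len(nr))
  ax <- c(Tm@x, 1, rep(1, nr), rep(-1, nr), rep(-1, nr), rep(-1, nr))
  rlb <- c(rep(0, m0), fraction * sol$objective_value,
           rep(-Inf, 2 * nr))
  obj <- c(numeric(nr), rep(1, nr))
  clb <- c(bounded$reactions$lower_bound, numeric(nr))
  cub <- c(bounded$reactions$upper_bound, rep(Inf, nr))
  set.seed(seed)
  hi <- pmax(ranges$max, ranges$min)
  refs <- matrix(runif(n * nr, min = rep(ranges$min, each = n),
                       max = rep(hi, each = n)), nrow = n)
  samples <- matrix(NA_real_, n, nr,
                    dimnames = list(NULL, bounded$reactions$id))
  n_failed <- 0L
  for (s in seq_len(n)) {
    rub <- c(rep(0, m0), Inf, refs[s, ], -refs[s, ])
    lp <- solve_lp(obj, list(i = ai, j = aj, x = ax, nrow = m0 + 1L + 2L * nr),
                   rlb, rub, clb, cub, maximize = FALSE)
    if (lp$status == "optimal") {
      samples[s, ] <- lp$x[seq_len(nr)]
    } else {
      n_failed <- n_failed + 1L
    }
  }
  structure(list(samples = samples[!is.na(samples[, 1]), , drop = FALSE],
                 structure = structure, seed = seed, fraction = fraction,
                 n_failed = n_failed, optimum = sol$objective_value),
            class = "flux_samples")
}

#' Common-language effect size between two flux samples
#'
#' The probability that a draw from `p` exceeds a draw from `q`, counting
#' ties with weight one half:
#' \eqn{A_w = (\#(p > q) + 0.5\,\#(p = q)) / (n_1 n_2)}. Computed through
#' midranks (equivalent to the exact pair count, including ties).
#'
#' @param p,q numeric sample vectors (nonempty).
#' @return `A_w` in `[0, 1]`; `A_w(p, q) + A_w(q, p) = 1`.
#' @examples
#' effect_size_aw(c(1, 2, 3), c(2, 2, 2))  # 0.5
#' @export
effect_size_aw <- function(p, q) {
  n1 <- length(p); n2 <- length(q)
  if (n1 == 0 || n2 == 0) stop("sample vectors must be nonempty")
  r <- rank(c(p, q))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Differentially activated reactions between two flux sample sets
#'
#' Computes `A_w` per reaction between matched sample columns and calls a
#' reaction differential at a threshold `t` when
#' `max(A_w, 1 - A_w) >= t` (direction-agnostic). Calls at stricter
#' thresholds are nested within calls at looser ones by construction.
#'
#' @param samples_a,samples_b `flux_samples` objects (or sample matrices)
#'   with identical reaction columns.
#' @param thresholds effect-size thresholds.
#' @param subsystems optional named vector reaction -> subsystem for the
#'   per-subsystem tally.
#' @return list with `aw` (named per-reaction A_w of a vs b), `calls`
#'   (list of reaction id vectors per threshold) and `tally` (data.frame
#'   threshold x subsystem counts, when subsystems are given).
#' @export
differential_reactions <- function(samples_a, samples_b,
                                   thresholds = c(0.6, 0.7, 0.8),
                                   subsystems = NULL) {
  a <- if (inherits(samples_a, "flux_samples")) samples_a$samples
       else samples_a
  b <- if (inherits(samples_b, "flux_samples")) samples_b$samples
       else samples_b
  if (!identical(colnames(a), colnames(b))) {
    stop("sample sets have mismatched reaction columns")
  }
  aw <- vapply(seq_len(ncol(a)), function(j) {
    effect_size_aw(a[, j], b[, j])
  }, numeric(1))
  names(aw) <- colnames(a)
  strength <- pmax(aw, 1 - aw)
  calls <- lapply(setNames(thresholds, thresholds), function(t) {
    names(aw)[strength >= t]
  })
  tally <- NULL
  if (!is.null(subsystems)) {
    tally <- do.call(rbind, lapply(names(calls), function(t) {
      ids <- calls[[t]]
      if (length(ids) == 0) return(NULL)
      tab <- table(subsystems[ids], useNA = "ifany")
      data.frame(threshold = as.numeric(t), subsystem = names(tab),
                 n = as.integer(tab), stringsAsFactors = FALSE)
    }))
  }
  list(aw = aw, calls = calls, tally = tally)
}
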