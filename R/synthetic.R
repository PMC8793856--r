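#' Generate a small enzyme-constrained toy model with known ground truth
#'
#' Builds a compartmentalized (extracellular / cytosol / peroxisome) toy
#' network that mirrors the structural features of a fungal genome-scale
#' model relevant to enzyme-constrained analysis: four sugar uptake routes
#' feeding a hexose pool, glycolysis-like branches, respiration, amino acid
#' and protein synthesis (with an enzyme complex), carbohydrate and lipid
#' biomass components, an obligatory palmitate-like lipid uptake (growth is
#' impossible without it), a myristate-like peroxisomal beta-oxidation
#' branch, a low-flux byproduct secretion pathway, subsystem labels, and a
#' biomass reaction whose coefficient-times-molecular-weight sum equals
#' 1 g gDW^-1. GPR rules cover single genes, isozyme pairs (`or`), enzyme
#' complexes (`and`) and one promiscuous gene catalyzing two reactions.
#'
#' The flux optimum of the default configuration has a closed form (the
#' network is a tree once the ATP balance is eliminated), which is stored as
#' ground truth and verified against an independent LP solve at generation
#' time.
#'
#' @param seed integer seed controlling the randomized parameters
#'   (respiratory ATP yield, biomass ATP demand, gene molecular weights).
#' @param n_branches number of parallel glycolysis-like branches (>= 1).
#' @return a `toy_gem` list: `model` (unsplit, default medium applied),
#'   `model_split` (split-irreversible counterpart), `enz` (an
#'   [enzyme_constraint_set()] for the split model), `kcat_table` and
#'   `kcat_expected` (planted turnover-number fixture), `ground_truth`
#'   (closed-form optimum, network parameters, media), and `mw` (per-gene
#'   molecular weights).
#' @export
generate_toy_model <- function(seed = 1, n_branches = 2) {
  if (n_branches < 1) stop("toy model needs at least one pathway branch")
  set.seed(seed)
  y_resp <- sample(c(8, 10, 12), 1)     # mol ATP per acetyl unit respired
  a_E <- round(runif(1, 4, 7), 2)       # biomass ATP demand (GAM-like)
  a_P <- 0.45; a_L <- 0.25; a_C <- 0.30 # biomass mass fractions (mw = 1)

  mets <- data.frame(
    id = c("glc_e", "fru_e", "raf_e", "mel_e", "xyl_e", "palm_e", "myr_e",
           "nh4_e",
           "hex_c", "pyr_c", "accoa_c", "atp_c", "aa_c", "prot_c", "lip_c",
           "carb_c", "nh4_c", "byp_c", "palm_c", "myr_p", "accoa_p"),
    name = c("D-glucose", "D-fructose", "raffinose", "melibiose",
             "D-xylose", "palmitate", "myristate", "ammonium",
             "hexose", "pyruvate", "acetyl-CoA", "ATP", "amino acids",
             "protein", "lipid", "carbohydrate", "ammonium", "byproduct",
             "palmitate", "myristate", "acetyl-CoA"),
    compartment = c(rep("e", 8), rep("c", 11), "p", "p"),
    stringsAsFactors = FALSE)

  rxn <- function(id, stoich, lb = 0, ub = 1000, gpr = "", ec = character(0),
                  subsystem = NA_character_) {
    list(id = id, stoich = stoich, lb = lb, ub = ub, gpr = gpr, ec = ec,
         subsystem = subsystem)
  }
  hex_mult <- c(glc_e = 1, fru_e = 1, raf_e = 3, mel_e = 2)
  defs <- list(
    rxn("EX_glc", c(glc_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("EX_fru", c(fru_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("EX_raf", c(raf_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("EX_mel", c(mel_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("EX_xyl", c(xyl_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("EX_palm", c(palm_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("EX_myr", c(myr_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("EX_nh4", c(nh4_e = -1), lb = 0, subsystem = "Exchange"),
    rxn("DM_atp", c(atp_c = -1), subsystem = "Sink"),
    rxn("sink_byp", c(byp_c = -1), subsystem = "Sink"),
    rxn("T_glc", c(glc_e = -1, hex_c = 1), gpr = "tG1 or tG2",
        subsystem = "Transport"),
    rxn("T_fru", c(fru_e = -1, hex_c = 1), gpr = "tF1",
        subsystem = "Transport"),
    rxn("T_raf", c(raf_e = -1, hex_c = 3), gpr = "tR1",
        subsystem = "Transport"),
    rxn("T_mel", c(mel_e = -1, hex_c = 2), gpr = "tM1",
        subsystem = "Transport"),
    rxn("T_palm", c(palm_e = -1, palm_c = 1), gpr = "tP1",
        subsystem = "Transport"),
    rxn("T_myr", c(myr_e = -1, myr_p = 1), gpr = "tY1",
        subsystem = "Transport"),
    rxn("T_nh4", c(nh4_e = -1, nh4_c = 1), gpr = "tN1",
        subsystem = "Transport"),
    rxn("T_acc", c(accoa_p = -1, accoa_c = 1), lb = -1000, gpr = "tA1",
        subsystem = "Transport"))
  for (b in seq_len(n_branches)) {
    defs <- c(defs, list(
      rxn(paste0("GLY_", b), c(hex_c = -1, pyr_c = 2, atp_c = 2),
          gpr = paste0("gB", b), ec = "2.7.1.2",
          subsystem = "Carbohydrate metabolism")))
  }
  defs <- c(defs, list(
    rxn("PDH", c(pyr_c = -1, accoa_c = 1), gpr = "gD1 and gD2",
        ec = "1.2.4.1", subsystem = "Carbohydrate metabolism"),
    rxn("RESP", setNames(c(-1, y_resp), c("accoa_c", "atp_c")), gpr = "gE1",
        ec = "3.6.3.14", subsystem = "Energy metabolism"),
    rxn("AAS", c(pyr_c = -1, nh4_c = -1, atp_c = -1, aa_c = 1), gpr = "gA1",
        ec = "2.6.1.2", subsystem = "Amino acid metabolism"),
    rxn("PROT", c(aa_c = -2, atp_c = -4, prot_c = 1), gpr = "gS1 and gS2",
        ec = "6.3.2.4", subsystem = "Amino acid metabolism"),
    rxn("CARB", c(hex_c = -1, atp_c = -1, carb_c = 1), gpr = "gA1",
        ec = "2.4.1.1", subsystem = "Carbohydrate metabolism"),
    rxn("LIPS", c(palm_c = -1, atp_c = -1, lip_c = 1), gpr = "gL1",
        ec = "2.3.1.20", subsystem = "Lipid metabolism"),
    rxn("BOX", c(myr_p = -1, accoa_p = 7), gpr = "gP1 and gP2",
        ec = "1.3.3.6", subsystem = "Beta-oxidation"),
    rxn("BYP", c(xyl_e = -1, byp_c = 1), gpr = "gX1", ec = "4.1.2.13",
        subsystem = "Secondary metabolism"),
    rxn("BIO", setNames(-c(a_P, a_L, a_C, a_E),
                        c("prot_c", "lip_c", "carb_c", "atp_c")),
        subsystem = "Biomass")))

  ids <- vapply(defs, `[[`, character(1), "id")
  S <- matrix(0, nrow(mets), length(defs),
              dimnames = list(mets$id, ids))
  for (k in seq_along(defs)) {
    S[names(defs[[k]]$stoich), k] <- defs[[k]]$stoich
  }
  reactions <- data.frame(
    id = ids,
    lower_bound = vapply(defs, `[[`, numeric(1), "lb"),
    upper_bound = vapply(defs, `[[`, numeric(1), "ub"),
    gpr = vapply(defs, `[[`, character(1), "gpr"),
    subsystem = vapply(defs, `[[`, character(1), "subsystem"),
    stringsAsFactors = FALSE)
  reactions$ec <- lapply(defs, function(d) as.character(d$ec))

  biomass_composition <- data.frame(
    metabolite = c("prot_c", "lip_c", "carb_c"),
    class = c("protein", "lipid", "carbohydrate"),
    mw = c(1, 1, 1), stringsAsFactors = FALSE)

  model <- metabolic_model(
    id = sprintf("toygem_seed%d", seed),
    metabolites = mets, reactions = reactions, S = S,
    biomass_reaction_id = "BIO",
    compartments = c("e", "c", "p"),
    biomass_composition = biomass_composition)

  default_medium <- c(glc_e = 10, palm_e = 5, nh4_e = 1000)
  model <- apply_medium(model, default_medium)

  params <- list(y_resp = y_resp, a_E = a_E, a_P = a_P, a_L = a_L,
                 a_C = a_C, hex_mult = hex_mult, n_branches = n_branches)
  gt_growth <- toy_growth_truth(params, glc_hex_supply = 10,
                                palm_uptake = 5)
  sol <- fba(model)
  if (abs(sol$objective_value - gt_growth) > 1e-9) {
    stop("toy generator self-check failed: LP optimum ",
         sol$objective_value, " != closed form ", gt_growth)
  }

  genes <- model$genes
  mw <- setNames(round(runif(length(genes), 30, 70), 2), genes)

  kc <- generate_kcat_table(seed = seed, n_branches = n_branches)
  model_split <- split_reversible(model)
  kcat_split <- setNames(
    kc$expected$value_per_s[match(sub("_rev$", "",
                                      model_split$reactions$id),
                                  kc$expected$reaction)] * 3600,
    model_split$reactions$id)
  kcat_split <- kcat_split[!is.na(kcat_split) &
                             nzchar(model_split$reactions$gpr)]
  enz <- enzyme_constraint_set(kcat_split, mw = mw, C = 0.106)

  structure(list(
    model = model, model_split = model_split, enz = enz, mw = mw,
    kcat_table = kc$table, kcat_expected = kc$expected,
    ground_truth = list(
      growth = gt_growth,
      params = params,
      default_medium = default_medium,
      palmitate_cap = params$a_L * gt_growth,
      structure_medium = c(glc_e = 0.8, xyl_e = 1, palm_e = 0.08,
                           nh4_e = 10),
      byp_pathway = c("EX_xyl", "BYP", "sink_byp"),
      peroxisomal_genes = c("gP1", "gP2"),
      obligatory_uptake = "palm_e",
      myristate = "myr_e",
      atp_sink = "DM_atp")),
    class = "toy_gem")
}

#' Closed-form optimum of the toy network
#'
#' With the ATP sink at its lower bound and the myristate branch closed, the
#' toy network is a tree: per unit growth the biomass demands fix the amino
#' acid, carbohydrate and lipid fluxes, the ATP balance fixes respiration,
#' and the hexose balance fixes total sugar demand. Growth is then the
#' minimum of the sugar-limited and the lipid-limited rate:
#' \deqn{g = \min\left(\frac{H}{a_C + a_P + \frac{D - 2 a_P}{2 (1 + y)}},
#'       \frac{u_{palm}}{a_L}\right)}
#' with hexose supply \eqn{H}, respiratory yield \eqn{y}, and total ATP
#' demand per unit growth \eqn{D = 6 a_P + a_C + a_L + a_E}.
#'
#' @param params parameter list as stored in a `toy_gem`'s ground truth
#'   (biomass coefficients may be overridden to reflect rescaling).
#' @param glc_hex_supply hexose supply (mmol gDW^-1 h^-1).
#' @param palm_uptake palmitate-like uptake bound.
#' @return the optimal growth rate (h^-1).
#' @export
toy_growth_truth <- function(params, glc_hex_supply, palm_uptake) {
  with(params, {
    D <- 6 * a_P + a_C + a_L + a_E
    hexcoef <- a_C + a_P + (D - 2 * a_P) / (2 * (1 + y_resp))
    min(glc_hex_supply / hexcoef, palm_uptake / a_L)
  })
}

#' Generate a turnover-number table with planted matching outcomes
#'
#' The emitted table exercises every rule of the kcat assignment cascade on
#' the toy model: duplicate records for one EC (maximum selection), a
#' substrate-filter case, fungal-versus-bacterial lineage cases, a match
#' reachable only by pruning the query EC to three and to one levels, and
#' reactions with no match at any level (median fallback). The expected
#' per-reaction outcome is returned alongside the table.
#'
#' @param seed integer seed (shuffles row order; the assignment is
#'   order-independent).
#' @param n_branches number of glycolysis-like branches in the paired toy
#'   model.
#' @return list with `table` (columns `ec`, `substrate`, `lineage`,
#'   `value_per_s`) and `expected` (columns `reaction`, `value_per_s`,
#'   `provenance`), where fallback reactions carry the expected median.
#' @export
generate_kcat_table <- function(seed = 1, n_branches = 2) {
  if (n_branches < 1) stop("toy model needs at least one pathway branch")
  table <- data.frame(
    ec = c("2.7.1.2", "2.7.1.2", "1.2.4.1", "1.2.4.1", "3.6.3.14",
           "2.4.1.1", "2.4.1.1", "2.3.1.7"),
    substrate = c("hexose", "hexose", "pyruvate", "pyruvate", NA,
                  "hexose", "sucrose", NA),
    lineage = c("Fungi", "Fungi", "Fungi", "Bacteria", "Fungi",
                "Fungi", "Bacteria", "Metazoa"),
    value_per_s = c(2, 5, 3, 30, 4, 1, 20, 1.5),
    stringsAsFactors = FALSE)
  set.seed(seed)
  table <- table[sample(nrow(table)), ]
  rownames(table) <- NULL

  matched <- data.frame(
    reaction = c(paste0("GLY_", seq_len(n_branches)),
                 "PDH", "RESP", "AAS", "CARB", "LIPS", "BOX"),
    value_per_s = c(rep(5, n_branches), 3, 4, 5, 1, 1.5, 3),
    provenance = c(rep("full-match", n_branches), "full-match",
                   "full-match", "pruned-level-1", "full-match",
                   "pruned-level-3", "pruned-level-1"),
    stringsAsFactors = FALSE)
  med <- median(matched$value_per_s)
  fallback <- data.frame(
    reaction = c("PROT", "BYP", "T_glc", "T_fru", "T_raf", "T_mel",
                 "T_palm", "T_myr", "T_nh4", "T_acc", "T_acc_rev"),
    value_per_s = med,
    provenance = "median-fallback",
    stringsAsFactors = FALSE)
  list(table = table, expected = rbind(matched, fallback))
}

#' Generate a 4 x 3 carbon-source condition design with planted dry weight
#'
#' Emulates a feeding experiment with four sugars at 10, 100 and 1000 mM:
#' each condition carries Michaelis-Menten transporter kinetics for its
#' sugar, a measured total protein content, and a planted "hyphal dry
#' weight" that is a fixed strictly monotone transform of the
#' enzyme-constrained growth prediction for that condition (computed at
#' generation time), so that a correct pipeline recovers a Spearman
#' correlation of exactly 1.
#'
#' @param toy a `toy_gem` from [generate_toy_model()].
#' @param seed integer seed for kinetics and protein contents.
#' @return list with `conditions` (data.frame ready for
#'   [simulate_condition_panel()]), `base_medium` (palmitate capped at its
#'   flux at the unconstrained optimum, ammonium open), `growth` (ground
#'   truth per condition) and `dry_weight`.
#' @export
generate_condition_design <- function(toy, seed = 1) {
  set.seed(seed)
  sources <- c("glc_e", "fru_e", "raf_e", "mel_e")
  kin <- data.frame(
    carbon_source = sources,
    vmax = round(runif(4, 2, 8), 2),
    km = round(runif(4, 20, 200), 1),
    stringsAsFactors = FALSE)
  conc <- c(10, 100, 1000)
  conditions <- merge(kin, data.frame(concentration_mM = conc))
  conditions <- conditions[order(match(conditions$carbon_source, sources),
                                 conditions$concentration_mM), ]
  conditions$condition <- paste(sub("_e$", "", conditions$carbon_source),
                                conditions$concentration_mM, sep = "_")
  conditions$protein_content <- round(runif(nrow(conditions), 0.05, 0.12), 4)
  rownames(conditions) <- NULL

  base_medium <- c(nh4_e = 1000)
  base_medium["palm_e"] <- toy$ground_truth$palmitate_cap
  panel <- simulate_condition_panel(toy$model_split, toy$enz, conditions,
                                    base_medium)
  growth <- panel$growth_emoment
  list(conditions = conditions,
       base_medium = base_medium,
       growth = growth,
       dry_weight = 2 * growth^0.8)
}

#' Generate three-structure transcript profiles with planted differences
#'
#' Emits averaged transcript counts for three developmental structures
#' (labelled ERM, IRM and ARB). Baseline counts are chosen so that under the
#' toy's structure-experiment medium every enzymatic reaction's
#' transcript-derived bound is comfortably above its operating flux --
#' except for the planted reactions, whose genes receive low counts so that
#' their bound limits their flux. The IRM and ARB profiles multiply the
#' planted genes by `sqrt(fold)` and `fold`; multiplicative lognormal noise
#' (sd `noise_sd`) is applied per structure.
#'
#' @param toy a `toy_gem`.
#' @param seed integer seed.
#' @param planted reaction ids whose bounds are planted low and raised
#'   across structures.
#' @param fold multiplier on the planted genes in the ARB profile (> 1, or
#'   1 for a null experiment).
#' @param noise_sd lognormal noise standard deviation.
#' @param planted_cap target flux capacity of the planted reactions in the
#'   baseline (ERM) profile, before noise.
#' @return list with `counts` (named list ERM/IRM/ARB of per-gene count
#'   vectors) and `ground_truth` (planted reaction ids, planted genes,
#'   fold).
#' @export
generate_structure_transcripts <- function(toy, seed = 1, planted = "BYP",
                                           fold = 10, noise_sd = 0.1,
                                           planted_cap = 0.03) {
  model <- toy$model_split
  unknown <- setdiff(planted, model$reactions$id)
  if (length(unknown)) {
    stop("planted reaction(s) not in toy model: ",
         paste(unknown, collapse = ", "))
  }
  if (fold < 1) stop("fold must be >= 1")
  genes <- model$genes
  kcat <- toy$enz$kcat
  # slowest turnover among each gene's reactions, h^-1
  gene_kcat <- vapply(genes, function(g) {
    rids <- model$reactions$id[vapply(model$gprs, function(e) {
      !is.null(e) && g %in% gpr_genes(e)
    }, logical(1))]
    min(kcat[intersect(rids, names(kcat))])
  }, numeric(1))
  planted_genes <- unique(unlist(lapply(model$gprs[planted], gpr_genes)))
  cap <- setNames(rep(1, length(genes)), genes)
  cap[c("tG1", "tG2")] <- 2          # carbon uptake must never throttle
  cap[planted_genes] <- planted_cap
  base <- 1e4 * toy$mw[genes] * cap / gene_kcat

  set.seed(seed)
  factor_by_structure <- c(ERM = 1, IRM = sqrt(fold), ARB = fold)
  counts <- lapply(factor_by_structure, function(f) {
    x <- base
    x[planted_genes] <- x[planted_genes] * f
    x * rlnorm(length(x), meanlog = 0, sdlog = noise_sd)
  })
  list(counts = counts,
       ground_truth = list(planted = planted, planted_genes = planted_genes,
                           fold = fold))
}

#' Run the full three-structure comparison on a toy model
#'
#' End-to-end driver: applies the toy's structure-experiment medium (lipid
#' uptake limiting, ATP sink closed so that the network is rigid up to the
#' planted degrees of freedom), converts each structure's transcript counts
#' to protein equivalents at the fixed protein content `C`, derives
#' transcript reaction bounds, predicts growth, computes 99%-optimum flux
#' variability, samples flux distributions, recombines them to net fluxes
#' on the original reactions, and calls differentially activated reactions
#' per structure pair via the common-language effect size.
#'
#' @param toy a `toy_gem`.
#' @param transcripts output of [generate_structure_transcripts()] (or a
#'   compatible named list of count vectors under `$counts`).
#' @param n flux samples per structure.
#' @param seed integer seed (one derived seed per structure).
#' @param C total protein content for all structures (g gDW^-1).
#' @param thresholds effect-size thresholds for differential calls.
#' @return list with `growth` (per structure), `samples` (per structure,
#'   net-flux matrices), `pairs` (per structure pair:
#'   [differential_reactions()] output) and `subsystems` lookup.
#' @export
run_structure_experiment <- function(toy, transcripts, n = 500, seed = 1,
                                     C = 0.106,
                                     thresholds = c(0.6, 0.7, 0.8)) {
  model <- apply_medium(toy$model_split, toy$ground_truth$structure_medium)
  model <- set_bounds(model, toy$ground_truth$atp_sink, upper = 0)
  model <- rescale_biomass(model, C)
  structures <- names(transcripts$counts)
  growth <- setNames(numeric(length(structures)), structures)
  samples <- list()
  for (k in seq_along(structures)) {
    st <- structures[k]
    profile <- transcript_to_protein(transcripts$counts[[st]], C = C,
                                     mw = toy$mw, structure = st)
    bounds <- transcript_reaction_bounds(model, profile, toy$enz$kcat)
    growth[st] <- structure_growth(model, bounds)$growth
    fs <- sample_fluxes(model, bounds, n = n, seed = seed * 1000 + k,
                        structure = st)
    bounded <- apply_structure_bounds(model, bounds)
    net <- t(apply(fs$samples, 1, function(v) {
      merge_irreversible_fluxes(bounded, v)
    }))
    samples[[st]] <- net
  }
  pair_names <- utils::combn(structures, 2, paste, collapse = "_vs_")
  pair_idx <- utils::combn(length(structures), 2)
  subsystems <- setNames(toy$model$reactions$subsystem,
                         toy$model$reactions$id)
  pairs <- lapply(seq_along(pair_names), function(p) {
    differential_reactions(samples[[pair_idx[1, p]]],
                           samples[[pair_idx[2, p]]],
                           thresholds = thresholds,
                           subsystems = subsystems)
  })
  names(pairs) <- pair_names
  list(growth = growth, samples = samples, pairs = pairs,
       subsystems = subsystems)
}

#' Generate a random linear-pathway toy for MILP cross-checks
#'
#' A short random chain (uptake, a few enzymatic conversions, biomass-like
#' sink) with random GPR patterns (single genes, isozymes, complexes, gene
#' reuse across reactions), random turnover numbers, molecular weights, a
#' tight protein budget and a non-negligible minimum expression level
#' `alpha`, so that the binary expression indicators genuinely matter.
#' Intended for comparing [solve_emoment()] against [emoment_enumerate()].
#'
#' @param seed integer seed.
#' @param n_genes size of the gene pool (<= 8 keeps enumeration cheap).
#' @param n_steps number of enzymatic chain steps.
#' @return list with `problem` (an `emoment_problem`) and the generating
#'   `model` and `enz`.
#' @export
random_enzyme_toy <- function(seed = 1, n_genes = 6, n_steps = 4) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  mets <- data.frame(
    id = c("s_e", paste0("m", seq_len(n_steps), "_c")),
    compartment = c("e", rep("c", n_steps)),
    stringsAsFactors = FALSE)
  random_gpr <- function() {
    pat <- sample(c("single", "or", "and", "mixed"), 1)
    g <- sample(genes, min(n_genes, 3))
    switch(pat,
           single = g[1],
           or = paste(g[1:2], collapse = " or "),
           and = paste(g[1:2], collapse = " and "),
           mixed = sprintf("(%s or %s) and %s", g[1], g[2], g[3]))
  }
  ids <- c("EX_s", "T_s",
           if (n_steps > 1) paste0("R", seq_len(n_steps - 1)), "BIO")
  stoich <- list(c(s_e = -1),
                 c(s_e = -1, m1_c = 1))
  if (n_steps > 1) {
    for (k in seq_len(n_steps - 1)) {
      stoich <- c(stoich, list(setNames(
        c(-1, 1), paste0("m", c(k, k + 1), "_c"))))
    }
  }
  stoich <- c(stoich, list(setNames(-1, paste0("m", n_steps, "_c"))))
  S <- matrix(0, nrow(mets), length(ids), dimnames = list(mets$id, ids))
  for (k in seq_along(ids)) S[names(stoich[[k]]), k] <- stoich[[k]]
  reactions <- data.frame(
    id = ids,
    lower_bound = 0,
    upper_bound = 1000,
    gpr = c("", vapply(seq_len(n_steps), function(k) random_gpr(),
                       character(1)), ""),
    stringsAsFactors = FALSE)
  model <- metabolic_model(
    id = sprintf("randtoy_seed%d", seed),
    metabolites = mets, reactions = reactions, S = S,
    biomass_reaction_id = "BIO", compartments = c("e", "c"))
  model <- apply_medium(model, c(s_e = round(runif(1, 5, 15), 2)))
  model <- split_reversible(model)
  enzymatic <- model$reactions$id[nzchar(model$reactions$gpr)]
  kcat <- setNames(round(runif(length(enzymatic), 0.5, 5), 3) * 3600,
                   enzymatic)
  mw <- setNames(round(runif(n_genes, 20, 80), 1), genes)
  enz <- enzyme_constraint_set(
    kcat, mw = mw, C = round(runif(1, 0.02, 0.08), 4),
    alpha = round(runif(1, 1e-5, 1e-4), 7))
  list(problem = build_emoment(model, enz), model = model, enz = enz)
}
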