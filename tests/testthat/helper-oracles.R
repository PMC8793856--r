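# Independent oracles and fixture builders shared across test files.

# Brute-force GPR evaluation by direct structural recursion, written
# independently of evaluate_gpr (no shared helpers).
brute_gpr <- function(expr, values, mode) {
  if (expr$op == "gene") return(values[[expr$gene]])
  vals <- sapply(expr$args, brute_gpr, values = values, mode = mode)
  if (expr$op == "and") min(vals)
  else if (mode == "enzyme") sum(vals) else max(vals)
}

# Random GPR tree with at most `max_leaves` leaves.
random_gpr_tree <- function(genes, max_leaves = 8) {
  build <- function(n) {
    if (n == 1) {
      return(structure(list(op = "gene", gene = sample(genes, 1)),
                       class = "gpr_expr"))
    }
    split <- sample(seq_len(n - 1), 1)
    structure(list(op = sample(c("and", "or"), 1),
                   args = list(build(split), build(n - split))),
              class = "gpr_expr")
  }
  build(sample(seq_len(max_leaves), 1))
}

# O(n1*n2) pair-counting effect size, the definitional form.
brute_aw <- function(p, q) {
  wins <- 0
  for (x in p) for (y in q) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(p) * length(q))
}

# Linear chain: EX_a (uptake <= uptake_max) -> T -> M1 -> ... -> biomass
# with `yield` biomass per substrate unit. FBA optimum = uptake_max * yield.
chain_model <- function(uptake_max = 10, yield = 0.5, n_steps = 2,
                        reversible_step = FALSE) {
  mets <- data.frame(
    id = c("a_e", paste0("m", seq_len(n_steps), "_c")),
    compartment = c("e", rep("c", n_steps)), stringsAsFactors = FALSE)
  ids <- c("EX_a", paste0("R", seq_len(n_steps)), "BIO")
  S <- matrix(0, nrow(mets), length(ids), dimnames = list(mets$id, ids))
  S["a_e", "EX_a"] <- -1
  S["a_e", "R1"] <- -1; S["m1_c", "R1"] <- 1
  if (n_steps > 1) {
    for (k in 2:n_steps) {
      S[paste0("m", k - 1, "_c"), paste0("R", k)] <- -1
      S[paste0("m", k, "_c"), paste0("R", k)] <- 1
    }
  }
  S[paste0("m", n_steps, "_c"), "BIO"] <- -1 / yield
  reactions <- data.frame(
    id = ids, lower_bound = c(-uptake_max, rep(0, n_steps), 0),
    upper_bound = 1000, stringsAsFactors = FALSE)
  if (reversible_step && n_steps > 1) reactions$lower_bound[3] <- -1000
  metabolic_model("chain", mets, reactions, S,
                  biomass_reaction_id = "BIO", compartments = c("e", "c"))
}

# Growth path s -> A -> B -> biomass plus an internal triangle
# A -> B (L1), B -> C (L2), A <-> C (L3, reversible): running L3 in reverse
# (C -> A) closes a stoichiometrically balanced cycle; making L3
# irreversible (forward only) removes it.
loop_model <- function(loop_reversible = TRUE) {
  mets <- data.frame(
    id = c("s_e", "A_c", "B_c", "C_c"),
    compartment = c("e", "c", "c", "c"), stringsAsFactors = FALSE)
  ids <- c("EX_s", "T1", "L1", "L2", "L3", "BIO")
  S <- matrix(0, nrow(mets), length(ids), dimnames = list(mets$id, ids))
  S["s_e", "EX_s"] <- -1
  S["s_e", "T1"] <- -1; S["A_c", "T1"] <- 1
  S["A_c", "L1"] <- -1; S["B_c", "L1"] <- 1
  S["B_c", "L2"] <- -1; S["C_c", "L2"] <- 1
  S["A_c", "L3"] <- -1; S["C_c", "L3"] <- 1
  S["B_c", "BIO"] <- -1
  reactions <- data.frame(
    id = ids,
    lower_bound = c(-10, 0, 0, 0, if (loop_reversible) -1000 else 0, 0),
    upper_bound = 1000, stringsAsFactors = FALSE)
  metabolic_model("loop", mets, reactions, S,
                  biomass_reaction_id = "BIO", compartments = c("e", "c"))
}

expect_fluxes_feasible <- function(model, fluxes, tol = 1e-6) {
  expect_lte(max(abs(as.numeric(model$S %*% fluxes))), tol)
  expect_true(all(fluxes >= model$reactions$lower_bound - tol))
  expect_true(all(fluxes <= model$reactions$upper_bound + tol))
}
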