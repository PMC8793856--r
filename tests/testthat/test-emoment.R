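# minimal enzyme-constrained chain: one enzymatic step, one gene
one_enzyme_problem <- function(kcat = 3600, mw = 1, C = 0.001) {
  m <- chain_model(uptake_max = 1000, yield = 1, n_steps = 1)
  m$reactions$gpr <- c("", "g1", "")
  m <- metabolic_model("one", m$metabolites, m$reactions, m$S,
                       biomass_reaction_id = "BIO",
                       compartments = c("e", "c"))
  m <- split_reversible(m)
  enz <- enzyme_constraint_set(c(R1 = kcat), mw = c(g1 = mw), C = C)
  build_emoment(m, enz)
}

test_that("transporter uptake bounds follow saturation kinetics", {
  expect_equal(uptake_bound(10, 5, 5), 5)           # half saturation
  expect_equal(uptake_bound(10, 5, 0), 0)
  expect_equal(uptake_bound(10, 5, 10), 20 / 3)
  expect_error(uptake_bound(10, 5, -1), "nonnegative")
  expect_error(uptake_bound(-1, 5, 1))
})

test_that("biomass rescaling fixes the protein fraction and conserves mass", {
  toy <- generate_toy_model(seed = 1)
  m <- rescale_biomass(toy$model, 0.2)
  j <- match("BIO", m$reactions$id)
  coef <- -m$S[c("prot_c", "lip_c", "carb_c"), j]
  expect_equal(unname(coef[1]), 0.2, tolerance = 1e-12)
  expect_equal(unname(coef[2]), 0.25 * 0.8 / 0.55, tolerance = 1e-12)
  expect_equal(unname(coef[3]), 0.30 * 0.8 / 0.55, tolerance = 1e-12)
  expect_equal(sum(coef), 1, tolerance = 1e-9)  # all mw = 1

  # rescaling to the current protein fraction is the identity
  m2 <- rescale_biomass(toy$model, 0.45)
  expect_equal(as.matrix(m2$S), as.matrix(toy$model$S), tolerance = 1e-12)
  expect_error(rescale_biomass(toy$model, 1.2), "in \\(0, 1\\)")
  expect_error(rescale_biomass(toy$model, 0), "in \\(0, 1\\)")
})

test_that("a single enzymatic step has the closed-form enzyme-limited optimum", {
  p <- one_enzyme_problem(kcat = 3600, mw = 1, C = 0.001)
  sol <- solve_emoment(p)
  expect_equal(sol$growth, 3.6, tolerance = 1e-8)
  # growth scales linearly with the protein budget when crowding binds
  expect_equal(solve_emoment(one_enzyme_problem(C = 0.002))$growth,
               7.2, tolerance = 1e-8)
})

test_that("generous protein budgets recover the plain FBA optimum", {
  toy <- generate_toy_model(seed = 2)
  enz <- toy$enz
  enz$C <- 100
  p <- build_emoment(toy$model_split, enz)
  expect_equal(solve_emoment(p)$growth, fba(toy$model)$objective_value,
               tolerance = 1e-6)
})

test_that("a zero protein budget stops growth", {
  toy <- generate_toy_model(seed = 1)
  enz <- toy$enz
  enz$C <- 0
  p <- build_emoment(toy$model_split, enz)
  expect_equal(solve_emoment(p)$growth, 0, tolerance = 1e-9)
})

test_that("missing molecular weights are reported at build time", {
  toy <- generate_toy_model(seed = 1)
  enz <- toy$enz
  enz$mw <- enz$mw[setdiff(names(enz$mw), c("gA1", "gE1"))]
  expect_error(build_emoment(toy$model_split, enz), "gA1.*gE1|gA1, gE1")
})

test_that("promiscuous genes split their abundance across reactions", {
  toy <- generate_toy_model(seed = 1)
  p <- build_emoment(toy$model_split, toy$enz)
  sol <- solve_emoment(p)
  # gA1 catalyzes both AAS and CARB; the enzyme demand implied by the two
  # fluxes can never exceed the gene's total abundance
  demand <- sol$fluxes[["AAS"]] / toy$enz$kcat[["AAS"]] +
    sol$fluxes[["CARB"]] / toy$enz$kcat[["CARB"]]
  expect_lte(demand, sol$gene_abundance[["gA1"]] + 1e-6)
})

test_that("forcing a gene off removes its enzyme-supported flux", {
  rt <- random_enzyme_toy(seed = 3)
  p <- rt$problem
  sol <- solve_emoment(p)
  on <- names(which(sol$y == 1))
  g <- on[1]
  clb <- p$clb; cub <- p$cub
  cub[p$y_idx[[g]]] <- 0
  obj <- numeric(p$nvar)
  obj[p$v_idx[[p$model$biomass_reaction_id]]] <- 1
  lp <- ecgem:::emoment_lp(p, obj, maximize = TRUE, clb = clb, cub = cub)
  if (lp$status == "optimal") {
    expect_equal(lp$x[p$Eg_idx[[g]]], 0, tolerance = 1e-9)
    expect_lte(lp$objective, sol$growth + 1e-9)
  } else {
    expect_equal(lp$status, "infeasible")
  }
})

test_that("the MILP matches exhaustive indicator enumeration", {
  for (seed in 1:6) {
    rt <- random_enzyme_toy(seed = seed)
    expect_equal(solve_emoment(rt$problem)$growth,
                 emoment_enumerate(rt$problem)$growth,
                 tolerance = 1e-6)
  }
})

test_that("eMOMENT growth never exceeds FBA growth and rises with C", {
  toy <- generate_toy_model(seed = 3)
  fba_growth <- fba(toy$model)$objective_value
  prev <- -Inf
  for (C in c(0.02, 0.05, 0.1, 0.3)) {
    enz <- toy$enz
    enz$C <- C
    g <- solve_emoment(build_emoment(toy$model_split, enz))$growth
    expect_lte(g, fba_growth + 1e-6)
    expect_gte(g, prev - 1e-8)
    prev <- g
  }
})

test_that("abundance variability collapses for an essential enzyme at the optimum", {
  p <- one_enzyme_problem()
  av <- abundance_variability(p, fraction = 1)
  expect_equal(av$min, av$max, tolerance = 1e-8)
  expect_equal(av$max, 0.001, tolerance = 1e-8)
  # relaxing the growth floor widens (or preserves) every interval
  av99 <- abundance_variability(p, fraction = 0.99)
  expect_true(all(av99$min <= av$min + 1e-9))
  expect_true(all(av99$max >= av$max - 1e-9))
})

test_that("abundance samples are feasible, seeded, and respect degenerate ranges", {
  p <- one_enzyme_problem()
  s <- sample_abundances(p, n = 10, fraction = 1, seed = 42)
  expect_equal(s$n_failed, 0)
  expect_true(all(abs(s$samples - 0.001) < 1e-7))  # point range

  toy <- generate_toy_model(seed = 1)
  tp <- build_emoment(toy$model_split, toy$enz)
  av <- abundance_variability(tp)
  s1 <- sample_abundances(tp, n = 25, seed = 7, ranges = av)
  s2 <- sample_abundances(tp, n = 25, seed = 7, ranges = av)
  expect_identical(s1$samples, s2$samples)
  crowd <- as.numeric(s1$samples %*% toy$enz$mw[colnames(s1$samples)])
  expect_true(all(crowd <= toy$enz$C + 1e-6))
  expect_true(all(s1$samples >= -1e-9))
})

test_that("condition growth is nondecreasing in substrate concentration", {
  toy <- generate_toy_model(seed = 1)
  conds <- data.frame(
    condition = paste0("glc_", c(10, 100, 1000)),
    carbon_source = "glc_e", concentration_mM = c(10, 100, 1000),
    vmax = 4, km = 80, protein_content = 0.09,
    stringsAsFactors = FALSE)
  bm <- c(nh4_e = 1000, palm_e = toy$ground_truth$palmitate_cap)
  panel <- simulate_condition_panel(toy$model_split, toy$enz, conds, bm)
  expect_true(all(diff(panel$uptake_bound) > 0))
  expect_true(all(diff(panel$growth_emoment) > -1e-8))
  expect_true(all(panel$growth_emoment <= panel$growth_fba + 1e-6))
})

test_that("uncapping the lipid source never decreases predicted growth", {
  toy <- generate_toy_model(seed = 1)
  conds <- data.frame(condition = "mel_1000", carbon_source = "mel_e",
                      concentration_mM = 1000, vmax = 6, km = 50,
                      protein_content = 0.1, stringsAsFactors = FALSE)
  capped <- simulate_condition_panel(
    toy$model_split, toy$enz, conds,
    c(nh4_e = 1000, palm_e = toy$ground_truth$palmitate_cap))
  open <- simulate_condition_panel(
    toy$model_split, toy$enz, conds, c(nh4_e = 1000, palm_e = 1000))
  expect_gte(open$growth_emoment, capped$growth_emoment - 1e-8)
})

test_that("splitting the protein pool reveals the beta-oxidation benefit", {
  toy <- generate_toy_model(seed = 1)
  m <- apply_medium(toy$model_split,
                    c(glc_e = 2, palm_e = toy$ground_truth$palmitate_cap,
                      nh4_e = 1000))
  ps <- protein_pool_split(m, toy$enz, toy$ground_truth$peroxisomal_genes,
                           alpha_grid = c(0, 0.1, 0.3, 0.5),
                           myristate = "myr_e")
  # no peroxisomal budget -> myristate cannot help
  expect_equal(ps$Z[ps$alpha_pool == 0], 1, tolerance = 1e-8)
  # the planted beta-oxidation branch pays off for some pool ratio
  expect_gt(max(ps$Z), 1)
  # growth without myristate is weakly decreasing in the diverted share
  expect_true(all(diff(ps$growth_without) < 1e-8))
  expect_error(protein_pool_split(m, toy$enz, character(0),
                                  myristate = "myr_e"), "nonempty")
})

test_that("plasticity CV follows the sample-sd convention and is scale-free", {
  a <- matrix(1, 5, 2, dimnames = list(NULL, c("x", "y")))
  b <- matrix(3, 5, 2, dimnames = list(NULL, c("x", "y")))
  cv <- plasticity_cv(list(c1 = a, c2 = b))
  expect_equal(unname(cv["x"]), sd(c(1, 3)) / 2)
  expect_equal(plasticity_cv(list(c1 = 2 * a, c2 = 2 * b)), cv)
  expect_equal(unname(plasticity_cv(list(c1 = a, c2 = a))["x"]), 0)
  zero <- matrix(0, 5, 2, dimnames = list(NULL, c("x", "y")))
  expect_true(all(is.na(plasticity_cv(list(c1 = zero, c2 = zero)))))
  expect_error(plasticity_cv(list(c1 = a)), "at least two")
})
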