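test_that("transcript normalization identities hold", {
  counts <- c(a = 2, b = 3, c = 5)
  mw <- c(a = 1, b = 1, c = 1)
  pr <- transcript_to_protein(counts, C = 0.1, mw = mw)
  expect_equal(sum(pr$normalized), 1, tolerance = 1e-12)
  expect_equal(unname(pr$protein), c(0.02, 0.03, 0.05), tolerance = 1e-12)

  # single gene: everything collapses to C / MW
  pr1 <- transcript_to_protein(c(g = 7), C = 0.2, mw = c(g = 4))
  expect_equal(unname(pr1$normalized), 1)
  expect_equal(unname(pr1$protein), 0.05)

  # sum(tc^p * MW) = C for arbitrary profiles
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:20, 1)
    cts <- setNames(runif(n, 0, 1000), paste0("g", 1:n))
    mws <- setNames(runif(n, 10, 90), names(cts))
    p <- transcript_to_protein(cts, C = 0.106, mw = mws)
    expect_equal(sum(p$protein * mws), 0.106, tolerance = 1e-9)
  }
  expect_error(transcript_to_protein(c(a = 0), 0.1, c(a = 1)), "positive")
  expect_error(transcript_to_protein(c(z = 1), 0.1, c(a = 1)),
               "molecular weights.*z")
})

test_that("transcript reaction bounds follow the min/max GPR rules", {
  toy <- generate_toy_model(seed = 1)
  counts <- setNames(rep(100, length(toy$model$genes)), toy$model$genes)
  # engineered protein equivalents: complex takes the minimum
  prof <- list(protein = setNames(rep(0.05, length(toy$model$genes)),
                                  toy$model$genes))
  prof$protein[c("gD1", "gD2")] <- c(0.01, 0.02)
  prof$protein[c("tG1", "tG2")] <- c(0, 0.03)
  class(prof) <- "transcript_profile"
  b <- transcript_reaction_bounds(toy$model_split, prof, toy$enz$kcat)
  expect_equal(unname(b[["PDH"]]), toy$enz$kcat[["PDH"]] * 0.01)
  # isozymes take the maximum; a zero isozyme is ignored
  expect_equal(unname(b[["T_glc"]]), toy$enz$kcat[["T_glc"]] * 0.03)
  # reactions without GPR are not bounded
  expect_false(any(c("BIO", "EX_glc", "DM_atp") %in% names(b)))

  # AND(A,B): tc^p 0.01/0.02 at kcat 100 -> bound 1.0
  expect_equal(100 * min(0.01, 0.02), 1)
})

test_that("zero transcripts close all enzymatic reactions", {
  toy <- generate_toy_model(seed = 1)
  prof <- list(protein = setNames(rep(0, length(toy$model$genes)),
                                  toy$model$genes))
  class(prof) <- "transcript_profile"
  b <- transcript_reaction_bounds(toy$model_split, prof, toy$enz$kcat)
  expect_true(all(b == 0))
  g <- structure_growth(toy$model_split, b)
  expect_equal(g$growth, 0, tolerance = 1e-9)
})

test_that("relaxing transcript bounds never decreases growth", {
  toy <- generate_toy_model(seed = 1)
  tr <- generate_structure_transcripts(toy, seed = 1)
  model <- apply_medium(toy$model_split, toy$ground_truth$structure_medium)
  prof <- transcript_to_protein(tr$counts$ERM, C = 0.106, mw = toy$mw)
  b <- transcript_reaction_bounds(model, prof, toy$enz$kcat)
  g1 <- structure_growth(model, b)$growth
  g2 <- structure_growth(model, b * 2)$growth
  expect_gte(g2, g1 - 1e-9)

  # error bars: growth at C - sigma <= growth at C <= growth at C + sigma
  g3 <- structure_growth(model, b, C = 0.106, sigma = 0.01)
  expect_lte(g3$growth_low, g3$growth + 1e-9)
  expect_gte(g3$growth_high, g3$growth - 1e-9)
})

test_that("a boosted growth-pathway profile grows strictly faster", {
  toy <- generate_toy_model(seed = 1)
  tr <- generate_structure_transcripts(toy, seed = 2, planted = "T_palm",
                                       fold = 10)
  ex <- run_structure_experiment(toy, tr, n = 5, seed = 2)
  expect_lt(ex$growth[["ERM"]], ex$growth[["ARB"]] - 1e-6)
})

test_that("flux samples are feasible, bounded and seed-reproducible", {
  toy <- generate_toy_model(seed = 1)
  tr <- generate_structure_transcripts(toy, seed = 1)
  model <- apply_medium(toy$model_split, toy$ground_truth$structure_medium)
  model <- set_bounds(model, "DM_atp", upper = 0)
  prof <- transcript_to_protein(tr$counts$ERM, C = 0.106, mw = toy$mw)
  b <- transcript_reaction_bounds(model, prof, toy$enz$kcat)
  bounded <- apply_structure_bounds(model, b)
  rng <- flux_variability_99(model, b)
  fs <- sample_fluxes(model, b, n = 30, seed = 9, ranges = rng)
  expect_equal(fs$n_failed, 0)
  for (k in seq_len(nrow(fs$samples))) {
    expect_fluxes_feasible(bounded, fs$samples[k, ])
  }
  # growth floor respected
  expect_true(all(fs$samples[, "BIO"] >= 0.99 * fs$optimum - 1e-6))
  fs2 <- sample_fluxes(model, b, n = 30, seed = 9, ranges = rng)
  expect_identical(fs$samples, fs2$samples)
})

test_that("the effect size matches its definitional pair count", {
  expect_equal(effect_size_aw(c(3, 4), c(1, 2)), 1)
  expect_equal(effect_size_aw(c(1, 1), c(1, 1)), 0.5)
  expect_equal(effect_size_aw(c(1, 2, 3), c(2, 2, 2)), 0.5)
  expect_error(effect_size_aw(numeric(0), 1), "nonempty")

  set.seed(13)
  for (i in 1:100) {
    n1 <- sample(1:200, 1); n2 <- sample(1:200, 1)
    # ties are likely: draw from a small integer support
    p <- sample(1:10, n1, replace = TRUE)
    q <- sample(1:10, n2, replace = TRUE)
    aw <- effect_size_aw(p, q)
    expect_identical(aw, brute_aw(p, q))
    expect_equal(aw + effect_size_aw(q, p), 1, tolerance = 1e-12)
    expect_gte(aw, 0); expect_lte(aw, 1)
  }
})

test_that("differential calls are direction-agnostic and nested across thresholds", {
  set.seed(21)
  a <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  b <- a
  b[, 2] <- b[, 2] + 5  # clear location shift
  d <- differential_reactions(a, b, thresholds = c(0.6, 0.7, 0.8),
                              subsystems = c(r1 = "s1", r2 = "s2",
                                             r3 = "s1"))
  expect_true("r2" %in% d$calls[["0.8"]])
  expect_true(all(d$calls[["0.8"]] %in% d$calls[["0.7"]]))
  expect_true(all(d$calls[["0.7"]] %in% d$calls[["0.6"]]))
  expect_equal(d$tally$subsystem[d$tally$threshold == 0.8], "s2")

  # identical sample sets are never called
  d0 <- differential_reactions(a, a)
  expect_length(unlist(d0$calls), 0)
  bad <- a; colnames(bad) <- c("x", "y", "z")
  expect_error(differential_reactions(a, bad), "mismatched")
})
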