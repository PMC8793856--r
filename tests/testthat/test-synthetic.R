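test_that("the toy generator's closed-form optimum matches the LP", {
  for (seed in c(1, 7, 23)) {
    toy <- generate_toy_model(seed = seed)
    expect_equal(fba(toy$model)$objective_value, toy$ground_truth$growth,
                 tolerance = 1e-9)
    expect_equal(fba(toy$model_split)$objective_value,
                 toy$ground_truth$growth, tolerance = 1e-9)
  }
  expect_error(generate_toy_model(n_branches = 0), "at least one")
})

test_that("the planted lipid dependency is obligatory", {
  toy <- generate_toy_model(seed = 1)
  no_lipid <- apply_medium(toy$model, c(glc_e = 10, nh4_e = 1000))
  expect_equal(fba(no_lipid)$objective_value, 0, tolerance = 1e-9)
  # even with every sugar wide open
  all_sugars <- apply_medium(toy$model,
                             c(glc_e = 100, fru_e = 100, raf_e = 100,
                               mel_e = 100, nh4_e = 1000))
  expect_equal(fba(all_sugars)$objective_value, 0, tolerance = 1e-9)
})

test_that("the toy model exercises every GPR pattern and compartment", {
  toy <- generate_toy_model(seed = 1)
  gprs <- toy$model$reactions$gpr
  expect_true(any(grepl(" or ", gprs)))    # isozymes
  expect_true(any(grepl(" and ", gprs)))   # complex
  # promiscuous gene: gA1 appears in more than one reaction rule
  expect_gte(sum(grepl("\\bgA1\\b", gprs)), 2)
  expect_setequal(toy$model$compartments, c("e", "c", "p"))
  expect_true("p" %in%
                toy$model$metabolites$compartment[
                  toy$model$metabolites$id == "accoa_p"])
  # biomass composition mass sum is 1 g/gDW
  comp <- toy$model$biomass_composition
  j <- match("BIO", toy$model$reactions$id)
  expect_equal(sum(abs(toy$model$S[comp$metabolite, j]) * comp$mw), 1,
               tolerance = 1e-12)
})

test_that("identical seeds yield byte-identical artifacts", {
  t1 <- generate_toy_model(seed = 5)
  t2 <- generate_toy_model(seed = 5)
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  write_sbml(t1$model, f1); write_sbml(t2$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t1$enz, t2$enz)
  expect_identical(generate_kcat_table(seed = 5),
                   generate_kcat_table(seed = 5))
  toy <- t1
  tr1 <- generate_structure_transcripts(toy, seed = 2)
  tr2 <- generate_structure_transcripts(toy, seed = 2)
  expect_identical(tr1, tr2)
})

test_that("the kcat fixture reproduces its planted assignment end to end", {
  toy <- generate_toy_model(seed = 2)
  ka <- assign_kcats(toy$model_split, toy$kcat_table)
  exp <- toy$kcat_expected
  merged <- merge(ka, exp, by = "reaction")
  expect_equal(nrow(merged), nrow(exp))
  expect_equal(merged$kcat_per_h, merged$value_per_s * 3600)
  expect_identical(merged$provenance.x, merged$provenance.y)
  expect_error(generate_kcat_table(n_branches = 0), "at least one")
})

test_that("condition designs plant a monotone dry-weight relation", {
  toy <- generate_toy_model(seed = 1)
  cd <- generate_condition_design(toy, seed = 2)
  expect_equal(nrow(cd$conditions), 12)
  expect_true(all(cd$conditions$protein_content > 0 &
                    cd$conditions$protein_content < 1))
  # uptake bounds strictly increase with concentration for each source
  for (src in unique(cd$conditions$carbon_source)) {
    rows <- cd$conditions[cd$conditions$carbon_source == src, ]
    ub <- uptake_bound(rows$vmax[1], rows$km[1], rows$concentration_mM)
    expect_true(all(diff(ub) > 0))
  }
  # dry weight is a strictly monotone transform of the planted growth
  expect_equal(order(cd$dry_weight), order(cd$growth))
  # and the pipeline recovers it with perfect rank correlation
  panel <- simulate_condition_panel(toy$model_split, toy$enz,
                                    cd$conditions, cd$base_medium)
  expect_equal(suppressWarnings(
    cor(panel$growth_emoment, cd$dry_weight, method = "spearman")), 1)
})

test_that("structure transcripts normalize and carry planted truth", {
  toy <- generate_toy_model(seed = 1)
  tr <- generate_structure_transcripts(toy, seed = 1, fold = 10)
  expect_named(tr$counts, c("ERM", "IRM", "ARB"))
  for (st in names(tr$counts)) {
    pr <- transcript_to_protein(tr$counts[[st]], C = 0.106, mw = toy$mw)
    expect_equal(sum(pr$normalized), 1, tolerance = 1e-9)
  }
  expect_equal(tr$ground_truth$planted, "BYP")
  expect_equal(tr$ground_truth$planted_genes, "gX1")
  expect_error(generate_structure_transcripts(toy, planted = "NOPE"),
               "NOPE")
  expect_error(generate_structure_transcripts(toy, fold = 0.5), "fold")
})

test_that("a null transcript experiment yields no differential calls", {
  toy <- generate_toy_model(seed = 1)
  tr <- generate_structure_transcripts(toy, seed = 4, fold = 1)
  ex <- run_structure_experiment(toy, tr, n = 150, seed = 4)
  expect_length(unlist(lapply(ex$pairs, function(p) p$calls[["0.6"]])), 0)
  # growth identical across structures (bounds differ only by noise on
  # reactions with ample slack)
  expect_equal(unname(ex$growth[["ERM"]]), unname(ex$growth[["ARB"]]),
               tolerance = 1e-8)
})

test_that("planted differential reactions are recovered end to end", {
  toy <- generate_toy_model(seed = 1)
  tr <- generate_structure_transcripts(toy, seed = 1, fold = 10)
  ex <- run_structure_experiment(toy, tr, n = 150, seed = 1)
  shadow <- toy$ground_truth$byp_pathway
  for (pn in names(ex$pairs)) {
    calls6 <- ex$pairs[[pn]]$calls[["0.6"]]
    expect_length(setdiff(calls6, shadow), 0)
  }
  expect_true("BYP" %in% ex$pairs$ERM_vs_ARB$calls[["0.8"]])
})
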