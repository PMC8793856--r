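test_that("FBA reproduces hand-computed chain optima and audits solutions", {
  m <- chain_model(uptake_max = 10, yield = 0.5)
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)
  expect_fluxes_feasible(m, sol$fluxes)

  # no carbon -> no growth
  closed <- set_bounds(m, "EX_a", lower = 0)
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA reports infeasible constraint sets", {
  m <- chain_model(uptake_max = 1)
  m <- set_bounds(m, "R1", lower = 5)  # demands more than uptake allows
  sol <- fba(m)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("pFBA suppresses futile cycles and keeps the optimum", {
  m <- loop_model(loop_reversible = TRUE)
  sol <- pfba(m)
  expect_equal(sol$objective_value, fba(m)$objective_value,
               tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[["L2"]]), 0, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[["L3"]]), 0, tolerance = 1e-8)

  # any optimum with cycle flux has larger total absolute flux
  cyc <- sol$fluxes
  cyc[c("L2")] <- cyc[["L2"]] + 1
  cyc[c("L3")] <- cyc[["L3"]] - 1  # C -> A direction
  cyc[c("L1")] <- cyc[["L1"]] + 1
  expect_fluxes_feasible(m, cyc)
  expect_lt(sol$total_flux, sum(abs(cyc)) )
})

test_that("pFBA equals FBA on a unique-optimum chain", {
  m <- chain_model()
  expect_equal(pfba(m)$fluxes, fba(m)$fluxes, tolerance = 1e-8)
})

test_that("FVA ranges collapse at fraction 1 and nest across fractions", {
  m <- chain_model(uptake_max = 10, yield = 0.5)
  r1 <- fva(m, fraction = 1)
  expect_true(all(r1$max - r1$min < 1e-7))

  r09 <- fva(m, fraction = 0.9)
  r05 <- fva(m, fraction = 0.5)
  expect_true(all(r05$min <= r09$min + 1e-9))
  expect_true(all(r05$max >= r09$max - 1e-9))

  # fraction 0 equals the unconstrained per-reaction min/max
  r0 <- fva(m, fraction = 0)
  expect_equal(r0$max[r0$reaction == "BIO"], 5, tolerance = 1e-9)
  expect_equal(r0$min[r0$reaction == "BIO"], 0, tolerance = 1e-9)
})

test_that("blocked reactions are exactly those with zero FVA width", {
  # dead-end metabolite: add a consumer of an unproduced metabolite
  mets <- data.frame(id = c("s_e", "A_c", "D_c", "E_c"),
                     compartment = c("e", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  ids <- c("EX_s", "T1", "DEAD", "BIO")
  S <- matrix(0, 4, 4, dimnames = list(mets$id, ids))
  S["s_e", "EX_s"] <- -1
  S["s_e", "T1"] <- -1; S["A_c", "T1"] <- 1
  S["D_c", "DEAD"] <- -1; S["E_c", "DEAD"] <- 1  # D_c never produced
  S["A_c", "BIO"] <- -1
  m <- metabolic_model("dead", mets,
                       data.frame(id = ids, lower_bound = c(-10, 0, 0, 0),
                                  upper_bound = 1000,
                                  stringsAsFactors = FALSE),
                       S, biomass_reaction_id = "BIO",
                       compartments = c("e", "c"))
  expect_equal(blocked_reactions(m), "DEAD")

  # fully connected chain -> nothing blocked
  expect_length(blocked_reactions(chain_model()), 0)

  # closing the sole carbon source blocks the whole growth path
  closed <- set_bounds(chain_model(), "EX_a", lower = 0)
  expect_setequal(blocked_reactions(closed),
                  c("EX_a", "R1", "R2", "BIO"))
})

test_that("stoichiometrically balanced cycles are detected and only them", {
  m <- loop_model(loop_reversible = TRUE)
  expect_setequal(detect_sbc(m), c("L1", "L2", "L3"))
  # breaking the cycle by making the closing reaction irreversible
  expect_length(detect_sbc(loop_model(loop_reversible = FALSE)), 0)
  # acyclic toy network
  toy <- generate_toy_model(seed = 1)
  expect_length(detect_sbc(toy$model), 0)
})

test_that("subsystem flux sums scale linearly on a single pathway", {
  m <- chain_model(uptake_max = 10, yield = 0.5)
  m$reactions$subsystem <- c(NA, "Chain", "Chain", "Chain")
  sp <- split_reversible(m)
  r <- subsystem_flux_range(sp, "Chain", fraction = 0.9)
  expect_equal(unname(r["min_sum"]), 0.9 * unname(r["max_sum"]),
               tolerance = 1e-8)
  expect_error(subsystem_flux_range(sp, "Nope"), "unknown subsystem")
  expect_error(subsystem_flux_range(m, "Chain"), "split")

  # pFBA subsystem sum lies within the range
  ps <- pfba(sp)
  s <- sum(ps$fluxes[sp$reactions$id[sp$reactions$subsystem %in% "Chain"]])
  expect_gte(s, r["min_sum"] - 1e-8)
  expect_lte(s, r["max_sum"] + 1e-8)
})

test_that("coupling classification partitions reactions as expected", {
  # unit-coefficient chain: every reaction hard-coupled to biomass
  m <- chain_model(uptake_max = 10, yield = 1)
  cc <- classify_coupling(m, fraction = 0.9, vmax = 1000)
  expect_true(all(cc$class %in%
                    c("hard", "soft", "partial", "uncoupled",
                      "non-carrying")))
  expect_true(all(cc$class[cc$reaction != "EX_a"] == "hard"))

  # two redundant parallel branches: never hard-coupled
  mets <- data.frame(id = c("s_e", "A_c"), compartment = c("e", "c"),
                     stringsAsFactors = FALSE)
  ids <- c("EX_s", "P1", "P2", "BIO")
  S <- matrix(0, 2, 4, dimnames = list(mets$id, ids))
  S["s_e", "EX_s"] <- -1
  S["s_e", "P1"] <- -1; S["A_c", "P1"] <- 1
  S["s_e", "P2"] <- -1; S["A_c", "P2"] <- 1
  S["A_c", "BIO"] <- -1
  m2 <- metabolic_model("par", mets,
                        data.frame(id = ids,
                                   lower_bound = c(-10, 0, 0, 0),
                                   upper_bound = c(1000, 2000, 2000, 1000),
                                   stringsAsFactors = FALSE),
                        S, biomass_reaction_id = "BIO",
                        compartments = c("e", "c"))
  cc2 <- classify_coupling(m2, fraction = 0.9, vmax = 2000)
  expect_false(any(cc2$class[cc2$reaction %in% c("P1", "P2")] == "hard"))
  # a reaction with full-width range is uncoupled by definition
  expect_true(all(cc2$class[cc2$reaction %in% c("P1", "P2")] %in%
                    c("partial", "uncoupled")))
})

test_that("ATP production scans respect growth floors and yield bases", {
  toy <- generate_toy_model(seed = 1)
  a0 <- atp_production(toy$model, "glc_e", atp_sink = "DM_atp",
                       growth_fraction = 0)
  a5 <- atp_production(toy$model, "glc_e", atp_sink = "DM_atp",
                       growth_fraction = 0.5)
  expect_gte(a0$max_atp_flux, a5$max_atp_flux - 1e-9)
  expect_gt(a0$max_atp_flux, 0)
  expect_equal(a0$atp_yield, a0$max_atp_flux / a0$carbon_uptake,
               tolerance = 1e-9)

  # no carbon uptake -> no ATP
  no_c <- apply_medium(toy$model, c(nh4_e = 1000, palm_e = 5))
  a <- atp_production(no_c, "glc_e", atp_sink = "DM_atp")
  expect_equal(a$max_atp_flux, 0, tolerance = 1e-9)
  expect_equal(a$atp_yield, 0)
  expect_error(atp_production(toy$model, "glc_e", atp_sink = "nope"),
               "not in model")
})

test_that("EC overlap by subsystem follows Jaccard set arithmetic", {
  make <- function(ecs) {
    m <- chain_model()
    m$reactions$subsystem <- c(NA, "S1", "S1", NA)
    m$reactions$ec <- list(character(0), ecs[[1]], ecs[[2]], character(0))
    m
  }
  a <- make(list("1.1.1.1", "2.7.1.1"))
  b <- make(list("2.7.1.1", "5.3.1.9"))
  ji <- jaccard_ec_overlap(a, b)
  expect_equal(ji$jaccard[ji$subsystem == "S1"], 1 / 3)
  # identical -> 1; disjoint -> 0
  expect_equal(jaccard_ec_overlap(a, a)$jaccard, 1)
  d <- make(list("9.9.9.9", "8.8.8.8"))
  expect_equal(jaccard_ec_overlap(a, d)$jaccard, 0)
})

test_that("every optimal solution satisfies steady state and bounds", {
  for (seed in 1:4) {
    toy <- generate_toy_model(seed = seed)
    sol <- fba(toy$model)
    expect_fluxes_feasible(toy$model, sol$fluxes)
    sol2 <- pfba(toy$model)
    expect_fluxes_feasible(toy$model, sol2$fluxes, tol = 1e-5)
  }
})
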