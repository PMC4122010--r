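test_that("FBA on a forced chain hits the uptake bound", {
  toy <- make_toy_model("chain", n_reactions = 4, uptake = 10)
  r <- solve_fba(toy$model)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 10, tolerance = 1e-9)
  # stoichiometric forcing: all chain fluxes equal
  expect_equal(unname(r$fluxes[["BIOMASS"]]), 10, tolerance = 1e-9)
  expect_equal(unname(r$fluxes[["EX_m1"]]), -10, tolerance = 1e-9)
})

test_that("optimal flux results satisfy mass balance and bounds", {
  core <- make_core_fixture()
  r <- solve_fba(core)
  expect_equal(r$status, "optimal")
  S <- stoichiometric_matrix(core, sparse = FALSE)
  expect_lt(max(abs(S %*% r$fluxes)), 1e-6)
  expect_true(all(r$fluxes >= core$rxns$lower_bound - 1e-9))
  expect_true(all(r$fluxes <= core$rxns$upper_bound + 1e-9))
  # reproducibility
  r2 <- solve_fba(core)
  expect_equal(r$objective_value, r2$objective_value, tolerance = 1e-12)
})

test_that("FBA matches the brute-force vertex oracle on random toys", {
  set.seed(202)
  for (k in 1:25) {
    topo <- sample(c("chain", "parallel", "diamond", "cycle"), 1)
    toy <- make_toy_model(topo, n_reactions = sample(4:8, 1),
                          uptake = round(stats::runif(1, 3, 15), 1),
                          seed = sample.int(1e6, 1))
    r <- solve_fba(toy$model)
    ref <- oracle_fba_model(toy$model)
    expect_equal(r$objective_value, ref, tolerance = 1e-8,
                 info = paste(topo, k))
    expect_equal(r$objective_value, toy$optimum, tolerance = 1e-8)
  }
})

test_that("infeasible and unbounded problems are reported, never silent zeros", {
  mets <- data.frame(id = c("a"))
  # demand lb forces flux the closed exchange cannot supply
  m <- metabolic_model("inf", mets, list(
    list(id = "EX_a", stoichiometry = c(a = -1), lower_bound = 0, upper_bound = 0),
    list(id = "DM_a", stoichiometry = c(a = -1), lower_bound = 5,
         upper_bound = 10, objective_coefficient = 1)))
  r <- solve_fba(m)
  expect_equal(r$status, "infeasible")
  expect_true(is.na(r$objective_value))

  m2 <- metabolic_model("unb", mets, list(
    list(id = "EX_a", stoichiometry = c(a = -1), lower_bound = -Inf,
         upper_bound = Inf),
    list(id = "DM_a", stoichiometry = c(a = -1), lower_bound = -Inf,
         upper_bound = Inf, objective_coefficient = 1)))
  # infinite lower bounds are rejected by the engine contract
  expect_error(solve_fba(m2), "finite")
})

test_that("apply_medium opens the chosen source and closes other carbon", {
  core <- make_core_fixture()
  m <- apply_medium(core, c(EX_glc_e = 10), aerobic = TRUE, o2_uptake = 18)
  gb <- function(mod, id) mod$rxns$lower_bound[mod$rxns$id == id]
  expect_equal(gb(m, "EX_glc_e"), -10)
  expect_equal(gb(m, "EX_o2_e"), -18)
  expect_equal(gb(m, "EX_ac_e"), 0)
  expect_equal(gb(m, "EX_succ_e"), 0)
  # non-carbon exchanges untouched
  expect_equal(gb(m, "EX_pi_e"), -1000)

  m2 <- apply_medium(core, c(EX_succ_e = 9), aerobic = FALSE)
  expect_equal(gb(m2, "EX_succ_e"), -9)
  expect_equal(gb(m2, "EX_glc_e"), 0)
  expect_equal(gb(m2, "EX_o2_e"), 0)

  expect_error(apply_medium(core, c(EX_nope = 5)), "valid exchanges")
  expect_error(apply_medium(core, c(EX_glc_e = -3)), ">= 0")
})

test_that("zero carbon uptake yields zero growth or infeasibility", {
  core <- make_core_fixture()
  m <- apply_medium(core, c(EX_glc_e = 0), aerobic = TRUE)
  r <- solve_fba(m)
  # NGAM > 0 cannot be met without carbon
  expect_equal(r$status, "infeasible")
  m2 <- set_bounds(m, "ATPM", lower = 0)
  r2 <- solve_fba(m2)
  expect_equal(r2$status, "optimal")
  expect_equal(r2$objective_value, 0, tolerance = 1e-9)
})

test_that("FVA intervals at fraction 1 contain the FBA fluxes", {
  core <- make_core_fixture()
  fba <- solve_fba(core)
  fva <- flux_variability(core, objective_fraction = 1.0)
  expect_true(all(fba$fluxes >= fva$min_flux - 1e-6))
  expect_true(all(fba$fluxes <= fva$max_flux + 1e-6))
  expect_true(all(fva$min_flux <= fva$max_flux + 1e-9))
  # biomass interval collapses onto the optimum
  bio <- fva[fva$reaction == "BIOMASS", ]
  expect_equal(bio$min_flux, fba$objective_value, tolerance = 1e-6)
  expect_equal(bio$max_flux, fba$objective_value, tolerance = 1e-6)
})

test_that("FVA classifies parallel slack and reversible cycles correctly", {
  # two parallel branches, each capacity 10, demand fixed at 10
  mets <- data.frame(id = c("m1", "m2"))
  m <- metabolic_model("par", mets, list(
    list(id = "EX_m1", stoichiometry = c(m1 = -1), lower_bound = -20,
         upper_bound = 0),
    list(id = "B1", stoichiometry = c(m1 = -1, m2 = 1), lower_bound = 0,
         upper_bound = 10),
    list(id = "B2", stoichiometry = c(m1 = -1, m2 = 1), lower_bound = 0,
         upper_bound = 10),
    list(id = "DM", stoichiometry = c(m2 = -1), lower_bound = 10,
         upper_bound = 10, objective_coefficient = 1)))
  fva <- flux_variability(m, 1.0)
  for (b in c("B1", "B2")) {
    row <- fva[fva$reaction == b, ]
    expect_equal(row$min_flux, 0, tolerance = 1e-8)
    expect_equal(row$max_flux, 10, tolerance = 1e-8)
    expect_equal(row$direction, "forward")
  }

  toy <- make_toy_model("cycle", n_reactions = 6, uptake = 10)
  fvac <- flux_variability(toy$model, 1.0)
  for (cyc in c("CYC1", "CYC2")) {
    expect_equal(fvac$direction[fvac$reaction == cyc], "bidirectional")
  }
  # the off-path cycle spans the full bound range (free circulation)
  expect_equal(fvac$max_flux[fvac$reaction == "CYC1"], 1000, tolerance = 1e-6)

  # a reaction that can never carry flux is blocked
  mets2 <- data.frame(id = c("a", "dead"))
  m2 <- metabolic_model("blk", mets2, list(
    list(id = "EX_a", stoichiometry = c(a = -1), lower_bound = -5,
         upper_bound = 0),
    list(id = "DM_a", stoichiometry = c(a = -1), lower_bound = 0,
         upper_bound = 5, objective_coefficient = 1),
    list(id = "DEADIN", stoichiometry = c(a = -1, dead = 1), lower_bound = 0,
         upper_bound = 10)))
  fvab <- flux_variability(m2, 1.0)
  expect_equal(fvab$direction[fvab$reaction == "DEADIN"], "blocked")
})

test_that("robustness scans show forcing, redundancy and self-scan shapes", {
  # essential chain reaction: objective falls as flux is forced down
  toy <- make_toy_model("chain", n_reactions = 4, uptake = 10)
  rc <- robustness_scan(toy$model, "R1", n_points = 11)
  expect_true(all(diff(rc$objective) > 0))        # monotone below the optimum
  expect_equal(rc$objective, rc$value, tolerance = 1e-8)  # 1:1 forcing

  # fully redundant branch: flat objective over its whole range
  mets <- data.frame(id = c("m1", "m2"))
  m <- metabolic_model("par", mets, list(
    list(id = "EX_m1", stoichiometry = c(m1 = -1), lower_bound = -10,
         upper_bound = 0),
    list(id = "B1", stoichiometry = c(m1 = -1, m2 = 1), lower_bound = 0,
         upper_bound = 10),
    list(id = "B2", stoichiometry = c(m1 = -1, m2 = 1), lower_bound = 0,
         upper_bound = 10),
    list(id = "DM", stoichiometry = c(m2 = -1), lower_bound = 0,
         upper_bound = 1000, objective_coefficient = 1)))
  rc2 <- robustness_scan(m, "B1", n_points = 6)
  expect_true(all(abs(rc2$objective - 10) < 1e-8))

  # scanning the biomass reaction itself: identity up to the optimum
  rc3 <- robustness_scan(toy$model, "BIOMASS", n_points = 6)
  feas <- !is.na(rc3$objective)
  expect_equal(rc3$objective[feas], rc3$value[feas], tolerance = 1e-8)
  expect_true(all(rc3$value[feas] <= 10 + 1e-8))

  expect_error(robustness_scan(toy$model, "NOPE"), "unknown reaction")
})
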