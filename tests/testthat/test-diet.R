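test_that("the stress criterion reproduces the ratio-window arithmetic", {
  x <- c(R1 = 1.2, R2 = 1.05, R3 = 0.5)
  y <- c(R1 = 1.0, R2 = 1.0, R3 = 1.0)
  rep <- diet_stress_reactions(x, y)
  expect_equal(rep$stressed[rep$reaction == "R1"], TRUE)    # > 1.1y
  expect_equal(rep$stressed[rep$reaction == "R2"], FALSE)   # inside (0.9, 1.1)
  expect_equal(rep$stressed[rep$reaction == "R3"], TRUE)    # < 0.9y
})

test_that("zero fluxes and sign flips follow the documented closure", {
  x <- c(a = 0, b = 0.5, c = 0, d = 1, e = -1)
  y <- c(a = 0, b = 0, c = 0.5, d = 1, e = 1)
  rep <- diet_stress_reactions(x, y)
  expect_equal(rep$stressed, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_true(is.na(rep$ratio[rep$reaction == "b"]))
  expect_error(diet_stress_reactions(c(a = 1), c(b = 1)), "different reaction")
})

test_that("the stress criterion is scale-free and reflexive-empty", {
  set.seed(17)
  x <- stats::setNames(stats::rnorm(20), paste0("r", 1:20))
  y <- stats::setNames(stats::rnorm(20), paste0("r", 1:20))
  base <- diet_stress_reactions(x, y)$stressed
  for (c in c(0.01, 3, 1e4)) {
    expect_identical(diet_stress_reactions(c * x, c * y)$stressed, base)
  }
  self <- diet_stress_reactions(x, x)
  expect_false(any(self$stressed))
})

test_that("glucose is the best of the four carbon sources at uptake 9", {
  core <- make_core_fixture()
  cond <- data.frame(source = c("EX_ac_e", "EX_etoh_e", "EX_glc_e", "EX_succ_e"),
                     uptake = 9, aerobic = TRUE, stringsAsFactors = FALSE)
  sim <- simulate_conditions(core, cond)
  g <- sim$growth
  expect_true(all(g$status == "optimal"))
  expect_true(all(g$growth > 0))
  expect_equal(g$source[which.max(g$growth)], "EX_glc_e")
})

test_that("anaerobic growth on glucose is positive but below aerobic", {
  core <- make_core_fixture()
  cond <- data.frame(source = "EX_glc_e", uptake = 9,
                     aerobic = c(TRUE, FALSE), stringsAsFactors = FALSE)
  sim <- simulate_conditions(core, cond)
  g <- sim$growth$growth
  expect_gt(g[2], 0)
  expect_gt(g[1], g[2])
})

test_that("infeasible conditions report zero growth with a flag", {
  core <- make_core_fixture()
  cond <- data.frame(source = c("EX_ac_e", "EX_glc_e"),
                     uptake = c(9, 0), aerobic = FALSE,
                     stringsAsFactors = FALSE)
  sim <- simulate_conditions(core, cond)
  expect_equal(sim$growth$growth, c(0, 0))
  expect_true(all(sim$growth$status == "infeasible"))
  expect_true(all(vapply(sim$fluxes, is.null, logical(1))))
  expect_error(simulate_conditions(core,
    data.frame(source = "EX_xyl_e", uptake = 9, aerobic = TRUE)),
    "EX_xyl_e")
})

test_that("a glucose-to-succinate shift stresses central carbon reactions", {
  core <- make_core_fixture()
  cond <- data.frame(source = c("EX_glc_e", "EX_succ_e"), uptake = 9,
                     aerobic = TRUE, stringsAsFactors = FALSE)
  sim <- simulate_conditions(core, cond)
  rep <- diet_stress_reactions(sim$fluxes[[1]], sim$fluxes[[2]])
  stressed <- rep$reaction[rep$stressed]
  expect_gt(length(stressed), 0)
  central <- c("GLCpts", "PFK", "FBA", "PGK", "ENO", "PYK", "PPC", "PPCK",
               "FBP", "PPS", "SUCCt", "SUCDi", "FUM", "MDH")
  expect_gt(length(intersect(stressed, central)), 0)
})

test_that("stress genes are the GPR-leaf union over stressed reactions", {
  core <- make_core_fixture()
  rep <- diet_stress_reactions(
    c(PFK = 2, PGK = 1, ATPM = 5, PDH = 1),
    c(PFK = 1, PGK = 1, ATPM = 1, PDH = 3))
  genes <- stress_genes(rep, core)
  # PFK (isozyme OR), ATPM (no GPR), PDH (AND complex); PGK unstressed
  expect_setequal(genes, c("g_pfkA", "g_pfkB", "g_aceE", "g_aceF"))

  rep0 <- diet_stress_reactions(c(PFK = 1), c(PFK = 1))
  expect_length(stress_genes(rep0, core), 0)

  # shared genes counted once
  rep2 <- diet_stress_reactions(c(ALCD = 1, ACALD = 1), c(ALCD = 0, ACALD = 0))
  expect_equal(sum(stress_genes(rep2, core) == "g_adhE"), 1)
})
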