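# A small hand-built pan network for LP-oracle-checkable extraction:
# source -> A; A -> B by a main route (gene g_main) and a bypass
# (gene g_byp); B -> biomass. The bypass is dispensable for growth.
# An essential variant gates the ONLY A -> B route by g_ess.
bypass_pan <- function() {
  mets <- data.frame(id = c("A", "B"))
  metabolic_model("bypass_pan", mets, list(
    list(id = "EX_A", stoichiometry = c(A = -1), lower_bound = -10,
         upper_bound = 0),
    list(id = "MAIN", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 1000, gpr = "g_main"),
    list(id = "BYPASS", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 1000, gpr = "g_byp"),
    list(id = "BIOMASS", stoichiometry = c(B = -1), lower_bound = 0,
         upper_bound = 1000, objective_coefficient = 1)))
}

test_that("reaction evidence follows GPR min/max with empty rules kept", {
  pan <- bypass_pan()
  ev <- reaction_evidence(pan, presence_profile("s", c(g_main = 1, g_byp = 0)))
  expect_equal(unname(ev[["MAIN"]]), 1)
  expect_equal(unname(ev[["BYPASS"]]), 0)
  expect_true(is.infinite(ev[["EX_A"]]))   # empty GPR: unconditional
  expect_true(is.infinite(ev[["BIOMASS"]]))

  core <- make_core_fixture()
  states <- stats::setNames(rep(1, length(model_genes(core))), model_genes(core))
  states["g_pfkA"] <- 0
  ev2 <- reaction_evidence(core, presence_profile("s", states))
  expect_equal(unname(ev2[["PFK"]]), 1)    # OR rescues the isozyme
  states["g_pfkB"] <- 0
  ev3 <- reaction_evidence(core, presence_profile("s", states))
  expect_equal(unname(ev3[["PFK"]]), 0)
  states2 <- states; states2["g_aceF"] <- 0
  ev4 <- reaction_evidence(core, presence_profile("s", states2))
  expect_equal(unname(ev4[["PDH"]]), 0)    # AND requires both
})

test_that("GIMME keeps everything when all genes are present", {
  pan <- bypass_pan()
  res <- gimme_extract(pan, presence_profile("s", c(g_main = 1, g_byp = 1)))
  expect_length(res$removed, 0)
  expect_identical(sort(res$model$rxns$id), sort(pan$rxns$id))
})

test_that("GIMME removes a dispensable bypass but keeps an essential reaction", {
  pan <- bypass_pan()
  res <- gimme_extract(pan, presence_profile("s", c(g_main = 1, g_byp = 0)))
  expect_identical(res$removed, "BYPASS")
  expect_gte(res$objective, 0.9 * 10)
  expect_length(res$inconsistent, 0)

  # the only route's gene absent: reaction must still carry flux -> kept,
  # flagged as an evidence/flux inconsistency
  res2 <- gimme_extract(pan, presence_profile("s", c(g_main = 0, g_byp = 0)))
  expect_true(all(c("MAIN", "BYPASS") %in% res2$model$rxns$id) ||
              sum(c("MAIN", "BYPASS") %in% res2$model$rxns$id) == 1)
  expect_gte(res2$objective, 9)
  expect_gte(length(res2$inconsistent), 1)
})

test_that("iMAT removes a low-evidence dead-end and agrees with GIMME here", {
  pan <- bypass_pan()
  for (prof in list(c(g_main = 1, g_byp = 0), c(g_main = 1, g_byp = 1))) {
    g <- gimme_extract(pan, presence_profile("s", prof))
    i <- imat_extract(pan, presence_profile("s", prof))
    expect_identical(sort(g$model$rxns$id), sort(i$model$rxns$id))
  }
  i2 <- imat_extract(pan, presence_profile("s", c(g_main = 1, g_byp = 0)))
  expect_identical(i2$removed, "BYPASS")
})

test_that("removed reactions take orphan metabolites with them", {
  mets <- data.frame(id = c("A", "B", "W"))
  pan <- metabolic_model("orphan", mets, list(
    list(id = "EX_A", stoichiometry = c(A = -1), lower_bound = -10,
         upper_bound = 0),
    list(id = "MAIN", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         gpr = "g_main"),
    list(id = "WASTE", stoichiometry = c(A = -1, W = 1), lower_bound = 0,
         gpr = "g_w"),
    list(id = "EX_W", stoichiometry = c(W = -1), lower_bound = 0,
         gpr = "g_w"),
    list(id = "BIOMASS", stoichiometry = c(B = -1), lower_bound = 0,
         objective_coefficient = 1)))
  res <- gimme_extract(pan, presence_profile("s", c(g_main = 1, g_w = 0)))
  expect_setequal(res$removed, c("WASTE", "EX_W"))
  expect_false("W" %in% res$model$mets$id)
})

test_that("extraction is monotone: adding genes never removes more reactions", {
  pw <- make_pan_with_strains(n_strains = 2, n_accessory = 5, seed = 77)
  prof <- pw$profiles[[1]]
  res <- gimme_extract(pw$pan, prof)
  # flip each absent accessory gene to present, one at a time
  for (g in names(prof$scores)[prof$scores == 0]) {
    sc <- prof$scores; sc[g] <- 1
    res_up <- gimme_extract(pw$pan, presence_profile(prof$strain, sc))
    expect_true(all(res$model$rxns$id %in% res_up$model$rxns$id))
  }
})

test_that("GIMME and iMAT agree and recover planted strains on pan models", {
  for (sd in c(101, 202)) {
    pw <- make_pan_with_strains(n_strains = 2, n_accessory = 6, seed = sd)
    for (s in names(pw$profiles)) {
      g <- gimme_extract(pw$pan, pw$profiles[[s]])
      i <- imat_extract(pw$pan, pw$profiles[[s]])
      planted <- sort(pw$strain_models[[s]]$rxns$id)
      expect_identical(sort(g$model$rxns$id), sort(i$model$rxns$id))
      expect_identical(sort(g$model$rxns$id), planted)
      expect_gte(g$objective, 0.9 * solve_fba(pw$pan)$objective_value - 1e-6)
    }
  }
})

test_that("model comparison isolates specific reactions, genes and metabolites", {
  pw <- make_pan_with_strains(n_strains = 3, n_accessory = 8, seed = 11)
  models <- pw$strain_models
  cmp <- compare_models(models)

  # identical models: empty specific sets
  cmp_id <- compare_models(list(a = models[[1]], b = models[[1]]))
  expect_length(cmp_id$specific_reactions$a, 0)
  expect_length(cmp_id$nonshared_metabolites, 0)

  # specific sets are disjoint from the shared core and from each other
  for (s in names(models)) {
    expect_length(intersect(cmp$specific_reactions[[s]], cmp$core_reactions), 0)
  }
  pairs <- utils::combn(names(models), 2, simplify = FALSE)
  for (p in pairs) {
    expect_length(intersect(cmp$specific_reactions[[p[1]]],
                            cmp$specific_reactions[[p[2]]]), 0)
  }

  # ground truth from the construction: reactions specific to strain s are
  # the pan reactions gated by genes only strain s carries
  for (s in names(models)) {
    others <- Reduce(union, lapply(models[-match(s, names(models))],
                                   function(m) m$rxns$id))
    truth <- setdiff(models[[s]]$rxns$id, others)
    expect_setequal(cmp$specific_reactions[[s]], truth)
  }

  # nonshared metabolites = union minus three-way intersection
  met_union <- Reduce(union, lapply(models, function(m) m$mets$id))
  met_core <- Reduce(intersect, lapply(models, function(m) m$mets$id))
  expect_setequal(cmp$nonshared_metabolites, setdiff(met_union, met_core))

  # counts table is consistent
  expect_equal(cmp$counts$specific_reactions,
               vapply(cmp$specific_reactions, length, integer(1)),
               ignore_attr = TRUE)
})
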