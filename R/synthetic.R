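#' Toy stoichiometric networks with analytically known optima
#'
#' Generates small networks whose FBA optimum has a closed form, for
#' solver validation. Topologies:
#' \describe{
#'   \item{chain}{source -> m1 -> ... -> biomass; optimum = min of the
#'     uptake bound and all conversion capacities.}
#'   \item{parallel}{k parallel branches between two metabolites;
#'     optimum = min(uptake, demand cap, sum of branch capacities).}
#'   \item{diamond}{two two-step arms A->B->D and A->C->D; optimum =
#'     min(uptake, demand cap, min(c1,c3) + min(c2,c4)).}
#'   \item{cycle}{a chain plus an off-path reversible 2-cycle whose
#'     members carry free circulation (bidirectional under FVA);
#'     optimum as for the chain.}
#' }
#'
#' @param topology One of `"chain"`, `"parallel"`, `"diamond"`, `"cycle"`.
#' @param n_reactions Total reaction count (chain/parallel; >= 3).
#' @param uptake Source exchange uptake bound.
#' @param seed Optional seed; when given, internal capacities are drawn
#'   uniformly from [2, 20] (otherwise all 1000).
#' @param demand_cap Capacity of the terminal demand/biomass reaction.
#' @param blocked_arm For `"diamond"`: close one arm (capacity 0).
#' @return List with elements `model` (a `metabolic_model`) and
#'   `optimum` (the analytic FBA optimum).
#' @export
make_toy_model <- function(topology = c("chain", "parallel", "diamond", "cycle"),
                           n_reactions = 5, uptake = 10, seed = NULL,
                           demand_cap = 1000, blocked_arm = FALSE) {
  topology <- match.arg(topology)
  if (!is.null(seed)) set.seed(seed)
  cap <- function(k) if (is.null(seed)) rep(1000, k) else round(stats::runif(k, 2, 20), 2)

  if (topology %in% c("chain", "cycle")) {
    n_conv <- max(1, n_reactions - 2 - if (topology == "cycle") 2 else 0)
    caps <- cap(n_conv)
    mets <- data.frame(id = c(paste0("m", seq_len(n_conv + 1)),
                              if (topology == "cycle") "mb"),
                       compartment = "c", stringsAsFactors = FALSE)
    rxns <- list(list(id = "EX_m1", stoichiometry = c(m1 = -1),
                      lower_bound = -uptake, upper_bound = 0))
    for (k in seq_len(n_conv)) {
      st <- stats::setNames(c(-1, 1), paste0("m", c(k, k + 1)))
      rxns <- c(rxns, list(list(id = paste0("R", k), stoichiometry = st,
                                lower_bound = 0, upper_bound = caps[k])))
    }
    rxns <- c(rxns, list(list(id = "BIOMASS",
                              stoichiometry = stats::setNames(-1, paste0("m", n_conv + 1)),
                              lower_bound = 0, upper_bound = demand_cap,
                              objective_coefficient = 1)))
    if (topology == "cycle") {
      rxns <- c(rxns,
        list(list(id = "CYC1", stoichiometry = c(m2 = -1, mb = 1),
                  lower_bound = -1000, upper_bound = 1000),
             list(id = "CYC2", stoichiometry = c(mb = -1, m2 = 1),
                  lower_bound = -1000, upper_bound = 1000)))
    }
    opt <- min(uptake, caps, demand_cap)
    return(list(model = metabolic_model(paste0("toy_", topology), mets, rxns),
                optimum = opt))
  }

  if (topology == "parallel") {
    k <- max(2, n_reactions - 2)
    caps <- cap(k)
    mets <- data.frame(id = c("m1", "m2"), compartment = "c",
                       stringsAsFactors = FALSE)
    rxns <- list(list(id = "EX_m1", stoichiometry = c(m1 = -1),
                      lower_bound = -uptake, upper_bound = 0))
    for (i in seq_len(k)) {
      rxns <- c(rxns, list(list(id = paste0("B", i),
                                stoichiometry = c(m1 = -1, m2 = 1),
                                lower_bound = 0, upper_bound = caps[i])))
    }
    rxns <- c(rxns, list(list(id = "BIOMASS", stoichiometry = c(m2 = -1),
                              lower_bound = 0, upper_bound = demand_cap,
                              objective_coefficient = 1)))
    opt <- min(uptake, demand_cap, sum(caps))
    return(list(model = metabolic_model("toy_parallel", mets, rxns),
                optimum = opt))
  }

  # diamond
  caps <- cap(4)
  if (blocked_arm) caps[2] <- 0
  mets <- data.frame(id = c("A", "B", "C", "D"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_A", stoichiometry = c(A = -1),
         lower_bound = -uptake, upper_bound = 0),
    list(id = "AB", stoichiometry = c(A = -1, B = 1), lower_bound = 0, upper_bound = caps[1]),
    list(id = "AC", stoichiometry = c(A = -1, C = 1), lower_bound = 0, upper_bound = caps[2]),
    list(id = "BD", stoichiometry = c(B = -1, D = 1), lower_bound = 0, upper_bound = caps[3]),
    list(id = "CD", stoichiometry = c(C = -1, D = 1), lower_bound = 0, upper_bound = caps[4]),
    list(id = "BIOMASS", stoichiometry = c(D = -1), lower_bound = 0,
         upper_bound = demand_cap, objective_coefficient = 1))
  opt <- min(uptake, demand_cap, min(caps[1], caps[3]) + min(caps[2], caps[4]))
  list(model = metabolic_model("toy_diamond", mets, rxns), optimum = opt)
}

#' Hand-curated core-metabolism fixture
#'
#' A deterministic ~55-reaction E. coli-style core network: glycolysis,
#' pentose-phosphate pathway, TCA cycle with glyoxylate shunt,
#' fermentation (acetate, ethanol, lactate), lumped oxidative
#' phosphorylation (P/O 2 for NADH, 1 for FADH2), exchanges for glucose,
#' acetate, ethanol, succinate, lactate, O2, CO2 and phosphate, an ATP
#' maintenance reaction (NGAM lower bound 8.39 mmol gDW^-1 h^-1, the
#' iAF1260 value; GAM lives inside the biomass stoichiometry), and a
#' biomass pseudo-reaction draining precursors. It grows aerobically and
#' anaerobically on glucose and on all four carbon sources aerobically,
#' and carries the reaction ids ACS, PTAr, ACKr, PGK, PGL, GND and RPI
#' used in scenario analyses. Cofactors use a single lumped NAD(H) pool
#' and internal metabolites carry no formulas; exchange metabolites have
#' real formulas so carbon-source handling can classify them.
#'
#' @return A `metabolic_model`.
#' @export
make_core_fixture <- function() {
  mets <- data.frame(
    id = c("glc_e", "ac_e", "etoh_e", "succ_e", "lac_e", "o2_e", "co2_e", "pi_e",
           "g6p", "f6p", "fdp", "g3p", "13dpg", "3pg", "pep", "pyr",
           "accoa", "coa", "actp", "ac", "acald", "etoh", "lac",
           "cit", "akg", "succ", "fum", "mal", "oaa", "glx",
           "6pgl", "6pgc", "ru5p", "r5p", "x5p", "e4p", "s7p",
           "nad", "nadh", "atp", "adp", "pi", "o2", "co2", "fad", "fadh2"),
    formula = c("C6H12O6", "C2H3O2", "C2H6O", "C4H4O4", "C3H5O3", "O2", "CO2", "HO4P",
                rep("", 38)),
    compartment = c(rep("e", 8), rep("c", 38)),
    stringsAsFactors = FALSE)

  r <- function(id, st, lb = -1000, ub = 1000, gpr = "", sub = "", obj = 0)
    list(id = id, stoichiometry = st, lower_bound = lb, upper_bound = ub,
         gpr = gpr, subsystem = sub, objective_coefficient = obj)

  rxns <- list(
    # exchanges (negative flux = uptake); default medium: glucose + O2
    r("EX_glc_e", c(glc_e = -1), -10, 1000, sub = "exchange"),
    r("EX_ac_e", c(ac_e = -1), 0, 1000, sub = "exchange"),
    r("EX_etoh_e", c(etoh_e = -1), 0, 1000, sub = "exchange"),
    r("EX_succ_e", c(succ_e = -1), 0, 1000, sub = "exchange"),
    r("EX_lac_e", c(lac_e = -1), 0, 1000, sub = "exchange"),
    r("EX_o2_e", c(o2_e = -1), -18, 1000, sub = "exchange"),
    r("EX_co2_e", c(co2_e = -1), 0, 1000, sub = "exchange"),
    r("EX_pi_e", c(pi_e = -1), -1000, 1000, sub = "exchange"),
    # transport
    r("GLCpts", c(glc_e = -1, pep = -1, g6p = 1, pyr = 1), 0, 1000,
      "g_ptsG", "transport"),
    r("ACt", c(ac_e = -1, ac = 1), gpr = "g_actP", sub = "transport"),
    r("ETOHt", c(etoh_e = -1, etoh = 1), sub = "transport"),
    r("SUCCt", c(succ_e = -1, succ = 1), gpr = "g_dctA", sub = "transport"),
    r("LACt", c(lac_e = -1, lac = 1), gpr = "g_lldP", sub = "transport"),
    r("O2t", c(o2_e = -1, o2 = 1), sub = "transport"),
    r("CO2t", c(co2 = -1, co2_e = 1), sub = "transport"),
    r("PIt", c(pi_e = -1, pi = 1), gpr = "g_pitA", sub = "transport"),
    # glycolysis / gluconeogenesis
    r("PGI", c(g6p = -1, f6p = 1), gpr = "g_pgi", sub = "glycolysis"),
    r("PFK", c(f6p = -1, atp = -1, fdp = 1, adp = 1), 0, 1000,
      "g_pfkA or g_pfkB", "glycolysis"),
    r("FBP", c(fdp = -1, f6p = 1, pi = 1), 0, 1000, "g_fbp", "gluconeogenesis"),
    r("FBA", c(fdp = -1, g3p = 2), gpr = "g_fbaA", sub = "glycolysis"),
    r("GAPD", c(g3p = -1, nad = -1, pi = -1, `13dpg` = 1, nadh = 1),
      gpr = "g_gapA", sub = "glycolysis"),
    r("PGK", c(`13dpg` = -1, adp = -1, `3pg` = 1, atp = 1),
      gpr = "g_pgk", sub = "glycolysis"),
    r("ENO", c(`3pg` = -1, pep = 1), gpr = "g_eno", sub = "glycolysis"),
    r("PYK", c(pep = -1, adp = -1, pyr = 1, atp = 1), 0, 1000,
      "g_pykA or g_pykF", "glycolysis"),
    r("PPS", c(pyr = -1, atp = -2, pep = 1, adp = 2, pi = 1), 0, 1000,
      "g_ppsA", "gluconeogenesis"),
    r("PDH", c(pyr = -1, coa = -1, nad = -1, accoa = 1, co2 = 1, nadh = 1),
      0, 1000, "g_aceE and g_aceF", "glycolysis"),
    # pentose-phosphate pathway
    r("G6PDH", c(g6p = -1, nad = -1, `6pgl` = 1, nadh = 1), 0, 1000,
      "g_zwf", "pentose phosphate"),
    r("PGL", c(`6pgl` = -1, `6pgc` = 1), 0, 1000, "g_pgl", "pentose phosphate"),
    r("GND", c(`6pgc` = -1, nad = -1, ru5p = 1, co2 = 1, nadh = 1), 0, 1000,
      "g_gnd", "pentose phosphate"),
    r("RPI", c(r5p = -1, ru5p = 1), gpr = "g_rpiA", sub = "pentose phosphate"),
    r("RPE", c(ru5p = -1, x5p = 1), gpr = "g_rpe", sub = "pentose phosphate"),
    r("TKT1", c(x5p = -1, r5p = -1, g3p = 1, s7p = 1), gpr = "g_tktA",
      sub = "pentose phosphate"),
    r("TALA", c(s7p = -1, g3p = -1, e4p = 1, f6p = 1), gpr = "g_talB",
      sub = "pentose phosphate"),
    r("TKT2", c(x5p = -1, e4p = -1, f6p = 1, g3p = 1), gpr = "g_tktB",
      sub = "pentose phosphate"),
    # anaplerosis
    r("PPC", c(pep = -1, co2 = -1, oaa = 1, pi = 1), 0, 1000,
      "g_ppc", "anaplerosis"),
    r("PPCK", c(oaa = -1, atp = -1, pep = 1, co2 = 1, adp = 1), 0, 1000,
      "g_pck", "gluconeogenesis"),
    # TCA cycle (citrate lumps aconitase; AKGDH lumps succinyl-CoA synthetase)
    r("CS", c(accoa = -1, oaa = -1, cit = 1, coa = 1), 0, 1000,
      "g_gltA", "TCA cycle"),
    r("ICDHyr", c(cit = -1, nad = -1, akg = 1, co2 = 1, nadh = 1),
      gpr = "g_icd", sub = "TCA cycle"),
    r("AKGDH", c(akg = -1, nad = -1, adp = -1, pi = -1,
                 succ = 1, co2 = 1, nadh = 1, atp = 1), 0, 1000,
      "g_sucA and g_sucB", "TCA cycle"),
    r("SUCDi", c(succ = -1, fad = -1, fum = 1, fadh2 = 1), 0, 1000,
      "g_sdhA", "TCA cycle"),
    r("FRD", c(fum = -1, nadh = -1, succ = 1, nad = 1), 0, 1000,
      "g_frdA", "fermentation"),
    r("FUM", c(fum = -1, mal = 1), gpr = "g_fumA or g_fumB", sub = "TCA cycle"),
    r("MDH", c(mal = -1, nad = -1, oaa = 1, nadh = 1), gpr = "g_mdh",
      sub = "TCA cycle"),
    # glyoxylate shunt
    r("ICL", c(cit = -1, succ = 1, glx = 1), 0, 1000, "g_aceA", "glyoxylate"),
    r("MALS", c(glx = -1, accoa = -1, mal = 1, coa = 1), 0, 1000,
      "g_aceB", "glyoxylate"),
    # acetate / ethanol / lactate metabolism
    r("PTAr", c(accoa = -1, pi = -1, actp = 1, coa = 1), gpr = "g_pta",
      sub = "fermentation"),
    r("ACKr", c(actp = -1, adp = -1, ac = 1, atp = 1), gpr = "g_ackA",
      sub = "fermentation"),
    r("ACS", c(ac = -1, atp = -2, coa = -1, accoa = 1, adp = 2, pi = 2),
      0, 1000, "g_acs", "acetate metabolism"),
    r("ALCD", c(etoh = -1, nad = -1, acald = 1, nadh = 1), gpr = "g_adhE",
      sub = "fermentation"),
    r("ACALD", c(acald = -1, nad = -1, coa = -1, accoa = 1, nadh = 1),
      gpr = "g_adhE or g_mhpF", sub = "fermentation"),
    r("LDH", c(pyr = -1, nadh = -1, lac = 1, nad = 1), gpr = "g_ldhA",
      sub = "fermentation"),
    # lumped oxidative phosphorylation
    r("NADHOR", c(nadh = -1, o2 = -0.5, adp = -2, pi = -2,
                  nad = 1, atp = 2), 0, 1000,
      "g_nuoA and g_nuoB", "oxidative phosphorylation"),
    r("FADOR", c(fadh2 = -1, o2 = -0.5, adp = -1, pi = -1, fad = 1, atp = 1),
      0, 1000, "g_cydA", "oxidative phosphorylation"),
    # maintenance + biomass (GAM = 45 mmol ATP per gDW inside the equation)
    r("ATPM", c(atp = -1, adp = 1, pi = 1), 8.39, 1000, sub = "maintenance"),
    r("BIOMASS",
      c(g6p = -0.3, r5p = -0.2, e4p = -0.1, pep = -0.4, pyr = -0.5,
        accoa = -1.0, oaa = -0.5, akg = -0.3, atp = -45, nadh = -4,
        adp = 45, pi = 45, nad = 4, coa = 1.0),
      0, 1000, sub = "biomass", obj = 1))

  metabolic_model("core_fixture", mets, rxns)
}

#' Synthetic pan-genome model with planted strain models
#'
#' Builds a pan-genome network as the core fixture plus `n_accessory`
#' growth-dispensable accessory reactions, each gated by its own gene:
#' either a duplicate (isozyme-like bypass) of an existing irreversible
#' internal reaction, or a peripheral byproduct branch (conversion of an
#' internal metabolite to a new one plus its secretion exchange, both
#' gated by the same gene). Dispensability by construction keeps the pan
#' optimum equal to every planted strain optimum, so GIMME/iMAT
#' extraction at any growth fraction is well-posed. Strain profiles set
#' all core genes present and each accessory gene present with
#' probability 1/2; the planted strain model is the pan model minus the
#' reactions whose GPR evaluates to absent.
#'
#' @param n_strains Number of strains (>= 2).
#' @param n_accessory Number of accessory reactions.
#' @param seed RNG seed (generation is deterministic given the seed).
#' @return List with `pan` (the pan `metabolic_model`), `profiles`
#'   (list of presence profiles: list(strain, scores)) and
#'   `strain_models` (planted `metabolic_model`s, same names).
#' @export
make_pan_with_strains <- function(n_strains = 3, n_accessory = 6, seed = 1) {
  stopifnot(n_strains >= 2, n_accessory >= 0)
  set.seed(seed)
  core <- make_core_fixture()

  dup_candidates <- c("PFK", "PDH", "G6PDH", "GND", "PPC", "CS", "AKGDH",
                      "ICL", "MALS", "PYK", "FBP", "PPCK")
  branch_sources <- c("pyr", "accoa", "akg", "mal", "f6p", "g3p", "oaa")

  mets <- core$mets
  rxns <- lapply(seq_len(nrow(core$rxns)), function(j) {
    st <- core$stoich[, j]
    list(id = core$rxns$id[j], name = core$rxns$name[j],
         stoichiometry = st[st != 0],
         lower_bound = core$rxns$lower_bound[j],
         upper_bound = core$rxns$upper_bound[j],
         subsystem = core$rxns$subsystem[j], gpr = core$rxns$gpr[j],
         objective_coefficient = core$rxns$objective_coefficient[j])
  })

  acc_genes <- character(n_accessory)
  for (i in seq_len(n_accessory)) {
    gene <- paste0("g_acc", i)
    acc_genes[i] <- gene
    if (stats::runif(1) < 0.5) {
      orig <- sample(dup_candidates, 1)
      j <- match(orig, core$rxns$id)
      st <- core$stoich[, j]
      rxns <- c(rxns, list(list(
        id = paste0("ACC", i, "_", orig), stoichiometry = st[st != 0],
        lower_bound = core$rxns$lower_bound[j],
        upper_bound = core$rxns$upper_bound[j],
        subsystem = "accessory", gpr = gene)))
    } else {
      src <- sample(branch_sources, 1)
      wmet <- paste0("w", i)
      mets <- rbind(mets, data.frame(id = wmet, name = wmet, formula = "",
                                     charge = 0L, compartment = "c",
                                     stringsAsFactors = FALSE))
      rxns <- c(rxns,
        list(list(id = paste0("ACC", i, "_", src, "_sec"),
                  stoichiometry = stats::setNames(c(-1, 1), c(src, wmet)),
                  lower_bound = 0, upper_bound = 1000,
                  subsystem = "accessory", gpr = gene),
             list(id = paste0("EX_", wmet),
                  stoichiometry = stats::setNames(-1, wmet),
                  lower_bound = 0, upper_bound = 1000,
                  subsystem = "accessory", gpr = gene)))
    }
  }

  pan <- metabolic_model(sprintf("pan_seed%d", seed), mets, rxns)
  core_genes <- setdiff(model_genes(pan), acc_genes)

  profiles <- vector("list", n_strains)
  strain_models <- vector("list", n_strains)
  for (s in seq_len(n_strains)) {
    present <- stats::rbinom(n_accessory, 1, 0.5)
    scores <- stats::setNames(c(rep(1, length(core_genes)), present),
                              c(core_genes, acc_genes))
    profile <- presence_profile(paste0("strain", s), scores)
    absent_rxns <- pan$rxns$id[vapply(seq_along(pan$gprs), function(j) {
      !is_empty_gpr(pan$gprs[[j]]) && evaluate_gpr(pan$gprs[[j]], scores) == 0
    }, logical(1))]
    profiles[[s]] <- profile
    strain_models[[s]] <- remove_reactions(pan, absent_rxns)
    strain_models[[s]]$id <- paste0("strain", s)
  }
  names(profiles) <- names(strain_models) <- paste0("strain", seq_len(n_strains))
  list(pan = pan, profiles = profiles, strain_models = strain_models)
}

#' Presence profile for one strain
#'
#' @param strain Strain id.
#' @param scores Named numeric vector gene id -> score (0/1 presence or
#'   real evidence, all >= 0). Genes not listed are treated as absent.
#' @return A `presence_profile`.
#' @export
presence_profile <- function(strain, scores) {
  stopifnot(is.character(strain), length(strain) == 1)
  if (length(scores) && is.null(names(scores)))
    stop("scores must be named by gene id")
  if (any(scores < 0)) stop("scores must be >= 0")
  structure(list(strain = strain, scores = scores), class = "presence_profile")
}

#' Planted cohort specification for alignment synthesis
#'
#' @param n_samples Number of metagenome samples.
#' @param strains data.frame with columns `strain`, `prevalence` (in
#'   [0,1]), `depth` (mean fold coverage when present) and `identity`
#'   (percent identity of reads).
#' @param read_length Read length in bp (default 100).
#' @param identity_sd Per-read identity jitter (default 0: clonal reads).
#' @param seed RNG seed.
#' @return A `planted_cohort`.
#' @export
planted_cohort <- function(n_samples, strains, read_length = 100,
                           identity_sd = 0, seed = 1) {
  strains <- as.data.frame(strains, stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "prevalence", "depth", "identity") %in% names(strains)),
            all(strains$prevalence >= 0 & strains$prevalence <= 1),
            all(strains$depth >= 0), n_samples >= 1)
  structure(list(n_samples = as.integer(n_samples), strains = strains,
                 read_length = read_length, identity_sd = identity_sd,
                 seed = as.integer(seed)),
            class = "planted_cohort")
}

#' Synthesize alignment tables for a planted cohort
#'
#' For each sample and each strain planted as present, places
#' `round(depth * genome_length / read_length)` reads by sequential
#' tiling (wrapping around the genome), so the realized post-placement
#' depth equals the planted depth exactly and breadth saturates once
#' depth >= 1. Read identities equal the strain's planted identity plus
#' optional Gaussian jitter. Each strain is present in exactly
#' `round(prevalence * n_samples)` samples (chosen at random under the
#' cohort seed). Absent strains contribute no alignments.
#'
#' @param cohort A `planted_cohort`.
#' @param genome_length Reference genome length in bp (default 50000).
#' @return List with `alignments` (per-sample data.frames with columns
#'   query, subject, identity, length, start, end, bitscore) and `truth`
#'   (data.frame sample, strain, present, depth, identity).
#' @export
make_alignments <- function(cohort, genome_length = 50000) {
  stopifnot(inherits(cohort, "planted_cohort"))
  set.seed(cohort$seed)
  n <- cohort$n_samples
  rl <- cohort$read_length
  strains <- cohort$strains

  present_in <- lapply(seq_len(nrow(strains)), function(i) {
    k <- round(strains$prevalence[i] * n)
    sort(sample.int(n, k))
  })

  truth <- expand.grid(sample = seq_len(n), strain = strains$strain,
                       stringsAsFactors = FALSE)
  truth$present <- FALSE
  truth$depth <- 0
  truth$identity <- NA_real_

  aligns <- vector("list", n)
  for (smp in seq_len(n)) {
    recs <- list()
    for (i in seq_len(nrow(strains))) {
      if (!(smp %in% present_in[[i]])) next
      d <- strains$depth[i]
      n_reads <- round(d * genome_length / rl)
      if (n_reads == 0) next
      starts <- ((seq_len(n_reads) - 1L) * rl) %% (genome_length - rl + 1L) + 1L
      ident <- rep(strains$identity[i], n_reads)
      if (cohort$identity_sd > 0)
        ident <- pmin(100, ident + stats::rnorm(n_reads, 0, cohort$identity_sd))
      recs[[length(recs) + 1]] <- data.frame(
        query = sprintf("s%d_%s_r%d", smp, strains$strain[i], seq_len(n_reads)),
        subject = strains$strain[i],
        identity = ident,
        length = rl,
        start = starts,
        end = starts + rl - 1L,
        bitscore = round(1.9 * rl),
        stringsAsFactors = FALSE)
      k <- truth$sample == smp & truth$strain == strains$strain[i]
      truth$present[k] <- TRUE
      truth$depth[k] <- n_reads * rl / genome_length
      truth$identity[k] <- strains$identity[i]
    }
    aligns[[smp]] <- if (length(recs)) do.call(rbind, recs) else
      data.frame(query = character(0), subject = character(0),
                 identity = numeric(0), length = integer(0),
                 start = integer(0), end = integer(0), bitscore = numeric(0),
                 stringsAsFactors = FALSE)
  }
  list(alignments = aligns, truth = truth, genome_length = genome_length)
}
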