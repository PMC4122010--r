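#' Per-reaction evidence scores from a gene presence profile
#'
#' Maps gene-level scores onto reactions through the GPR rules
#' (AND = min, OR = max). Reactions with an empty GPR are unconditionally
#' catalyzed and receive evidence `Inf` (always above any threshold).
#' Profile genes absent from the model's gene namespace are ignored with
#' a message; model genes missing from the profile score 0.
#'
#' @param pan A `metabolic_model`.
#' @param profile A `presence_profile` (or named numeric score vector).
#' @return Named numeric vector: reaction id -> evidence score.
#' @export
reaction_evidence <- function(pan, profile) {
  scores <- if (inherits(profile, "presence_profile")) profile$scores else profile
  if (length(scores) && is.null(names(scores)))
    stop("profile scores must be named by gene id")
  extra <- setdiff(names(scores), model_genes(pan))
  if (length(extra))
    message(length(extra), " profile gene(s) not in the model namespace (ignored)")
  ev <- vapply(pan$gprs, function(g) {
    if (is_empty_gpr(g)) Inf else evaluate_gpr(g, scores)
  }, numeric(1))
  stats::setNames(ev, pan$rxns$id)
}

#' GIMME: context-specific model extraction by linear programming
#'
#' Minimizes total penalized flux through low-evidence reactions while
#' guaranteeing at least `growth_fraction` of the pan-model FBA optimum:
#' min sum_j penalty_j |v_j| over reactions with evidence < threshold
#' (penalty_j = threshold - evidence_j), subject to S v = 0, bounds, and
#' c'v >= growth_fraction * optimum. |v| is linearized by an auxiliary
#' variable per penalized reaction. A low-evidence reaction is removed
#' when its flux can be zero without degrading the penalty optimum or
#' the growth guarantee; candidates are examined in lexicographic
#' reaction-id order, which makes the removal set deterministic under
#' alternate optima. Orphan metabolites are dropped with the reactions.
#'
#' @param pan A `metabolic_model` with a positive FBA optimum.
#' @param profile A `presence_profile` or named gene score vector.
#' @param threshold Evidence threshold below which a reaction is
#'   penalized (default 0.5, the midpoint for binary profiles).
#' @param growth_fraction Required fraction of the pan optimum (0.9).
#' @return An `extraction_result`: list with `model`, `removed`,
#'   `algorithm`, `objective` (growth of the extracted model),
#'   `inconsistent` (low-evidence reactions kept because they must carry
#'   flux).
#' @export
gimme_extract <- function(pan, profile, threshold = 0.5, growth_fraction = 0.9) {
  stopifnot(growth_fraction > 0, growth_fraction <= 1)
  fba <- solve_fba(pan)
  if (fba$status != "optimal" || fba$objective_value <= 0)
    stop("pan-model FBA optimum must be positive (status: ", fba$status, ")")
  opt <- fba$objective_value
  ev <- reaction_evidence(pan, profile)
  pen_idx <- which(ev < threshold)

  p <- lp_pieces(pan)
  n <- ncol(p$S)
  if (length(pen_idx) == 0) {
    return(new_extraction_result(pan, character(0), "gimme",
                                 opt, character(0)))
  }

  npen <- length(pen_idx)
  pen_w <- threshold - ev[pen_idx]
  # variables: v (n), w (npen) with w_j >= |v_j|
  A <- cbind(p$S, matrix(0, nrow(p$S), npen))
  b <- rep(0, nrow(p$S))
  # w_j - v_j >= 0 ; w_j + v_j >= 0 ; growth
  G <- rbind(
    cbind(-diag(n)[pen_idx, , drop = FALSE], diag(npen)),
    cbind(diag(n)[pen_idx, , drop = FALSE], diag(npen)),
    c(p$obj, rep(0, npen)))
  h <- c(rep(0, 2 * npen), growth_fraction * opt - 1e-9)
  wmax <- pmax(abs(p$lb[pen_idx]), abs(p$ub[pen_idx]))
  lb <- c(p$lb, rep(0, npen))
  ub <- c(p$ub, wmax)
  obj <- c(rep(0, n), pen_w)

  base <- solve_lp(obj, A, b, lb, ub, "min", G = G, h = h)
  if (base$status != 0)
    stop("GIMME LP ", base$status_str,
         " at growth_fraction ", growth_fraction,
         "; try a lower growth fraction")
  zstar <- base$objective

  # deterministic removal: fix candidate fluxes to zero in id order while
  # the penalty optimum and growth guarantee are preserved
  ord <- pen_idx[order(pan$rxns$id[pen_idx])]
  fixed <- integer(0)
  for (j in ord) {
    lb2 <- lb; ub2 <- ub
    lb2[c(fixed, j)] <- 0; ub2[c(fixed, j)] <- 0
    r <- solve_lp(obj, A, b, lb2, ub2, "min", G = G, h = h)
    if (r$status == 0 && r$objective <= zstar + 1e-6) fixed <- c(fixed, j)
  }
  removed <- pan$rxns$id[sort(fixed)]
  inconsistent <- setdiff(pan$rxns$id[pen_idx], removed)

  sub <- remove_reactions(pan, removed)
  chk <- solve_fba(sub)
  if (chk$status != "optimal" || chk$objective_value < growth_fraction * opt - 1e-6)
    stop("internal error: extracted model fails the growth guarantee")
  new_extraction_result(sub, removed, "gimme", chk$objective_value, inconsistent)
}

#' iMAT: context-specific extraction by mixed-integer programming
#'
#' Maximizes the number of high-evidence reactions carrying flux of at
#' least `epsilon` (in either direction) plus the number of low-evidence
#' reactions with zero flux, using binary indicators linked to fluxes by
#' big-M constraints, subject to S v = 0, bounds and a growth guarantee.
#' The MILP is solved by depth-first branch and bound on the LP
#' relaxation (the branching order is deterministic). Low-evidence
#' reactions inactive in the optimum are removed; orphan metabolites are
#' dropped.
#'
#' @param pan A `metabolic_model` with a positive FBA optimum.
#' @param profile A `presence_profile` or named gene score vector.
#' @param high_threshold Evidence at or above this is "high" (0.5).
#' @param low_threshold Evidence below this is "low" (0.5).
#' @param epsilon Minimum activating flux for high-evidence reactions
#'   (default 1.0 mmol gDW^-1 h^-1).
#' @param growth_fraction Required fraction of the pan optimum (0.9).
#' @param big_m Big-M constant linking indicators to fluxes (1000, the
#'   default bound magnitude).
#' @param max_nodes Branch-and-bound node budget; exceeding it is an
#'   error suggesting a smaller model.
#' @return An `extraction_result` (see [gimme_extract()]).
#' @export
imat_extract <- function(pan, profile, high_threshold = 0.5,
                         low_threshold = 0.5, epsilon = 1.0,
                         growth_fraction = 0.9, big_m = 1000,
                         max_nodes = 5000) {
  stopifnot(low_threshold <= high_threshold)
  fba <- solve_fba(pan)
  if (fba$status != "optimal" || fba$objective_value <= 0)
    stop("pan-model FBA optimum must be positive (status: ", fba$status, ")")
  opt <- fba$objective_value
  ev <- reaction_evidence(pan, profile)
  hi <- which(is.finite(ev) & ev >= high_threshold)
  lo <- which(ev < low_threshold)

  p <- lp_pieces(pan)
  n <- ncol(p$S)
  growth_rhs <- growth_fraction * opt - 1e-9

  # Tighten flux bounds by FVA under the growth guarantee. This keeps
  # every MILP-feasible point (all satisfy the growth row) while making
  # the indicator constraints near-exact, so the LP relaxation bound is
  # sharp and branch and bound prunes well.
  Ggrow <- matrix(p$obj, nrow = 1)
  for (j in seq_len(n)) {
    cj <- numeric(n); cj[j] <- 1
    rlo <- solve_lp(cj, p$S, rep(0, nrow(p$S)), p$lb, p$ub, "min",
                    G = Ggrow, h = growth_rhs)
    rhi <- solve_lp(cj, p$S, rep(0, nrow(p$S)), p$lb, p$ub, "max",
                    G = Ggrow, h = growth_rhs)
    if (rlo$status == 0) p$lb[j] <- max(p$lb[j], rlo$objective - 1e-7)
    if (rhi$status == 0) p$ub[j] <- min(p$ub[j], rhi$objective + 1e-7)
  }
  p$lb <- pmax(p$lb, -big_m); p$ub <- pmin(p$ub, big_m)

  # variables: v (n), yf (|hi|), yr (|hi|), y0 (|lo|)
  nh <- length(hi); nl <- length(lo)
  nv <- n + 2 * nh + nl
  iyf <- n + seq_len(nh)
  iyr <- n + nh + seq_len(nh)
  iy0 <- n + 2 * nh + seq_len(nl)

  A <- cbind(p$S, matrix(0, nrow(p$S), nv - n))
  b <- rep(0, nrow(p$S))

  ylb <- rep(0, nv - n)
  yub <- rep(1, nv - n)

  Glist <- list(); hlist <- list()
  add_ineq <- function(row, rhs) {
    Glist[[length(Glist) + 1]] <<- row; hlist[[length(hlist) + 1]] <<- rhs
  }
  for (k in seq_len(nh)) {
    j <- hi[k]
    # forward activity: v_j >= lb_j + yf (eps - lb_j)
    if (p$ub[j] < epsilon - 1e-9) yub[iyf[k] - n] <- 0   # can never reach eps
    row <- numeric(nv); row[j] <- 1; row[iyf[k]] <- -(epsilon - p$lb[j])
    add_ineq(row, p$lb[j])
    # reverse activity: v_j <= ub_j - yr (ub_j + eps)
    if (p$lb[j] > -epsilon + 1e-9) yub[iyr[k] - n] <- 0
    row <- numeric(nv); row[j] <- -1; row[iyr[k]] <- -(p$ub[j] + epsilon)
    add_ineq(row, -p$ub[j])
    # yf + yr <= 1
    row <- numeric(nv); row[iyf[k]] <- -1; row[iyr[k]] <- -1
    add_ineq(row, -1)
  }
  for (k in seq_len(nl)) {
    j <- lo[k]
    # inactive: lb_j (1 - y0) <= v_j <= ub_j (1 - y0)
    row <- numeric(nv); row[j] <- -1; row[iy0[k]] <- -p$ub[j]
    add_ineq(row, -p$ub[j])
    row <- numeric(nv); row[j] <- 1; row[iy0[k]] <- p$lb[j]
    add_ineq(row, p$lb[j])
    if (abs(p$lb[j]) < 1e-9 && abs(p$ub[j]) < 1e-9) ylb[iy0[k] - n] <- 1
  }
  # growth guarantee
  row <- numeric(nv); row[seq_len(n)] <- p$obj
  add_ineq(row, growth_rhs)

  G <- do.call(rbind, Glist); h <- unlist(hlist)
  lb <- c(p$lb, ylb)
  ub <- c(p$ub, yub)
  obj <- c(rep(0, n), rep(1, 2 * nh), rep(1, nl))

  sol <- milp_branch_bound(obj, A, b, lb, ub, G, h,
                           int_idx = c(iyf, iyr, iy0), max_nodes = max_nodes)
  if (is.null(sol))
    stop("iMAT branch and bound exceeded ", max_nodes,
         " nodes; consider a smaller model or fewer evidence categories")

  v <- sol$x[seq_len(n)]
  removed <- pan$rxns$id[lo][abs(v[lo]) <= 1e-6]
  inconsistent <- setdiff(pan$rxns$id[lo], removed)
  sub <- remove_reactions(pan, removed)
  chk <- solve_fba(sub)
  if (chk$status != "optimal" || chk$objective_value < growth_fraction * opt - 1e-6)
    stop("internal error: extracted model fails the growth guarantee")
  new_extraction_result(sub, removed, "imat", chk$objective_value, inconsistent)
}

# Depth-first branch and bound for maximization with binary variables.
# Returns list(x, objective) or NULL if the node budget is exhausted.
milp_branch_bound <- function(obj, A, b, lb, ub, G, h, int_idx,
                              max_nodes = 5000, int_tol = 1e-6) {
  best <- NULL; best_obj <- -Inf
  # stack of nodes: each node carries its own lb/ub
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1
    if (nodes > max_nodes) return(NULL)
    r <- solve_lp(obj, A, b, node$lb, node$ub, "max", G = G, h = h)
    if (r$status != 0) next
    # objective is a count, so the relaxation bound can be rounded down
    if (floor(r$objective + 1e-6) <= round(best_obj)) next
    frac <- abs(r$x[int_idx] - round(r$x[int_idx]))
    if (all(frac <= int_tol)) {
      if (r$objective > best_obj + 1e-9) {
        best_obj <- r$objective
        best <- list(x = r$x, objective = r$objective)
      }
      next
    }
    bj <- int_idx[which.max(frac)]
    up <- node; up$lb[bj] <- 1
    dn <- node; dn$ub[bj] <- 0
    # explore the rounded-up branch first (activity is usually achievable)
    stack[[length(stack) + 1]] <- dn
    stack[[length(stack) + 1]] <- up
  }
  best
}

new_extraction_result <- function(model, removed, algorithm, objective,
                                  inconsistent) {
  structure(list(model = model, removed = removed, algorithm = algorithm,
                 objective = objective, inconsistent = inconsistent),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result> %s: %d reactions kept, %d removed, growth %.4g\n",
              x$algorithm, nrow(x$model$rxns), length(x$removed), x$objective))
  if (length(x$inconsistent))
    cat("  kept despite low evidence:", paste(x$inconsistent, collapse = ", "), "\n")
  invisible(x)
}

#' Compare strain metabolic models
#'
#' For each model, reports the reactions present in it and absent from
#' every other model (model-specific reactions), the genes catalyzing
#' them (union of their GPR leaves), and subsystem tallies; plus the
#' metabolites not shared by all models (union minus intersection) and
#' the shared reaction core.
#'
#' @param models Named list of `metabolic_model`s (>= 2).
#' @return A `model_comparison`: list with `specific_reactions`,
#'   `specific_genes`, `specific_subsystems` (per model),
#'   `core_reactions`, `nonshared_metabolites`, `counts` (data.frame).
#' @export
compare_models <- function(models) {
  stopifnot(is.list(models), length(models) >= 2)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, function(m) m$id, character(1))
  rxn_sets <- lapply(models, function(m) m$rxns$id)
  met_sets <- lapply(models, function(m) m$mets$id)

  specific <- lapply(seq_along(models), function(i) {
    others <- Reduce(union, rxn_sets[-i])
    setdiff(rxn_sets[[i]], others)
  })
  names(specific) <- names(models)
  specific_genes <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    sort(unique(unlist(lapply(m$gprs[specific[[i]]], gpr_genes),
                       use.names = FALSE)))
  })
  names(specific_genes) <- names(models)
  specific_subsystems <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    idx <- match(specific[[i]], m$rxns$id)
    tab <- table(m$rxns$subsystem[idx])
    if (length(tab)) tab[order(-as.integer(tab), names(tab))] else tab
  })
  names(specific_subsystems) <- names(models)

  core <- Reduce(intersect, rxn_sets)
  met_union <- Reduce(union, met_sets)
  met_core <- Reduce(intersect, met_sets)
  nonshared <- sort(setdiff(met_union, met_core))

  counts <- data.frame(
    model = names(models),
    reactions = vapply(rxn_sets, length, integer(1)),
    metabolites = vapply(met_sets, length, integer(1)),
    specific_reactions = vapply(specific, length, integer(1)),
    specific_genes = vapply(specific_genes, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(specific_reactions = specific,
                 specific_genes = specific_genes,
                 specific_subsystems = specific_subsystems,
                 core_reactions = sort(core),
                 nonshared_metabolites = nonshared,
                 counts = counts),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$counts, row.names = FALSE)
  cat("shared reaction core:", length(x$core_reactions),
      "| metabolites not shared by all:", length(x$nonshared_metabolites), "\n")
  invisible(x)
}
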