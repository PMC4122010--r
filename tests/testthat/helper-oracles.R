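# Independent oracles used across the suite. These deliberately avoid the
# package's LP code paths.

# Brute-force FBA oracle: enumerate candidate vertices of
# {v : S v = 0, lb <= v <= ub} by fixing (n - m) variables at a bound in
# all combinations, solving the remaining square system, and keeping
# feasible points. Returns the maximal objective, or -Inf if no feasible
# vertex was found. Only for small n.
oracle_fba_optimum <- function(S, lb, ub, obj) {
  S <- as.matrix(S)
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  nfix <- n - r
  best <- -Inf
  if (nfix == 0) {
    v <- rep(0, n)  # Sv=0 full column rank => v = 0 the only candidate
    if (all(v >= lb - 1e-8 & v <= ub + 1e-8)) best <- sum(obj * v)
    return(best)
  }
  combs <- utils::combn(n, nfix)
  for (ci in seq_len(ncol(combs))) {
    fx <- combs[, ci]
    free <- setdiff(seq_len(n), fx)
    Af <- S[, free, drop = FALSE]
    if (qr(Af)$rank < length(free)) next
    grid <- expand.grid(rep(list(1:2), nfix))
    for (gi in seq_len(nrow(grid))) {
      xv <- numeric(n)
      bnd <- ifelse(unlist(grid[gi, ]) == 1, lb[fx], ub[fx])
      if (any(!is.finite(bnd))) next
      xv[fx] <- bnd
      rhs <- -S[, fx, drop = FALSE] %*% xv[fx]
      sol <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(S[, free, drop = FALSE] %*% sol - rhs)) > 1e-7) next
      xv[free] <- sol
      if (all(xv >= lb - 1e-8 & xv <= ub + 1e-8)) {
        best <- max(best, sum(obj * xv))
      }
    }
  }
  best
}

oracle_fba_model <- function(model) {
  oracle_fba_optimum(stoichiometric_matrix(model, sparse = FALSE),
                     model$rxns$lower_bound, model$rxns$upper_bound,
                     model$rxns$objective_coefficient)
}

# Exhaustive hypergeometric tail: P(X >= k) computed term by term from
# binomial coefficients (log scale), independent of stats::phyper.
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(n, K)
  terms <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(terms[ks >= k])
}

# Elemental balance of a reaction column given complete metabolite formulas.
oracle_element_balance <- function(model, rxn_id) {
  j <- match(rxn_id, model$rxns$id)
  col <- stoichiometric_matrix(model, sparse = FALSE)[, j]
  nz <- which(col != 0)
  tot <- list()
  for (i in nz) {
    el <- formula_elements(model$mets$formula[i])
    for (e in names(el)) tot[[e]] <- (tot[[e]] %||% 0) + col[i] * el[[e]]
  }
  unlist(tot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small helper: build a metabolic model from a compact reaction table.
quick_model <- function(id, rxns, mets = NULL, formulas = NULL) {
  met_ids <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  if (is.null(mets))
    mets <- data.frame(id = met_ids, stringsAsFactors = FALSE)
  if (!is.null(formulas)) mets$formula <- formulas[mets$id]
  metabolic_model(id, mets, rxns)
}
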