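# Internal LP interface over the C++ bounded-variable simplex.
#
# Problems are stated as:  optimize c'x  s.t.  A x = b,  G x >= h,
# lb <= x <= ub.  Inequalities are converted to equalities with
# nonnegative surplus variables before the solver is called.

LP_STATUS <- c(`0` = "optimal", `1` = "infeasible", `2` = "unbounded",
               `3` = "iteration_limit")

solve_lp <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                     G = NULL, h = NULL, maxit = 50000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == nrow(A))
  if (!is.null(G)) {
    G <- as.matrix(G)
    stopifnot(ncol(G) == n, length(h) == nrow(G))
    k <- nrow(G)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(G, -diag(k)))
    b <- c(b, h)
    obj <- c(obj, rep(0, k))
    lb <- c(lb, rep(0, k))
    ub <- c(ub, rep(Inf, k))
  }
  res <- .simplex_lp(A, as.numeric(b), as.numeric(obj),
                     as.numeric(lb), as.numeric(ub),
                     maximize = (sense == "max"), maxit = as.integer(maxit))
  res$status_str <- unname(LP_STATUS[as.character(res$status)])
  res$x <- res$x[seq_len(n)]
  res
}

# FBA problem pieces for a model: dense S, bounds, objective vector.
lp_pieces <- function(model) {
  list(S = as.matrix(model$stoich),
       lb = model$rxns$lower_bound,
       ub = model$rxns$upper_bound,
       obj = model$rxns$objective_coefficient)
}
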