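#' Apply a growth medium to a model
#'
#' Opens the listed exchange reactions for uptake (lower bound set to
#' minus the uptake rate), closes uptake through every other
#' carbon-containing exchange, and sets the oxygen exchange according to
#' the aerobic flag. Non-carbon exchanges (phosphate, CO2, water, ...)
#' are left untouched. Uptake is negative flux by convention.
#'
#' @param model A `metabolic_model`.
#' @param medium Named numeric vector: exchange reaction id -> maximum
#'   uptake rate (>= 0, mmol gDW^-1 h^-1).
#' @param aerobic Logical; when `TRUE` the oxygen exchange lower bound is
#'   set to `-o2_uptake`, when `FALSE` to 0.
#' @param o2_uptake Oxygen uptake cap under aerobic conditions
#'   (default 18 mmol gDW^-1 h^-1).
#' @param o2_id Oxygen exchange reaction id; auto-detected from the
#'   metabolite formula "O2" (or an id matching "o2") when `NULL`.
#' @return The model with modified exchange bounds.
#' @export
apply_medium <- function(model, medium, aerobic = TRUE, o2_uptake = 18,
                         o2_id = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  ex <- exchange_reactions(model)
  if (length(medium)) {
    if (is.null(names(medium))) stop("medium must be a named vector")
    if (any(medium < 0)) stop("uptake rates must be >= 0")
    unknown <- setdiff(names(medium), ex)
    if (length(unknown))
      stop("unknown exchange reaction(s): ", paste(unknown, collapse = ", "),
           "\nvalid exchanges: ", paste(ex, collapse = ", "))
  }
  if (is.null(o2_id)) o2_id <- find_o2_exchange(model)

  # classify exchanges by the carbon content of their single metabolite
  ex_idx <- match(ex, model$rxns$id)
  ex_met <- vapply(ex_idx, function(j) {
    rownames(model$stoich)[which(model$stoich[, j] != 0)[1]]
  }, character(1))
  carbon <- vapply(ex_met, function(m) {
    met_has_carbon(model$mets$formula[match(m, model$mets$id)])
  }, logical(1))

  for (k in seq_along(ex)) {
    rid <- ex[k]
    if (rid %in% names(medium)) {
      model <- set_bounds(model, rid, lower = -medium[[rid]])
    } else if (!is.na(o2_id) && rid == o2_id) {
      model <- set_bounds(model, rid, lower = if (aerobic) -o2_uptake else 0)
    } else if (carbon[k]) {
      model <- set_bounds(model, rid,
                          lower = 0,
                          upper = max(model$rxns$upper_bound[ex_idx[k]], 0))
    }
  }
  if (is.na(o2_id) && !aerobic)
    warning("no oxygen exchange found; anaerobic flag had no effect")
  model
}

find_o2_exchange <- function(model) {
  ex <- exchange_reactions(model)
  ex_idx <- match(ex, model$rxns$id)
  for (k in seq_along(ex)) {
    m <- rownames(model$stoich)[which(model$stoich[, ex_idx[k]] != 0)[1]]
    f <- model$mets$formula[match(m, model$mets$id)]
    if (identical(toupper(f), "O2")) return(ex[k])
  }
  hit <- grep("(^|_)o2(_|$)", ex, ignore.case = TRUE, value = TRUE)
  if (length(hit)) hit[1] else NA_character_
}

#' Flux balance analysis
#'
#' Solves the linear program optimize c'v subject to S v = 0 and
#' lb <= v <= ub, where c is the model's objective (normally the biomass
#' pseudo-reaction, whose flux is the growth rate in h^-1).
#'
#' @param model A `metabolic_model` with an objective reaction.
#' @param sense `"max"` (default) or `"min"`.
#' @return A `flux_result`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value` and `fluxes`
#'   (named vector over all reactions).
#' @export
solve_fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  validate_model(model, require_objective = TRUE)
  p <- lp_pieces(model)
  res <- solve_lp(p$obj, p$S, rep(0, nrow(p$S)), p$lb, p$ub, sense = sense)
  fluxes <- stats::setNames(res$x, model$rxns$id)
  if (res$status != 0) {
    return(structure(list(status = res$status_str,
                          objective_value = NA_real_,
                          fluxes = fluxes * NA_real_),
                     class = "flux_result"))
  }
  resid <- max(abs(p$S %*% res$x))
  if (resid > 1e-6)
    warning(sprintf("mass-balance residual %.2e exceeds tolerance", resid))
  structure(list(status = "optimal",
                 objective_value = res$objective,
                 fluxes = fluxes),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> status=%s objective=%.6g (%d reactions)\n",
              x$status, x$objective_value, length(x$fluxes)))
  invisible(x)
}

#' Flux variability analysis
#'
#' First computes the FBA optimum, then, for each reaction, minimizes and
#' maximizes its flux subject to the original constraints plus
#' c'v >= objective_fraction * optimum. Each reaction is classified as
#' `forward` (min >= 0, max > 0), `reverse` (max <= 0, min < 0),
#' `bidirectional` (min < 0 < max) or `blocked` (|min|, |max| < 1e-9).
#'
#' @param model A `metabolic_model` with an objective.
#' @param objective_fraction Fraction of the optimum to enforce, in (0, 1]
#'   (default 1.0, the optimal face).
#' @param reactions Reaction ids to analyse (default all).
#' @return An `fva_result` data.frame with columns `reaction`, `min_flux`,
#'   `max_flux`, `direction`; attributes `optimum` and `objective_fraction`.
#' @export
flux_variability <- function(model, objective_fraction = 1.0, reactions = NULL) {
  stopifnot(objective_fraction > 0, objective_fraction <= 1)
  fba <- solve_fba(model)
  if (fba$status != "optimal")
    stop("base FBA problem is ", fba$status, "; cannot run FVA")
  opt <- fba$objective_value
  if (is.null(reactions)) reactions <- model$rxns$id
  unknown <- setdiff(reactions, model$rxns$id)
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))

  p <- lp_pieces(model)
  G <- matrix(p$obj, nrow = 1)
  h <- objective_fraction * opt - 1e-9  # breathing room against cutting the optimum
  n <- ncol(p$S)
  out <- data.frame(reaction = reactions,
                    min_flux = NA_real_, max_flux = NA_real_,
                    direction = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$rxns$id)
    cj <- numeric(n); cj[j] <- 1
    lo <- solve_lp(cj, p$S, rep(0, nrow(p$S)), p$lb, p$ub, "min", G = G, h = h)
    hi <- solve_lp(cj, p$S, rep(0, nrow(p$S)), p$lb, p$ub, "max", G = G, h = h)
    if (lo$status != 0 || hi$status != 0)
      stop("FVA subproblem not optimal for reaction ", reactions[k])
    out$min_flux[k] <- lo$objective
    out$max_flux[k] <- hi$objective
  }
  tol <- 1e-9
  out$min_flux[abs(out$min_flux) < tol] <- 0
  out$max_flux[abs(out$max_flux) < tol] <- 0
  out$direction <- ifelse(out$min_flux == 0 & out$max_flux == 0, "blocked",
                   ifelse(out$min_flux >= 0 & out$max_flux > 0, "forward",
                   ifelse(out$max_flux <= 0 & out$min_flux < 0, "reverse",
                          "bidirectional")))
  attr(out, "optimum") <- opt
  attr(out, "objective_fraction") <- objective_fraction
  class(out) <- c("fva_result", "data.frame")
  out
}

#' Robustness scan of a reaction's effect on the objective
#'
#' Fixes the chosen reaction's flux at `n_points` evenly spaced values
#' across its feasible range (min/max flux subject to mass balance and
#' bounds, objective unconstrained) and re-solves FBA at each point.
#'
#' @param model A `metabolic_model` with an objective.
#' @param reaction_id Reaction to scan.
#' @param n_points Number of grid points (>= 2, default 20).
#' @return A `robustness_curve` data.frame with columns `value`,
#'   `objective`, `status`; infeasible points carry `NA` objectives.
#' @export
robustness_scan <- function(model, reaction_id, n_points = 20) {
  stopifnot(n_points >= 2)
  j <- match(reaction_id, model$rxns$id)
  if (is.na(j)) stop("unknown reaction: ", reaction_id)
  validate_model(model, require_objective = TRUE)
  p <- lp_pieces(model)
  n <- ncol(p$S)
  cj <- numeric(n); cj[j] <- 1
  lo <- solve_lp(cj, p$S, rep(0, nrow(p$S)), p$lb, p$ub, "min")
  hi <- solve_lp(cj, p$S, rep(0, nrow(p$S)), p$lb, p$ub, "max")
  if (lo$status != 0 || hi$status != 0)
    stop("model infeasible; cannot scan ", reaction_id)
  grid <- seq(lo$objective, hi$objective, length.out = n_points)
  out <- data.frame(value = grid, objective = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(n_points)) {
    mk <- set_bounds(model, reaction_id, lower = grid[k], upper = grid[k])
    r <- solve_fba(mk)
    out$objective[k] <- if (r$status == "optimal") r$objective_value else NA_real_
    out$status[k] <- r$status
  }
  attr(out, "reaction") <- reaction_id
  class(out) <- c("robustness_curve", "data.frame")
  out
}
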