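#' Simulate growth under a set of diet conditions
#'
#' For each condition (one open carbon source at a given uptake rate,
#' aerobic or anaerobic) the medium is applied and FBA solved.
#' Infeasible conditions (typically: maintenance ATP cannot be met) are
#' reported as zero growth with their status flagged.
#'
#' @param model A `metabolic_model`.
#' @param conditions data.frame with columns `source` (carbon exchange
#'   reaction id), `uptake` (> 0, mmol gDW^-1 h^-1) and `aerobic`
#'   (logical); an optional `condition` column names each row.
#' @param o2_uptake Oxygen bound under aerobic conditions (default 18).
#' @return A list with `growth` (data.frame: condition, source, uptake,
#'   aerobic, growth, status) and `fluxes` (named list of full flux
#'   vectors, NULL entries for infeasible conditions).
#' @export
simulate_conditions <- function(model, conditions, o2_uptake = 18) {
  stopifnot(is.data.frame(conditions),
            all(c("source", "uptake", "aerobic") %in% names(conditions)))
  if (any(conditions$uptake < 0)) stop("uptake rates must be >= 0")
  ex <- exchange_reactions(model)
  missing_ex <- setdiff(unique(conditions$source), ex)
  if (length(missing_ex))
    stop("model lacks exchange reaction(s): ",
         paste(missing_ex, collapse = ", "))
  cond_names <- conditions$condition %||% paste0(
    sub("^EX_", "", conditions$source), "_",
    ifelse(conditions$aerobic, "aerobic", "anaerobic"))

  growth <- data.frame(condition = cond_names,
                       source = conditions$source,
                       uptake = conditions$uptake,
                       aerobic = conditions$aerobic,
                       growth = NA_real_, status = NA_character_,
                       stringsAsFactors = FALSE)
  fluxes <- stats::setNames(vector("list", nrow(conditions)), cond_names)
  for (i in seq_len(nrow(conditions))) {
    m <- apply_medium(model,
                      stats::setNames(conditions$uptake[i], conditions$source[i]),
                      aerobic = conditions$aerobic[i], o2_uptake = o2_uptake)
    r <- solve_fba(m)
    if (r$status == "optimal") {
      growth$growth[i] <- r$objective_value
      fluxes[[i]] <- r$fluxes
    } else {
      growth$growth[i] <- 0
    }
    growth$status[i] <- r$status
  }
  list(growth = growth, fluxes = fluxes)
}

#' Diet-stress reactions between two flux distributions
#'
#' A reaction is diet-stressed between conditions x and y when its
#' optimal flux changes by more than 10%: |flux_x| > 1.1 |flux_y| or
#' |flux_x| < 0.9 |flux_y|. The comparison is on flux magnitudes; a
#' reaction that reverses direction (nonzero fluxes of opposite sign) is
#' always stressed, a flux appearing from or vanishing to zero is
#' stressed, and a zero/zero pair never is (the ratio criterion is
#' undefined at y = 0; this closure is the documented convention).
#'
#' @param flux_x,flux_y Named flux vectors over identical reaction sets.
#' @param lower,upper Ratio window bounds (defaults 0.9 and 1.1).
#' @param zero_tol Magnitudes below this count as zero flux (1e-9).
#' @return A `diet_stress_report`: data.frame with columns `reaction`,
#'   `flux_x`, `flux_y`, `ratio` (|x|/|y|, NA when |y| = 0) and
#'   `stressed`.
#' @export
diet_stress_reactions <- function(flux_x, flux_y, lower = 0.9, upper = 1.1,
                                  zero_tol = 1e-9) {
  if (is.null(names(flux_x)) || is.null(names(flux_y)))
    stop("flux vectors must be named by reaction id")
  if (!setequal(names(flux_x), names(flux_y)))
    stop("flux vectors cover different reaction sets")
  flux_y <- flux_y[names(flux_x)]
  ax <- abs(flux_x); ay <- abs(flux_y)
  zero_x <- ax < zero_tol; zero_y <- ay < zero_tol
  sign_flip <- !zero_x & !zero_y & (sign(flux_x) != sign(flux_y))
  ratio <- ifelse(zero_y, NA_real_, ax / ay)
  stressed <- ifelse(zero_x & zero_y, FALSE,
              ifelse(xor(zero_x, zero_y), TRUE,
              ifelse(sign_flip, TRUE,
                     ratio > upper | ratio < lower)))
  out <- data.frame(reaction = names(flux_x),
                    flux_x = as.numeric(flux_x),
                    flux_y = as.numeric(flux_y),
                    ratio = ratio, stressed = stressed,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("diet_stress_report", "data.frame")
  out
}

#' Genes associated with diet-stressed reactions
#'
#' The union of GPR leaf genes over the stressed reactions; reactions
#' with an empty GPR contribute nothing.
#'
#' @param report A `diet_stress_report`.
#' @param model The `metabolic_model` the fluxes came from.
#' @return Sorted character vector of gene ids.
#' @export
stress_genes <- function(report, model) {
  stopifnot(inherits(report, "diet_stress_report"),
            inherits(model, "metabolic_model"))
  stressed <- report$reaction[report$stressed]
  unknown <- setdiff(stressed, model$rxns$id)
  if (length(unknown))
    stop("stressed reaction(s) not in model: ", paste(unknown, collapse = ", "))
  sort(unique(unlist(lapply(model$gprs[stressed], gpr_genes),
                     use.names = FALSE)))
}
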