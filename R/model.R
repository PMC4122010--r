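#' Construct a metabolic model
#'
#' The central container for constraint-based analysis: metabolites,
#' reactions with bounds and GPR rules, and the stoichiometric matrix.
#' Bounds are in mmol gDW^-1 h^-1; the sign convention for exchange
#' reactions is negative flux = uptake, positive flux = secretion.
#'
#' @param id Model identifier.
#' @param metabolites data.frame with columns `id` (required) and
#'   optionally `name`, `formula`, `charge`, `compartment`.
#' @param reactions list of reactions, each a list with elements `id`,
#'   `stoichiometry` (named numeric, metabolite id -> coefficient,
#'   negative = consumed), and optionally `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `gpr` (rule string),
#'   `objective_coefficient`. Missing bounds default to [-1000, 1000]
#'   when `reversible = TRUE` (the default) or [0, 1000] otherwise.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions) {
  stopifnot(is.character(id), length(id) == 1)
  mets <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(mets$id)) stop("metabolites need an 'id' column")
  mets$id <- as.character(mets$id)
  for (col in c("name", "formula", "compartment")) {
    if (is.null(mets[[col]])) mets[[col]] <- ""
    mets[[col]] <- as.character(mets[[col]])
  }
  if (is.null(mets$charge)) mets$charge <- 0L
  mets$charge[is.na(mets$charge)] <- 0L
  mets$compartment[!nzchar(mets$compartment)] <- "c"
  mets <- mets[, c("id", "name", "formula", "charge", "compartment")]
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (any(!nzchar(mets$id))) stop("empty metabolite id")

  rids <- vapply(reactions, function(r) as.character(r$id %||% ""), character(1))
  if (any(!nzchar(rids))) stop("every reaction needs a non-empty id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))

  n <- length(reactions); m <- nrow(mets)
  get_num <- function(r, f, d) { v <- r[[f]]; if (is.null(v) || is.na(v)) d else as.numeric(v) }
  rev_default <- vapply(reactions, function(r) isTRUE(r$reversible %||% TRUE), logical(1))
  lb <- mapply(function(r, rv) get_num(r, "lower_bound", if (rv) -1000 else 0),
               reactions, rev_default)
  ub <- vapply(reactions, function(r) get_num(r, "upper_bound", 1000), numeric(1))
  if (any(lb > ub)) stop("reaction with lower_bound > upper_bound: ",
                         paste(rids[lb > ub], collapse = ", "))

  rxns <- data.frame(
    id = rids,
    name = vapply(reactions, function(r) as.character(r$name %||% r$id), character(1)),
    lower_bound = as.numeric(lb),
    upper_bound = as.numeric(ub),
    subsystem = vapply(reactions, function(r) as.character(r$subsystem %||% ""), character(1)),
    objective_coefficient = vapply(reactions, function(r)
      get_num(r, "objective_coefficient", 0), numeric(1)),
    gpr = vapply(reactions, function(r) {
      g <- r$gpr %||% ""
      if (inherits(g, "gpr_rule")) gpr_to_string(g) else as.character(g)
    }, character(1)),
    stringsAsFactors = FALSE
  )

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_len(m), mets$id)
  for (j in seq_len(n)) {
    st <- reactions[[j]]$stoichiometry
    if (is.null(st) || length(st) == 0)
      stop("reaction '", rids[j], "' has empty stoichiometry")
    st <- st[st != 0]
    if (length(st) == 0)
      stop("reaction '", rids[j], "' has all-zero stoichiometry")
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction '", rids[j], "' references undeclared metabolites: ",
           paste(unknown, collapse = ", "))
    ii <- c(ii, met_index[names(st)])
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n),
                            dimnames = list(mets$id, rxns$id))

  gprs <- lapply(rxns$gpr, parse_gpr)
  names(gprs) <- rxns$id

  structure(list(id = id, mets = mets, rxns = rxns, stoich = S, gprs = gprs),
            class = "metabolic_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$mets), nrow(x$rxns), length(model_genes(x))))
  obj <- x$rxns$id[x$rxns$objective_coefficient != 0]
  if (length(obj)) cat("  objective:", paste(obj, collapse = ", "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Rows follow metabolite declaration order, columns reaction declaration
#' order; `S[i, j]` is the coefficient of metabolite i in reaction j
#' (negative = consumed).
#'
#' @param model A `metabolic_model`.
#' @param sparse Return the sparse `Matrix` form (default) or a dense matrix.
#' @return m x n matrix with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (sparse) model$stoich else as.matrix(model$stoich)
}

#' Gene ids appearing in a model's GPR rules
#' @param model A `metabolic_model`.
#' @return Sorted character vector.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$gprs, gpr_genes), use.names = FALSE)))
}

#' Exchange reactions of a model
#'
#' An exchange (or demand/sink) reaction involves exactly one metabolite:
#' its column of S has a single nonzero entry.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- Matrix::colSums(model$stoich != 0)
  model$rxns$id[nz == 1]
}

objective_index <- function(model) {
  which(model$rxns$objective_coefficient != 0)
}

#' Validate a metabolic model's invariants
#'
#' Checks id uniqueness, bound ordering, stoichiometry references and
#' (optionally) the presence of an objective reaction.
#'
#' @param model A `metabolic_model`.
#' @param require_objective Require at least one reaction with a nonzero
#'   objective coefficient (needed for growth simulations).
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_model <- function(model, require_objective = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (anyDuplicated(model$mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(model$rxns$id)) stop("duplicate reaction ids")
  if (any(model$rxns$lower_bound > model$rxns$upper_bound))
    stop("lower_bound > upper_bound")
  if (any(Matrix::colSums(model$stoich != 0) == 0))
    stop("reaction with empty stoichiometry column")
  if (require_objective && length(objective_index(model)) == 0)
    stop("model has no objective reaction")
  invisible(TRUE)
}

#' Restrict a model to a subset of reactions
#'
#' Drops the named reactions and then any orphan metabolites (metabolites
#' appearing in no remaining reaction). This removal semantics defines
#' "model-specific metabolites" in model comparisons.
#'
#' @param model A `metabolic_model`.
#' @param remove Character vector of reaction ids to drop.
#' @return A new `metabolic_model`.
#' @export
remove_reactions <- function(model, remove) {
  stopifnot(inherits(model, "metabolic_model"))
  unknown <- setdiff(remove, model$rxns$id)
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  keep <- !(model$rxns$id %in% remove)
  S <- model$stoich[, keep, drop = FALSE]
  met_keep <- Matrix::rowSums(S != 0) > 0
  out <- model
  out$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(out$rxns) <- NULL
  out$mets <- model$mets[met_keep, , drop = FALSE]
  rownames(out$mets) <- NULL
  out$stoich <- S[met_keep, , drop = FALSE]
  out$gprs <- model$gprs[keep]
  out
}

#' Set reaction bounds
#'
#' @param model A `metabolic_model`.
#' @param reaction Reaction id.
#' @param lower,upper New bounds (either may be `NULL` to keep current).
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  i <- match(reaction, model$rxns$id)
  if (is.na(i)) stop("unknown reaction: ", reaction)
  if (!is.null(lower)) model$rxns$lower_bound[i] <- lower
  if (!is.null(upper)) model$rxns$upper_bound[i] <- upper
  if (model$rxns$lower_bound[i] > model$rxns$upper_bound[i])
    stop("lower_bound > upper_bound for ", reaction)
  model
}

#' Parse a chemical formula into element counts
#'
#' Accepts Hill-style formulas, possibly with R pseudo-elements for
#' residues (e.g. "C3H6NOR"). Used for carbon-source detection and
#' elemental balance checks.
#'
#' @param formula Character scalar (may be empty).
#' @return Named numeric vector of element counts (empty for empty input).
#' @export
formula_elements <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(gsub("[^A-Za-z0-9]", "", formula))) {
    warning("formula not fully parsed: ", formula)
  }
  el <- sub("[0-9]*$", "", parts)
  cnt <- as.numeric(sub("^[A-Za-z]+", "", parts))
  cnt[is.na(cnt)] <- 1
  tapply(cnt, el, sum)[unique(el)]
}

met_has_carbon <- function(formula) {
  el <- formula_elements(formula)
  "C" %in% names(el) && el[["C"]] > 0
}
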