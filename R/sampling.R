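#' Uniform flux sampling by artificial-centering hit-and-run
#'
#' Draws near-uniform samples from the feasible flux polytope
#' \{v : S v = 0, lb <= v <= ub\}. Warmup points are optimal vertices of
#' LPs with standard-normal random objectives; chain directions are
#' differences between a random warmup point and the running center of
#' mass, so every step remains in the null space of S. One integer seed
#' controls warmup objectives and the chain; the same seed yields a
#' bit-identical sample matrix.
#'
#' @param model A `metabolic_model` (must be feasible).
#' @param n_samples Number of samples to return (>= 1).
#' @param seed Integer seed.
#' @param thinning Chain steps per retained sample (default 100).
#' @param n_warmup Number of warmup vertices (default 2 x n_reactions).
#' @param at_optimum Optional fraction f in (0, 1]: restricts sampling to
#'   \{c'v >= f * FBA optimum\}. `NULL` (default) samples the whole
#'   solution space.
#' @return A `flux_samples` object: list with `samples` (n_samples x
#'   n_reactions matrix, columns named by reaction id), `seed`,
#'   `thinning`, `n_warmup`.
#' @export
sample_fluxes <- function(model, n_samples, seed, thinning = 100,
                          n_warmup = NULL, at_optimum = NULL) {
  stopifnot(inherits(model, "metabolic_model"), n_samples >= 1)
  p <- lp_pieces(model)
  n <- ncol(p$S)
  if (is.null(n_warmup)) n_warmup <- 2L * n
  n_warmup <- max(4L, as.integer(n_warmup))

  G <- NULL; h <- NULL
  if (!is.null(at_optimum)) {
    stopifnot(at_optimum > 0, at_optimum <= 1)
    fba <- solve_fba(model)
    if (fba$status != "optimal") stop("model is ", fba$status, "; cannot sample")
    G <- matrix(p$obj, nrow = 1)
    h <- at_optimum * fba$objective_value - 1e-9
  } else {
    # feasibility check before sampling
    chk <- solve_lp(rep(0, n), p$S, rep(0, nrow(p$S)), p$lb, p$ub, "min")
    if (chk$status != 0)
      stop("model is ", chk$status_str, "; cannot sample")
  }

  set.seed(seed)
  warmup <- matrix(NA_real_, n_warmup, n)
  for (k in seq_len(n_warmup)) {
    cc <- stats::rnorm(n)
    r <- solve_lp(cc, p$S, rep(0, nrow(p$S)), p$lb, p$ub, "max", G = G, h = h)
    if (r$status != 0) stop("warmup LP ", k, " returned ", r$status_str)
    warmup[k, ] <- r$x
  }

  Gm <- if (is.null(G)) matrix(0, 0, n) else G
  hv <- if (is.null(h)) numeric(0) else h
  samples <- .achr_chain(warmup, p$lb, p$ub, Gm, hv,
                         as.integer(n_samples), as.integer(thinning))
  colnames(samples) <- model$rxns$id
  structure(list(samples = samples, seed = seed, thinning = thinning,
                 n_warmup = n_warmup, at_optimum = at_optimum,
                 model_id = model$id),
            class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat(sprintf("<flux_samples> %d samples x %d reactions (seed %d, thinning %d)\n",
              nrow(x$samples), ncol(x$samples), x$seed, x$thinning))
  invisible(x)
}

#' Pairwise Pearson correlations between sampled reaction fluxes
#'
#' @param samples A `flux_samples`.
#' @param pairs Two-column matrix/data.frame of reaction id pairs, or a
#'   list of length-2 character vectors.
#' @return data.frame with columns `rxn1`, `rxn2`, `correlation`,
#'   `n_samples`. Pairs where either flux is constant across samples get
#'   `NA` correlation (undefined).
#' @export
flux_correlations <- function(samples, pairs) {
  stopifnot(inherits(samples, "flux_samples"))
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  known <- colnames(samples$samples)
  unknown <- setdiff(unique(as.vector(pairs)), known)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  n <- nrow(samples$samples)
  out <- data.frame(rxn1 = pairs[, 1], rxn2 = pairs[, 2],
                    correlation = NA_real_, n_samples = n,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    a <- samples$samples[, pairs[k, 1]]
    b <- samples$samples[, pairs[k, 2]]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) next  # constant: undefined
    out$correlation[k] <- stats::cor(a, b)
  }
  out
}

#' Write a sampling report: histograms, scatterplots and correlations
#'
#' Produces one flux histogram per reaction, one scatterplot per
#' reaction pair, and the full correlation matrix as TSV.
#'
#' @param samples A `flux_samples`.
#' @param reactions Character vector of reactions to report on.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (paths written) and
#'   `correlations` (the correlation matrix).
#' @export
sampling_report <- function(samples, reactions, dir) {
  stopifnot(inherits(samples, "flux_samples"))
  if (length(reactions) == 0) {
    warning("no reactions requested; empty report")
    return(invisible(list(files = character(0), correlations = matrix(0, 0, 0))))
  }
  unknown <- setdiff(reactions, colnames(samples$samples))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  for (rid in reactions) {
    f <- file.path(dir, paste0("hist_", gsub("[^A-Za-z0-9_.-]", "_", rid), ".pdf"))
    grDevices::pdf(f, width = 4, height = 4)
    graphics::hist(samples$samples[, rid], breaks = 30, main = rid,
                   xlab = "flux (mmol gDW^-1 h^-1)", col = "grey80")
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (length(reactions) >= 2) {
    combs <- utils::combn(reactions, 2)
    for (k in seq_len(ncol(combs))) {
      a <- combs[1, k]; b <- combs[2, k]
      f <- file.path(dir, paste0("scatter_",
             gsub("[^A-Za-z0-9_.-]", "_", a), "_vs_",
             gsub("[^A-Za-z0-9_.-]", "_", b), ".pdf"))
      grDevices::pdf(f, width = 4, height = 4)
      graphics::plot(samples$samples[, a], samples$samples[, b],
                     pch = 16, cex = 0.4, col = grDevices::grey(0.2, 0.35),
                     xlab = a, ylab = b)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  cm <- stats::cor(samples$samples[, reactions, drop = FALSE])
  ctab <- file.path(dir, "correlations.tsv")
  utils::write.table(round(cm, 6), ctab, sep = "\t", quote = FALSE,
                     col.names = NA)
  files <- c(files, ctab)
  invisible(list(files = files, correlations = cm))
}
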