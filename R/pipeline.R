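#' Run the end-to-end strain analysis pipeline
#'
#' Orchestrates the analysis stages in dependency order — strain
#' detection from alignments, context-specific model extraction, model
#' comparison, FBA, FVA, flux sampling and diet simulation — writing
#' per-stage TSV/JSON outputs and a JSON run manifest (inputs, seeds,
#' stage status, output checksums). Re-running with an existing manifest
#' skips stages whose outputs are already present unless `force = TRUE`.
#'
#' @param config A configuration list, or the path of a YAML file
#'   holding one. Recognized fields:
#'   \describe{
#'     \item{out_dir}{Output directory (required).}
#'     \item{seed}{Integer seed for stochastic stages (default 1).}
#'     \item{stages}{Character vector among `detect`, `extract`,
#'       `compare`, `fba`, `fva`, `sample`, `diet` (default all).}
#'     \item{pan_model}{Path to the pan-genome model (SBML/JSON).
#'       When absent, the synthetic pan generator is used.}
#'     \item{profiles}{Named list of TSV paths (gene_id, score) per
#'       strain; synthetic profiles are used when absent.}
#'     \item{alignments}{Named list (per sample) of BLAST outfmt-6
#'       paths; a synthetic cohort is generated when absent.}
#'     \item{genome_length}{Reference genome length for coverage.}
#'     \item{thresholds}{List overriding `identity` (99), `depth` (10),
#'       `gene_fraction` (0.8), `growth_fraction` (0.9),
#'       `fva_fraction` (1.0), `extraction` ("gimme" or "imat").}
#'     \item{sampling}{List: `n_samples` (500), `thinning` (100).}
#'     \item{diet}{data.frame-able list of conditions (source, uptake,
#'       aerobic); defaults to the four carbon sources at uptake 9.}
#'   }
#' @param force Re-run stages whose outputs already exist.
#' @return The run manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("detect", "extract", "compare", "fba",
                                 "fva", "sample", "diet")
  th <- utils::modifyList(
    list(identity = 99, depth = 10, gene_fraction = 0.8,
         growth_fraction = 0.9, fva_fraction = 1.0, extraction = "gimme"),
    config$thresholds %||% list())
  smp <- utils::modifyList(list(n_samples = 500, thinning = 100),
                           config$sampling %||% list())

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(seed = seed, thresholds = th, stages = list())

  done <- function(files) all(file.exists(files))
  record <- function(stage, files, skipped = FALSE) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      skipped = skipped)
  }
  run_stage <- function(stage, files, fun) {
    if (!(stage %in% stages)) return(invisible(NULL))
    if (!force && done(files)) { record(stage, files, skipped = TRUE); return(invisible(NULL)) }
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) stop("pipeline stage '", stage,
                                            "' failed: ", conditionMessage(e),
                                            call. = FALSE))
    record(stage, files)
  }

  # ---- inputs ----
  if (!is.null(config$pan_model)) {
    pw <- NULL
    pan <- read_model(config$pan_model)
    profiles <- lapply(config$profiles %||% list(), function(p) {
      tab <- utils::read.delim(p, header = TRUE, stringsAsFactors = FALSE)
      presence_profile(tools::file_path_sans_ext(basename(p)),
                       stats::setNames(tab[[2]], tab[[1]]))
    })
  } else {
    pw <- make_pan_with_strains(seed = seed)
    pan <- pw$pan
    profiles <- pw$profiles
  }

  # ---- detect ----
  f_detect <- file.path(out_dir, c("strain_calls.tsv"))
  run_stage("detect", f_detect, function() {
    if (!is.null(config$alignments)) {
      alns <- lapply(config$alignments, read_alignments)
      glen <- config$genome_length %||% stop("genome_length required")
    } else {
      coh <- planted_cohort(
        n_samples = 10,
        strains = data.frame(strain = c("HS", "UTI89", "CFT073"),
                             prevalence = c(1.0, 0.8, 0.6),
                             depth = c(20, 15, 12),
                             identity = c(99.6, 99.5, 99.4)),
        seed = seed)
      ma <- make_alignments(coh)
      alns <- ma$alignments
      glen <- ma$genome_length
    }
    cov <- coverage_table(alns, glen, min_identity = th$identity)
    calls <- call_strains(cov, depth_threshold = th$depth)
    utils::write.table(calls, f_detect[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # ---- extract ----
  strain_files <- file.path(out_dir, paste0("model_", names(profiles), ".json"))
  run_stage("extract", strain_files, function() {
    for (i in seq_along(profiles)) {
      res <- if (th$extraction == "imat")
        imat_extract(pan, profiles[[i]], growth_fraction = th$growth_fraction)
      else
        gimme_extract(pan, profiles[[i]], growth_fraction = th$growth_fraction)
      write_model(res$model, strain_files[i])
    }
  })

  # ---- compare ----
  f_cmp <- file.path(out_dir, c("comparison_counts.tsv", "comparison.json"))
  run_stage("compare", f_cmp, function() {
    models <- lapply(strain_files, read_model)
    names(models) <- names(profiles)
    cmp <- compare_models(models)
    utils::write.table(cmp$counts, f_cmp[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(specific_reactions = cmp$specific_reactions,
           specific_genes = cmp$specific_genes,
           nonshared_metabolites = cmp$nonshared_metabolites),
      f_cmp[2], auto_unbox = FALSE, pretty = TRUE)
  })

  # ---- fba ----
  f_fba <- file.path(out_dir, "fba_fluxes.tsv")
  run_stage("fba", f_fba, function() {
    r <- solve_fba(pan)
    utils::write.table(
      data.frame(reaction = names(r$fluxes), flux = as.numeric(r$fluxes)),
      f_fba, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # ---- fva ----
  f_fva <- file.path(out_dir, "fva.tsv")
  run_stage("fva", f_fva, function() {
    fva <- flux_variability(pan, objective_fraction = th$fva_fraction)
    utils::write.table(fva, f_fva, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # ---- sample ----
  f_smp <- file.path(out_dir, "samples.tsv")
  run_stage("sample", f_smp, function() {
    s <- sample_fluxes(pan, n_samples = smp$n_samples, seed = seed,
                       thinning = smp$thinning)
    utils::write.table(round(s$samples, 8), f_smp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # ---- diet ----
  f_diet <- file.path(out_dir, "diet_growth.tsv")
  run_stage("diet", f_diet, function() {
    cond <- if (!is.null(config$diet)) as.data.frame(config$diet) else
      data.frame(source = c("EX_ac_e", "EX_etoh_e", "EX_glc_e", "EX_succ_e"),
                 uptake = 9, aerobic = TRUE, stringsAsFactors = FALSE)
    sim <- simulate_conditions(pan, cond)
    utils::write.table(sim$growth, f_diet, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a markdown summary from a pipeline manifest
#'
#' Builds a deterministic markdown report from the stage outputs
#' recorded in a manifest: strain calls, model comparison counts,
#' diet growth table and FVA ranges. Sections whose outputs are missing
#' are omitted with a notice.
#'
#' @param manifest A manifest list (from [run_pipeline()]) or the path
#'   of a `manifest.json`.
#' @param path Output markdown file; default `report.md` next to the
#'   manifest outputs.
#' @return The report path, invisibly.
#' @export
render_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    mdir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest)
  } else {
    first <- unlist(lapply(manifest$stages, function(s) unlist(s$outputs)))
    mdir <- if (length(first)) dirname(first[[1]]) else "."
  }
  if (is.null(path)) path <- file.path(mdir, "report.md")
  lines <- c("# gutflux pipeline report", "")

  get_out <- function(stage) {
    s <- manifest$stages[[stage]]
    if (is.null(s)) return(NULL)
    f <- unlist(s$outputs)
    f[file.exists(f)]
  }
  tsv_section <- function(stage, title, file_match = NULL) {
    f <- get_out(stage)
    if (!is.null(file_match) && length(f)) f <- grep(file_match, f, value = TRUE)
    if (length(f) == 0) {
      lines <<- c(lines, paste0("## ", title), "",
                  "_stage output missing; section omitted_", "")
      return(invisible(NULL))
    }
    tab <- utils::read.delim(f[1], stringsAsFactors = FALSE)
    lines <<- c(lines, paste0("## ", title), "", md_table(tab), "")
  }

  tsv_section("detect", "Strain calls")
  tsv_section("compare", "Model comparison", "counts")
  tsv_section("diet", "Growth by diet condition")
  tsv_section("fva", "Flux variability")
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df, max_rows = 30) {
  df <- utils::head(df, max_rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 5))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}
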