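#' Read a metabolic model from SBML or JSON
#'
#' Supports two SBML dialects: legacy Level 2 with bounds in
#' `kineticLaw` parameters (`LOWER_BOUND`, `UPPER_BOUND`,
#' `OBJECTIVE_COEFFICIENT`) and GPRs in notes (`GENE_ASSOCIATION: ...`),
#' and Level 3 with the `fbc` package (flux-bound parameters, gene
#' product associations, objectives). The JSON dialect mirrors the
#' model container: `metabolites[]` and `reactions[]` with stoichiometry
#' maps, bounds, a `gpr` string and an objective coefficient.
#' Missing bounds default to [-1000, 1000] for reversible and [0, 1000]
#' for irreversible reactions.
#'
#' @param path File path.
#' @param format `"auto"` (sniff by extension/content), `"sbml"` or `"json"`.
#' @return A `metabolic_model`.
#' @seealso [write_model()]
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
      else if (ext == "json") "json"
      else {
        head <- readChar(path, nchars = 200)
        if (grepl("^\\s*[{\\[]", head)) "json" else "sbml"
      }
  }
  switch(format, sbml = read_model_sbml(path), json = read_model_json(path))
}

#' Write a metabolic model to SBML (Level 3 + fbc) or JSON
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  stopifnot(inherits(model, "metabolic_model"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "sbml"
  }
  switch(format,
         sbml = write_model_sbml(model, path),
         json = write_model_json(model, path))
  invisible(path)
}

## ---- JSON dialect ----

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("JSON model must contain 'metabolites' and 'reactions' arrays")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id %||% stop("metabolite without id"),
               name = m$name %||% "", formula = m$formula %||% "",
               charge = as.integer(m$charge %||% 0L),
               compartment = m$compartment %||% "c",
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    list(id = r$id %||% stop("reaction without id"),
         name = r$name %||% r$id,
         stoichiometry = st,
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem %||% "",
         gpr = r$gpr %||% "",
         objective_coefficient = r$objective_coefficient %||% 0)
  })
  metabolic_model(doc$id %||% tools::file_path_sans_ext(basename(path)),
                  mets, rxns)
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$mets)), function(i) {
      m <- model$mets[i, ]
      list(id = m$id, name = m$name, formula = m$formula,
           charge = m$charge, compartment = m$compartment)
    }),
    reactions = lapply(seq_len(nrow(model$rxns)), function(j) {
      r <- model$rxns[j, ]
      col <- model$stoich[, j]
      nz <- which(col != 0)
      list(id = r$id, name = r$name,
           stoichiometry = as.list(stats::setNames(col[nz], rownames(model$stoich)[nz])),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           subsystem = r$subsystem, gpr = r$gpr,
           objective_coefficient = r$objective_coefficient)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## ---- SBML ----

sbml_mangle <- function(id) {
  # SBML SIds cannot contain arbitrary punctuation; digit-leading ids are
  # legal here because the writer always adds an M_/R_/G_ type prefix
  gsub("[^A-Za-z0-9_]", "__", id)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("XML parse error in ", path, ": ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  # fbc flux-bound parameters (L3)
  params <- xml2::xml_find_all(model_node, ".//*[local-name()='parameter']")
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  # fbc gene products id -> label
  gps <- xml2::xml_find_all(model_node, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           xml2::xml_attr(gps, "id"), xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  # fbc objective
  fluxobjs <- xml2::xml_find_all(model_node, ".//*[local-name()='fluxObjective']")
  obj_map <- stats::setNames(
    as.numeric(sapply(fluxobjs, function(n) {
      v <- xml2::xml_attr(n, "coefficient")
      if (is.na(v)) 1 else as.numeric(v)
    })),
    sapply(fluxobjs, function(n) xml2::xml_attr(n, "reaction")))

  sp <- xml2::xml_find_all(model_node,
          ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp) == 0) stop("no species found in ", path)
  sp_boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "", xml2::xml_attr(sp, "name")),
    formula = vapply(sp, sbml_species_formula, character(1)),
    charge = vapply(sp, sbml_species_charge, numeric(1)),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "c",
                         xml2::xml_attr(sp, "compartment")),
    stringsAsFactors = FALSE
  )
  boundary_ids <- mets$id[sp_boundary]
  mets <- mets[!sp_boundary, , drop = FALSE]

  # COBRA-convention prefixes: strip uniform M_ / R_ prefixes on read
  strip_prefix <- function(ids, pre) {
    if (length(ids) && all(startsWith(ids, pre))) substring(ids, nchar(pre) + 1)
    else ids
  }
  met_map <- stats::setNames(strip_prefix(mets$id, "M_"), mets$id)
  mets$id <- unname(met_map)

  rx_nodes <- xml2::xml_find_all(model_node,
          ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop("no reactions found in ", path)

  rxns <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) stop("reaction without id in ", path)
    reversible <- !identical(xml2::xml_attr(node, "reversible"), "false")

    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (length(refs) == 0) next
      sids <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      for (k in seq_along(sids)) {
        if (sids[k] %in% boundary_ids) next
        cur <- if (sids[k] %in% names(st)) st[[sids[k]]] else 0
        st[sids[k]] <- cur + coef[k]
      }
    }
    st <- st[st != 0]
    if (length(st) == 0)
      stop("reaction '", rid, "' has no (non-boundary) stoichiometry")
    names(st) <- ifelse(names(st) %in% names(met_map),
                        met_map[names(st)], names(st))

    # bounds: L3 fbc attributes, else L2 kineticLaw parameters, else defaults
    lbattr <- xml2::xml_attr(node, "lowerFluxBound")
    ubattr <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lbattr) && lbattr %in% names(pvals)) pvals[[lbattr]] else NA_real_
    ub <- if (!is.na(ubattr) && ubattr %in% names(pvals)) pvals[[ubattr]] else NA_real_
    obj <- if (rid %in% names(obj_map)) obj_map[[rid]] else 0
    kl <- xml2::xml_find_all(node, sprintf(
      ".//*[local-name()='kineticLaw']//*[local-name()='parameter']"))
    if (length(kl)) {
      kp <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                            xml2::xml_attr(kl, "id"))
      if (is.na(lb) && "LOWER_BOUND" %in% names(kp)) lb <- kp[["LOWER_BOUND"]]
      if (is.na(ub) && "UPPER_BOUND" %in% names(kp)) ub <- kp[["UPPER_BOUND"]]
      if (obj == 0 && "OBJECTIVE_COEFFICIENT" %in% names(kp))
        obj <- kp[["OBJECTIVE_COEFFICIENT"]]
    }

    # GPR: L3 fbc geneProductAssociation, else notes GENE_ASSOCIATION
    gpr <- ""
    gpa <- xml2::xml_find_first(node,
             "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      gpr <- sbml_fbc_gpr(xml2::xml_children(gpa)[[1]], gp_label)
    } else {
      gpr <- sbml_notes_field(node, "GENE_ASSOCIATION")
    }
    subsystem <- sbml_notes_field(node, "SUBSYSTEM")

    list(id = rid,
         name = xml2::xml_attr(node, "name") %|na|% rid,
         stoichiometry = st,
         lower_bound = if (is.na(lb)) NULL else lb,
         upper_bound = if (is.na(ub)) NULL else ub,
         reversible = reversible,
         subsystem = subsystem, gpr = gpr,
         objective_coefficient = obj)
  })

  rids <- vapply(rxns, function(r) r$id, character(1))
  if (length(rids) && all(startsWith(rids, "R_"))) {
    for (k in seq_along(rxns)) rxns[[k]]$id <- substring(rxns[[k]]$id, 3)
  }
  metabolic_model(model_id, mets, rxns)
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Extract a "KEY: value" field from an SBML notes block, searching each
# text node separately (notes bodies hold one field per <p>).
sbml_notes_field <- function(node, key) {
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return("")
  texts <- xml2::xml_text(xml2::xml_find_all(notes, ".//text()"))
  pat <- paste0("^\\s*", key, ":")
  hit <- grep(pat, texts, value = TRUE)
  if (length(hit) == 0) return("")
  trimws(sub(pat, "", hit[1]))
}

sbml_species_formula <- function(node) {
  f <- xml2::xml_attr(node, "chemicalFormula")  # fbc attribute (any ns)
  if (!is.na(f)) return(f)
  attrs <- xml2::xml_attrs(node)
  hit <- grep("chemicalFormula$", names(attrs), value = TRUE)
  if (length(hit)) return(attrs[[hit[1]]])
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (!inherits(notes, "xml_missing")) {
    txt <- xml2::xml_text(notes)
    m <- regmatches(txt, regexpr("FORMULA:[^\n<]*", txt))
    if (length(m)) return(trimws(sub("FORMULA:", "", m)))
  }
  ""
}

sbml_species_charge <- function(node) {
  ch <- xml2::xml_attr(node, "charge")
  if (!is.na(ch)) return(as.numeric(ch))
  attrs <- xml2::xml_attrs(node)
  hit <- grep(":charge$|^charge$", names(attrs), value = TRUE)
  if (length(hit)) return(as.numeric(attrs[[hit[1]]]))
  0
}

sbml_fbc_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lbl <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(lbl)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_fbc_gpr, character(1), gp_label = gp_label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  genes <- model_genes(model)
  gene_sid <- stats::setNames(paste0("G_", sbml_mangle(genes)), genes)

  # collect distinct bounds as shared parameters
  bounds <- sort(unique(c(model$rxns$lower_bound, model$rxns$upper_bound)))
  bid <- stats::setNames(
    paste0("fb_", seq_along(bounds)), sprintf("%.17g", bounds))
  bname <- function(v) bid[[sprintf("%.17g", v)]]

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }

  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1" ',
    'xmlns:fbc="', fbc, '" fbc:required="false">')
  w('  <model id="', sbml_mangle(model$id), '" fbc:strict="true">')

  comps <- unique(model$mets$compartment)
  w('    <listOfCompartments>')
  for (cp in comps)
    w('      <compartment id="', sbml_mangle(cp), '" constant="true"/>')
  w('    </listOfCompartments>')

  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    extra <- ""
    if (nzchar(m$formula))
      extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
    extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
    w('      <species id="M_', sbml_mangle(m$id), '" name="', esc(m$name),
      '" compartment="', sbml_mangle(m$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
      extra, '/>')
  }
  w('    </listOfSpecies>')

  w('    <listOfParameters>')
  for (k in seq_along(bounds))
    w('      <parameter id="fb_', k, '" value="',
      format(bounds[k], digits = 17), '" constant="true"/>')
  w('    </listOfParameters>')

  w('    <listOfReactions>')
  for (j in seq_len(nrow(model$rxns))) {
    r <- model$rxns[j, ]
    col <- model$stoich[, j]
    nz <- which(col != 0)
    ids <- rownames(model$stoich)[nz]
    coef <- col[nz]
    w('      <reaction id="R_', sbml_mangle(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(r$lower_bound < 0),
      '" fast="false" fbc:lowerFluxBound="', bname(r$lower_bound),
      '" fbc:upperFluxBound="', bname(r$upper_bound), '">')
    if (nzchar(r$subsystem)) {
      w('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: ',
        esc(r$subsystem), '</p></body></notes>')
    }
    if (any(coef < 0)) {
      w('        <listOfReactants>')
      for (k in which(coef < 0))
        w('          <speciesReference species="M_', sbml_mangle(ids[k]),
          '" stoichiometry="', format(-coef[k], digits = 17), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (any(coef > 0)) {
      w('        <listOfProducts>')
      for (k in which(coef > 0))
        w('          <speciesReference species="M_', sbml_mangle(ids[k]),
          '" stoichiometry="', format(coef[k], digits = 17), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    gpr <- model$gprs[[j]]
    if (!is_empty_gpr(gpr)) {
      w('        <fbc:geneProductAssociation>')
      w(gpr_fbc_xml(gpr, gene_sid, indent = "          "))
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')

  obj <- which(model$rxns$objective_coefficient != 0)
  if (length(obj)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    for (j in obj)
      w('          <fbc:fluxObjective fbc:reaction="R_', sbml_mangle(model$rxns$id[j]),
        '" fbc:coefficient="',
        format(model$rxns$objective_coefficient[j], digits = 17), '"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }

  if (length(genes)) {
    w('    <fbc:listOfGeneProducts>')
    for (g in genes)
      w('      <fbc:geneProduct fbc:id="', gene_sid[[g]], '" fbc:label="',
        esc(g), '"/>')
    w('    </fbc:listOfGeneProducts>')
  }

  w('  </model>')
  w('</sbml>')
  invisible(path)
}

gpr_fbc_xml <- function(node, gene_sid, indent) {
  if (node$op == "gene") {
    return(paste0(indent, '<fbc:geneProductRef fbc:geneProduct="',
                  gene_sid[[node$gene]], '"/>'))
  }
  tag <- if (node$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(node$args, gpr_fbc_xml, character(1),
                  gene_sid = gene_sid, indent = paste0(indent, "  "))
  paste0(indent, "<", tag, ">\n",
         paste(inner, collapse = "\n"), "\n",
         indent, "</", tag, ">")
}
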