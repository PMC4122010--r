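#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers using `and`,
#' `or` and parentheses (case-insensitive, SBML-notes convention). The
#' empty string denotes an unconditional reaction: it is catalyzed
#' regardless of gene content.
#'
#' @param rule Character scalar, e.g. `"(b0001 and b0002) or b0003"`.
#' @return A GPR expression tree of class `gpr_rule`: `NULL` for the empty
#'   rule, otherwise nested lists with elements `op` (`"and"`, `"or"` or
#'   `"gene"`) and either `args` (sub-trees) or `gene` (a gene id).
#' @examples
#' parse_gpr("(b0001 and b0002) or b0003")
#' parse_gpr("")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0) return(empty_gpr())
  stopifnot(is.character(rule), length(rule) == 1)
  if (is.na(rule) || !nzchar(trimws(rule))) return(empty_gpr())

  toks <- gpr_tokenize(rule)
  st <- list(pos = 1L, toks = toks, input = rule)
  res <- gpr_parse_or(st)
  st <- res$state
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error at token %d ('%s') in rule '%s'",
                 st$pos, st$toks[[st$pos]]$text, rule))
  }
  structure(res$node, class = "gpr_rule")
}

empty_gpr <- function() structure(list(), class = c("gpr_rule", "gpr_empty"))

is_empty_gpr <- function(rule) {
  is.null(rule) || inherits(rule, "gpr_empty") ||
    (is.list(rule) && length(rule) == 0)
}

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, rule)[[1]]
  if (m[1] == -1) return(list())
  texts <- regmatches(rule, gregexpr(pat, rule))[[1]]
  lapply(seq_along(texts), function(i) {
    t <- texts[i]
    type <- if (t == "(") "lpar" else if (t == ")") "rpar"
      else if (tolower(t) %in% c("and", "&", "&&")) "and"
      else if (tolower(t) %in% c("or", "|", "||")) "or"
      else "gene"
    list(type = type, text = t, pos = m[i])
  })
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st) {
  res <- gpr_parse_and(st)
  st <- res$state
  args <- list(res$node)
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    res <- gpr_parse_and(st)
    st <- res$state
    args <- c(args, list(res$node))
  }
  node <- if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  list(node = node, state = st)
}

gpr_parse_and <- function(st) {
  res <- gpr_parse_atom(st)
  st <- res$state
  args <- list(res$node)
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    res <- gpr_parse_atom(st)
    st <- res$state
    args <- c(args, list(res$node))
  }
  node <- if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  list(node = node, state = st)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error: unexpected end of rule '%s' (dangling operator?)",
                 st$input))
  }
  if (tk$type == "lpar") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_or(st)
    st <- res$state
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != "rpar") {
      stop(sprintf("GPR parse error: unbalanced parenthesis at position %d in rule '%s'",
                   tk$pos, st$input))
    }
    st$pos <- st$pos + 1L
    return(list(node = res$node, state = st))
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(list(node = list(op = "gene", gene = tk$text), state = st))
  }
  stop(sprintf("GPR parse error: unexpected token '%s' at position %d in rule '%s'",
               tk$text, tk$pos, st$input))
}

#' Evaluate a GPR rule against gene states or scores
#'
#' Evaluation uses `AND = min` and `OR = max`, which reduces to boolean
#' logic on 0/1 states and extends to real-valued evidence scores.
#' Genes missing from `gene_states` evaluate as absent (score 0).
#' The empty rule evaluates to 1 (unconditional reaction).
#'
#' @param rule A `gpr_rule` (from [parse_gpr()]) or a rule string.
#' @param gene_states Named numeric vector of gene states/scores.
#' @return Numeric scalar (0/1 for boolean states).
#' @examples
#' evaluate_gpr(parse_gpr("(a and b) or c"), c(a = 1, b = 0, c = 1))
#' @export
evaluate_gpr <- function(rule, gene_states) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is_empty_gpr(rule)) return(1)
  if (is.null(names(gene_states)) && length(gene_states) > 0)
    stop("gene_states must be a named vector")
  gpr_eval_node(rule, gene_states)
}

gpr_eval_node <- function(node, states) {
  switch(node$op,
    gene = {
      i <- match(node$gene, names(states))
      if (is.na(i) || is.na(states[[i]])) 0 else as.numeric(states[[i]])
    },
    and = min(vapply(node$args, gpr_eval_node, numeric(1), states = states)),
    or  = max(vapply(node$args, gpr_eval_node, numeric(1), states = states)),
    stop("malformed GPR node")
  )
}

#' Genes referenced by a GPR rule
#'
#' @param rule A `gpr_rule` or rule string.
#' @return Character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is_empty_gpr(rule)) return(character(0))
  unique(gpr_collect_genes(rule))
}

gpr_collect_genes <- function(node) {
  if (node$op == "gene") return(node$gene)
  unlist(lapply(node$args, gpr_collect_genes), use.names = FALSE)
}

#' Serialize a GPR rule back to its string form
#'
#' @param rule A `gpr_rule`.
#' @return Character scalar ("" for the empty rule).
#' @export
gpr_to_string <- function(rule) {
  if (is.character(rule)) return(rule)
  if (is_empty_gpr(rule)) return("")
  gpr_node_string(rule, parent = NA_character_)
}

gpr_node_string <- function(node, parent) {
  if (node$op == "gene") return(node$gene)
  sep <- if (node$op == "and") " and " else " or "
  s <- paste(vapply(node$args, gpr_node_string, character(1), parent = node$op),
             collapse = sep)
  needs_paren <- !is.na(parent) && parent != node$op
  if (needs_paren) paste0("(", s, ")") else s
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr>", if (is_empty_gpr(x)) "(unconditional)" else gpr_to_string(x), "\n")
  invisible(x)
}
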