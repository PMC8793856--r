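#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `and`
#' encodes enzyme complexes (all subunits required) and `or` encodes isozymes
#' (any one suffices). `and` binds tighter than `or`, matching the common
#' SBML-fbc convention; parentheses override precedence. Operators are
#' case-insensitive.
#'
#' @param text GPR string, e.g. `"(g1 or g2) and g3"`.
#' @return an object of class `gpr_expr`: a nested list with elements
#'   `op` (`"gene"`, `"and"` or `"or"`) and either `gene` (for leaves) or
#'   `args` (a list of child expressions).
#' @examples
#' parse_gpr("a and b")
#' parse_gpr("a or b and c")  # = a or (b and c)
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("GPR rule must be a nonempty string")
  }
  tokens <- gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  expr <- gpr_parse_or(state)
  if (state$pos <= length(state$tokens)) {
    stop(sprintf("GPR parse error near token %d ('%s') in rule '%s'",
                 state$pos, state$tokens[state$pos], text))
  }
  expr
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

gpr_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_
  else state$tokens[state$pos]
}

gpr_parse_or <- function(state) {
  args <- list(gpr_parse_and(state))
  while (!is.na(tok <- gpr_peek(state)) && tolower(tok) == "or") {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_and(state)))
  }
  if (length(args) == 1) args[[1]] else gpr_node("or", args)
}

gpr_parse_and <- function(state) {
  args <- list(gpr_parse_atom(state))
  while (!is.na(tok <- gpr_peek(state)) && tolower(tok) == "and") {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_atom(state)))
  }
  if (length(args) == 1) args[[1]] else gpr_node("and", args)
}

gpr_parse_atom <- function(state) {
  tok <- gpr_peek(state)
  if (is.na(tok)) stop("GPR parse error: unexpected end of rule")
  if (tok == "(") {
    state$pos <- state$pos + 1L
    expr <- gpr_parse_or(state)
    if (is.na(gpr_peek(state)) || gpr_peek(state) != ")") {
      stop(sprintf("GPR parse error: unbalanced parentheses at token %d",
                   state$pos))
    }
    state$pos <- state$pos + 1L
    return(expr)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop(sprintf("GPR parse error: empty operand at token %d ('%s')",
                 state$pos, tok))
  }
  state$pos <- state$pos + 1L
  structure(list(op = "gene", gene = tok), class = "gpr_expr")
}

gpr_node <- function(op, args) {
  structure(list(op = op, args = args), class = "gpr_expr")
}

#' Genes referenced by a GPR expression
#'
#' @param expr a `gpr_expr` (or `NULL`).
#' @return character vector of unique gene identifiers (empty for `NULL`).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (expr$op == "gene") return(expr$gene)
  unique(unlist(lapply(expr$args, gpr_genes)))
}

#' Deparse a GPR expression back to rule text
#'
#' @param expr a `gpr_expr`.
#' @return a GPR rule string with explicit parentheses.
#' @export
gpr_to_string <- function(expr) {
  if (is.null(expr)) return("")
  if (expr$op == "gene") return(expr$gene)
  parts <- vapply(expr$args, function(a) {
    s <- gpr_to_string(a)
    if (a$op %in% c("and", "or")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}

#' Evaluate a GPR expression over per-gene values
#'
#' Two recursive semantics are supported. In `"enzyme"` mode the value of a
#' complex (`and`) is the minimum of its subunits and the value of an isozyme
#' set (`or`) is the sum of the alternatives -- the abundance-style rules used
#' when relating reaction-level enzyme capacity to gene-level abundances. In
#' `"transcript"` mode `and` is again the minimum but `or` takes the maximum,
#' the rules used to map transcript-derived protein equivalents onto
#' reactions.
#'
#' @param expr a `gpr_expr`.
#' @param values named nonnegative numeric vector with one entry per gene.
#' @param mode `"enzyme"` or `"transcript"`.
#' @return a nonnegative scalar.
#' @examples
#' e <- parse_gpr("a and b")
#' evaluate_gpr(e, c(a = 2, b = 3), "enzyme")      # 2
#' evaluate_gpr(parse_gpr("a or b"), c(a = 2, b = 3), "enzyme")      # 5
#' evaluate_gpr(parse_gpr("a or b"), c(a = 2, b = 3), "transcript")  # 3
#' @export
evaluate_gpr <- function(expr, values, mode = c("enzyme", "transcript")) {
  mode <- match.arg(mode)
  if (expr$op == "gene") {
    if (!expr$gene %in% names(values)) {
      stop(sprintf("no value supplied for gene '%s'", expr$gene))
    }
    return(unname(values[[expr$gene]]))
  }
  child <- vapply(expr$args, evaluate_gpr, numeric(1),
                  values = values, mode = mode)
  if (expr$op == "and") return(min(child))
  if (mode == "enzyme") sum(child) else max(child)
}
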