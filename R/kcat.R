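#' Read a turnover-number (kcat) parameter table
#'
#' Expected TSV columns: `ec` (dotted EC number, 1--4 levels, trailing `-`
#' wildcards allowed), `substrate` (optional, may be empty), `lineage`
#' (taxonomic tags, e.g. `"Fungi"`, optional) and `value_per_s`
#' (kcat in s^-1, > 0).
#'
#' @param path file path.
#' @return data.frame with the columns above.
#' @export
read_kcat_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_kcat_table(tab)
}

validate_kcat_table <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  stopifnot(all(c("ec", "substrate", "lineage", "value_per_s") %in%
                  names(tab)))
  if (any(tab$value_per_s <= 0)) stop("kcat values must be positive")
  ok <- grepl("^[0-9]+(\\.([0-9]+|-)){0,3}$", tab$ec)
  if (!all(ok)) {
    stop("malformed EC number(s): ", paste(tab$ec[!ok], collapse = ", "))
  }
  tab
}

ec_levels <- function(ec) strsplit(ec, ".", fixed = TRUE)

ec_truncate <- function(ec, level) {
  vapply(ec_levels(ec), function(parts) {
    parts <- parts[parts != "-"]
    paste(parts[seq_len(min(level, length(parts)))], collapse = ".")
  }, character(1))
}

ec_depth <- function(ec) {
  vapply(ec_levels(ec), function(parts) sum(parts != "-"), integer(1))
}

#' Match a kcat value for a reaction's EC numbers
#'
#' Implements the matching cascade used to parameterize enzyme-constrained
#' models from an EC-indexed kcat table:
#' \enumerate{
#'   \item candidates are all records matching any of the reaction's full
#'     (4-level) EC numbers;
#'   \item if any candidate's substrate matches one of the reaction's
#'     substrate names (case-insensitive), non-matching records are dropped;
#'   \item if any surviving candidate stems from the fungi kingdom,
#'     non-fungal records are dropped;
#'   \item the maximum kcat among the final candidates is returned.
#' }
#' Each filter is applied only when it leaves the candidate set nonempty.
#' When no full EC match exists, the ECs are pruned one level at a time
#' (4 to 3 to 2 to 1) and the same procedure is repeated at each level.
#'
#' @param ecs character vector of EC numbers (at least one).
#' @param substrates character vector of substrate metabolite names (may be
#'   empty).
#' @param table kcat table as from [read_kcat_table()].
#' @param lineage_kingdom kingdom used by the lineage filter.
#' @return list with `value` (s^-1) and `provenance` (`"full-match"` or
#'   `"pruned-level-<k>"`), or `NULL` when no record matches at any level.
#' @export
match_kcat <- function(ecs, substrates, table, lineage_kingdom = "Fungi") {
  if (length(ecs) == 0) stop("at least one EC number required")
  table <- validate_kcat_table(table)
  rec_depth <- ec_depth(table$ec)
  for (level in 4:1) {
    q <- unique(ec_truncate(ecs, level))
    q <- q[ec_depth(q) >= level]
    if (length(q) == 0) next
    cand <- which(rec_depth >= level & ec_truncate(table$ec, level) %in% q)
    if (length(cand) == 0) next
    sub_hit <- cand[!is.na(table$substrate[cand]) &
                      tolower(table$substrate[cand]) %in%
                        tolower(substrates)]
    if (length(sub_hit)) cand <- sub_hit
    fun_hit <- cand[grepl(lineage_kingdom, table$lineage[cand] %|NA|% "",
                          ignore.case = TRUE)]
    if (length(fun_hit)) cand <- fun_hit
    return(list(value = max(table$value_per_s[cand]),
                provenance = if (level == 4) "full-match"
                             else sprintf("pruned-level-%d", level)))
  }
  NULL
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Assign turnover numbers to all enzymatic reactions of a model
#'
#' Every reaction carrying a GPR rule receives a kcat: the matched table
#' value when [match_kcat()] succeeds, otherwise the median of all matched
#' values (median fallback). Values are converted from s^-1 to h^-1
#' (multiplied by 3600). Reactions without a GPR (exchanges, sinks, biomass,
#' spontaneous reactions) are never enzyme-constrained and are absent from
#' the assignment. Substrate names are taken from the metabolites consumed
#' by each reaction. Forward and reverse copies of a split reversible
#' reaction are matched independently but have identical EC/GPR annotation
#' and therefore receive the same value.
#'
#' @param model a `metabolic_model` (reversible reactions already split).
#' @param table kcat table as from [read_kcat_table()].
#' @param lineage_kingdom kingdom used by the lineage filter.
#' @return a `kcat_assignment`: data.frame with columns `reaction`,
#'   `kcat_per_h`, `provenance`, with the fallback median (h^-1) in
#'   attribute `median_per_h`.
#' @export
assign_kcats <- function(model, table, lineage_kingdom = "Fungi") {
  if (any(model$reactions$lower_bound < 0)) {
    stop("split reversible reactions before assigning kcats")
  }
  enz <- which(nzchar(model$reactions$gpr))
  if (length(enz) == 0) stop("model has no reactions with GPR rules")
  met_names <- setNames(model$metabolites$name, model$metabolites$id)
  matches <- lapply(enz, function(j) {
    ecs <- model$reactions$ec[[j]]
    if (length(ecs) == 0) return(NULL)
    subs <- met_names[model$metabolites$id[which(model$S[, j] < 0)]]
    match_kcat(ecs, subs, table, lineage_kingdom)
  })
  matched <- !vapply(matches, is.null, logical(1))
  if (!any(matched)) {
    stop("no reaction matched any kcat record; median fallback undefined")
  }
  values_s <- vapply(matches[matched], `[[`, numeric(1), "value")
  med <- median(values_s)
  kcat_per_h <- numeric(length(enz))
  provenance <- character(length(enz))
  kcat_per_h[matched] <- values_s * 3600
  provenance[matched] <- vapply(matches[matched], `[[`, character(1),
                                "provenance")
  kcat_per_h[!matched] <- med * 3600
  provenance[!matched] <- "median-fallback"
  out <- data.frame(reaction = model$reactions$id[enz],
                    kcat_per_h = kcat_per_h,
                    provenance = provenance,
                    stringsAsFactors = FALSE)
  attr(out, "median_per_h") <- med * 3600
  class(out) <- c("kcat_assignment", "data.frame")
  out
}
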