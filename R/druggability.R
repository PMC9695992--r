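# Direction-aware druggability screening of uniformly activated or
# suppressed modules against a drug-gene interaction table.

#' Default drug-action direction classes
#'
#' Controlled vocabulary mapping drug-gene interaction-type tokens to the
#' activator-like and inhibitor-like classes. Tokens outside the map never
#' match (conservative). The map is user-editable: pass a modified copy to
#' \code{\link{screen_module}}.
#'
#' @return List with character vectors \code{activator_like} and
#'   \code{inhibitor_like}.
#' @export
default_direction_map <- function() {
  list(activator_like = c("activator", "agonist", "inducer"),
       inhibitor_like = c("inhibitor", "antagonist", "blocker", "suppressor"))
}

#' Read a drug-gene interaction table
#'
#' DGIdb-style TSV with columns \code{gene}, \code{drug},
#' \code{interaction_type} and \code{approved}. Interaction types are
#' lowercased; several tokens may be given separated by \code{|}, \code{,}
#' or \code{;}. Duplicate (gene, drug) records are collapsed by the union of
#' their type tokens (approved if any record is approved).
#'
#' @param path TSV file.
#' @return data.frame of class \code{DrugInteractionTable}: \code{gene},
#'   \code{drug}, \code{interaction_types} (\code{|}-joined tokens),
#'   \code{approved}.
#' @export
load_drug_table <- function(path) {
  tab <- read_text_table(path, header = TRUE)
  names(tab) <- tolower(names(tab))
  need <- c("gene", "drug", "interaction_type", "approved")
  if (!all(need %in% names(tab))) {
    stop("drug table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  drug_interaction_table(data.frame(
    gene = as.character(tab$gene), drug = as.character(tab$drug),
    interaction_types = as.character(tab$interaction_type),
    approved = parse_flag(tab$approved), stringsAsFactors = FALSE))
}

#' @noRd
parse_flag <- function(x) {
  v <- tolower(as.character(x))
  out <- v %in% c("true", "t", "1", "yes", "y", "approved")
  bad <- !out & !v %in% c("false", "f", "0", "no", "n", "")
  if (any(bad)) stop("unparseable approved flag: ", v[bad][1], call. = FALSE)
  out
}

#' Validate and normalize a drug-gene interaction table
#'
#' @param df data.frame with \code{gene}, \code{drug},
#'   \code{interaction_types}, \code{approved}.
#' @return Normalized data.frame of class \code{DrugInteractionTable}.
#' @export
drug_interaction_table <- function(df) {
  stopifnot(all(c("gene", "drug", "interaction_types", "approved") %in% names(df)))
  if (any(!nzchar(df$gene) | !nzchar(df$drug))) {
    stop("gene and drug must be non-empty", call. = FALSE)
  }
  toks <- lapply(strsplit(tolower(df$interaction_types), "[|,;]"), trimws)
  key <- paste(df$gene, df$drug, sep = "\r")
  agg_types <- tapply(toks, key, function(l) sort(unique(unlist(l))))
  agg_appr <- tapply(df$approved, key, any)
  keys <- sort(unique(key))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[[`, character(1), 1L),
    drug = vapply(parts, `[[`, character(1), 2L),
    interaction_types = vapply(agg_types[keys], paste, character(1), collapse = "|"),
    approved = as.logical(agg_appr[keys]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DrugInteractionTable", "data.frame")
  out
}

#' Screen a module's proteins for direction-matched, approved drugs
#'
#' Modules with mixed interaction states are ineligible and are not
#' screened. For uniformly suppressed modules, drugs with activator-like
#' action are sought; for uniformly activated modules, inhibitor-like
#' action. Only FDA-approved records count. A gene is druggable iff at least
#' one surviving record targets it.
#'
#' @param m a \code{Module}.
#' @param table a \code{DrugInteractionTable}.
#' @param direction_map see \code{\link{default_direction_map}}.
#' @param screen \code{"members"} (default: all module proteins, which are
#'   all DIHCPs by construction) or \code{"hubs"}.
#' @return List of class \code{DruggabilityReport}: \code{module},
#'   \code{cancer_type}, \code{state}, \code{eligible},
#'   \code{druggable_genes}, \code{undruggable_genes}, \code{matched_drugs}
#'   (named list gene -> drug vector), \code{druggable_fraction}.
#' @export
screen_module <- function(m, table, direction_map = default_direction_map(),
                          screen = c("members", "hubs")) {
  screen <- match.arg(screen)
  stopifnot(inherits(m, "Module"))
  genes <- if (screen == "members") m$members else m$hubs
  base <- list(module = m$name, cancer_type = m$cancer_type, state = m$state,
               eligible = m$state != "MIXED",
               druggable_genes = character(0),
               undruggable_genes = character(0),
               matched_drugs = list(),
               druggable_fraction = NA_real_)
  class(base) <- "DruggabilityReport"
  if (m$state == "MIXED") return(base)
  wanted <- if (m$state == "ALL_SUPPRESSED") direction_map$activator_like
            else direction_map$inhibitor_like
  tab <- table[table$approved & table$gene %in% genes, , drop = FALSE]
  toks <- strsplit(tab$interaction_types, "|", fixed = TRUE)
  hit <- vapply(toks, function(tt) any(tt %in% wanted), logical(1))
  tab <- tab[hit, , drop = FALSE]
  matched <- split(tab$drug, tab$gene)
  matched <- lapply(matched, function(d) sort(unique(d)))
  base$druggable_genes <- sort(names(matched))
  base$undruggable_genes <- sort(setdiff(genes, names(matched)))
  base$matched_drugs <- matched
  base$druggable_fraction <- length(base$druggable_genes) / length(genes)
  base
}

#' Cross-cancer drug specificity
#'
#' Tallies, over a collection of druggability reports, the cancer types whose
#' modules each matched drug hits, and the fraction of drugs specific to a
#' single cancer type.
#'
#' @param reports list of \code{DruggabilityReport}s (possibly across cancer
#'   types).
#' @return List with \code{table} (data.frame \code{drug},
#'   \code{n_cancer_types}, \code{cancer_types}) and
#'   \code{fraction_specific}.
#' @export
drug_specificity <- function(reports) {
  if (length(reports) < 1L) stop("need at least one report", call. = FALSE)
  pairs <- do.call(rbind, lapply(reports, function(r) {
    drugs <- unique(unlist(r$matched_drugs, use.names = FALSE))
    if (length(drugs) == 0L) return(NULL)
    data.frame(drug = drugs, cancer_type = r$cancer_type,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(table = data.frame(drug = character(0),
                                   n_cancer_types = integer(0),
                                   cancer_types = character(0)),
                fraction_specific = NA_real_))
  }
  pairs <- unique(pairs)
  sp <- split(pairs$cancer_type, pairs$drug)
  tab <- data.frame(
    drug = names(sp),
    n_cancer_types = vapply(sp, function(x) length(unique(x)), integer(1)),
    cancer_types = vapply(sp, function(x) paste(sort(unique(x)), collapse = ","),
                          character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$drug), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, fraction_specific = mean(tab$n_cancer_types == 1L))
}
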