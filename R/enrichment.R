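# Local over-representation analysis (Fisher/hypergeometric, one-sided) with
# Benjamini-Hochberg correction, and the module x hallmark profile.

#' Benjamini-Hochberg adjustment
#'
#' Validates that all p-values lie in (0, 1] and applies the standard
#' step-up adjustment (\code{p.adjust(method = "BH")}), which preserves the
#' input order.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' One-sided over-representation test of a gene set query
#'
#' For each annotation set, computes the hypergeometric upper-tail
#' probability P(X >= k) of observing k or more query genes in the set,
#' where K is the set size within the universe, n the query size and N the
#' universe size; this equals the one-sided Fisher exact test for
#' over-representation. P-values are BH-adjusted over all tested sets.
#'
#' @param query character vector of gene symbols; genes outside the universe
#'   are dropped with a warning.
#' @param sets a \code{HallmarkGeneSets} or named list of gene vectors.
#' @param universe background gene universe (>= 2 genes); typically the node
#'   set of the reconstructed hallmark network.
#' @param alpha adjusted-p significance cut-off (default 0.01).
#' @return data.frame sorted by adjusted p: \code{set}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{p_adj}, \code{significant}.
#' @export
fisher_enrich <- function(query, sets, universe, alpha = 0.01) {
  universe <- unique(universe)
  if (length(universe) < 2L) stop("universe must contain >= 2 genes", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)), call. = FALSE)
  }
  query <- intersect(query, universe)
  if (length(query) == 0L) stop("query is empty after intersecting with the universe", call. = FALSE)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Module-by-hallmark membership and enrichment profile
#'
#' For every module and hallmark set: the count of module members annotated
#' to the hallmark and the over-representation significance of the module's
#' members against that hallmark. Suitable for heat-map rendering after
#' export.
#'
#' @param mods list of \code{Module}s.
#' @param sets a \code{HallmarkGeneSets}.
#' @param universe background universe; defaults to the union of all set
#'   members and module members.
#' @param alpha adjusted-p cut-off (default 0.01).
#' @return Long data.frame: \code{module}, \code{hallmark}, \code{count},
#'   \code{p}, \code{p_adj}, \code{significant}.
#' @export
hallmark_profile <- function(mods, sets, universe = NULL, alpha = 0.01) {
  if (is.null(universe)) {
    universe <- unique(c(unlist(sets, use.names = FALSE),
                         unlist(lapply(mods, `[[`, "members"), use.names = FALSE)))
  }
  out <- lapply(mods, function(m) {
    enr <- suppressWarnings(
      fisher_enrich(m$members, sets, universe, alpha = alpha))
    counts <- vapply(names(sets), function(nm) {
      length(intersect(m$members, unique(sets[[nm]])))
    }, integer(1))
    enr <- enr[match(names(sets), enr$set), , drop = FALSE]
    data.frame(module = m$name, hallmark = names(sets),
               count = as.integer(counts),
               p = enr$p, p_adj = enr$p_adj, significant = enr$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
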