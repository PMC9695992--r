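# Differential interactome: per-sample interaction observation, the
# interactome q-value and the activated/suppressed state calls.
#
# Note on terminology: the q-value here is the relative frequency of
# observation of an interaction in the tumor phenotype, q = f_T/(f_T + f_N).
# It is NOT a false-discovery-rate q-value.

#' Binarize gene expression into a per-sample activity matrix
#'
#' A protein-protein interaction can only be "observed" in a sample when both
#' partner genes are expressed there, so expression is first reduced to a
#' binary activity call per gene and sample. Three rules are available; the
#' default is the standard expressed-gene convention FPKM >= 1.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param rule \code{"fixed_threshold"} (gene active iff expression >= tau),
#'   \code{"per_gene_median"} (active iff >= that gene's median across
#'   samples) or \code{"per_gene_quantile"} (active iff >= that gene's
#'   alpha-quantile).
#' @param tau fixed FPKM threshold, used by \code{fixed_threshold}; >= 0.
#' @param alpha quantile in (0,1), used by \code{per_gene_quantile}.
#' @return Object of class \code{ActivityMatrix}: list with binary matrix
#'   \code{active} (same dimnames as the expression matrix), the phenotype
#'   map and a \code{rule} record.
#' @export
binarize <- function(ds, rule = c("fixed_threshold", "per_gene_median",
                                  "per_gene_quantile"),
                     tau = 1.0, alpha = 0.5) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  rule <- match.arg(rule)
  v <- ds$values
  thr <- switch(rule,
    fixed_threshold = {
      if (!is.numeric(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
      rep(tau, nrow(v))
    },
    per_gene_median = apply(v, 1L, stats::median),
    per_gene_quantile = {
      if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
        stop("alpha must be in (0,1)", call. = FALSE)
      }
      apply(v, 1L, stats::quantile, probs = alpha, names = FALSE)
    })
  active <- (v >= thr) * 1L
  dimnames(active) <- dimnames(v)
  structure(list(active = active, phenotype = ds$phenotype,
                 rule = list(name = rule,
                             parameter = if (rule == "per_gene_quantile") alpha
                                         else if (rule == "fixed_threshold") tau
                                         else NA_real_)),
            class = "ActivityMatrix")
}

#' Per-sample observation of network interactions
#'
#' An interaction is observed in a sample iff both endpoint genes are active
#' there (logical AND of the activity rows). Edges with an endpoint missing
#' from the activity matrix are dropped with a warning.
#'
#' @param act an \code{ActivityMatrix}.
#' @param net an \code{InteractionNetwork}.
#' @return Binary edges x samples matrix; rownames are \code{"A|B"} edge
#'   keys, attribute \code{edges} holds the surviving edge table.
#' @export
observe_interactions <- function(act, net) {
  stopifnot(inherits(act, "ActivityMatrix"), inherits(net, "InteractionNetwork"))
  genes <- rownames(act$active)
  present <- net$edges[, 1] %in% genes & net$edges[, 2] %in% genes
  if (!all(present)) {
    warning(sprintf("dropping %d edge(s) with endpoints absent from the expression data",
                    sum(!present)), call. = FALSE)
  }
  edges <- net$edges[present, , drop = FALSE]
  if (nrow(edges) == 0L) stop("no network edge has both endpoints measured", call. = FALSE)
  obs <- act$active[edges[, 1], , drop = FALSE] *
         act$active[edges[, 2], , drop = FALSE]
  rownames(obs) <- paste(edges[, 1], edges[, 2], sep = "|")
  attr(obs, "edges") <- edges
  obs
}

#' Interaction observation frequencies and the interactome q-value
#'
#' Given per-phenotype observation counts, computes the normalized
#' observation frequencies f_T = count_T/n_T and f_N = count_N/n_N and the
#' relative frequency of observation in the tumor phenotype,
#' q = f_T/(f_T + f_N). When an interaction is observed in neither phenotype
#' the q-value is undefined (\code{NA}) and the edge is reported as
#' unobserved.
#'
#' @param count_T,count_N integer vectors of samples in which the interaction
#'   was observed, per phenotype.
#' @param n_T,n_N phenotype sample sizes (>= 1).
#' @return data.frame with columns \code{f_T}, \code{f_N}, \code{q}.
#' @export
q_value <- function(count_T, count_N, n_T, n_N) {
  if (n_T < 1L || n_N < 1L) stop("n_T and n_N must be >= 1", call. = FALSE)
  if (any(count_T < 0 | count_T > n_T)) {
    stop("count_T out of range [0, n_T]", call. = FALSE)
  }
  if (any(count_N < 0 | count_N > n_N)) {
    stop("count_N out of range [0, n_N]", call. = FALSE)
  }
  f_T <- count_T / n_T
  f_N <- count_N / n_N
  tot <- f_T + f_N
  q <- ifelse(tot > 0, f_T / tot, NA_real_)
  data.frame(f_T = f_T, f_N = f_N, q = q)
}

#' Call the differential state of an interaction
#'
#' An interaction is significantly suppressed in the tumor state when
#' q < 0.10 and significantly activated when q > 0.90, in both cases provided
#' the normalized observation frequency exceeds 20\% in the tumor or the
#' normal phenotype (all three inequalities strict). Everything else is
#' non-significant; undefined q means the edge was never observed.
#'
#' @param f_T,f_N,q as returned by \code{\link{q_value}} (vectors allowed).
#' @param q_low,q_high,min_freq the three thresholds (defaults 0.10, 0.90,
#'   0.20).
#' @return Character vector with values \code{ACTIVATED},
#'   \code{SUPPRESSED}, \code{NONSIGNIFICANT}, \code{UNOBSERVED}.
#' @export
call_state <- function(f_T, f_N, q, q_low = 0.10, q_high = 0.90,
                       min_freq = 0.20) {
  freq_ok <- pmax(f_T, f_N) > min_freq
  out <- rep("NONSIGNIFICANT", length(q))
  out[!is.na(q) & q < q_low & freq_ok] <- "SUPPRESSED"
  out[!is.na(q) & q > q_high & freq_ok] <- "ACTIVATED"
  out[is.na(q)] <- "UNOBSERVED"
  out
}

#' Run the differential interactome analysis
#'
#' Chains activity binarization, per-sample interaction observation, the
#' q-value computation and state calling for every edge of the network. The
#' cohort criterion of at least 30 tumor and 30 normal samples is enforced
#' unless \code{force = TRUE}.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param net an \code{InteractionNetwork} (typically the output of
#'   \code{\link{reconstruct_network}}).
#' @param rule,tau,alpha binarization rule, see \code{\link{binarize}}.
#' @param q_low,q_high,min_freq state-calling thresholds, see
#'   \code{\link{call_state}}.
#' @param min_samples minimum per-phenotype sample count (default 30).
#' @param force bypass the cohort-size check.
#' @return data.frame of class \code{DifferentialInteractome} with one row
#'   per edge: \code{protein_a}, \code{protein_b}, \code{count_T},
#'   \code{count_N}, \code{f_T}, \code{f_N}, \code{q}, \code{state}.
#'   Attributes record the binarization rule and phenotype sizes.
#' @export
run_differential_interactome <- function(ds, net,
                                         rule = "fixed_threshold",
                                         tau = 1.0, alpha = 0.5,
                                         q_low = 0.10, q_high = 0.90,
                                         min_freq = 0.20,
                                         min_samples = 30L, force = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  n_T <- sum(ds$phenotype == "TUMOR")
  n_N <- sum(ds$phenotype == "NORMAL")
  if (!force && (n_T < min_samples || n_N < min_samples)) {
    stop(sprintf(paste("cohort too small (%d tumor / %d normal; need >= %d each);",
                       "use force = TRUE to override"),
                 n_T, n_N, min_samples), call. = FALSE)
  }
  act <- binarize(ds, rule = rule, tau = tau, alpha = alpha)
  obs <- observe_interactions(act, net)
  edges <- attr(obs, "edges")
  is_T <- ds$phenotype[colnames(obs)] == "TUMOR"
  count_T <- as.integer(rowSums(obs[, is_T, drop = FALSE]))
  count_N <- as.integer(rowSums(obs[, !is_T, drop = FALSE]))
  qv <- q_value(count_T, count_N, n_T, n_N)
  state <- call_state(qv$f_T, qv$f_N, qv$q,
                      q_low = q_low, q_high = q_high, min_freq = min_freq)
  res <- data.frame(protein_a = edges[, 1], protein_b = edges[, 2],
                    count_T = count_T, count_N = count_N,
                    f_T = qv$f_T, f_N = qv$f_N, q = qv$q, state = state,
                    stringsAsFactors = FALSE)
  res <- res[order(res$protein_a, res$protein_b), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rule") <- act$rule
  attr(res, "n_T") <- n_T
  attr(res, "n_N") <- n_N
  attr(res, "thresholds") <- c(q_low = q_low, q_high = q_high,
                               min_freq = min_freq)
  class(res) <- c("DifferentialInteractome", "data.frame")
  n_act <- sum(state == "ACTIVATED")
  n_sup <- sum(state == "SUPPRESSED")
  message(sprintf("differential interactome: %d edges, %d activated + %d suppressed dHCPPIs",
                  nrow(res), n_act, n_sup))
  res
}
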