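# Diagnostic scoring of modules: repeated balanced subsampling, PCA on the
# module genes and leave-one-out nearest-centroid classification in the
# top-3-PC space, summarised as averaged sensitivity and specificity.

#' One diagnostic PCA simulation
#'
#' Draws \code{n_per_class} tumor and normal samples without replacement,
#' z-scores each module gene over the drawn samples, projects the samples
#' onto the first three principal components and classifies every sample by
#' leave-one-out nearest phenotype centroid in that space (tumor = positive
#' class).
#'
#' Reproducibility design: the random draw for each phenotype pool is made
#' on an RNG substream derived from the simulation seed and a hash of the
#' pool's sorted sample IDs. Draws are thereby attached to the pool's
#' content, not its label, so relabelling phenotypes swaps the groups (and
#' hence sensitivity and specificity) without changing which samples are
#' drawn.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param module_genes character vector of module gene symbols; genes absent
#'   from the dataset are dropped with a warning (at least 2 must remain).
#' @param n_per_class samples drawn per phenotype (default 30).
#' @param seed integer seed for this simulation.
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{variance_fraction} (top-3 cumulative explained variance),
#'   \code{scores} (samples x PCs) and \code{labels}.
#' @export
simulate_once <- function(ds, module_genes, n_per_class = 30L, seed = 1L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  genes <- intersect(unique(module_genes), rownames(ds$values))
  if (length(genes) < length(unique(module_genes))) {
    warning(sprintf("%d module gene(s) absent from the expression data were dropped",
                    length(unique(module_genes)) - length(genes)), call. = FALSE)
  }
  if (length(genes) < 2L) stop("need >= 2 module genes present in the dataset", call. = FALSE)
  if (n_per_class < 2L) stop("n_per_class must be >= 2", call. = FALSE)
  pools <- list(NORMAL = sort(names(ds$phenotype)[ds$phenotype == "NORMAL"]),
                TUMOR = sort(names(ds$phenotype)[ds$phenotype == "TUMOR"]))
  drawn <- character(0)
  for (pool in pools) {
    if (length(pool) < n_per_class) {
      stop(sprintf("phenotype pool has %d samples; need >= %d",
                   length(pool), n_per_class), call. = FALSE)
    }
    set.seed(derive_seed(seed, string_hash(paste(pool, collapse = ","))))
    drawn <- c(drawn, pool[sample.int(length(pool), n_per_class)])
  }
  drawn <- sort(drawn)
  x <- t(ds$values[genes, drawn, drop = FALSE])
  zs <- zscore_columns(x)
  x <- zs$x[, !zs$constant, drop = FALSE]       # zero-variance genes dropped
  if (ncol(x) < 1L) stop("all module genes have zero variance over the draw", call. = FALSE)
  sv <- svd(x)
  k <- min(3L, ncol(x))
  scores <- x %*% sv$v[, seq_len(k), drop = FALSE]
  ev <- sv$d^2
  variance_fraction <- sum(ev[seq_len(k)]) / sum(ev)
  labels <- ds$phenotype[drawn]
  pred <- loo_nearest_centroid(scores, labels)
  tp <- sum(labels == "TUMOR" & pred == "TUMOR")
  fn <- sum(labels == "TUMOR" & pred == "NORMAL")
  tn <- sum(labels == "NORMAL" & pred == "NORMAL")
  fp <- sum(labels == "NORMAL" & pred == "TUMOR")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       variance_fraction = variance_fraction,
       scores = scores, labels = labels)
}

# Leave-one-out nearest-centroid classification of PC scores.
#' @noRd
loo_nearest_centroid <- function(scores, labels) {
  cls <- c("NORMAL", "TUMOR")
  sums <- lapply(cls, function(cl) colSums(scores[labels == cl, , drop = FALSE]))
  names(sums) <- cls
  ns <- table(factor(labels, levels = cls))
  pred <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    d <- vapply(cls, function(cl) {
      cen <- if (labels[i] == cl) {
        (sums[[cl]] - scores[i, ]) / (ns[[cl]] - 1L)
      } else {
        sums[[cl]] / ns[[cl]]
      }
      sum((scores[i, ] - cen)^2)
    }, numeric(1))
    pred[i] <- cls[which.min(d)]
  }
  pred
}

#' Evaluate a module as a diagnostic biomarker
#'
#' Repeats \code{\link{simulate_once}} until the running means of
#' sensitivity and specificity are stable (each varies by less than
#' \code{stability_tol} over the last \code{window} simulations, after a
#' minimum of \code{min_sims}) or \code{max_sims} is reached. A module is
#' diagnostic when both means reach at least 0.90.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param module_genes module gene symbols.
#' @param module_name label carried into the result.
#' @param n_per_class samples drawn per phenotype and simulation.
#' @param stability_tol,window,min_sims,max_sims stopping rule knobs.
#' @param threshold diagnostic cut-off on both means (default 0.90).
#' @param seed master seed; the result is fully reproducible from it.
#' @return Object of class \code{DiagnosticResult}.
#' @export
evaluate_diagnostic <- function(ds, module_genes, module_name = "module",
                                n_per_class = 30L, stability_tol = 0.005,
                                window = 10L, min_sims = 20L, max_sims = 200L,
                                threshold = 0.90, seed = 1L) {
  genes <- intersect(unique(module_genes), rownames(ds$values))
  if (length(genes) < length(unique(module_genes))) {
    warning(sprintf("module %s: %d gene(s) absent from the expression data",
                    module_name, length(unique(module_genes)) - length(genes)),
            call. = FALSE)
  }
  sens <- spec <- varfrac <- numeric(0)
  run_sens <- run_spec <- numeric(0)
  for (i in seq_len(max_sims)) {
    r <- simulate_once(ds, genes, n_per_class = n_per_class,
                       seed = derive_seed(seed, i))
    sens[i] <- r$sensitivity
    spec[i] <- r$specificity
    varfrac[i] <- r$variance_fraction
    run_sens[i] <- mean(sens)
    run_spec[i] <- mean(spec)
    if (i >= max(min_sims, window + 1L)) {
      w <- seq.int(i - window + 1L, i)
      if (diff(range(run_sens[w])) < stability_tol &&
          diff(range(run_spec[w])) < stability_tol) break
    }
  }
  structure(list(module = module_name,
                 n_simulations = length(sens),
                 mean_sensitivity = mean(sens),
                 mean_specificity = mean(spec),
                 mean_top3_variance_fraction = mean(varfrac),
                 top3_variance_at_least_80pct = mean(varfrac) >= 0.80,
                 is_diagnostic = mean(sens) >= threshold && mean(spec) >= threshold,
                 threshold = threshold,
                 seed = seed),
            class = "DiagnosticResult")
}

#' @export
print.DiagnosticResult <- function(x, ...) {
  cat(sprintf("DiagnosticResult %s: sens %.3f, spec %.3f over %d simulations -> %s\n",
              x$module, x$mean_sensitivity, x$mean_specificity,
              x$n_simulations,
              if (x$is_diagnostic) "diagnostic" else "not diagnostic"))
  invisible(x)
}
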