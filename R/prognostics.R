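# Prognostic scoring of modules: Cox prognostic index, median-split risk
# groups, two-group log-rank test and the observed/expected hazard ratio
# HR = (O1/E1)/(O2/E2).

#' Fit a Cox proportional-hazards model on module genes
#'
#' Expression covariates are z-scored for numerical stability and the
#' partial likelihood is maximised with Breslow tie handling
#' (\code{survival::coxph}). If the information matrix is singular (some
#' coefficients inestimable) the fit falls back to a lightly ridge-penalised
#' model, flagged in the result.
#'
#' @param expr numeric samples x genes matrix; rownames are sample IDs.
#' @param surv a \code{SurvivalTable}; samples absent from either input are
#'   dropped with a warning.
#' @param standardize z-score the covariates before fitting (default TRUE).
#' @param ridge_penalty ridge penalty used by the fallback (default 1e-4).
#' @return Object of class \code{CoxFit}: list with named \code{beta},
#'   the z-scoring \code{center}/\code{scale}, \code{ridge} flag,
#'   \code{n_events} and the \code{samples} used.
#' @export
fit_cox <- function(expr, surv, standardize = TRUE, ridge_penalty = 1e-4) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  common <- intersect(rownames(expr), surv$sample)
  dropped <- length(union(rownames(expr), surv$sample)) - length(common)
  if (dropped > 0L) {
    warning(sprintf("%d sample(s) unmatched between expression and survival were dropped",
                    dropped), call. = FALSE)
  }
  if (length(common) < 4L) stop("fewer than 4 matched samples", call. = FALSE)
  expr <- expr[common, , drop = FALSE]
  sv <- surv[match(common, surv$sample), , drop = FALSE]
  if (sum(sv$event) < 2L) stop("need at least 2 observed events", call. = FALSE)
  if (standardize) {
    zs <- zscore_columns(expr)
    if (any(zs$constant)) {
      warning("dropping constant gene(s): ",
              paste(colnames(expr)[zs$constant], collapse = ", "), call. = FALSE)
    }
    x <- zs$x[, !zs$constant, drop = FALSE]
    center <- zs$center[!zs$constant]
    scale <- zs$scale[!zs$constant]
  } else {
    x <- expr
    center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
    names(center) <- names(scale) <- colnames(x)
  }
  if (ncol(x) == 0L) stop("no non-constant covariates left", call. = FALSE)
  genes <- colnames(x)
  dat <- data.frame(.time = sv$time, .event = sv$event, x, check.names = FALSE)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100L)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", genes), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = dat, ties = "breslow",
                                     control = ctrl)),
    error = function(e) NULL)
  ridge_used <- FALSE
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    ridge_used <- TRUE
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~ survival::ridge(",
      paste(sprintf("`%s`", genes), collapse = ", "),
      sprintf(", theta = %g, scale = FALSE)", ridge_penalty)))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(fml, data = dat, ties = "breslow",
                                       control = ctrl)),
      error = function(e) {
        stop("Cox fit failed even with ridge fallback: ", conditionMessage(e),
             call. = FALSE)
      })
  }
  beta <- as.numeric(stats::coef(fit))
  names(beta) <- genes
  if (anyNA(beta)) stop("Cox fit did not produce finite coefficients", call. = FALSE)
  structure(list(beta = beta, center = center, scale = scale,
                 standardize = standardize, ridge = ridge_used,
                 n_events = sum(sv$event), samples = common),
            class = "CoxFit")
}

#' Prognostic index (linear predictor of the Cox model)
#'
#' PI(sample) = sum_i beta_i x_i over the module genes, with x_i on the same
#' (z-scored) scale as used in the fit.
#'
#' @param fit a \code{CoxFit}, or a bare named coefficient vector (in which
#'   case \code{expr} is used as-is).
#' @param expr numeric samples x genes matrix containing every fitted gene.
#' @return Named numeric vector of PI values per sample.
#' @export
prognostic_index <- function(fit, expr) {
  if (inherits(fit, "CoxFit")) {
    beta <- fit$beta
    missing_genes <- setdiff(names(beta), colnames(expr))
    if (length(missing_genes) > 0L) {
      stop("expression matrix lacks fitted gene(s): ",
           paste(missing_genes, collapse = ", "), call. = FALSE)
    }
    x <- expr[, names(beta), drop = FALSE]
    x <- sweep(sweep(x, 2L, fit$center, "-"), 2L,
               ifelse(fit$scale > 0, fit$scale, 1), "/")
  } else {
    beta <- fit
    missing_genes <- setdiff(names(beta), colnames(expr))
    if (length(missing_genes) > 0L) {
      stop("expression matrix lacks gene(s): ",
           paste(missing_genes, collapse = ", "), call. = FALSE)
    }
    x <- expr[, names(beta), drop = FALSE]
  }
  pi_values <- as.numeric(x %*% beta)
  names(pi_values) <- rownames(expr)
  pi_values
}

#' Split samples into risk groups at the median prognostic index
#'
#' HIGH: PI strictly above the median; LOW: PI at or below it (ties go to
#' LOW).
#'
#' @param pi_values named numeric vector with >= 4 samples.
#' @return Named character vector of \code{"HIGH"}/\code{"LOW"}.
#' @export
split_groups <- function(pi_values) {
  if (length(pi_values) < 4L) stop("need >= 4 samples to form risk groups", call. = FALSE)
  med <- stats::median(pi_values)
  group <- ifelse(pi_values > med, "HIGH", "LOW")
  names(group) <- names(pi_values)
  if (!any(group == "HIGH") || !any(group == "LOW")) {
    stop("degenerate PI: all prognostic-index values identical", call. = FALSE)
  }
  group
}

#' Two-group log-rank test with observed/expected hazard ratio
#'
#' Standard log-rank via \code{survival::survdiff}: at each distinct event
#' time the expected deaths are apportioned by at-risk counts; the statistic
#' is chi-square with 1 df. The hazard ratio follows the observed/expected
#' form HR = (O1/E1)/(O2/E2) with group 1 = HIGH.
#'
#' @param surv a \code{SurvivalTable} covering every grouped sample.
#' @param group named character vector of \code{"HIGH"}/\code{"LOW"}.
#' @return List of class \code{LogrankResult}: \code{O1}, \code{E1},
#'   \code{O2}, \code{E2}, \code{chi2}, \code{p}, \code{hazard_ratio}.
#' @export
logrank_test <- function(surv, group) {
  idx <- match(names(group), surv$sample)
  if (anyNA(idx)) {
    stop("survival table lacks sample(s): ",
         paste(names(group)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sv <- surv[idx, , drop = FALSE]
  g <- factor(group, levels = c("HIGH", "LOW"))
  if (any(table(g) == 0L)) stop("both risk groups must be non-empty", call. = FALSE)
  if (sum(sv$event) < 1L) stop("no observed events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g, rho = 0)
  obs <- as.numeric(sd$obs)
  expd <- as.numeric(sd$exp)
  # survdiff orders strata by factor level: HIGH then LOW
  O1 <- obs[1]; O2 <- obs[2]; E1 <- expd[1]; E2 <- expd[2]
  if (E1 <= 0 || E2 <= 0 || !is.finite(sd$chisq)) {
    stop("degenerate risk tables: log-rank variance is zero", call. = FALSE)
  }
  chi2 <- as.numeric(sd$chisq)
  structure(list(O1 = O1, E1 = E1, O2 = O2, E2 = E2,
                 chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 hazard_ratio = (O1 / E1) / (O2 / E2)),
            class = "LogrankResult")
}

#' Evaluate a module as a prognostic biomarker
#'
#' Chains \code{\link{fit_cox}} -> \code{\link{prognostic_index}} ->
#' \code{\link{split_groups}} -> \code{\link{logrank_test}} on the tumor
#' samples with clinical follow-up. A module is prognostic when the log-rank
#' p-value is below \code{p_cutoff} (default 0.01). Kaplan-Meier step
#' coordinates per risk group are included for plotting or export.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param surv a \code{SurvivalTable} for the tumor samples.
#' @param module_genes module gene symbols (absent genes dropped with a
#'   warning).
#' @param module_name label carried into the result.
#' @param p_cutoff log-rank significance cut-off (default 0.01).
#' @return Object of class \code{PrognosticResult}.
#' @export
evaluate_prognostic <- function(ds, surv, module_genes, module_name = "module",
                                p_cutoff = 0.01) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  genes <- intersect(unique(module_genes), rownames(ds$values))
  if (length(genes) < length(unique(module_genes))) {
    warning(sprintf("module %s: %d gene(s) absent from the expression data",
                    module_name, length(unique(module_genes)) - length(genes)),
            call. = FALSE)
  }
  if (length(genes) < 1L) stop("no module gene present in the dataset", call. = FALSE)
  tumor <- names(ds$phenotype)[ds$phenotype == "TUMOR"]
  keep <- intersect(tumor, surv$sample)
  if (length(keep) < 4L) stop("fewer than 4 tumor samples with survival data", call. = FALSE)
  expr <- t(ds$values[genes, keep, drop = FALSE])
  fit <- fit_cox(expr, surv)
  expr <- expr[fit$samples, , drop = FALSE]
  pi_values <- prognostic_index(fit, expr)
  group <- split_groups(pi_values)
  lr <- logrank_test(surv, group)
  idx <- match(names(group), surv$sample)
  g <- factor(group, levels = c("HIGH", "LOW"))
  sf <- survival::survfit(survival::Surv(surv$time[idx], surv$event[idx]) ~ g)
  strata <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  km <- rbind(data.frame(group = c("HIGH", "LOW"), time = 0, survival = 1),
              data.frame(group = strata, time = sf$time, survival = sf$surv))
  km <- km[order(km$group, km$time), , drop = FALSE]
  rownames(km) <- NULL
  structure(list(module = module_name, beta = fit$beta, ridge = fit$ridge,
                 pi_values = pi_values, group = group,
                 O1 = lr$O1, E1 = lr$E1, O2 = lr$O2, E2 = lr$E2,
                 hazard_ratio = lr$hazard_ratio,
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 is_prognostic = lr$p < p_cutoff, p_cutoff = p_cutoff,
                 km = km),
            class = "PrognosticResult")
}

#' @export
print.PrognosticResult <- function(x, ...) {
  cat(sprintf("PrognosticResult %s: HR %.3f, log-rank chi2 %.2f, p %.3g -> %s\n",
              x$module, x$hazard_ratio, x$logrank_chi2, x$logrank_p,
              if (x$is_prognostic) "prognostic" else "not prognostic"))
  invisible(x)
}
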