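# Cox prognostic index, median-split groups, log-rank test and the O/E
# hazard ratio.

six_subject_fixture <- function() {
  # single binary covariate, no ties
  data.frame(sample = sprintf("s%d", 1:6),
             time = c(2, 5, 7, 10, 14, 19),
             event = c(1, 1, 0, 1, 1, 0),
             x = c(0, 1, 1, 0, 1, 0))
}

test_that("Cox coefficient matches a 1-D partial-likelihood oracle", {
  fx <- six_subject_fixture()
  surv <- survival_table(fx[, c("sample", "time", "event")])
  expr <- matrix(fx$x, ncol = 1, dimnames = list(fx$sample, "gene1"))
  fit <- fit_cox(expr, surv, standardize = FALSE)
  oracle <- optimize(function(b) cox_loglik_1d(b, fx$time, fx$event, fx$x),
                     c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-6)
  expect_false(fit$ridge)

  # same oracle holds on the z-scored covariate used by the default fit
  fit_z <- fit_cox(expr, surv, standardize = TRUE)
  xz <- as.numeric(scale(fx$x))
  oracle_z <- optimize(function(b) cox_loglik_1d(b, fx$time, fx$event, xz),
                       c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(fit_z$beta), oracle_z, tolerance = 1e-6)
})

test_that("Cox fit recovers a planted coefficient and is null-calibrated", {
  set.seed(2024)
  n <- 500
  x <- rnorm(n)
  tt <- rexp(n, rate = 0.01 * exp(1.0 * x))
  cc <- rexp(n, rate = 0.004)
  surv <- survival_table(data.frame(sample = sprintf("p%03d", 1:n),
                                    time = pmin(tt, cc),
                                    event = as.integer(tt <= cc)))
  expr <- matrix(x, ncol = 1, dimnames = list(surv$sample, "g"))
  fit <- fit_cox(expr, surv, standardize = FALSE)
  expect_lt(abs(unname(fit$beta) - 1.0), 0.15)

  # null covariate: Wald z stays within +/-2.6 essentially always
  # (true coverage of |z|<2.6 is ~99.1%; the bound below is 3 binomial SDs)
  set.seed(77)
  inside <- vapply(1:500, function(i) {
    n <- 200
    x <- rnorm(n)
    tt <- rexp(n, 0.02)
    sv <- survival_table(data.frame(sample = sprintf("q%03d", 1:n),
                                    time = tt, event = 1L))
    df <- data.frame(time = sv$time, event = sv$event, x = x)
    f <- survival::coxph(survival::Surv(time, event) ~ x, df, ties = "breslow")
    abs(unname(coef(f)) / sqrt(f$var[1, 1])) < 2.6
  }, logical(1))
  expect_gte(mean(inside), 0.978)
})

test_that("prognostic index is the linear predictor", {
  beta <- c(gA = 1, gB = -1)
  expr <- matrix(c(2, 2), 1, 2, dimnames = list("s1", c("gA", "gB")))
  expect_equal(unname(prognostic_index(beta, expr)), 0)
  expect_equal(unname(prognostic_index(c(gA = 0, gB = 0), expr)), 0)

  set.seed(3)
  b <- setNames(rnorm(5), sprintf("g%d", 1:5))
  x <- matrix(rnorm(40), 8, 5,
              dimnames = list(sprintf("s%d", 1:8), names(b)))
  oracle <- apply(x, 1, function(r) sum(r * b))   # brute-force dot product
  expect_equal(prognostic_index(b, x), oracle)
  expect_error(prognostic_index(c(zz = 1), x), "zz")
})

test_that("median split puts ties in LOW and rejects degenerate PI", {
  g <- split_groups(setNames(c(1, 2, 3, 4), sprintf("s%d", 1:4)))
  expect_equal(unname(g), c("LOW", "LOW", "HIGH", "HIGH"))
  g3 <- split_groups(setNames(c(1, 2, 3, 9), sprintf("s%d", 1:4)))
  expect_equal(sum(g3 == "HIGH"), 2L)
  expect_error(split_groups(setNames(rep(1, 5), sprintf("s%d", 1:5))),
               "degenerate")
  expect_error(split_groups(setNames(1:3, c("a", "b", "c"))), ">= 4")
})

test_that("log-rank O/E/chi2 match an independent risk-table enumeration", {
  fx <- six_subject_fixture()
  surv <- survival_table(fx[, c("sample", "time", "event")])
  group <- setNames(ifelse(fx$x == 1, "HIGH", "LOW"), fx$sample)
  lr <- logrank_test(surv, group)
  oracle <- logrank_oracle(fx$time, fx$event, group)
  expect_equal(lr$O1, oracle$O1)
  expect_equal(lr$E1, oracle$E1, tolerance = 1e-10)
  expect_equal(lr$chi2, oracle$chi2, tolerance = 1e-8)
  expect_equal(lr$hazard_ratio,
               (oracle$O1 / oracle$E1) / (oracle$O2 / oracle$E2),
               tolerance = 1e-10)

  # random instances, including tied event times
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    sv <- survival_table(data.frame(
      sample = sprintf("r%02d", 1:n),
      time = sample(1:15, n, replace = TRUE),
      event = rbinom(n, 1, 0.7)))
    grp <- setNames(sample(c("HIGH", "LOW"), n, replace = TRUE), sv$sample)
    lr <- logrank_test(sv, grp)
    orc <- logrank_oracle(sv$time, sv$event, grp)
    expect_equal(lr$O1, orc$O1)
    expect_equal(lr$E1, orc$E1, tolerance = 1e-8)
    expect_equal(lr$chi2, orc$chi2, tolerance = 1e-6)
  }
})

test_that("log-rank conserves events and honours the null identity", {
  base <- data.frame(time = c(3, 6, 8, 12, 15), event = c(1, 1, 0, 1, 0))
  sv <- survival_table(data.frame(
    sample = sprintf("s%d", 1:10),
    time = rep(base$time, 2), event = rep(base$event, 2)))
  grp <- setNames(rep(c("HIGH", "LOW"), each = 5), sv$sample)
  lr <- logrank_test(sv, grp)
  expect_equal(lr$O1 + lr$O2, sum(sv$event))
  expect_equal(lr$E1 + lr$E2, sum(sv$event), tolerance = 1e-10)
  expect_equal(lr$O1, lr$E1, tolerance = 1e-10)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_equal(lr$hazard_ratio, 1, tolerance = 1e-12)
})

test_that("swapping risk-group labels inverts HR and preserves chi2 and p", {
  set.seed(12)
  n <- 60
  sv <- survival_table(data.frame(sample = sprintf("s%02d", 1:n),
                                  time = rexp(n, 0.05),
                                  event = rbinom(n, 1, 0.8)))
  grp <- setNames(sample(c("HIGH", "LOW"), n, replace = TRUE), sv$sample)
  swapped <- setNames(ifelse(grp == "HIGH", "LOW", "HIGH"), names(grp))
  a <- logrank_test(sv, grp)
  b <- logrank_test(sv, swapped)
  expect_equal(b$hazard_ratio, 1 / a$hazard_ratio, tolerance = 1e-10)
  expect_equal(b$chi2, a$chi2, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-10)
})

test_that("Cox fit is invariant to subject duplication and affine rescaling", {
  fx <- six_subject_fixture()
  surv <- survival_table(fx[, c("sample", "time", "event")])
  expr <- matrix(fx$x + rnorm(6, sd = 0.01), ncol = 1,
                 dimnames = list(fx$sample, "g"))
  fit1 <- fit_cox(expr, surv, standardize = FALSE)
  dup <- rbind(fx, transform(fx, sample = paste0(sample, "b")))
  surv2 <- survival_table(dup[, c("sample", "time", "event")])
  expr2 <- rbind(expr, expr)
  rownames(expr2) <- dup$sample
  fit2 <- fit_cox(expr2, surv2, standardize = FALSE)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-6)

  # per-gene affine rescaling leaves the standardized fit and groups unchanged
  fitA <- fit_cox(expr, surv, standardize = TRUE)
  fitB <- fit_cox(expr * 3 + 10, surv, standardize = TRUE)
  expect_equal(fitA$beta, fitB$beta, tolerance = 1e-8)
  piA <- prognostic_index(fitA, expr)
  piB <- prognostic_index(fitB, expr * 3 + 10)
  expect_identical(split_groups(piA), split_groups(piB))
})

test_that("modules with a planted hazard effect are prognostic, null ones are not", {
  sc <- synthetic_scenario(seed = 21, n_tumor = 300, n_normal = 40,
                           gamma = 1.5,
                           stars = list(list(state = "ACTIVATED",
                                             n_partners = 12)))
  g <- generate_scenario(sc)
  genes <- g$manifest$prognostic_genes
  pr <- evaluate_prognostic(g$expression, g$survival, genes, "planted")
  expect_true(pr$is_prognostic)
  expect_gt(pr$hazard_ratio, 1)
})

test_that("single-gene null modules are rarely called prognostic", {
  # The in-sample prognostic index is fit and tested on the same cohort, so
  # rejection under the null exceeds the nominal 1% and grows with module
  # size (see the methods vignette); for a single covariate the chained
  # procedure rejects ~1.5% of the time, bounded here at 3 binomial SDs.
  rejections <- vapply(1:100, function(i) {
    set.seed(20000 + i)
    n <- 120
    x <- matrix(rnorm(n), n, 1,
                dimnames = list(sprintf("s%03d", 1:n), "g1"))
    tt <- rexp(n, 0.01); cc <- rexp(n, 0.004)
    sv <- survival_table(data.frame(sample = rownames(x),
                                    time = pmin(tt, cc),
                                    event = as.integer(tt <= cc)))
    fit <- fit_cox(x, sv)
    grp <- split_groups(prognostic_index(fit, x))
    logrank_test(sv, grp)$p < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.06)
})

test_that("Kaplan-Meier curves are non-increasing step functions from 1", {
  g <- generate_scenario(synthetic_scenario(
    seed = 22, n_tumor = 80, n_normal = 40, gamma = 1.0,
    stars = list(list(state = "ACTIVATED", n_partners = 12))))
  pr <- evaluate_prognostic(g$expression, g$survival,
                            g$manifest$prognostic_genes)
  for (grp in c("HIGH", "LOW")) {
    km <- pr$km[pr$km$group == grp, ]
    expect_equal(km$survival[1], 1)
    expect_true(all(diff(km$survival) <= 1e-12))
  }
})
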