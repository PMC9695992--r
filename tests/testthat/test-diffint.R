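# Activity binarization, interaction observation, the interactome q-value
# and state calling.

test_that("binarization rules follow the >=-threshold convention", {
  ds <- tiny_dataset()
  act <- binarize(ds, "fixed_threshold", tau = 1.0)
  expect_equal(unname(act$active["G1", ]), c(0, 0, 1, 1))

  act_med <- binarize(ds, "per_gene_median")
  expect_equal(unname(act_med$active["G2", ]), c(0, 0, 1, 1))  # median 2.5

  zero <- expression_dataset(
    matrix(0, 1, 4, dimnames = list("Z", names(ds$phenotype))),
    ds$phenotype, "TST")
  expect_equal(sum(binarize(zero, "fixed_threshold", tau = 1)$active), 0)

  expect_error(binarize(ds, "fixed_threshold", tau = -1), "tau")
  expect_error(binarize(ds, "per_gene_quantile", alpha = 1.5), "alpha")
})

test_that("interaction observation is the AND of endpoint activity", {
  active <- rbind(A = c(1, 1, 0, 0), B = c(0, 1, 1, 0), C = c(0, 0, 0, 0))
  colnames(active) <- sprintf("s%d", 1:4)
  act <- as_activity(active, c(TRUE, TRUE, FALSE, FALSE))
  net <- interaction_network(c("A", "A"), c("B", "C"))
  obs <- observe_interactions(act, net)
  expect_equal(unname(obs["A|B", ]), c(0, 1, 0, 0))
  expect_equal(sum(obs["A|C", ]), 0)

  net2 <- interaction_network(c("A", "A"), c("B", "MISSING"))
  expect_warning(obs2 <- observe_interactions(act, net2), "absent")
  expect_equal(nrow(obs2), 1L)
})

test_that("per-edge counts match a brute-force double loop on random instances", {
  inst <- random_activity_instance(seed = 101)
  act <- as_activity(inst$active, inst$is_T)
  net <- interaction_network(inst$edges)
  obs <- observe_interactions(act, net)
  edges <- attr(obs, "edges")
  got_T <- as.integer(rowSums(obs[, inst$is_T]))
  got_N <- as.integer(rowSums(obs[, !inst$is_T]))
  oracle <- bf_edge_counts(inst$active, edges, inst$is_T)
  expect_identical(got_T, oracle$count_T)
  expect_identical(got_N, oracle$count_N)
})

test_that("q-value arithmetic, symmetry and undefined case", {
  r <- q_value(19, 1, 20, 20)
  expect_equal(r$f_T, 0.95)
  expect_equal(r$f_N, 0.05)
  expect_equal(r$q, 0.95)

  for (k in c(1, 5, 20)) expect_equal(q_value(k, k, 20, 20)$q, 0.5)
  expect_true(is.na(q_value(0, 0, 20, 20)$q))

  expect_error(q_value(21, 0, 20, 20), "count_T")
  expect_error(q_value(0, -1, 20, 20), "count_N")
  expect_error(q_value(0, 0, 0, 20), "n_T")
})

test_that("q is invariant to duplicating every sample in both phenotypes", {
  r1 <- q_value(12, 3, 40, 35)
  r2 <- q_value(24, 6, 80, 70)
  expect_equal(r1$q, r2$q)
})

test_that("state calling uses strict thresholds exactly", {
  expect_equal(call_state(0.95, 0.05, 0.95), "ACTIVATED")
  expect_equal(call_state(0.19, 0.01, 0.95), "NONSIGNIFICANT")  # freq rule
  expect_equal(call_state(0.90, 0.10, 0.90), "NONSIGNIFICANT")  # boundary q
  expect_equal(call_state(0.05, 0.95, 0.05), "SUPPRESSED")
  expect_equal(call_state(0.10, 0.90, 0.10), "NONSIGNIFICANT")  # boundary q
  expect_equal(call_state(0.20, 0.20, 0.95), "NONSIGNIFICANT")  # boundary freq
  expect_equal(call_state(0, 0, NA), "UNOBSERVED")
})

test_that("identical tumor and normal columns yield zero differential calls", {
  vals <- matrix(runif(20 * 30, 0, 5), 20, 30)
  vals <- cbind(vals, vals)
  dimnames(vals) <- list(sprintf("g%02d", 1:20),
                         c(sprintf("T%02d", 1:30), sprintf("N%02d", 1:30)))
  ph <- setNames(rep(c("TUMOR", "NORMAL"), each = 30), colnames(vals))
  ds <- expression_dataset(vals, ph, "TST")
  net <- interaction_network(t(combn(sprintf("g%02d", 1:10), 2)))
  d <- suppressMessages(run_differential_interactome(ds, net))
  expect_true(all(d$state %in% c("NONSIGNIFICANT", "UNOBSERVED")))
  expect_true(all(is.na(d$q) | d$q == 0.5))
})

test_that("sample order permutation leaves the result unchanged", {
  g <- generate_scenario(synthetic_scenario(seed = 5, n_decoys = 50,
                                            n_activated = 3, n_suppressed = 3))
  ds <- g$expression
  set.seed(1)
  perm <- sample(ncol(ds$values))
  ds2 <- expression_dataset(ds$values[, perm], ds$phenotype[perm], ds$cancer_type)
  d1 <- suppressMessages(run_differential_interactome(ds, g$network))
  d2 <- suppressMessages(run_differential_interactome(ds2, g$network))
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("label swap maps q to 1-q and exchanges activated/suppressed", {
  g <- generate_scenario(synthetic_scenario(seed = 8, n_decoys = 100,
                                            n_activated = 5, n_suppressed = 5))
  ds <- g$expression
  ph2 <- setNames(ifelse(ds$phenotype == "TUMOR", "NORMAL", "TUMOR"),
                  names(ds$phenotype))
  ds2 <- expression_dataset(ds$values, ph2, ds$cancer_type)
  d1 <- suppressMessages(run_differential_interactome(ds, g$network))
  d2 <- suppressMessages(run_differential_interactome(ds2, g$network))
  expect_equal(d2$q, 1 - d1$q)
  expect_identical(d2$state[d1$state == "ACTIVATED"],
                   rep("SUPPRESSED", sum(d1$state == "ACTIVATED")))
  expect_identical(d2$state[d1$state == "SUPPRESSED"],
                   rep("ACTIVATED", sum(d1$state == "SUPPRESSED")))
})

test_that("cohort-size criterion is enforced unless forced", {
  ds <- tiny_dataset()
  net <- interaction_network("G1", "G2")
  expect_error(run_differential_interactome(ds, net), "cohort")
  d <- suppressMessages(run_differential_interactome(ds, net, force = TRUE))
  expect_equal(nrow(d), 1L)
})
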