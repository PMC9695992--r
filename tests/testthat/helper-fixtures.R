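# Shared fixtures and independent oracles used across the test files.
# All fixtures are built in code; oracles are deliberately naive (double
# loops, direct enumeration) and independent of the package's code paths.

# Small expression dataset built directly in memory.
tiny_dataset <- function() {
  values <- matrix(c(0.0, 0.5, 2.0, 7.1,
                     1.0, 2.0, 3.0, 4.0,
                     5.0, 0.2, 8.0, 0.1),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("G1", "G2", "G3"),
                                   c("T1", "T2", "N1", "N2")))
  ph <- c(T1 = "TUMOR", T2 = "TUMOR", N1 = "NORMAL", N2 = "NORMAL")
  expression_dataset(values, ph, "TST")
}

# Random activity + edges instance for counting-oracle checks.
random_activity_instance <- function(seed, n_genes = 20, n_samples = 40,
                                     n_edges = 50, p_active = 0.5) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  active <- matrix(rbinom(n_genes * n_samples, 1, p_active),
                   n_genes, n_samples, dimnames = list(genes, samples))
  is_T <- rep(c(TRUE, FALSE), each = n_samples / 2)
  edges <- unique(t(replicate(n_edges * 2, sort(sample(genes, 2)))))
  edges <- edges[seq_len(min(n_edges, nrow(edges))), , drop = FALSE]
  list(active = active, edges = edges, is_T = is_T,
       genes = genes, samples = samples)
}

# Brute-force per-edge observation counts: explicit double loop.
bf_edge_counts <- function(active, edges, is_T) {
  out <- data.frame(count_T = integer(nrow(edges)),
                    count_N = integer(nrow(edges)))
  for (e in seq_len(nrow(edges))) {
    cT <- 0L; cN <- 0L
    for (s in seq_len(ncol(active))) {
      obs <- active[edges[e, 1], s] == 1 && active[edges[e, 2], s] == 1
      if (obs && is_T[s]) cT <- cT + 1L
      if (obs && !is_T[s]) cN <- cN + 1L
    }
    out$count_T[e] <- cT; out$count_N[e] <- cN
  }
  out
}

# Activity matrix object wrapper for tests that call observe_interactions
# directly on a hand-made binary matrix.
as_activity <- function(active, is_T) {
  ph <- ifelse(is_T, "TUMOR", "NORMAL")
  names(ph) <- colnames(active)
  structure(list(active = active, phenotype = ph,
                 rule = list(name = "fixed_threshold", parameter = 1)),
            class = "ActivityMatrix")
}

# Build a Module via the public construction path (star of edges around a
# hub).
mk_module <- function(hub, partners, states, cancer_type = "TST") {
  df <- data.frame(protein_a = pmin(hub, partners),
                   protein_b = pmax(hub, partners),
                   count_T = 1L, count_N = 0L, f_T = 1, f_N = 0, q = 1,
                   state = states, stringsAsFactors = FALSE)
  mods <- build_modules(df, cancer_type = cancer_type,
                        min_size = length(partners) + 1L)
  nm <- canonical_module_name(hub)
  mods[[which(vapply(mods, `[[`, character(1), "name") == nm)]]
}

# Independent two-group log-rank oracle: explicit risk-table enumeration
# (group 1 = HIGH).
logrank_oracle <- function(time, event, group) {
  O1 <- sum(event[group == "HIGH"])
  E1 <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == "HIGH")
    d <- sum(event == 1 & time == t)
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O2 <- sum(event) - O1
  E2 <- sum(event) - E1
  list(O1 = O1, E1 = E1, O2 = O2, E2 = E2, chi2 = (O1 - E1)^2 / V)
}

# Breslow log partial likelihood for a single covariate, written out
# directly; used as a 1-D maximisation oracle for the Cox fit.
cox_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Hypergeometric upper-tail by direct pmf summation.
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random module collections for pooling property tests.
random_module_collection <- function(seed, n_modules = 8, pool_size = 40) {
  set.seed(seed)
  genes <- sprintf("P%02d", seq_len(pool_size))
  mods <- list()
  for (i in seq_len(n_modules)) {
    hub <- sprintf("HUB%02d", i)
    partners <- sample(genes, sample(3:8, 1))
    mods[[i]] <- mk_module(hub, partners,
                           sample(c("ACTIVATED", "SUPPRESSED"), 1))
  }
  mods
}

# Expression datasets with perfectly separated / exchangeable phenotypes.
separable_dataset <- function(n_genes = 10, n_per_class = 40, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("T%02d", 1:n_per_class), sprintf("N%02d", 1:n_per_class))
  vals <- matrix(c(50 + runif(n_genes * n_per_class),
                   runif(n_genes * n_per_class)), n_genes, 2 * n_per_class)
  dimnames(vals) <- list(sprintf("g%02d", 1:n_genes), samples)
  ph <- setNames(rep(c("TUMOR", "NORMAL"), each = n_per_class), samples)
  expression_dataset(vals, ph, "TST")
}

null_dataset <- function(n_genes = 10, n_per_class = 40, seed = 2) {
  set.seed(seed)
  samples <- c(sprintf("T%02d", 1:n_per_class), sprintf("N%02d", 1:n_per_class))
  vals <- matrix(rlnorm(n_genes * 2 * n_per_class, 1, 0.8),
                 n_genes, 2 * n_per_class,
                 dimnames = list(sprintf("g%02d", 1:n_genes), samples))
  ph <- setNames(rep(c("TUMOR", "NORMAL"), each = n_per_class), samples)
  expression_dataset(vals, ph, "TST")
}

module_signature <- function(mods) {
  sig <- vapply(mods, function(m) {
    paste(m$name, paste(m$members, collapse = ","), m$state, sep = ";")
  }, character(1))
  sort(sig)
}
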