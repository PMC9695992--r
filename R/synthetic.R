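# Synthetic-data generator: scale-free decoy network, planted differential
# co-activity, FPKM-like expression, survival with a planted hazard effect,
# hallmark sets and a drug table, plus a ground-truth manifest.
#
# Construction notes (see the methods vignette for the full rationale):
# * planted differential edges are endpoint-disjoint pairs whose co-activity
#   is exactly Bernoulli(p_on) per phenotype; decoy edges are sampled from a
#   preferential-attachment backbone over background genes only, so the
#   planted/decoy ground truth is unambiguous;
# * planted star modules use per-gene activity probability sqrt(p_on) per
#   phenotype, giving each hub-partner edge co-activity p_on.

HALLMARK_NAMES <- c("AID", "AIM", "DCE", "ERI", "EGS",
                    "GIM", "IA", "RCD", "SPS", "TPI")

#' Define a synthetic study scenario
#'
#' Defaults are the package's reference study conditions: 50 tumor and 50
#' normal samples, 10 activated and 10 suppressed planted interactions with
#' tumor/normal co-activity 0.95/0.02, 200 decoy interactions from a
#' preferential-attachment backbone, background activity probability 0.5,
#' and log-normal FPKM-like expression straddling the activity threshold of
#' 1 FPKM.
#'
#' @param seed integer master seed; the generated data are byte-identical
#'   for identical seeds.
#' @param n_background_genes backbone genes feeding the decoy network.
#' @param pa_m preferential-attachment edges per new node.
#' @param n_decoys decoy edges sampled from the backbone (NULL keeps the
#'   whole backbone).
#' @param n_activated,n_suppressed planted differential edge counts.
#' @param p_on_T,p_on_N per-sample co-activity probability of a planted
#'   activated edge in tumor/normal (suppressed edges swap them).
#' @param p0 background per-gene activity probability.
#' @param n_tumor,n_normal sample counts.
#' @param mu_hi,mu_lo,sigma log-normal expression parameters for active and
#'   inactive gene-samples; must satisfy mu_lo < log(fpkm_threshold) < mu_hi.
#' @param fpkm_threshold activity threshold the expression scales straddle.
#' @param stars list of planted hub-star modules, each a list with
#'   \code{state} ("ACTIVATED"/"SUPPRESSED"), \code{n_partners}, and
#'   optionally \code{p_on_T}, \code{p_on_N}.
#' @param lambda0 baseline exponential hazard (per day).
#' @param gamma log-hazard effect of the designated module's z-scored mean
#'   expression.
#' @param censoring target censoring fraction (independent exponential
#'   censoring calibrated at the baseline hazard).
#' @param prognostic_genes \code{"auto"} (first star's genes, else activated
#'   pair genes) or an explicit gene vector.
#' @param hallmark_prob per-hallmark membership probability per gene.
#' @param cancer_type label for the generated dataset.
#' @return Object of class \code{SyntheticScenario}.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_background_genes = 200L, pa_m = 2L,
                               n_decoys = 200L,
                               n_activated = 10L, n_suppressed = 10L,
                               p_on_T = 0.95, p_on_N = 0.02, p0 = 0.5,
                               n_tumor = 50L, n_normal = 50L,
                               mu_hi = log(8), mu_lo = log(0.1), sigma = 0.5,
                               fpkm_threshold = 1.0,
                               stars = list(),
                               lambda0 = 0.001, gamma = 0, censoring = 0.3,
                               prognostic_genes = "auto",
                               hallmark_prob = 0.15,
                               cancer_type = "SYN") {
  probs <- c(p_on_T, p_on_N, p0, hallmark_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (censoring < 0 || censoring >= 1) stop("censoring must lie in [0, 1)", call. = FALSE)
  if (!(mu_lo < log(fpkm_threshold) && log(fpkm_threshold) < mu_hi)) {
    stop("need mu_lo < log(fpkm_threshold) < mu_hi", call. = FALSE)
  }
  if (lambda0 <= 0) stop("lambda0 must be positive", call. = FALSE)
  for (s in stars) {
    if (!s$state %in% c("ACTIVATED", "SUPPRESSED")) {
      stop("star state must be ACTIVATED or SUPPRESSED", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "SyntheticScenario")
}

#' Generate a synthetic dataset from a scenario
#'
#' Draws per-gene, per-sample binary activity (background genes i.i.d.,
#' planted pairs with phenotype-dependent joint co-activity, star genes with
#' sqrt(p_on) marginals), samples expression conditional on activity,
#' survival times with hazard lambda0 * exp(gamma * z) where z is the
#' z-scored mean expression of the designated module genes over tumor
#' samples, hallmark memberships, and a drug table with known
#' direction-matched hits. Every planted truth is recorded in the manifest.
#'
#' @param scenario a \code{SyntheticScenario}.
#' @return Object of class \code{SyntheticData}: list with
#'   \code{expression} (\code{ExpressionDataset}), \code{survival}
#'   (\code{SurvivalTable}), \code{network} (\code{InteractionNetwork}),
#'   \code{gene_sets} (\code{HallmarkGeneSets}), \code{drugs}
#'   (\code{DrugInteractionTable}) and \code{manifest}.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  sc <- scenario
  set.seed(sc$seed)

  # --- decoy backbone ------------------------------------------------------
  bg_names <- sprintf("BG%04d", seq_len(sc$n_background_genes))
  ig <- igraph::sample_pa(sc$n_background_genes, power = 1, m = sc$pa_m,
                          directed = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  backbone <- canonical_edges(bg_names[el[, 1]], bg_names[el[, 2]])
  if (!is.null(sc$n_decoys)) {
    if (nrow(backbone) < sc$n_decoys) {
      stop(sprintf("backbone has only %d edges; cannot sample %d decoys",
                   nrow(backbone), sc$n_decoys), call. = FALSE)
    }
    backbone <- backbone[sort(sample.int(nrow(backbone), sc$n_decoys)), ,
                         drop = FALSE]
  }

  # --- planted differential pairs (endpoint-disjoint) ----------------------
  pair_edge <- function(prefix, i) c(sprintf("%s%02dA", prefix, i),
                                     sprintf("%s%02dB", prefix, i))
  act_pairs <- lapply(seq_len(sc$n_activated), function(i) pair_edge("ACT", i))
  sup_pairs <- lapply(seq_len(sc$n_suppressed), function(i) pair_edge("SUP", i))
  planted <- rbind(
    if (sc$n_activated > 0)
      data.frame(protein_a = vapply(act_pairs, `[`, character(1), 1L),
                 protein_b = vapply(act_pairs, `[`, character(1), 2L),
                 state = "ACTIVATED", p_on_T = sc$p_on_T, p_on_N = sc$p_on_N,
                 stringsAsFactors = FALSE),
    if (sc$n_suppressed > 0)
      data.frame(protein_a = vapply(sup_pairs, `[`, character(1), 1L),
                 protein_b = vapply(sup_pairs, `[`, character(1), 2L),
                 state = "SUPPRESSED", p_on_T = sc$p_on_N, p_on_N = sc$p_on_T,
                 stringsAsFactors = FALSE))

  # --- planted star modules ------------------------------------------------
  star_defs <- list()
  star_edges <- NULL
  for (j in seq_along(sc$stars)) {
    s <- sc$stars[[j]]
    hub <- sprintf("HUB%d", j)
    partners <- sprintf("HUB%dP%02d", j, seq_len(s$n_partners))
    pT <- s$p_on_T %||% if (s$state == "ACTIVATED") sc$p_on_T else sc$p_on_N
    pN <- s$p_on_N %||% if (s$state == "ACTIVATED") sc$p_on_N else sc$p_on_T
    star_defs[[j]] <- list(hub = hub, partners = partners, state = s$state,
                           p_on_T = pT, p_on_N = pN)
    star_edges <- rbind(star_edges, cbind(hub, partners))
  }

  edges <- rbind(backbone,
                 if (!is.null(planted)) as.matrix(planted[, 1:2]),
                 star_edges)
  net <- interaction_network(edges)

  samples <- c(sprintf("T%03d", seq_len(sc$n_tumor)),
               sprintf("N%03d", seq_len(sc$n_normal)))
  phenotype <- stats::setNames(rep(c("TUMOR", "NORMAL"),
                                   c(sc$n_tumor, sc$n_normal)), samples)
  is_T <- phenotype == "TUMOR"

  genes <- sort(unique(c(bg_names,
                         if (!is.null(planted)) c(planted$protein_a, planted$protein_b),
                         unlist(lapply(star_defs, function(s) c(s$hub, s$partners))))))
  n_g <- length(genes)
  n_s <- length(samples)

  # --- activity ------------------------------------------------------------
  active <- matrix(stats::rbinom(n_g * n_s, 1L, sc$p0), n_g, n_s,
                   dimnames = list(genes, samples))
  if (!is.null(planted)) {
    for (r in seq_len(nrow(planted))) {
      a <- planted$protein_a[r]; b <- planted$protein_b[r]
      for (ph in c(TRUE, FALSE)) {
        idx <- which(is_T == ph)
        p_on <- if (ph) planted$p_on_T[r] else planted$p_on_N[r]
        co <- stats::runif(length(idx)) < p_on
        side_a <- stats::runif(length(idx)) < 0.5   # which lone endpoint is on
        active[a, idx] <- as.integer(co | side_a)
        active[b, idx] <- as.integer(co | !side_a)
      }
    }
  }
  for (s in star_defs) {
    sg <- c(s$hub, s$partners)
    for (ph in c(TRUE, FALSE)) {
      idx <- which(is_T == ph)
      p_marg <- sqrt(if (ph) s$p_on_T else s$p_on_N)
      active[sg, idx] <- matrix(
        stats::rbinom(length(sg) * length(idx), 1L, p_marg),
        length(sg), length(idx))
    }
  }

  # --- expression conditional on activity ----------------------------------
  meanlog <- sc$mu_lo + active * (sc$mu_hi - sc$mu_lo)
  values <- matrix(stats::rlnorm(n_g * n_s, meanlog = meanlog, sdlog = sc$sigma),
                   n_g, n_s, dimnames = list(genes, samples))
  ds <- expression_dataset(values, phenotype, sc$cancer_type)

  # --- hallmark sets --------------------------------------------------------
  member <- matrix(stats::rbinom(n_g * 10L, 1L, sc$hallmark_prob), n_g, 10L,
                   dimnames = list(genes, HALLMARK_NAMES))
  none <- rowSums(member) == 0L
  if (any(none)) {
    member[cbind(which(none), sample.int(10L, sum(none), replace = TRUE))] <- 1L
  }
  sets <- lapply(HALLMARK_NAMES, function(h) genes[member[, h] == 1L])
  names(sets) <- HALLMARK_NAMES
  sets <- structure(sets, class = "HallmarkGeneSets")

  # --- survival -------------------------------------------------------------
  prog_genes <- sc$prognostic_genes
  if (identical(prog_genes, "auto")) {
    prog_genes <- if (length(star_defs) > 0) {
      c(star_defs[[1]]$hub, star_defs[[1]]$partners)
    } else if (!is.null(planted) && any(planted$state == "ACTIVATED")) {
      act <- planted[planted$state == "ACTIVATED", ]
      c(act$protein_a, act$protein_b)
    } else {
      genes[seq_len(min(10L, n_g))]
    }
  }
  tum <- samples[is_T]
  mexpr <- colMeans(values[prog_genes, tum, drop = FALSE])
  z <- if (stats::sd(mexpr) > 0) as.numeric(scale(mexpr)) else rep(0, length(tum))
  rate <- sc$lambda0 * exp(sc$gamma * z)
  t_event <- stats::rexp(length(tum), rate)
  rc <- sc$lambda0 * sc$censoring / (1 - sc$censoring)
  t_cens <- if (rc > 0) stats::rexp(length(tum), rc) else rep(Inf, length(tum))
  surv <- survival_table(data.frame(
    sample = tum,
    time = round(pmin(t_event, t_cens), 3),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE))

  # --- drug table -----------------------------------------------------------
  act_genes <- sort(unique(c(
    if (!is.null(planted)) with(planted[planted$state == "ACTIVATED", ],
                                c(protein_a, protein_b)),
    unlist(lapply(star_defs[vapply(star_defs, function(s)
      s$state == "ACTIVATED", logical(1))],
      function(s) c(s$hub, s$partners))))))
  sup_genes <- sort(unique(c(
    if (!is.null(planted)) with(planted[planted$state == "SUPPRESSED", ],
                                c(protein_a, protein_b)),
    unlist(lapply(star_defs[vapply(star_defs, function(s)
      s$state == "SUPPRESSED", logical(1))],
      function(s) c(s$hub, s$partners))))))
  drug_rows <- rbind(
    if (length(act_genes) > 0)
      data.frame(gene = act_genes, drug = paste0("inh-", tolower(act_genes)),
                 interaction_types = "inhibitor", approved = TRUE,
                 stringsAsFactors = FALSE),
    if (length(sup_genes) > 0)
      data.frame(gene = sup_genes, drug = paste0("actv-", tolower(sup_genes)),
                 interaction_types = "activator", approved = TRUE,
                 stringsAsFactors = FALSE),
    # decoys: unapproved correct-direction and approved wrong-direction hits
    if (length(act_genes) > 0)
      data.frame(gene = act_genes, drug = paste0("trial-", tolower(act_genes)),
                 interaction_types = "inhibitor", approved = FALSE,
                 stringsAsFactors = FALSE),
    if (length(act_genes) > 0)
      data.frame(gene = act_genes, drug = paste0("wrongdir-", tolower(act_genes)),
                 interaction_types = "agonist", approved = TRUE,
                 stringsAsFactors = FALSE),
    data.frame(gene = bg_names[seq_len(min(20L, length(bg_names)))],
               drug = "bg-panacea", interaction_types = "inhibitor",
               approved = TRUE, stringsAsFactors = FALSE))
  drugs <- drug_interaction_table(drug_rows)

  manifest <- list(
    seed = sc$seed, cancer_type = sc$cancer_type,
    n_tumor = sc$n_tumor, n_normal = sc$n_normal,
    n_decoys = nrow(backbone),
    planted_edges = planted %||% data.frame(),
    stars = star_defs,
    expected_q_activated = sc$p_on_T / (sc$p_on_T + sc$p_on_N),
    prognostic_genes = prog_genes, gamma = sc$gamma,
    lambda0 = sc$lambda0, censoring = sc$censoring,
    direction_matched_genes = list(activated = act_genes,
                                   suppressed = sup_genes))

  structure(list(expression = ds, survival = surv, network = net,
                 gene_sets = sets, drugs = drugs, manifest = manifest),
            class = "SyntheticData")
}

#' Write a synthetic dataset to disk in the package's input formats
#'
#' Writes \code{expression.tsv}, \code{phenotype.tsv}, \code{survival.tsv},
#' \code{network.tsv}, \code{hallmarks.gmt}, \code{drugs.tsv} and
#' \code{manifest.json}, in exactly the formats the loaders read (round-trip
#' tested). A missing directory is created; existing files are only
#' overwritten with \code{force = TRUE}.
#'
#' @param x a \code{SyntheticData}.
#' @param dir destination directory.
#' @param force overwrite existing files.
#' @return Invisibly, the named vector of written paths.
#' @export
write_scenario <- function(x, dir, force = FALSE) {
  stopifnot(inherits(x, "SyntheticData"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c(expression = "expression.tsv",
                            phenotype = "phenotype.tsv",
                            survival = "survival.tsv",
                            network = "network.tsv",
                            gene_sets = "hallmarks.gmt",
                            drugs = "drugs.tsv",
                            manifest = "manifest.json"))
  names(paths) <- c("expression", "phenotype", "survival", "network",
                    "gene_sets", "drugs", "manifest")
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0L && !force) {
    stop("refusing to overwrite existing file(s) without force = TRUE: ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }
  write_expression(x$expression, paths[["expression"]], paths[["phenotype"]])
  utils::write.table(as.data.frame(x$survival), paths[["survival"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(x$network, paths[["network"]])
  write_gene_sets(x$gene_sets, paths[["gene_sets"]])
  drg <- as.data.frame(x$drugs)
  names(drg)[names(drg) == "interaction_types"] <- "interaction_type"
  utils::write.table(drg, paths[["drugs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(x$manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
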