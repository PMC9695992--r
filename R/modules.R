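# Hub-centered differential modules: DIHCP extraction, star-module
# construction, size filtering and pooling of near-duplicate modules.

#' Extract differentially interacting hallmark proteins (DIHCPs)
#'
#' A DIHCP is any protein incident to at least one differential interaction
#' (state ACTIVATED or SUPPRESSED). Proteins are additionally classified by
#' the direction of their differential interactions; a protein with both
#' kinds appears in both groups.
#'
#' @param diffs a \code{DifferentialInteractome} data.frame.
#' @return List with sorted character vectors \code{all}, \code{activated},
#'   \code{suppressed}.
#' @export
extract_dihcps <- function(diffs) {
  act <- diffs$state == "ACTIVATED"
  sup <- diffs$state == "SUPPRESSED"
  activated <- sort(unique(c(diffs$protein_a[act], diffs$protein_b[act])))
  suppressed <- sort(unique(c(diffs$protein_a[sup], diffs$protein_b[sup])))
  list(all = sort(unique(c(activated, suppressed))),
       activated = activated, suppressed = suppressed)
}

#' @noRd
new_module <- function(hubs, members, edge_states, cancer_type) {
  m <- structure(list(name = canonical_module_name(hubs),
                      hubs = sort(unique(hubs)),
                      members = sort(unique(members)),
                      cancer_type = cancer_type,
                      edge_states = edge_states,
                      state = NA_character_),
                 class = "Module")
  m$state <- module_state(m)
  m
}

#' @export
print.Module <- function(x, ...) {
  cat(sprintf("Module %s [%s]: %d members, %d edges, state %s\n",
              x$name, x$cancer_type, length(x$members),
              nrow(x$edge_states), x$state))
  invisible(x)
}

#' Canonical module name from its hub symbols
#'
#' Singleton modules are named "m" + hub symbol. Pooled proteasome-subunit
#' modules (all hubs PSM*) are named \code{mPSMcomp} and pooled 14-3-3
#' modules (all hubs YWHA* or SFN, the 14-3-3 sigma gene) \code{mYWHAcomp};
#' other pooled modules join their sorted hub symbols with "+".
#'
#' @param hubs character vector of hub gene symbols.
#' @return Module name string.
#' @export
canonical_module_name <- function(hubs) {
  hubs <- sort(unique(hubs))
  if (length(hubs) == 1L) return(paste0("m", hubs))
  if (all(startsWith(hubs, "PSM"))) return("mPSMcomp")
  if (all(startsWith(hubs, "YWHA") | hubs == "SFN")) return("mYWHAcomp")
  paste0("m", paste(hubs, collapse = "+"))
}

#' Build hub-centered candidate modules
#'
#' Every DIHCP is a candidate hub; its module consists of the hub plus all
#' proteins sharing a differential interaction with it. Modules with fewer
#' than \code{min_size} members (hub included) are discarded.
#'
#' @param diffs a \code{DifferentialInteractome}.
#' @param cancer_type label attached to the modules.
#' @param min_size minimum member count, default 10.
#' @return List of \code{Module} objects, sorted by name.
#' @export
build_modules <- function(diffs, cancer_type = "NA", min_size = 10L) {
  if (min_size < 2L) stop("min_size must be >= 2", call. = FALSE)
  de <- diffs[diffs$state %in% c("ACTIVATED", "SUPPRESSED"), , drop = FALSE]
  hubs <- sort(unique(c(de$protein_a, de$protein_b)))
  mods <- list()
  for (h in hubs) {
    inc <- de$protein_a == h | de$protein_b == h
    partners <- setdiff(unique(c(de$protein_a[inc], de$protein_b[inc])), h)
    members <- c(h, partners)
    if (length(members) < min_size) next
    es <- data.frame(protein_a = de$protein_a[inc], protein_b = de$protein_b[inc],
                     state = de$state[inc], stringsAsFactors = FALSE)
    mods[[length(mods) + 1L]] <- new_module(h, members, es, cancer_type)
  }
  mods[order(vapply(mods, `[[`, character(1), "name"))]
}

#' Composite interaction state of a module
#'
#' @param m a \code{Module} with at least one differential edge.
#' @return \code{"ALL_ACTIVATED"}, \code{"ALL_SUPPRESSED"} or \code{"MIXED"}.
#' @export
module_state <- function(m) {
  st <- m$edge_states$state
  if (length(st) == 0L) stop("module has no differential edges", call. = FALSE)
  if (all(st == "ACTIVATED")) return("ALL_ACTIVATED")
  if (all(st == "SUPPRESSED")) return("ALL_SUPPRESSED")
  "MIXED"
}

#' @noRd
module_overlap <- function(a, b, metric) {
  inter <- length(intersect(a$members, b$members))
  if (metric == "overlap") {
    inter / min(length(a$members), length(b$members))
  } else {
    inter / length(union(a$members, b$members))
  }
}

#' Pool near-duplicate modules
#'
#' Modules of one cancer type sharing at least \code{overlap_threshold} of
#' the proteins of the smaller module (overlap coefficient
#' \eqn{|A \cap B| / \min(|A|,|B|)}) are merged iteratively until no
#' qualifying pair remains. Merging unions hubs, members and edge states and
#' renames the module canonically (\code{\link{canonical_module_name}});
#' candidate pairs are processed in lexicographic name order, which together
#' with canonical renaming makes the result independent of input order.
#'
#' @param mods list of \code{Module}s with a common cancer type.
#' @param overlap_threshold in (0, 1]; default 0.70.
#' @param metric \code{"overlap"} (default) or \code{"jaccard"}.
#' @return List of pooled \code{Module}s, sorted by name.
#' @export
pool_modules <- function(mods, overlap_threshold = 0.70,
                         metric = c("overlap", "jaccard")) {
  metric <- match.arg(metric)
  if (!is.numeric(overlap_threshold) || overlap_threshold <= 0 ||
      overlap_threshold > 1) {
    stop("overlap_threshold must be in (0, 1]", call. = FALSE)
  }
  if (length(mods) <= 1L) return(mods)
  ct <- unique(vapply(mods, `[[`, character(1), "cancer_type"))
  if (length(ct) > 1L) stop("pool_modules requires a single cancer type", call. = FALSE)
  mods <- mods[order(vapply(mods, `[[`, character(1), "name"))]
  repeat {
    n <- length(mods)
    if (n <= 1L) break
    nms <- vapply(mods, `[[`, character(1), "name")
    ord <- order(nms)
    mods <- mods[ord]
    nms <- nms[ord]
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (module_overlap(mods[[i]], mods[[j]], metric) >= overlap_threshold) {
          best <- c(i, j)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) break
    a <- mods[[best[1]]]; b <- mods[[best[2]]]
    es <- unique(rbind(a$edge_states, b$edge_states))
    rownames(es) <- NULL
    merged <- new_module(c(a$hubs, b$hubs), c(a$members, b$members), es, a$cancer_type)
    mods <- c(mods[-best], list(merged))
  }
  mods[order(vapply(mods, `[[`, character(1), "name"))]
}

#' Export modules as a TSV table
#'
#' One row per module: name, cancer type, hubs, state, member count and the
#' comma-separated member list.
#'
#' @param mods list of \code{Module}s.
#' @param path destination TSV (optional; omit to just get the data.frame).
#' @return data.frame (invisibly when written).
#' @export
modules_table <- function(mods, path = NULL) {
  df <- data.frame(
    module = vapply(mods, `[[`, character(1), "name"),
    cancer_type = vapply(mods, `[[`, character(1), "cancer_type"),
    hubs = vapply(mods, function(m) paste(m$hubs, collapse = ","), character(1)),
    state = vapply(mods, `[[`, character(1), "state"),
    n_members = vapply(mods, function(m) length(m$members), integer(1)),
    members = vapply(mods, function(m) paste(m$members, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @noRd
modules_igraph <- function(mods) {
  edges <- do.call(rbind, lapply(mods, function(m) {
    cbind(m$edge_states$protein_a, m$edge_states$protein_b,
          m$edge_states$state, m$name)
  }))
  edges <- unique(edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               state = edges[, 3], module = edges[, 4],
               stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' Export module edges for Cytoscape
#'
#' Writes the union of module edges in SIF (\code{A <state> B}) and GraphML
#' formats.
#'
#' @param mods list of \code{Module}s.
#' @param sif_path,graphml_path destinations; either may be NULL to skip.
#' @export
write_modules_graph <- function(mods, sif_path = NULL, graphml_path = NULL) {
  if (length(mods) == 0L) {
    if (!is.null(sif_path)) writeLines(character(0), sif_path)
    if (!is.null(graphml_path)) {
      igraph::write_graph(igraph::make_empty_graph(directed = FALSE),
                          graphml_path, format = "graphml")
    }
    return(invisible(NULL))
  }
  if (!is.null(sif_path)) {
    rows <- unique(do.call(rbind, lapply(mods, function(m) {
      cbind(m$edge_states$protein_a, tolower(m$edge_states$state),
            m$edge_states$protein_b)
    })))
    writeLines(apply(rows, 1L, paste, collapse = "\t"), sif_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(modules_igraph(mods), graphml_path, format = "graphml")
  }
  invisible(NULL)
}
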