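#' Protein-protein interaction network container
#'
#' Undirected simple graph stored as a canonical edge table: no self-loops,
#' unordered duplicates merged, smaller endpoint symbol first.
#'
#' @param a,b character vectors of endpoint gene symbols (recycled pairwise).
#' @return Object of class \code{InteractionNetwork}: list with \code{edges}
#'   (two-column character matrix), \code{nodes}, \code{n_edges},
#'   \code{n_nodes}.
#' @export
interaction_network <- function(a, b = NULL) {
  if (is.null(b)) {                      # allow a two-column matrix/data.frame
    stopifnot(ncol(a) >= 2L)
    b <- as.character(a[, 2]); a <- as.character(a[, 1])
  }
  edges <- canonical_edges(a, b)
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  structure(list(edges = edges, nodes = nodes,
                 n_edges = nrow(edges), n_nodes = length(nodes)),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d interactions among %d proteins\n",
              x$n_edges, x$n_nodes))
  invisible(x)
}

#' Read a protein-protein interaction network
#'
#' Two dialects are supported: \code{edge_list}, a two-column TSV of gene
#' symbols, and \code{biogrid_tab}, a BioGRID tab-delimited export from which
#' only the "Official Symbol Interactor A"/"B" columns are used (interaction
#' type and throughput filtering is assumed done upstream). Self-loops are
#' removed and unordered duplicate edges merged.
#'
#' @param path input file.
#' @param dialect \code{"edge_list"} or \code{"biogrid_tab"}.
#' @return An \code{\link{interaction_network}}.
#' @export
load_network <- function(path, dialect = c("edge_list", "biogrid_tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "edge_list") {
    tab <- read_text_table(path, header = FALSE,
                           colClasses = "character")
    if (ncol(tab) < 2L) stop("edge list needs two columns", call. = FALSE)
    a <- as.character(tab[[1]]); b <- as.character(tab[[2]])
    # drop a header line if present (common in exported edge lists)
    if (length(a) > 0L && grepl("protein|gene|symbol|interactor", a[1],
                                ignore.case = TRUE)) {
      a <- a[-1]; b <- b[-1]
    }
  } else {
    tab <- read_text_table(path, header = TRUE, colClasses = "character")
    ca <- grep("^Official Symbol Interactor A$", names(tab))
    cb <- grep("^Official Symbol Interactor B$", names(tab))
    if (length(ca) != 1L || length(cb) != 1L) {
      stop("BioGRID file lacks 'Official Symbol Interactor A/B' columns",
           call. = FALSE)
    }
    a <- as.character(tab[[ca]]); b <- as.character(tab[[cb]])
  }
  net <- interaction_network(a, b)
  if (net$n_edges < 1L) {
    stop("no edges left after removing self-loops and duplicates: ", path,
         call. = FALSE)
  }
  message(sprintf("loaded %d interactions among %d proteins from %s",
                  net$n_edges, net$n_nodes, basename(path)))
  net
}

#' Read hallmark (or pathway) gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields set name, description, then member
#' gene symbols. Duplicate members within a set are removed; a gene may
#' belong to several sets.
#'
#' @param path GMT file.
#' @return Object of class \code{HallmarkGeneSets}: a named list of character
#'   vectors.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  sets <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm, call. = FALSE)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("empty gene set: ", nm, call. = FALSE)
    sets[[nm]] <- members
  }
  if (length(sets) == 0L) stop("no gene sets found in ", path, call. = FALSE)
  structure(sets, class = "HallmarkGeneSets")
}

#' Write gene sets to a GMT file
#' @param sets a \code{HallmarkGeneSets} (named list of character vectors).
#' @param path destination.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Restrict an interaction network to hallmark-annotated, measured proteins
#'
#' Keeps only edges whose both endpoints lie in the intersection of the
#' hallmark gene universe and the genes measured in the expression data; the
#' node set becomes the endpoints of the surviving edges. This is the
#' hallmark-restricted interactome all downstream stages operate on.
#'
#' @param net an \code{InteractionNetwork}.
#' @param hallmark_genes character vector of hallmark gene symbols.
#' @param measured_genes character vector of genes present in the expression
#'   matrix.
#' @return The induced \code{InteractionNetwork}.
#' @export
reconstruct_network <- function(net, hallmark_genes, measured_genes) {
  stopifnot(inherits(net, "InteractionNetwork"))
  universe <- intersect(unique(hallmark_genes), unique(measured_genes))
  keep <- net$edges[, 1] %in% universe & net$edges[, 2] %in% universe
  if (!any(keep)) {
    stop(paste("no interactions survive the hallmark/measured restriction;",
               "check that the expression matrix, network and gene sets use",
               "the same identifier namespace (official gene symbols)"),
         call. = FALSE)
  }
  interaction_network(net$edges[keep, , drop = FALSE])
}

#' Write a network as a two-column TSV edge list
#' @param net an \code{InteractionNetwork}.
#' @param path destination.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(net)
}
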