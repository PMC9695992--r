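#' Expression dataset container
#'
#' Bundles a genes x samples matrix of non-negative FPKM-like expression
#' values with a tumor/normal phenotype map and an optional cancer-type
#' label. Gene and protein identifiers are treated as the same token
#' (official gene symbols) throughout the package.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs). All values must be finite
#'   and non-negative.
#' @param phenotype named character vector mapping every sample ID to
#'   \code{"TUMOR"} or \code{"NORMAL"} (case-insensitive on input).
#' @param cancer_type short label such as \code{"BRCA"}.
#' @return An object of class \code{ExpressionDataset}: a list with elements
#'   \code{values}, \code{phenotype} (named, uppercase) and
#'   \code{cancer_type}.
#' @export
expression_dataset <- function(values, phenotype, cancer_type = "NA") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene IDs: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid expression value at gene '%s', sample '%s' (%s)",
                 genes[bad[1, 1]], samples[bad[1, 2]],
                 format(values[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  phenotype <- toupper(phenotype)
  missing_ph <- setdiff(samples, names(phenotype))
  if (length(missing_ph) > 0L) {
    stop("missing phenotype for sample(s): ",
         paste(missing_ph, collapse = ", "), call. = FALSE)
  }
  phenotype <- phenotype[samples]
  if (!all(phenotype %in% c("TUMOR", "NORMAL"))) {
    stop("phenotype values must be TUMOR or NORMAL", call. = FALSE)
  }
  if (sum(phenotype == "TUMOR") < 1L || sum(phenotype == "NORMAL") < 1L) {
    stop("need at least one tumor and one normal sample", call. = FALSE)
  }
  structure(list(values = values, phenotype = phenotype,
                 cancer_type = as.character(cancer_type)),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset [%s]: %d genes x %d samples (%d tumor / %d normal)\n",
              x$cancer_type, nrow(x$values), ncol(x$values),
              sum(x$phenotype == "TUMOR"), sum(x$phenotype == "NORMAL")))
  invisible(x)
}

#' Read an expression matrix and phenotype map from TSV files
#'
#' The expression file is tab-separated with a header row of sample IDs and
#' gene symbols in the first column. The phenotype file has two columns:
#' sample ID and \code{tumor}/\code{normal}. Comment lines starting with
#' \code{#} and CRLF line endings are tolerated. Duplicated gene rows are
#' collapsed by keeping the row with the highest mean expression (a warning
#' reports the collapsed symbols).
#'
#' @param path path to the expression TSV.
#' @param phenotype_path path to the two-column phenotype TSV.
#' @param cancer_type cancer-type label stored in the dataset.
#' @return An \code{\link{expression_dataset}}.
#' @export
load_expression <- function(path, phenotype_path, cancer_type = "NA") {
  tab <- read_text_table(path, header = TRUE)
  if (ncol(tab) < 2L) stop("expression file needs >= 1 sample column", call. = FALSE)
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                     v[bad[1]], genes[bad[1]], colnames(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative expression value %s at gene '%s', sample '%s'",
                 format(m[neg[1, , drop = FALSE]]),
                 genes[neg[1, 1]], colnames(m)[neg[1, 2]]), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("collapsing duplicated gene row(s) by highest mean expression: ",
            paste(dups, collapse = ", "), call. = FALSE)
    means <- rowMeans(m)
    ord <- order(-means)            # highest-mean row wins
    m <- m[ord, , drop = FALSE]
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    m <- m[order(match(rownames(m), unique(genes))), , drop = FALSE]
  }
  ph <- load_phenotype(phenotype_path)
  expression_dataset(m, ph, cancer_type)
}

#' Read a two-column sample-to-phenotype map
#'
#' @param path TSV with columns sample ID and phenotype
#'   (\code{tumor}/\code{normal}, case-insensitive). A header line is
#'   detected and skipped when its second field is not a phenotype value.
#' @return Named character vector sample -> \code{TUMOR}/\code{NORMAL}.
#' @export
load_phenotype <- function(path) {
  tab <- read_text_table(path, header = FALSE)
  if (ncol(tab) < 2L) stop("phenotype file needs two columns", call. = FALSE)
  if (!toupper(tab[1, 2]) %in% c("TUMOR", "NORMAL")) tab <- tab[-1, , drop = FALSE]
  ph <- toupper(as.character(tab[[2]]))
  names(ph) <- as.character(tab[[1]])
  if (anyDuplicated(names(ph))) {
    stop("duplicate sample IDs in phenotype file", call. = FALSE)
  }
  ph
}

#' Read a clinical survival table
#'
#' @param path TSV with three columns: sample ID, follow-up time in days and
#'   event indicator (1 = death observed, 0 = censored). A header line is
#'   detected and skipped.
#' @return data.frame of class \code{SurvivalTable} with columns
#'   \code{sample}, \code{time}, \code{event}.
#' @export
load_survival <- function(path) {
  tab <- read_text_table(path, header = FALSE)
  if (ncol(tab) < 3L) stop("survival file needs three columns", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
  survival_table(data.frame(sample = as.character(tab[[1]]),
                            time = as.numeric(tab[[2]]),
                            event = as.integer(tab[[3]]),
                            stringsAsFactors = FALSE))
}

#' Validate a survival table
#'
#' @param df data.frame with columns \code{sample}, \code{time} (days, >= 0)
#'   and \code{event} (0/1).
#' @return The validated data.frame with class \code{SurvivalTable} prepended.
#' @export
survival_table <- function(df) {
  stopifnot(all(c("sample", "time", "event") %in% names(df)))
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in survival table", call. = FALSE)
  if (any(!is.finite(df$time) | df$time < 0)) stop("survival times must be >= 0", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1", call. = FALSE)
  class(df) <- c("SurvivalTable", "data.frame")
  df
}

#' Write an expression dataset back to TSV files
#'
#' Inverse of \code{\link{load_expression}}; used for round-trips and by the
#' synthetic-data writer.
#'
#' @param ds an \code{ExpressionDataset}.
#' @param path expression TSV destination.
#' @param phenotype_path phenotype TSV destination.
#' @export
write_expression <- function(ds, path, phenotype_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  tab <- data.frame(gene = rownames(ds$values), ds$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(sample = names(ds$phenotype),
                   phenotype = tolower(ds$phenotype))
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ds)
}
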