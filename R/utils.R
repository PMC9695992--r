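# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
read_text_table <- function(path, header = TRUE, colClasses = NA) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)                  # tolerate CRLF
  lines <- lines[!grepl("^#", lines)]             # tolerate comment lines
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("file is empty after removing comments: ", path, call. = FALSE)
  }
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    header = header, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = colClasses,
                    quote = "")
}

# Canonical unordered edge representation: two-column character matrix with
# the lexicographically smaller endpoint first, self-loops and duplicates
# removed.
#' @noRd
canonical_edges <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  keep <- a != b & nzchar(a) & nzchar(b)
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  dup <- duplicated(key)
  cbind(protein_a = lo[!dup], protein_b = hi[!dup])
}

#' @noRd
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Column-wise z-scoring that reports zero-variance columns instead of
# producing NaN.
#' @noRd
zscore_columns <- function(x) {
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  list(x = sweep(sweep(x, 2L, ctr, "-"), 2L, ifelse(sds > 0, sds, 1), "/"),
       center = ctr, scale = sds, constant = sds == 0)
}

# Deterministic polynomial string hash within 32-bit integer range, used to
# derive RNG substreams that depend on a sample pool's content rather than
# its label. All intermediates stay below 2^53 so the arithmetic is exact.
#' @noRd
string_hash <- function(s) {
  h <- 5381
  for (v in utf8ToInt(s)) {
    h <- (h * 131 + v) %% 2147483629
  }
  as.integer(h)
}

#' @noRd
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) string_hash(paste(p, collapse = ",")) else as.integer(p)
  }, integer(1))
  s <- as.integer(seed)
  for (p in parts) s <- as.integer((as.double(s) * 31 + as.double(p)) %% 2147483629)
  s
}
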