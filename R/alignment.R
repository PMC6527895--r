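# Alignment container and per-column classification.
#
# An alignment is stored as a character matrix (samples x columns) over the
# alphabet {A,C,G,T,N,-}; N and '-' are treated as missing data unless gaps
# are explicitly promoted to a fifth state.

ALN_BASES <- c("A", "C", "G", "T")
ALN_MISSING <- c("N", "-")
ALN_ALPHABET <- c(ALN_BASES, ALN_MISSING)

new_alignment <- function(mat, name = "aln") {
  stopifnot(is.matrix(mat), is.character(mat))
  structure(mat, class = "cb_aln", aln_name = name)
}

#' Build an alignment from sequence strings
#'
#' @param seqs character vector, one string per sample, all of equal length,
#'   over the alphabet `A,C,G,T,N,-`. Lowercase letters are upper-cased;
#'   any other symbol (including IUPAC ambiguity codes other than N) is
#'   normalised to `N` with a warning.
#' @param ids sample identifiers; defaults to `names(seqs)`. Must be unique.
#' @param name label for the alignment (used as the chromosome name in BED
#'   output).
#' @return an object of class `cb_aln`: a samples x columns character matrix
#'   with sample ids as row names.
#' @examples
#' aln <- as_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' dim(aln)
#' @export
as_alignment <- function(seqs, ids = names(seqs), name = "aln") {
  if (length(seqs) == 0)
    stop("input error: alignment must contain at least one sequence")
  if (is.null(ids))
    ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids))
    stop("identity error: duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment-shape error: sequences have unequal lengths (",
         paste(sort(unique(widths)), collapse = ", "), ")")
  if (widths[1] < 1L)
    stop("input error: alignment has zero columns")
  mat <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- !(mat %in% ALN_ALPHABET)
  if (any(bad)) {
    warning("normalised ", sum(bad), " symbol(s) outside {A,C,G,T,N,-} to N: ",
            paste(sort(unique(mat[bad])), collapse = ", "))
    mat[bad] <- "N"
  }
  new_alignment(mat, name = name)
}

#' Read a multiple sequence alignment from FASTA
#'
#' Records may be line-wrapped or unwrapped. Sequences are case-normalised;
#' IUPAC ambiguity codes other than `N` are demoted to `N` with a warning
#' (upstream consensus reconstructions emit them, masking them keeps the
#' missing-data bookkeeping honest).
#'
#' @param path path to a FASTA file.
#' @param name alignment label; defaults to the file name without extension.
#' @return a [as_alignment()] object.
#' @export
read_alignment <- function(path, name = NULL) {
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0)
    stop("input error: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(name))
    name <- sub("\\.(fa|fasta|fna|aln)$", "", basename(path), ignore.case = TRUE)
  as_alignment(as.character(set), ids = ids, name = name)
}

#' Write an alignment to FASTA
#'
#' @param aln a `cb_aln` object.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln_seqs(aln))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Sequence strings of an alignment
#'
#' @param aln a `cb_aln` object.
#' @return named character vector, one string per sample.
#' @export
aln_seqs <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' @export
print.cb_aln <- function(x, ...) {
  cat(sprintf("<alignment '%s': %d samples x %d columns>\n",
              attr(x, "aln_name"), nrow(x), ncol(x)))
  invisible(x)
}

aln_name <- function(aln) attr(aln, "aln_name") %||% "aln"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify alignment columns
#'
#' For every column, counts the four nucleotide states among samples and
#' flags the column as variable (at least two distinct states among
#' `A,C,G,T`) and/or parsimony-informative (at least two states each carried
#' by at least two samples). `N` and `-` are missing data by default; set
#' `gap_as_state = TRUE` to count the gap as a fifth character state for
#' variability/PIS calls (then only `N` is missing).
#'
#' @param aln a `cb_aln` object.
#' @param gap_as_state treat `-` as a fifth state instead of missing data.
#' @return data.frame with one row per column: `column` (0-based index),
#'   `A`, `C`, `G`, `T` counts, `missing` count, `missing_fraction`,
#'   `variable`, `pis`.
#' @examples
#' aln <- as_alignment(c(a = "AAAC", b = "AACC", c = "ANCC", d = "A-CC"))
#' classify_columns(aln)
#' @export
classify_columns <- function(aln, gap_as_state = FALSE) {
  mat <- unclass(aln)
  n <- nrow(mat)
  L <- ncol(mat)
  states <- if (gap_as_state) c(ALN_BASES, "-") else ALN_BASES
  counts <- vapply(states, function(b) .colSums(mat == b, n, L), numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, states))
  miss_states <- if (gap_as_state) "N" else ALN_MISSING
  missing <- .colSums(matrix(mat %in% miss_states, n, L), n, L)
  data.frame(
    column = seq_len(L) - 1L,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    missing = as.integer(missing),
    missing_fraction = missing / n,
    variable = rowSums(counts > 0L) >= 2L,
    pis = rowSums(counts >= 2L) >= 2L
  )
}

#' Percentage of sites, rounded half-up
#'
#' `100 * count / length`, rounded half-up to two decimal places — the
#' rounding that reproduces published percent-variable and
#' percent-parsimony-informative values from their integer counts.
#'
#' @param count non-negative integer, `count <= length`.
#' @param length positive integer.
#' @return numeric percentage with two decimals.
#' @examples
#' percent(39, 1530) # 2.55
#' percent(48, 501)  # 9.58
#' @export
percent <- function(count, length) {
  if (any(length <= 0)) stop("domain error: length must be positive")
  if (any(count < 0) || any(count > length))
    stop("domain error: need 0 <= count <= length")
  floor(count * 10000 / length + 0.5) / 100
}

#' Write a per-column summary table
#'
#' TSV with header `column_1based, A, C, G, T, missing, variable, pis`;
#' coordinates are 1-based in this human-facing report.
#'
#' @param summary result of [classify_columns()].
#' @param path output TSV path.
#' @export
write_column_summary <- function(summary, path) {
  out <- data.frame(
    column_1based = summary$column + 1L,
    A = summary$A, C = summary$C, G = summary$G, T = summary$T,
    missing = summary$missing,
    variable = summary$variable, pis = summary$pis
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
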