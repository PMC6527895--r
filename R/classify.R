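# Query classification against a diagnostic matrix.
#
# The pharmacopoeial framing is pass/fail: a query is compatible with an
# OPU only if every resolved query state equals the OPU's state at that
# position. Missing query data (N) never excludes an OPU, and an OPU cell
# of N or "polymorphic" carries no exclusionary information, so it matches
# any query state.

#' Build a query profile over the matrix positions
#'
#' Accepts either a pre-aligned state vector (one symbol per matrix
#' position) or a named list/vector of per-region sequences whose names
#' match the matrix's region labels. Per-region sequences must have exactly
#' the region length recorded in the matrix (align first if not); the state
#' at each matrix position is read off, and anything outside `A,C,G,T`
#' becomes `N`.
#'
#' @param query character vector: either length `ncol(matrix)` of single
#'   states, or named per-region sequences.
#' @param matrix a `cb_diag_matrix`.
#' @param query_id identifier for reports.
#' @return object of class `cb_profile`: list with `query_id`, `states`.
#' @export
profile_query <- function(query, matrix, query_id = "query") {
  k <- length(matrix$labels)
  query <- toupper(unlist(query))
  if (is.null(names(query)) || all(nchar(query) == 1L)) {
    if (length(query) != k)
      stop("interface error: expected ", k, " states, got ", length(query))
    states <- query
  } else {
    regions <- unique(matrix$region)
    missing_regions <- setdiff(regions, names(query))
    if (length(missing_regions))
      stop("interface error: no sequence for region(s): ",
           paste(missing_regions, collapse = ", "))
    if (!is.null(matrix$region_lengths)) {
      for (rg in regions) {
        want <- matrix$region_lengths[[rg]]
        if (!is.null(want) && nchar(query[[rg]]) != want)
          stop("interface error: region '", rg, "' sequence is ",
               nchar(query[[rg]]), " bp but the matrix expects ", want,
               " bp; align the query to the region first")
      }
    }
    states <- vapply(seq_len(k), function(j) {
      seq <- query[[matrix$region[j]]]
      p <- matrix$pos1[j]
      if (p > nchar(seq)) "N" else substr(seq, p, p)
    }, "")
  }
  states[!(states %in% ALN_BASES)] <- "N"
  structure(list(query_id = query_id, states = unname(states)),
            class = "cb_profile")
}

#' Classify one query profile
#'
#' An OPU is compatible when the number of conflicting positions (query and
#' OPU both resolved to a base, and different) is at most `max_mismatch`
#' (default 0, the pass/fail standard). The call is `unique` for exactly
#' one compatible OPU, `ambiguous` for several, `no_match` for none, and
#' `unidentifiable` when every query state is missing (then all OPUs are
#' trivially compatible).
#'
#' @param profile a [profile_query()] object.
#' @param matrix a `cb_diag_matrix`.
#' @param max_mismatch tolerated conflicting positions per OPU (default 0).
#' @return object of class `cb_classification`: list with `query_id`,
#'   `compatible_opus`, `call`, `mismatch_detail` (per-OPU conflicting
#'   position labels).
#' @export
classify_query <- function(profile, matrix, max_mismatch = 0L) {
  q <- profile$states
  k <- length(matrix$labels)
  if (length(q) != k)
    stop("interface error: profile has ", length(q),
         " states for a matrix with ", k, " positions")
  opus <- rownames(matrix$profiles)
  detail <- lapply(opus, function(o) {
    st <- matrix$profiles[o, ]
    conflict <- q %in% ALN_BASES & st %in% ALN_BASES & q != st
    matrix$labels[conflict]
  })
  names(detail) <- opus
  compatible <- opus[lengths(detail) <= max_mismatch]
  call <- if (all(q == "N")) "unidentifiable"
          else if (length(compatible) == 1L) "unique"
          else if (length(compatible) == 0L) "no_match"
          else "ambiguous"
  structure(list(
    query_id = profile$query_id,
    compatible_opus = compatible,
    call = call,
    mismatch_detail = detail[lengths(detail) > 0L]
  ), class = "cb_classification")
}

#' @export
print.cb_classification <- function(x, ...) {
  cat(sprintf("query '%s': %s (%s)\n", x$query_id, x$call,
              paste(x$compatible_opus, collapse = ", ")))
  invisible(x)
}

#' Classify several queries into a report table
#'
#' @param profiles list of [profile_query()] objects.
#' @param matrix a `cb_diag_matrix`.
#' @param max_mismatch see [classify_query()].
#' @return data.frame: `query`, `call`, `compatible_opus` (comma-joined),
#'   `n_compatible`, `mismatches` (per-OPU conflict summary).
#' @export
classify_queries <- function(profiles, matrix, max_mismatch = 0L) {
  rows <- lapply(profiles, function(p) {
    r <- classify_query(p, matrix, max_mismatch)
    data.frame(
      query = r$query_id,
      call = r$call,
      compatible_opus = paste(r$compatible_opus, collapse = ","),
      n_compatible = length(r$compatible_opus),
      mismatches = paste(
        vapply(names(r$mismatch_detail), function(o)
          sprintf("%s[%s]", o, paste(r$mismatch_detail[[o]], collapse = ";")),
          ""),
        collapse = " ")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a classification report
#'
#' @param report result of [classify_queries()].
#' @param path output TSV path; a sibling `.json` is written too.
#' @export
write_classification <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read query profiles from TSV
#'
#' TSV with a `query` column and one column per matrix position (labels
#' must match the matrix's `region:position` labels).
#'
#' @param path TSV path.
#' @param matrix a `cb_diag_matrix`.
#' @return list of `cb_profile` objects.
#' @export
read_query_profiles <- function(path, matrix) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!"query" %in% colnames(df))
    stop("input error: profile TSV needs a 'query' column")
  missing_cols <- setdiff(matrix$labels, colnames(df))
  if (length(missing_cols))
    stop("interface error: profile TSV lacks position column(s): ",
         paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    states <- as.character(df[i, matrix$labels])
    double <- grepl("^([ACGTN])\\1$", states)
    states[double] <- substr(states[double], 1, 1)
    profile_query(states, matrix, query_id = df$query[i])
  })
}
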