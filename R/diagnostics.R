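# Clade-diagnostic position discovery and the diagnostic matrix.
#
# An OPU (Operational Phylogenetic Unit) is a clade chosen on a reference
# phylogeny as the identification target. A nucleotide state is diagnostic
# for an OPU when it is fixed among the OPU's non-missing members and absent
# from every non-missing member of every other OPU ("simple pure diagnostic
# character"). Positions that merely separate some pair of OPUs still feed
# profile-based discrimination, so they are retained in the matrix.

#' Construct an OPU assignment
#'
#' @param samples sample ids.
#' @param opus OPU label per sample.
#' @return object of class `cb_opus`: list with `mapping` (named character,
#'   sample -> OPU) and `opu_labels` (in order of first appearance).
#' @export
opu_assignment <- function(samples, opus) {
  stopifnot(length(samples) == length(opus))
  if (length(samples) == 0)
    stop("input error: empty OPU assignment")
  dup <- duplicated(samples)
  if (any(dup)) {
    for (s in unique(samples[dup])) {
      if (length(unique(opus[samples == s])) > 1L)
        stop("assignment error: sample '", s,
             "' listed with conflicting OPUs")
    }
    opus <- opus[!dup]
    samples <- samples[!dup]
  }
  structure(list(
    mapping = stats::setNames(as.character(opus), samples),
    opu_labels = unique(as.character(opus))
  ), class = "cb_opus")
}

#' Read a sample-to-OPU table
#'
#' Two-column TSV (`sample`, `opu`); a header row is optional and detected
#' by name. Duplicate rows are tolerated when consistent; a sample mapped to
#' two different OPUs is an error.
#'
#' @param path TSV path.
#' @return a [opu_assignment()] object.
#' @export
read_opu_table <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", comment.char = "#",
                      strip.white = TRUE),
    error = function(e) stop("input error: cannot parse OPU table: ",
                             conditionMessage(e)))
  if (ncol(raw) < 2L)
    stop("input error: OPU table needs two columns (sample, opu)")
  if (tolower(raw[1, 1]) == "sample" && tolower(raw[1, 2]) == "opu")
    raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0)
    stop("input error: OPU table has no data rows")
  opu_assignment(raw[[1]], raw[[2]])
}

#' @export
print.cb_opus <- function(x, ...) {
  cat(sprintf("<OPU assignment: %d samples in %d OPUs>\n",
              length(x$mapping), length(x$opu_labels)))
  print(table(x$mapping))
  invisible(x)
}

# Per-OPU state call at a set of columns.
# counts: 4 x k base counts among the OPU's members; size: OPU sample count.
# Fixed state if exactly one base observed, >=1 member observed and the
# within-OPU missing fraction is at most max_missing; all-missing -> "N";
# otherwise "polymorphic".
.opu_states <- function(counts, size, max_missing) {
  observed <- colSums(counts)
  n_states <- colSums(counts > 0L)
  miss_frac <- (size - observed) / size
  state <- rep("polymorphic", ncol(counts))
  state[observed == 0L | miss_frac > max_missing] <- "N"
  fixed <- n_states == 1L & observed > 0L & miss_frac <= max_missing
  state[fixed] <- ALN_BASES[apply(counts[, fixed, drop = FALSE], 2L, which.max)]
  state
}

#' Find clade-diagnostic alignment positions
#'
#' Scans every variable column and calls each OPU's state: the shared base
#' when all non-missing members agree (requiring at least one observed
#' member and a within-OPU missing fraction of at most
#' `max_missing_in_group`), `N` when unobserved or too gappy, else
#' `polymorphic`. A state is diagnostic for an OPU when fixed within it and
#' absent from all non-missing members of every other OPU. Columns are
#' reported when they are diagnostic for some OPU or separate at least one
#' pair of OPUs with fixed, different states.
#'
#' Samples present in the alignment but absent from the assignment are
#' excluded with a message; samples in the assignment but missing from the
#' alignment are an error.
#'
#' @param aln a `cb_aln` object.
#' @param opus a [opu_assignment()] object.
#' @param max_missing_in_group maximum within-OPU missing fraction for a
#'   fixed-state call (default 0.5).
#' @param regions optional `cb_regions` table used to express position
#'   labels as `region:pos` with 1-based positions inside each region;
#'   without it labels are `alignmentname:pos` over the whole alignment.
#' @return object of class `cb_positions`: list with `columns` (0-based),
#'   `labels`, `region`, `pos1`, `states` (OPU x position character
#'   matrix), `diagnostic_for` (list of OPU vectors per position).
#' @export
find_diagnostic_positions <- function(aln, opus, max_missing_in_group = 0.5,
                                      regions = NULL) {
  mapping <- opus$mapping
  miss_tab <- setdiff(rownames(aln), names(mapping))
  if (length(miss_tab)) {
    message("excluding ", length(miss_tab),
            " sample(s) absent from the OPU table: ",
            paste(miss_tab, collapse = ", "))
  }
  absent <- setdiff(names(mapping), rownames(aln))
  if (length(absent))
    stop("assignment error: sample(s) not in alignment: ",
         paste(absent, collapse = ", "))
  keep <- intersect(rownames(aln), names(mapping))
  mat <- unclass(aln)[keep, , drop = FALSE]
  grp <- mapping[keep]
  labels <- opus$opu_labels[opus$opu_labels %in% grp]
  if (length(labels) < 2L) {
    warning("fewer than two OPUs with samples in the alignment; ",
            "no position can be diagnostic")
    return(structure(list(
      columns = integer(0), labels = character(0),
      region = character(0), pos1 = integer(0),
      states = matrix(character(0), length(labels), 0,
                      dimnames = list(labels, NULL)),
      diagnostic_for = list(), opu_labels = labels,
      max_missing_in_group = max_missing_in_group
    ), class = "cb_positions"))
  }

  sub_aln <- new_alignment(mat, name = aln_name(aln))
  cs <- classify_columns(sub_aln)
  cand <- which(cs$variable)
  k <- length(cand)
  n_opu <- length(labels)
  if (k == 0L) {
    return(structure(list(
      columns = integer(0), labels = character(0),
      region = character(0), pos1 = integer(0),
      states = matrix(character(0), n_opu, 0,
                      dimnames = list(labels, NULL)),
      diagnostic_for = list(), opu_labels = labels,
      max_missing_in_group = max_missing_in_group
    ), class = "cb_positions"))
  }

  # per-OPU 4 x k base counts
  counts <- lapply(labels, function(o) {
    rows <- mat[grp == o, cand, drop = FALSE]
    cnt <- t(matrix(vapply(ALN_BASES,
                           function(b) .colSums(rows == b, nrow(rows), k),
                           numeric(k)), nrow = max(k, 0L)))
    rownames(cnt) <- ALN_BASES
    cnt
  })
  names(counts) <- labels
  sizes <- table(grp)[labels]
  total <- Reduce(`+`, counts)

  states <- matrix("N", n_opu, k, dimnames = list(labels, NULL))
  for (o in labels)
    states[o, ] <- .opu_states(counts[[o]], sizes[[o]], max_missing_in_group)

  diagnostic_for <- vector("list", k)
  separating <- logical(k)
  for (j in seq_len(k)) {
    st <- states[, j]
    fixed <- st %in% ALN_BASES
    separating[j] <- length(unique(st[fixed])) >= 2L
    diag_opus <- character(0)
    for (o in labels[fixed]) {
      s <- states[o, j]
      elsewhere <- total[s, j] - counts[[o]][s, j]
      if (elsewhere == 0L) diag_opus <- c(diag_opus, o)
    }
    diagnostic_for[[j]] <- diag_opus
  }
  emit <- separating | lengths(diagnostic_for) > 0L

  cols <- cand[emit] - 1L   # back to 0-based
  loc <- .locate_columns(cols, regions, aln_name(aln))
  structure(list(
    columns = cols,
    labels = loc$label,
    region = loc$region,
    pos1 = loc$pos1,
    states = states[, emit, drop = FALSE],
    diagnostic_for = diagnostic_for[emit],
    opu_labels = labels,
    max_missing_in_group = max_missing_in_group
  ), class = "cb_positions")
}

# Map 0-based alignment columns to region:pos1 labels.
.locate_columns <- function(cols, regions, default_name) {
  if (is.null(regions) || nrow(regions) == 0) {
    pos1 <- cols + 1L
    return(list(region = rep(default_name, length(cols)),
                pos1 = pos1,
                label = sprintf("%s:%d", default_name, pos1)))
  }
  region <- rep(default_name, length(cols))
  pos1 <- cols + 1L
  for (i in seq_len(nrow(regions))) {
    inside <- cols >= regions$start[i] & cols < regions$end[i]
    region[inside] <- as.character(regions$name[i])
    pos1[inside] <- cols[inside] - regions$start[i] + 1L
  }
  list(region = region, pos1 = pos1,
       label = sprintf("%s:%d", region, pos1))
}

#' @export
print.cb_positions <- function(x, ...) {
  cat(sprintf("<%d informative positions over %d OPUs>\n",
              length(x$columns), nrow(x$states)))
  df <- data.frame(label = x$labels,
                   diagnostic_for = vapply(x$diagnostic_for, paste, "",
                                           collapse = ","))
  print(utils::head(df, 20))
  invisible(x)
}

# Shared internal constructor: profiles is an OPU x position character
# matrix over {A,C,G,T,N,polymorphic}. diagnostic_for may be supplied
# (member-level calls) or is derived at consensus level, where a state is
# diagnostic only if every other OPU has a fixed, different state (a
# polymorphic cell conservatively blocks the call).
new_diag_matrix <- function(profiles, region, pos1, columns = NULL,
                            diagnostic_for = NULL, region_lengths = NULL) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  k <- ncol(profiles)
  if (k < 1L) stop("domain error: diagnostic matrix needs >= 1 position")
  labels <- sprintf("%s:%d", region, pos1)
  if (is.null(columns)) columns <- seq_len(k) - 1L
  if (is.null(diagnostic_for)) {
    diagnostic_for <- lapply(seq_len(k), function(j) {
      st <- profiles[, j]
      fixed <- st %in% ALN_BASES
      out <- character(0)
      for (o in rownames(profiles)[fixed]) {
        others <- st[setdiff(rownames(profiles), o)]
        if (all(others %in% ALN_BASES) && !any(others == st[o]))
          out <- c(out, o)
      }
      out
    })
  }
  key <- apply(profiles, 1L, paste, collapse = "|")
  dup_groups <- split(rownames(profiles), key)
  collisions <- unname(dup_groups[lengths(dup_groups) > 1L])
  unique_opus <- rownames(profiles)[key %in% names(dup_groups)[lengths(dup_groups) == 1L]]
  structure(list(
    profiles = profiles,
    columns = columns,
    labels = labels,
    region = region,
    pos1 = pos1,
    diagnostic_for = diagnostic_for,
    unique_opus = unique_opus,
    profile_collisions = collisions,
    region_lengths = region_lengths
  ), class = "cb_diag_matrix")
}

#' Assemble the diagnostic matrix
#'
#' Rows are OPUs, columns are informative positions, cells are consensus
#' states. OPUs whose full state profile differs from every other OPU's are
#' `unique_opus`; OPUs sharing an identical profile form a
#' `profile_collisions` set and cannot be told apart by these positions
#' (profile comparison is exact: `N` equals only `N`).
#'
#' @param positions a [find_diagnostic_positions()] object.
#' @param opus the matching [opu_assignment()] (optional, for validation).
#' @return object of class `cb_diag_matrix`.
#' @export
build_matrix <- function(positions, opus = NULL) {
  if (length(positions$columns) < 1L)
    stop("domain error: no informative positions to build a matrix from")
  new_diag_matrix(
    profiles = positions$states,
    region = positions$region,
    pos1 = positions$pos1,
    columns = positions$columns,
    diagnostic_for = positions$diagnostic_for
  )
}

#' @export
print.cb_diag_matrix <- function(x, ...) {
  cat(sprintf("<diagnostic matrix: %d OPUs x %d positions>\n",
              nrow(x$profiles), ncol(x$profiles)))
  m <- x$profiles
  colnames(m) <- x$labels
  print(m)
  cat("unique OPUs: ", paste(x$unique_opus, collapse = ", "), "\n")
  if (length(x$profile_collisions))
    cat("profile collisions: ",
        paste(vapply(x$profile_collisions, paste, "", collapse = "="),
              collapse = "; "), "\n")
  invisible(x)
}

# number of OPUs with a unique profile when restricted to position subset S
.unique_count <- function(profiles, S) {
  if (length(S) == 0L) return(0L)
  key <- apply(profiles[, S, drop = FALSE], 1L, paste, collapse = "|")
  sum(!(key %in% key[duplicated(key)]))
}

.unique_set <- function(profiles, S) {
  if (length(S) == 0L) return(character(0))
  key <- apply(profiles[, S, drop = FALSE], 1L, paste, collapse = "|")
  rownames(profiles)[!(key %in% key[duplicated(key)])]
}

#' Search for a minimal diagnostic position set
#'
#' Finds a smallest set of matrix positions that uniquely identifies as many
#' OPUs as the full matrix does (uniqueness is monotone in the position
#' set, so the full matrix attains the maximum). With at most
#' `exhaustive_limit` candidate positions the search enumerates subsets by
#' increasing cardinality and returns the lexicographically smallest
#' optimum (by column index); beyond the limit a greedy pair-separation
#' cover is used, followed by redundancy pruning. OPUs with identical full
#' profiles are reported as unresolvable by any subset.
#'
#' @param matrix a `cb_diag_matrix`.
#' @param exhaustive_limit maximum candidate count for exact search
#'   (default 20).
#' @return list: `positions` (indices into the matrix), `labels`, `columns`
#'   (0-based alignment columns), `size`, `unique_opus` achieved,
#'   `unresolvable` (full-matrix collisions), `method` (`"exact"` or
#'   `"greedy"`).
#' @export
minimal_diagnostic_set <- function(matrix, exhaustive_limit = 20L) {
  profiles <- matrix$profiles
  k <- ncol(profiles)
  target <- .unique_count(profiles, seq_len(k))
  result <- NULL
  if (target == 0L) {
    result <- list(S = integer(0), method = "exact")
  } else if (k <= exhaustive_limit) {
    for (m in seq_len(k)) {
      combos <- utils::combn(k, m)
      for (ci in seq_len(ncol(combos))) {
        S <- combos[, ci]
        if (.unique_count(profiles, S) == target) {
          result <- list(S = S, method = "exact")
          break
        }
      }
      if (!is.null(result)) break
    }
  } else {
    # greedy cover over separable OPU pairs, then prune
    pairs <- utils::combn(rownames(profiles), 2)
    sep <- vapply(seq_len(ncol(pairs)), function(p) {
      any(profiles[pairs[1, p], ] != profiles[pairs[2, p], ])
    }, logical(1))
    pairs <- pairs[, sep, drop = FALSE]
    uncovered <- seq_len(ncol(pairs))
    S <- integer(0)
    while (length(uncovered)) {
      gain <- vapply(seq_len(k), function(j) {
        if (j %in% S) return(-1L)
        sum(vapply(uncovered, function(p) {
          profiles[pairs[1, p], j] != profiles[pairs[2, p], j]
        }, logical(1)))
      }, integer(1))
      j <- which.max(gain)
      if (gain[j] <= 0L) break
      S <- c(S, j)
      uncovered <- uncovered[vapply(uncovered, function(p) {
        profiles[pairs[1, p], j] == profiles[pairs[2, p], j]
      }, logical(1))]
    }
    S <- sort(S)
    for (j in rev(S)) {   # prune redundant members, largest index first
      S2 <- setdiff(S, j)
      if (.unique_count(profiles, S2) == target) S <- S2
    }
    result <- list(S = S, method = "greedy")
  }
  S <- result$S
  list(
    positions = S,
    labels = matrix$labels[S],
    columns = matrix$columns[S],
    size = length(S),
    unique_opus = .unique_set(profiles, S),
    unresolvable = matrix$profile_collisions,
    method = result$method
  )
}

#' Diagnostic set with per-OPU redundancy
#'
#' Augments the minimal set so that each OPU keeps up to `r` positions that
#' are individually diagnostic for it (in column order) — insurance against
#' sequencing failure at a single site, which is why published matrices
#' often carry paired diagnostic positions for the key clade.
#'
#' @param matrix a `cb_diag_matrix`.
#' @param r redundancy level (default 2).
#' @param minimal optional precomputed [minimal_diagnostic_set()] result.
#' @return same shape as [minimal_diagnostic_set()], plus `r`.
#' @export
redundant_diagnostic_set <- function(matrix, r = 2L, minimal = NULL) {
  if (is.null(minimal)) minimal <- minimal_diagnostic_set(matrix)
  S <- minimal$positions
  for (o in rownames(matrix$profiles)) {
    mine <- which(vapply(matrix$diagnostic_for, function(d) o %in% d,
                         logical(1)))
    S <- union(S, utils::head(mine, r))
  }
  S <- sort(S)
  list(
    positions = S,
    labels = matrix$labels[S],
    columns = matrix$columns[S],
    size = length(S),
    unique_opus = .unique_set(matrix$profiles, S),
    unresolvable = matrix$profile_collisions,
    method = minimal$method,
    r = r
  )
}

#' Write the diagnostic matrix as TSV
#'
#' Rows are OPUs, columns are `region:position` labels, cells are consensus
#' states. `genotype_style = TRUE` writes each haploid state twice
#' (`"AA"`, `"CC"`), the presentation used in printed matrices.
#'
#' @param matrix a `cb_diag_matrix`.
#' @param path output TSV path.
#' @param genotype_style double each state letter.
#' @export
write_diag_matrix <- function(matrix, path, genotype_style = FALSE) {
  m <- matrix$profiles
  if (genotype_style) {
    single <- m %in% c(ALN_BASES, "N")
    m[single] <- paste0(m[single], m[single])
  }
  df <- data.frame(opu = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("opu", matrix$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a diagnostic matrix from TSV
#'
#' Inverse of [write_diag_matrix()]; doubled-letter cells (`"AA"`) are
#' folded back to single states.
#'
#' @param path TSV with an `opu` column and `region:position` columns.
#' @return a `cb_diag_matrix`.
#' @export
read_diag_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!"opu" %in% colnames(df))
    stop("input error: matrix TSV needs an 'opu' column")
  m <- as.matrix(df[, setdiff(colnames(df), "opu"), drop = FALSE])
  rownames(m) <- df$opu
  double <- grepl("^([ACGTN])\\1$", m)
  m[double] <- substr(m[double], 1, 1)
  labels <- colnames(m)
  region <- sub(":[0-9]+$", "", labels)
  pos1 <- as.integer(sub("^.*:", "", labels))
  colnames(m) <- NULL
  new_diag_matrix(m, region = region, pos1 = pos1)
}

#' JSON report for a diagnostic matrix
#'
#' @param matrix a `cb_diag_matrix`.
#' @param path output JSON path.
#' @param minimal optional [minimal_diagnostic_set()] result to include.
#' @export
write_diag_report <- function(matrix, path, minimal = NULL) {
  if (is.null(minimal)) minimal <- minimal_diagnostic_set(matrix)
  rep <- list(
    n_opus = nrow(matrix$profiles),
    n_positions = ncol(matrix$profiles),
    positions = matrix$labels,
    unique_opus = matrix$unique_opus,
    profile_collisions = lapply(matrix$profile_collisions, identity),
    minimal_set = list(
      labels = minimal$labels, size = minimal$size,
      unique_opus = minimal$unique_opus, method = minimal$method
    )
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
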