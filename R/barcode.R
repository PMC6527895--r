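# Barcode region evaluation: sub-alignment extraction, summary statistics
# (length, variable and parsimony-informative sites) and haplotype
# collapsing with per-group sharing — the computational content behind
# haplotype networks, without the layout.

#' Extract a region sub-alignment
#'
#' Column slice of the alignment over a half-open interval; sample order is
#' preserved and the region name becomes the alignment name.
#'
#' @param aln a `cb_aln` object.
#' @param region one-row region ([barcode_region()] or a `cb_regions` row).
#' @return a `cb_aln` over the region's columns.
#' @export
extract_region <- function(aln, region) {
  start <- region$start
  end <- region$end
  if (start < 0 || end > ncol(aln) || end <= start)
    stop("interval error: region [", start, ",", end,
         ") outside alignment of length ", ncol(aln))
  mat <- unclass(aln)[, (start + 1L):end, drop = FALSE]
  new_alignment(mat, name = as.character(region$name))
}

#' Barcode summary statistics
#'
#' Length, variable-site and parsimony-informative-site counts with their
#' half-up two-decimal percentages, in the column order of a published
#' barcode-selection table.
#'
#' @param sub a `cb_aln` (typically from [extract_region()]).
#' @param name barcode label; defaults to the alignment name.
#' @return one-row data.frame: `name`, `length`, `var_count`, `pct_var`,
#'   `pis_count`, `pct_pis`.
#' @export
barcode_stats <- function(sub, name = aln_name(sub)) {
  cs <- classify_columns(sub)
  L <- ncol(sub)
  v <- sum(cs$variable)
  p <- sum(cs$pis)
  data.frame(
    name = name, length = L,
    var_count = v, pct_var = percent(v, L),
    pis_count = p, pct_pis = percent(p, L)
  )
}

#' Write a barcode statistics table
#'
#' @param stats rows from [barcode_stats()] (rbind-ed).
#' @param path output TSV path.
#' @export
write_stats <- function(stats, path) {
  out <- stats
  names(out) <- c("barcode", "length_bp", "var", "pct_var", "pis", "pct_pis")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse aligned sequences into haplotypes
#'
#' Samples with identical sequences share a haplotype; by default identity
#' is exact symbol equality, so `N` matches only `N` (reproducible, if
#' conservative). With `collapse_missing = TRUE` a sample joins the first
#' existing haplotype it matches over mutually non-missing columns — a
#' greedy, order-dependent rule useful for partially sequenced material.
#' Haplotypes are labelled with Roman numerals in order of first occurrence,
#' and each haplotype records the group/species labels of its members, so
#' haplotype sharing between groups is immediate.
#'
#' @param sub a `cb_aln` over the barcode region.
#' @param labels named character vector mapping sample id to a group or
#'   species label; unlabelled samples get `"unassigned"`.
#' @param collapse_missing merge sequences identical over mutually
#'   non-missing columns (greedy, order-dependent).
#' @return object of class `cb_haplotypes`: list with `table` (data.frame
#'   `haplotype`, `size`, `members`, `labels`), `membership` (named
#'   haplotype id per sample) and `representatives` (named sequences).
#' @export
collapse_haplotypes <- function(sub, labels = NULL, collapse_missing = FALSE) {
  seqs <- aln_seqs(sub)
  ids <- names(seqs)
  if (is.null(labels)) labels <- character(0)
  lab <- labels[ids]
  lab[is.na(lab)] <- "unassigned"
  names(lab) <- ids

  if (!collapse_missing) {
    group <- match(seqs, unique(seqs))
  } else {
    mat <- unclass(sub)
    reps <- list()   # row indices of representatives
    group <- integer(length(ids))
    for (i in seq_along(ids)) {
      hit <- 0L
      for (k in seq_along(reps)) {
        a <- mat[reps[[k]], ]
        b <- mat[i, ]
        seen <- !(a %in% ALN_MISSING) & !(b %in% ALN_MISSING)
        if (all(a[seen] == b[seen])) { hit <- k; break }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- i
        hit <- length(reps)
      }
      group[i] <- hit
    }
  }

  n_h <- max(group)
  hap_ids <- as.character(utils::as.roman(seq_len(n_h)))
  first <- match(seq_len(n_h), group)
  members <- split(ids, group)
  labsets <- split(unname(lab), group)
  tab <- data.frame(
    haplotype = hap_ids,
    size = lengths(members),
    members = vapply(members, paste, "", collapse = ","),
    labels = vapply(labsets, function(x) {
      t <- table(x)
      paste(sprintf("%s:%d", names(t), as.integer(t)), collapse = ",")
    }, "")
  )
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    membership = stats::setNames(hap_ids[group], ids),
    representatives = stats::setNames(seqs[first], hap_ids),
    label_sets = stats::setNames(labsets, hap_ids)
  ), class = "cb_haplotypes")
}

#' @export
print.cb_haplotypes <- function(x, ...) {
  cat(sprintf("<%d haplotypes over %d samples>\n",
              nrow(x$table), sum(x$table$size)))
  print(x$table)
  invisible(x)
}

#' Pairwise Hamming distances between haplotypes
#'
#' Counts columns where two representative sequences carry different
#' non-missing symbols; columns where either sequence is `N` or `-` are
#' skipped, so the matrix feeds network tools without missing-data noise.
#'
#' @param haps a [collapse_haplotypes()] object.
#' @return symmetric integer matrix with haplotype ids as dimnames.
#' @export
haplotype_distances <- function(haps) {
  reps <- haps$representatives
  m <- do.call(rbind, strsplit(reps, "", fixed = TRUE))
  k <- length(reps)
  d <- matrix(0L, k, k, dimnames = list(names(reps), names(reps)))
  if (k < 2) return(d)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    seen <- !(m[i, ] %in% ALN_MISSING) & !(m[j, ] %in% ALN_MISSING)
    d[i, j] <- d[j, i] <- sum(m[i, seen] != m[j, seen])
  }
  d
}

#' Which labels have haplotypes of their own?
#'
#' A label (species or group) is haplotype-unique iff no haplotype contains
#' one of its samples together with a sample of another label. A
#' pharmacopoeial species that shares every haplotype with congeners cannot
#' be identified by haplotype membership alone.
#'
#' @param haps a [collapse_haplotypes()] object.
#' @return named logical vector over labels.
#' @export
haplotype_unique_labels <- function(haps) {
  all_labels <- unique(unlist(haps$label_sets, use.names = FALSE))
  shared <- vapply(all_labels, function(l) {
    any(vapply(haps$label_sets,
               function(s) l %in% s && length(unique(s)) > 1L, logical(1)))
  }, logical(1))
  !shared
}

#' Write the haplotype table
#'
#' TSV with columns `haplotype, size, members, labels`.
#'
#' @param haps a [collapse_haplotypes()] object.
#' @param path output TSV path.
#' @export
write_haplotypes <- function(haps, path) {
  utils::write.table(haps$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
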