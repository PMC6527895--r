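# Seeded alignment simulator with exact column-class accounting.
#
# The background is a constant random base per column (not a substitution
# model): published barcode tables state exact counts of variable and
# parsimony-informative columns, so the generator must hit counts exactly,
# not in expectation. Variation is planted on top of the constant
# background: clade-diagnostic columns (fixed inside one OPU, fixed for a
# different base outside), extra variable columns carried by a single
# sample (variable, not parsimony-informative) or by two samples
# (parsimony-informative), and masked N blocks.

#' Specify a simulated alignment
#'
#' @param length alignment length in columns.
#' @param opu_sizes integer vector of samples per OPU; names become OPU
#'   labels (default `OPU1`, `OPU2`, ...).
#' @param planted_diagnostics data.frame with columns `opu`, `column`
#'   (0-based), `state` — one clade-diagnostic column each: fixed for
#'   `state` inside `opu`, fixed for a different base outside.
#' @param n_extra_variable non-diagnostic variable columns to add.
#' @param n_pis how many of the extra variable columns are
#'   parsimony-informative (minor state carried by two samples).
#' @param masked_blocks list of `list(samples=, start=, end=)` entries
#'   (sample ids or indices; 0-based half-open columns) overwritten with
#'   `N`. Masked blocks must not touch planted or extra variable columns so
#'   the truth record stays exact.
#' @param seed integer seed; the same spec and seed always reproduce the
#'   same alignment.
#' @return validated list of class `cb_simspec`.
#' @export
sim_spec <- function(length, opu_sizes, planted_diagnostics = NULL,
                     n_extra_variable = 0L, n_pis = 0L,
                     masked_blocks = list(), seed = 1L) {
  stopifnot(length >= 1, all(opu_sizes >= 1), n_extra_variable >= 0,
            n_pis >= 0, n_pis <= n_extra_variable)
  if (is.null(names(opu_sizes)))
    names(opu_sizes) <- paste0("OPU", seq_along(opu_sizes))
  if (is.null(planted_diagnostics))
    planted_diagnostics <- data.frame(opu = character(), column = integer(),
                                      state = character())
  pd <- planted_diagnostics
  if (nrow(pd)) {
    stopifnot(all(c("opu", "column", "state") %in% colnames(pd)))
    if (!all(pd$opu %in% names(opu_sizes)))
      stop("spec error: planted OPU not in opu_sizes")
    if (!all(pd$state %in% ALN_BASES))
      stop("spec error: planted state must be one of A,C,G,T")
    if (anyDuplicated(pd$column))
      stop("spec error: planted columns overlap")
    if (any(pd$column < 0 | pd$column >= length))
      stop("spec error: planted column outside alignment")
  }
  if (nrow(pd) + n_extra_variable > length)
    stop("spec error: more variable columns requested than alignment length")
  n <- sum(opu_sizes)
  if (n_pis > 0 && n < 4)
    stop("spec error: parsimony-informative columns need >= 4 samples")
  structure(list(
    length = as.integer(length), opu_sizes = opu_sizes,
    planted_diagnostics = pd,
    n_extra_variable = as.integer(n_extra_variable),
    n_pis = as.integer(n_pis),
    masked_blocks = masked_blocks, seed = as.integer(seed)
  ), class = "cb_simspec")
}

#' Simulate an alignment from a spec
#'
#' Deterministic given the spec (including its seed); the caller's RNG
#' state is left untouched. The returned truth record states exactly which
#' columns are variable, parsimony-informative and diagnostic, and the
#' expected whole-alignment counts; generated alignments satisfy it by
#' construction.
#'
#' Carriers of extra-variable minor states are drawn from OPUs with at
#' least two members and every carrier OPU keeps a major-state member, so
#' extra columns are neither diagnostic for any OPU nor separate any pair
#' of OPUs. When no OPU has two members this is infeasible; carriers are
#' then arbitrary and the truth record flags `clean = FALSE`.
#'
#' @param spec a [sim_spec()] object.
#' @return list: `alignment` (`cb_aln`), `opus` ([opu_assignment()]),
#'   `truth` (list).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "cb_simspec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  sizes <- spec$opu_sizes
  n <- sum(sizes)
  L <- spec$length
  opu_of <- rep(names(sizes), sizes)
  ids <- unlist(lapply(names(sizes), function(o)
    sprintf("%s_s%d", o, seq_len(sizes[[o]]))), use.names = FALSE)

  bg <- sample(ALN_BASES, L, replace = TRUE)
  mat <- matrix(rep(bg, each = n), nrow = n, dimnames = list(ids, NULL))

  pd <- spec$planted_diagnostics
  for (i in seq_len(nrow(pd))) {
    j <- pd$column[i] + 1L
    s <- pd$state[i]
    outside <- sample(setdiff(ALN_BASES, s), 1L)
    mat[, j] <- outside
    mat[opu_of == pd$opu[i], j] <- s
  }

  avail <- setdiff(seq_len(L), pd$column + 1L)
  extra <- sort(sample(avail, spec$n_extra_variable))
  pis_cols <- utils::head(extra, spec$n_pis)

  eligible <- names(sizes)[sizes >= 2L]
  clean <- length(eligible) > 0L
  rot <- 0L
  pick_carrier_opus <- function(n_carriers) {
    if (!clean) return(NULL)
    if (n_carriers == 1L) {
      rot <<- rot %% length(eligible) + 1L
      return(eligible[rot])
    }
    if (length(eligible) >= 2L) {
      rot <<- rot %% length(eligible) + 1L
      a <- eligible[rot]
      b <- eligible[if (rot == length(eligible)) 1L else rot + 1L]
      return(c(a, b))
    }
    if (sizes[[eligible]] >= 3L) return(rep(eligible, 2L))
    NULL
  }
  sample1 <- function(x) x[sample.int(length(x), 1L)]
  for (j in extra) {
    minor <- sample1(setdiff(ALN_BASES, bg[j]))
    n_car <- if (j %in% pis_cols) 2L else 1L
    car_opus <- pick_carrier_opus(n_car)
    if (is.null(car_opus)) {
      clean <- FALSE
      carriers <- sample.int(n, n_car)
    } else {
      carriers <- integer(0)
      for (ci in seq_len(n_car)) {
        members <- which(opu_of == car_opus[ci])
        carriers <- c(carriers, sample1(setdiff(members, carriers)))
      }
    }
    mat[carriers, j] <- minor
  }

  var_cols0 <- sort(c(pd$column, extra - 1L))
  masked_cells <- 0L
  for (b in spec$masked_blocks) {
    rows <- if (is.character(b$samples)) match(b$samples, ids) else b$samples
    if (anyNA(rows)) stop("spec error: unknown sample in masked block")
    cols <- (b$start + 1L):b$end
    if (any((cols - 1L) %in% var_cols0))
      stop("spec error: masked block overlaps a variable column")
    mat[rows, cols] <- "N"
    masked_cells <- masked_cells + length(rows) * length(cols)
  }

  planted_pis <- sum(sizes[pd$opu] >= 2L & (n - sizes[pd$opu]) >= 2L)
  truth <- list(
    planted = pd,
    extra_variable_columns = extra - 1L,
    pis_columns = sort(c(pis_cols - 1L,
                         pd$column[sizes[pd$opu] >= 2L &
                                     (n - sizes[pd$opu]) >= 2L])),
    variable_columns = var_cols0,
    expected_var = nrow(pd) + spec$n_extra_variable,
    expected_pis = spec$n_pis + planted_pis,
    masked_cells = masked_cells,
    clean = clean,
    seed = spec$seed
  )
  aln <- new_alignment(mat, name = sprintf("sim_seed%d", spec$seed))
  list(
    alignment = aln,
    opus = opu_assignment(ids, opu_of),
    truth = truth
  )
}

#' Write a simulation to disk
#'
#' FASTA alignment, sample-to-OPU TSV and truth JSON.
#'
#' @param sim result of [simulate_alignment()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"sim"`).
#' @return named character vector of the three paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    opus = file.path(dir, paste0(prefix, "_opus.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_alignment(sim$alignment, paths["fasta"])
  utils::write.table(
    data.frame(sample = names(sim$opus$mapping),
               opu = unname(sim$opus$mapping)),
    paths["opus"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE)
  paths
}
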