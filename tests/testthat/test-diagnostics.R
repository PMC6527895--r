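# OPU assignment, diagnostic position discovery, matrix analysis and
# minimal-set search.

test_that("OPU tables parse with or without a header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\topu", "s1\tg1", "s2\tg1", "s3\tg2"), path)
  a <- read_opu_table(path)
  expect_equal(length(a$mapping), 3L)
  expect_equal(a$opu_labels, c("g1", "g2"))

  writeLines(c("s1\tg1", "s2\tg2"), path)
  expect_equal(read_opu_table(path)$opu_labels, c("g1", "g2"))
})

test_that("OPU table validation catches conflicts and empty input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tg1", "s1\tg2"), path)
  expect_error(read_opu_table(path), "assignment error")
  writeLines(c("s1\tg1", "s1\tg1", "s2\tg2"), path)  # consistent dup is fine
  expect_equal(length(read_opu_table(path)$mapping), 2L)
  file.create(path)
  expect_error(read_opu_table(path), "input error")
})

test_that("a column fixed for different states in two OPUs is diagnostic for both", {
  aln <- as_alignment(c(a1 = "AAT", a2 = "AAT", b1 = "CAT", b2 = "CAT"))
  opus <- opu_assignment(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  pos <- find_diagnostic_positions(aln, opus)
  expect_equal(pos$columns, 0L)
  expect_setequal(pos$diagnostic_for[[1]], c("A", "B"))
})

test_that("within-OPU polymorphism blocks diagnosis but not separation", {
  # 3 OPUs x 2 samples; column: A is {A,C} polymorphic, B fixed G, C fixed T
  aln <- aln_from_cols(list(c("A", "C", "G", "G", "T", "T")),
                       ids = c("a1", "a2", "b1", "b2", "c1", "c2"))
  opus <- opu_assignment(c("a1", "a2", "b1", "b2", "c1", "c2"),
                         rep(c("A", "B", "C"), each = 2))
  pos <- find_diagnostic_positions(aln, opus)
  expect_equal(unname(pos$states[, 1]), c("polymorphic", "G", "T"))
  expect_setequal(pos$diagnostic_for[[1]], c("B", "C"))

  # a state fixed in one OPU but present inside another is not diagnostic
  aln2 <- aln_from_cols(list(c("A", "A", "A", "G", "T", "T")),
                        ids = c("a1", "a2", "b1", "b2", "c1", "c2"))
  pos2 <- find_diagnostic_positions(aln2, opus)
  expect_equal(unname(pos2$states[, 1]), c("A", "polymorphic", "T"))
  expect_equal(pos2$diagnostic_for[[1]], "C")
})

test_that("missing data drives the state call to N, never diagnostic", {
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2")
  aln <- aln_from_cols(list(c("N", "N", "C", "C", "G", "G"),
                            c("A", "N", "C", "C", "G", "G")), ids = ids)
  opus <- opu_assignment(ids, rep(c("A", "B", "C"), each = 2))
  pos <- find_diagnostic_positions(aln, opus)
  # column 0: OPU A all-missing -> state N, never diagnostic; B and C fixed
  # for states absent elsewhere -> diagnostic for both
  expect_equal(unname(pos$states["A", 1]), "N")
  expect_setequal(pos$diagnostic_for[[1]], c("B", "C"))
  # column 1: OPU A has 1/2 missing, within the 0.5 tolerance -> state A
  expect_equal(unname(pos$states["A", 2]), "A")
  expect_setequal(pos$diagnostic_for[[2]], c("A", "B", "C"))
  # a tighter tolerance pushes the half-missing OPU back to N
  pos_strict <- find_diagnostic_positions(aln, opus,
                                          max_missing_in_group = 0.4)
  expect_equal(unname(pos_strict$states["A", ]), c("N", "N"))
  expect_setequal(pos_strict$diagnostic_for[[2]], c("B", "C"))
})

test_that("samples outside the OPU table are excluded with a message", {
  aln <- as_alignment(c(a1 = "AT", a2 = "AT", b1 = "CT", xx = "GT"))
  opus <- opu_assignment(c("a1", "a2", "b1"), c("A", "A", "B"))
  expect_message(pos <- find_diagnostic_positions(aln, opus), "xx")
  expect_equal(nrow(pos$states), 2L)
  opus_bad <- opu_assignment(c("a1", "a2", "zz"), c("A", "A", "B"))
  expect_error(find_diagnostic_positions(aln, opus_bad), "zz")
})

test_that("matrix profile comparison finds unique OPUs and collisions", {
  ref <- berberis_reference()
  m <- ref$matrix
  expect_equal(ncol(m$profiles), 9L)
  expect_equal(nrow(m$profiles), 9L)
  expect_length(m$unique_opus, 7L)
  expect_length(m$profile_collisions, 1L)
  expect_setequal(m$profile_collisions[[1]], c("clade_3", "SA_clade_8"))
  # unique + collided partitions the OPU set
  expect_setequal(c(m$unique_opus, unlist(m$profile_collisions)),
                  rownames(m$profiles))
})

test_that("degenerate profile matrices are handled", {
  one <- cladebar:::new_diag_matrix(
    matrix("A", 1, 2, dimnames = list("solo", NULL)),
    region = c("r", "r"), pos1 = 1:2)
  expect_equal(one$unique_opus, "solo")

  same <- cladebar:::new_diag_matrix(
    matrix("A", 3, 2, dimnames = list(c("x", "y", "z"), NULL)),
    region = c("r", "r"), pos1 = 1:2)
  expect_length(same$unique_opus, 0L)
  expect_setequal(same$profile_collisions[[1]], c("x", "y", "z"))
  ms <- minimal_diagnostic_set(same)
  expect_equal(ms$size, 0L)
  expect_length(ms$unresolvable, 1L)
})

test_that("minimal set on a 3-OPU toy returns the lexicographic optimum", {
  m <- cladebar:::new_diag_matrix(
    matrix(c("A", "A", "C",
             "A", "C", "A",
             "C", "A", "A"), 3, 3, byrow = TRUE,
           dimnames = list(c("o1", "o2", "o3"), NULL)),
    region = rep("r", 3), pos1 = 1:3)
  ms <- minimal_diagnostic_set(m)
  expect_equal(ms$size, 2L)
  expect_equal(ms$positions, c(1L, 2L))   # any 2 work; lexicographic wins
  expect_length(ms$unique_opus, 3L)
})

test_that("exact search matches a brute-force subset oracle", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_profile_matrix(sample(3:6, 1), sample(3:8, 1))
    ms <- minimal_diagnostic_set(m)
    orc <- oracle_minimal(m$profiles)
    expect_equal(ms$size, orc$size)
    expect_length(ms$unique_opus, orc$target)
  }
})

test_that("greedy search attains the exact unique count at >= exact size", {
  set.seed(202)
  for (i in 1:15) {
    m <- random_profile_matrix(sample(4:7, 1), sample(4:10, 1))
    exact <- minimal_diagnostic_set(m)
    greedy <- minimal_diagnostic_set(m, exhaustive_limit = 0L)
    expect_equal(greedy$method, "greedy")
    expect_setequal(greedy$unique_opus, exact$unique_opus)
    expect_gte(greedy$size, exact$size)
  }
})

test_that("every diagnostic OPU has a unique full profile (soundness)", {
  set.seed(77)
  for (i in 1:10) {
    sizes <- setNames(sample(2:4, 3, replace = TRUE), c("g1", "g2", "g3"))
    pd <- data.frame(opu = c("g1", "g2"), column = c(5L, 20L),
                     state = c("C", "T"))
    sim <- simulate_alignment(sim_spec(60, sizes, pd,
                                       n_extra_variable = 4, n_pis = 2,
                                       seed = i))
    pos <- find_diagnostic_positions(sim$alignment, sim$opus)
    m <- build_matrix(pos)
    diag_opus <- unique(unlist(pos$diagnostic_for))
    expect_true(all(diag_opus %in% m$unique_opus))
  }
})

test_that("adding a consensus-matching sample never shrinks diagnostic_for", {
  aln <- as_alignment(c(a1 = "CAT", a2 = "CAT", b1 = "GAT", b2 = "GAT"))
  opus <- opu_assignment(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  before <- find_diagnostic_positions(aln, opus)
  grown <- as_alignment(c(aln_seqs(aln), a3 = "CAT"))
  opus2 <- opu_assignment(c("a1", "a2", "a3", "b1", "b2"),
                          c("A", "A", "A", "B", "B"))
  after <- find_diagnostic_positions(grown, opus2)
  expect_equal(after$columns, before$columns)
  for (j in seq_along(before$columns))
    expect_true(all(before$diagnostic_for[[j]] %in% after$diagnostic_for[[j]]))
})

test_that("redundancy keeps up to r diagnostic positions per OPU", {
  ref <- berberis_reference()
  minimal <- minimal_diagnostic_set(ref$matrix)
  expect_equal(minimal$size, 7L)
  r2 <- redundant_diagnostic_set(ref$matrix, r = 2)
  # the aristata clade keeps its paired diagnostic positions
  expect_true(all(c("matK:755", "matK:857") %in% r2$labels))
  expect_equal(r2$size, 9L)
  expect_setequal(r2$unique_opus, ref$matrix$unique_opus)
})

test_that("matrix TSV round-trips, including genotype-style doubling", {
  ref <- berberis_reference()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diag_matrix(ref$matrix, path, genotype_style = TRUE)
  raw <- read.delim(path, check.names = FALSE)
  expect_equal(raw[raw$opu == "aristata_clade_4", "matK:755"], "CC")
  back <- read_diag_matrix(path)
  expect_equal(back$profiles, ref$matrix$profiles)
  expect_setequal(back$unique_opus, ref$matrix$unique_opus)
})
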