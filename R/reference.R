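# Packaged reference diagnostic matrix for the Berberis OPU barcode:
# nine OPUs scored at nine positions across three plastid barcode regions
# (matK, the ndhI-ndhG intergenic spacer and a non-coding stretch of the
# small single copy region), plus the three commercial market samples used
# to exercise the classification step.

#' Reference Berberis OPU diagnostic matrix and test profiles
#'
#' The nine-OPU, nine-position diagnostic matrix for medicinal *Berberis*
#' (OPUs defined on a whole-plastome phylogeny; the pharmacopoeial species
#' *B. aristata* is polyphyletic, so its clade — not the species — is the
#' identification target), with the three commercial "Market" query
#' profiles. Positions are 1-based within each barcode region; `columns`
#' index a concatenation matK + ndhI-ndhG + SSC_noncoding2
#' (1530 + 501 + 790 bp). Clades 3 and 8 carry identical profiles and are
#' not separable at these positions.
#'
#' @return list with `matrix` (a `cb_diag_matrix`) and `queries` (list of
#'   three `cb_profile` objects: Market1, Market2, Market3).
#' @examples
#' ref <- berberis_reference()
#' ref$matrix$unique_opus
#' classify_query(ref$queries$Market3, ref$matrix)
#' @export
berberis_reference <- function() {
  opus <- c("clade_1", "clade_2", "clade_3", "aristata_clade_4",
            "asiatica_clade_5", "clade_6", "clade_7", "SA_clade_8",
            "Mahonia_clade_9")
  region <- c(rep("matK", 4), rep("ndhI-ndhG", 3), rep("SSC_noncoding2", 2))
  pos1 <- c(755L, 857L, 976L, 1428L, 151L, 182L, 326L, 47L, 700L)
  region_lengths <- c(matK = 1530L, `ndhI-ndhG` = 501L,
                      SSC_noncoding2 = 790L)
  offsets <- c(matK = 0L, `ndhI-ndhG` = 1530L, SSC_noncoding2 = 2031L)
  profiles <- matrix(c(
    # matK755 matK857 matK976 matK1428 ndhI151 ndhI182 ndhI326 SSC47 SSC700
    "A", "G", "G", "G", "C", "A", "C", "A", "G",  # clade_1
    "A", "G", "G", "A", "C", "A", "C", "A", "A",  # clade_2
    "A", "G", "G", "G", "A", "A", "C", "A", "A",  # clade_3
    "C", "A", "G", "G", "C", "A", "C", "A", "A",  # aristata_clade_4
    "A", "G", "G", "G", "C", "C", "C", "A", "A",  # asiatica_clade_5
    "A", "G", "G", "G", "C", "A", "C", "A", "A",  # clade_6
    "A", "G", "A", "G", "C", "A", "C", "A", "A",  # clade_7
    "A", "G", "G", "G", "A", "A", "C", "A", "A",  # SA_clade_8
    "A", "G", "G", "G", "A", "A", "A", "C", "A"   # Mahonia_clade_9
  ), nrow = 9, byrow = TRUE, dimnames = list(opus, NULL))
  m <- new_diag_matrix(
    profiles,
    region = region, pos1 = pos1,
    columns = offsets[region] + pos1 - 1L,
    region_lengths = region_lengths
  )
  queries <- list(
    Market1 = profile_query(c("A", "G", "G", "G", "A", "A", "N", "C", "A"),
                            m, query_id = "Market1"),
    Market2 = profile_query(c("A", "G", "G", "G", "A", "A", "N", "C", "A"),
                            m, query_id = "Market2"),
    Market3 = profile_query(c("A", "G", "G", "G", "C", "C", "C", "A", "A"),
                            m, query_id = "Market3")
  )
  list(matrix = m, queries = queries)
}
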