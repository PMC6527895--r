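# cladebar

Character-based DNA barcode design for clades, not species.

In evolutionarily complex plant groups — recent radiations with
hybridisation, chloroplast capture or incomplete lineage sorting — the
species named in a pharmacopoeia can be polyphyletic on the plastid tree,
and distance-based barcoding has no gap to work with. `cladebar` implements
the alternative used for medicinal *Berberis*: choose clades on a
whole-plastome phylogeny as the identification targets (*Operational
Phylogenetic Units*, OPUs), mine the plastome alignment for short highly
variable regions, and reduce them to a matrix of *diagnostic nucleotide
states* — a state fixed within one OPU and absent from all others. A test
sample passes or fails by comparing its states at those positions to the
matrix, which is exactly the form a pharmacopoeial standard needs.

The package is aimed at people designing or applying such standards:
given a multiple sequence alignment (FASTA over `A,C,G,T,N,-`) and a
sample-to-OPU table (TSV), it provides

* per-column statistics: variable sites and parsimony-informative sites
  (PIS), with missing-data accounting (`classify_columns`, `percent`);
* a 500-bp window scan of SNP density with candidate selection
  (variability strictly > 5%, masked cells strictly < 3%), merging of
  adjacent windows into barcode regions and 50-bp sub-window refinement
  (`scan_windows`, `select_candidates`, `merge_candidates`,
  `refine_region`);
* barcode evaluation: length / Var / %Var / PIS / %PIS tables and
  haplotype collapsing with per-species sharing (`barcode_stats`,
  `collapse_haplotypes`);
* diagnostic-character discovery, the OPU × position matrix with unique
  profiles and collisions, and exact or greedy minimal-set search
  (`find_diagnostic_positions`, `build_matrix`,
  `minimal_diagnostic_set`, `redundant_diagnostic_set`);
* query classification with missing-data tolerance (`profile_query`,
  `classify_query`), including the packaged nine-position *Berberis*
  reference matrix and its three commercial test samples
  (`berberis_reference`);
* a seeded simulator that plants exact numbers of variable, PIS and
  diagnostic columns for validation (`sim_spec`, `simulate_alignment`).

## Worked example

Simulate a 2000-column alignment for three OPUs with two dense diagnostic
blocks, scan it, and recover a barcode:

```r
library(cladebar)

spec <- sim_spec(2000, c(aristata = 5, asiatica = 5, outgroup = 5),
  planted_diagnostics = data.frame(
    opu = rep(c("aristata", "asiatica"), each = 30),
    column = as.integer(c(seq(510, 990, length.out = 30),
                          seq(1005, 1490, length.out = 30))),
    state = rep(c("C", "T"), each = 30)),
  n_extra_variable = 10, n_pis = 4, seed = 42)
sim <- simulate_alignment(spec)

(w <- scan_windows(sim$alignment, 500))
#>   start  end snp_count variability masked_fraction
#> 1     0  500         3       0.006               0
#> 2   500 1000        31       0.062               0
#> 3  1000 1500        31       0.062               0
#> 4  1500 2000         5       0.010               0

(regions <- merge_candidates(select_candidates(w)))
#>           name start  end       source
#> 1 bar_501_1500   500 1500 window-merge
```

Windows 2 and 3 clear the strict 5% variability threshold and merge into
one 1000-bp candidate. Score it and extract its diagnostic matrix:

```r
sub <- extract_region(sim$alignment, regions[1, ])
barcode_stats(sub)
#>           name length var_count pct_var pis_count pct_pis
#> 1 bar_501_1500   1000        62     6.2        61     6.1

pos <- find_diagnostic_positions(sub, sim$opus)
ms <- minimal_diagnostic_set(build_matrix(pos))
ms$labels
#> [1] "bar_501_1500:11"  "bar_501_1500:506"
```

Two positions (one fixed `C` in the aristata OPU, one fixed `T` in the
asiatica OPU, 1-based within the region) already give every OPU a unique
profile — the 62 variable sites collapse to a 2-position barcode.

Classifying the packaged commercial test samples against the reference
matrix (Market1 has missing data at one diagnostic position; the call is
still unique because `N` never excludes an OPU):

```r
ref <- berberis_reference()
classify_query(ref$queries$Market1, ref$matrix)
#> query 'Market1': unique (Mahonia_clade_9)
classify_query(ref$queries$Market3, ref$matrix)
#> query 'Market3': unique (asiatica_clade_5)
```

A thin command-line launcher (`inst/scripts/cladebar.R`) exposes the same
steps as `scan`, `stats`, `diagnose`, `classify` and `simulate`
subcommands for shell pipelines.

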