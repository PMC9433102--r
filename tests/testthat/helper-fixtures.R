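# Shared fixture builders: everything is generated in code at test time.

# A clonotype table with the given UMI counts and distinct junctions.
mk_table <- function(counts, chain = "beta", sample_id = "S1", donor = "D1",
                     visit = 1L) {
  n <- length(counts)
  junctions <- vapply(seq_len(n), function(i) {
    paste0("TGT", strrep(c("GCA", "GCC", "GCG", "GCT")[(i - 1) %% 4 + 1],
                         ((i - 1) %/% 4) + 2), "TTT")
  }, character(1))
  clonotype_table(
    tibble::tibble(
      v_call = paste0("TRBV", ((seq_len(n) - 1) %% 5) + 1),
      j_call = paste0("TRBJ", ((seq_len(n) - 1) %% 3) + 1),
      junction = junctions,
      junction_aa = tcrlong:::translate_nt(junctions),
      duplicate_count = as.integer(counts)
    ),
    sample_id = sample_id, donor = donor, visit = visit, chain = chain
  )
}

# A table from explicit clonotype identities (for overlap set algebra).
mk_set_table <- function(ids, counts = rep(1L, length(ids)), chain = "beta",
                         donor = "D1", sample_id = "S1", visit = 1L) {
  # distinct amino acids per id (K, P, G, E, H, M, L, S) so nucleotide and
  # amino-acid clonotype keys both separate these identities
  base <- c(a = "TGTAAATTT", b = "TGTCCCTTT", c = "TGTGGGTTT",
            d = "TGTGAATTT", e = "TGTCACTTT", x = "TGTATGTTT",
            y = "TGTTTGTTT", z = "TGTTCCTTT")
  junctions <- base[ids]
  clonotype_table(
    tibble::tibble(
      v_call = "TRBV1", j_call = "TRBJ1",
      junction = unname(junctions),
      junction_aa = tcrlong:::translate_nt(unname(junctions)),
      duplicate_count = as.integer(counts)
    ),
    sample_id = sample_id, donor = donor, visit = visit, chain = chain
  )
}

# A small cohort with sequence-level clone universes.
mk_small_cohort <- function(n_donors = 2, richness = 60, seed = 42,
                            retention = 0.5, error_rate = 0) {
  cfg <- generative_config(
    n_donors = n_donors, true_richness = richness, seed = seed,
    retention_fraction = retention, error_rate = error_rate,
    intercept_sd = 0.1, residual_sd = 0.05
  )
  simulate_cohort(cfg)
}

# Hand-rolled reads for consensus unit tests: one UMI, given insert
# sequences, constant quality.
mk_umi_reads <- function(inserts, umi = "AAAACCCCGGGG", barcode = "ACGTACGT",
                         quality_char = "?") {
  seqs <- paste0(barcode, umi, inserts)
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(seqs)),
    sequence = seqs,
    quality = strrep(quality_char, nchar(seqs))
  )
}

# Exact expected number of unique clonotypes when drawing n cells without
# replacement from a population with per-clone cell counts `cells`
# (hypergeometric inclusion probabilities).
expected_unique_hyper <- function(cells, n) {
  N <- sum(cells)
  sum(1 - exp(lchoose(N - cells, n) - lchoose(N, n)))
}
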