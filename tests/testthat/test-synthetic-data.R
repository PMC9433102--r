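test_that("config validation rejects bad probabilities and distributions", {
  expect_error(generative_config(retention_fraction = 1.5), "configuration error")
  expect_error(generative_config(true_richness = 0), "configuration error")
  expect_error(
    generative_config(clone_size_distribution = list(name = "zipfian")),
    "configuration error"
  )
  expect_s3_class(generative_config(n_donors = 2), "generative_config")
})

test_that("cohort bookkeeping: donor count, ages, visit gap", {
  cfg <- generative_config(n_donors = 30, true_richness = 50, seed = 11)
  co <- simulate_cohort(cfg, clones = FALSE)
  expect_length(co$truth, 30)
  expect_equal(nrow(co$profiles), 60)
  for (tr in co$truth) {
    expect_equal(tr$age_v2, tr$age_v1 + tr$gap, tolerance = 1e-12)
    expect_true(tr$gap >= 7 && tr$gap <= 13)
  }
  expect_equal(sort(unique(co$profiles$sex)), c("female", "male"))
})

test_that("zero slope and zero noise give identical visit richness", {
  cfg <- generative_config(
    n_donors = 5, true_richness = 300, annual_pct_change = 0,
    intercept_sd = 0.2, residual_sd = 0, seed = 3
  )
  co <- simulate_cohort(cfg, clones = FALSE)
  for (tr in co$truth) {
    wide <- tidyr::pivot_wider(tr$richness[, c("subset", "chain", "visit", "true_richness")],
                               names_from = "visit", values_from = "true_richness")
    expect_equal(wide$`2`, wide$`1`, tolerance = 1e-12)
  }
})

test_that("nonzero slope compounds richness over the visit gap (closed form)", {
  cfg <- generative_config(
    n_donors = 6, true_richness = 1000, annual_pct_change = -3.0,
    visit_gap_years = c(mean = 10, min = 10, max = 10),
    intercept_sd = 0.25, residual_sd = 0, seed = 5
  )
  co <- simulate_cohort(cfg, clones = FALSE)
  for (tr in co$truth) {
    wide <- tidyr::pivot_wider(tr$richness[, c("subset", "chain", "visit", "true_richness")],
                               names_from = "visit", values_from = "true_richness")
    expect_equal(wide$`2`, wide$`1` * (1 - 0.03)^10, tolerance = 1e-10)
  }
})

test_that("fixed seed reproduces the cohort and reads byte-identically", {
  co1 <- mk_small_cohort(seed = 99)
  co2 <- mk_small_cohort(seed = 99)
  expect_identical(co1$profiles, co2$profiles)
  expect_identical(co1$truth[[1]]$clones, co2$truth[[1]]$clones)
  tab <- simulate_repertoire(co1$truth[[1]], "CD4_naive", "beta",
                             n_cells = 50, seed = 8)
  r1 <- simulate_reads(tab, reads_per_umi = 3, error_rate = 0.01, seed = 21)
  r2 <- simulate_reads(tab, reads_per_umi = 3, error_rate = 0.01, seed = 21)
  expect_identical(r1$reads, r2$reads)
})

test_that("truth records respect retention and frequency invariants", {
  co <- mk_small_cohort(n_donors = 3, richness = 80, seed = 12)
  for (tr in co$truth) {
    cl <- tr$clones
    for (grp in split(cl, paste(cl$subset, cl$chain))) {
      v1 <- grp$clone_id[grp$cells_v1 > 0]
      v2 <- grp$clone_id[grp$cells_v2 > 0]
      ret <- grp$clone_id[grp$retained]
      expect_true(all(ret %in% intersect(v1, v2)))
      expect_equal(sum(grp$freq_v1), 1, tolerance = 1e-12)
      expect_equal(sum(grp$freq_v2), 1, tolerance = 1e-12)
    }
  }
})

test_that("census sampling recovers the full richness; n=1 gives one clone", {
  co <- mk_small_cohort(n_donors = 1, richness = 40, seed = 31)
  tr <- co$truth[[1]]
  cl <- tr$clones[tr$clones$subset == "CD8_naive" & tr$clones$chain == "alpha", ]
  pop_size <- sum(cl$cells_v1)
  tab <- simulate_repertoire(tr, "CD8_naive", "alpha", visit = 1,
                             n_cells = pop_size, seed = 1)
  expect_equal(nrow(tab), sum(cl$cells_v1 > 0))
  expect_equal(total_umi(tab), pop_size)
  one <- simulate_repertoire(tr, "CD8_naive", "alpha", n_cells = 1, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_equal(one$duplicate_count, 1L)
  expect_error(
    simulate_repertoire(tr, "CD8_naive", "alpha", n_cells = pop_size + 1),
    "exceeds population size"
  )
})

test_that("subsampled unique counts match the hypergeometric expectation", {
  co <- mk_small_cohort(n_donors = 1, richness = 500, seed = 77)
  tr <- co$truth[[1]]
  cl <- tr$clones[tr$clones$subset == "CD4_memory" & tr$clones$chain == "beta", ]
  cells <- cl$cells_v1[cl$cells_v1 > 0]
  n_draw <- round(0.4 * sum(cells))
  uniq <- vapply(1:100, function(s) {
    nrow(simulate_repertoire(tr, "CD4_memory", "beta", n_cells = n_draw,
                             seed = s))
  }, numeric(1))
  expected <- expected_unique_hyper(cells, n_draw)
  # mean over 100 replicates within 4 standard errors of the exact value
  expect_lt(abs(mean(uniq) - expected), 4 * stats::sd(uniq) / sqrt(100) + 1e-9)
})

test_that("clone sequences are deterministic, unique, and in frame", {
  co <- mk_small_cohort(n_donors = 1, richness = 120, seed = 13)
  tr <- co$truth[[1]]
  s1 <- clone_sequences(tr, "CD4_naive", "alpha")
  s2 <- clone_sequences(tr, "CD4_naive", "alpha")
  expect_identical(s1, s2)
  expect_false(anyDuplicated(paste(s1$v_call, s1$j_call, s1$junction)) > 0)
  expect_true(all(nchar(s1$junction) %% 3 == 0))
  expect_false(any(grepl("\\*", s1$junction_aa)))
})

test_that("error-free reads reproduce the source sequence exactly", {
  co <- mk_small_cohort(n_donors = 1, richness = 30, seed = 17)
  cl <- co$truth[[1]]$clones
  pop <- sum(cl$cells_v1[cl$subset == "CD4_naive" & cl$chain == "beta"])
  tab <- simulate_repertoire(co$truth[[1]], "CD4_naive", "beta",
                             n_cells = min(40, pop), seed = 4)
  sim <- simulate_reads(tab, reads_per_umi = 3, error_rate = 0,
                        reads_dist = "fixed", seed = 5)
  expect_equal(nrow(sim$reads), 3 * total_umi(tab))
  ref <- tcr_reference()
  tags <- setNames(ref$tag, ref$gene)
  expected <- paste0(sim$barcode, sim$truth$umi, tags[sim$truth$v_call],
                     sim$truth$junction, tags[sim$truth$j_call])
  umi_of_read <- rep(seq_len(nrow(sim$truth)), sim$truth$n_reads)
  expect_identical(sim$reads$sequence, unname(expected[umi_of_read]))
})

test_that("substitution errors match the binomial expectation", {
  co <- mk_small_cohort(n_donors = 1, richness = 50, seed = 19)
  tab <- simulate_repertoire(co$truth[[1]], "CD8_memory", "beta",
                             n_cells = 120, seed = 6)
  sim <- simulate_reads(tab, reads_per_umi = 4, error_rate = 0.01,
                        reads_dist = "fixed", seed = 7)
  ref <- tcr_reference()
  tags <- setNames(ref$tag, ref$gene)
  expected <- paste0(sim$barcode, sim$truth$umi, tags[sim$truth$v_call],
                     sim$truth$junction, tags[sim$truth$j_call])
  umi_of_read <- rep(seq_len(nrow(sim$truth)), sim$truth$n_reads)
  truth_seq <- unname(expected[umi_of_read])
  mismatches <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim$reads$sequence, truth_seq)
  n_bases <- sum(nchar(truth_seq))
  # total mismatches ~ Binomial(n_bases, 0.01); check within 5 sigma
  expected_total <- 0.01 * n_bases
  sigma <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(sum(mismatches) - expected_total), 5 * sigma)
})

test_that("paired single-cell simulation controls the dual-alpha fraction", {
  sc0 <- simulate_paired_sc(50, dual_alpha_fraction = 0, seed = 1)
  counts <- table(sc0$cell_id, sc0$chain)
  expect_true(all(counts[, "alpha"] == 1))
  expect_true(all(counts[, "beta"] == 1))
  one <- simulate_paired_sc(1, dual_alpha_fraction = 0.5, seed = 2)
  expect_equal(sum(one$chain == "beta"), 1L)
  sc <- simulate_paired_sc(10000, dual_alpha_fraction = 0.13, seed = 3)
  f <- single_alpha_fraction(sc)
  # binomial 99.9% interval around 0.87 at n = 10000
  expect_lt(abs(f - 0.87), 3.3 * sqrt(0.87 * 0.13 / 10000))
})
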