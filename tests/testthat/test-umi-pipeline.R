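test_that("demultiplex splits reads by barcode and routes unknowns", {
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(paste0("AAAAAAAA", strrep("A", 40)),
                 paste0("CCCCCCCC", strrep("A", 40)),
                 paste0("GGGGGGGG", strrep("A", 40))),
    quality = strrep("?", 48)
  )
  out <- demultiplex(reads, c(S1 = "AAAAAAAA", S2 = "CCCCCCCC"))
  expect_named(out, c("S1", "S2", "undetermined"))
  expect_equal(nrow(out$S1), 1)
  expect_equal(nrow(out$undetermined), 1)
  expect_error(demultiplex(reads, c(S1 = "AAAAAAAA", S2 = "AAAAAAAA")),
               "duplicate")
})

test_that("demultiplex splits an error-free two-sample run exactly", {
  co <- mk_small_cohort(n_donors = 2, richness = 30, seed = 23)
  tabs <- lapply(1:2, function(i) {
    simulate_repertoire(co$truth[[i]], "CD4_naive", "beta", n_cells = 30,
                        seed = i)
  })
  barcodes <- c(S1 = "AAAACCCC", S2 = "GGGGTTTT")
  sims <- lapply(1:2, function(i) {
    simulate_reads(tabs[[i]], reads_per_umi = 3, error_rate = 0,
                   reads_dist = "fixed", barcode = barcodes[[i]], seed = i)
  })
  all_reads <- dplyr::bind_rows(sims[[1]]$reads, sims[[2]]$reads)
  all_reads$read_id <- sprintf("r%04d", seq_len(nrow(all_reads)))
  out <- demultiplex(all_reads, barcodes)
  expect_equal(nrow(out$S1), nrow(sims[[1]]$reads))
  expect_equal(nrow(out$S2), nrow(sims[[2]]$reads))
  expect_false("undetermined" %in% names(out))
})

test_that("consensus requires min_reads and splits conflicting variants", {
  x <- strrep("ACGT", 15)
  y <- paste0(strrep("TGCA", 10), strrep("ACGT", 5))  # >10% divergent from x
  # 2 reads only: below the 3-read minimum, no consensus
  expect_equal(nrow(build_consensus(mk_umi_reads(c(x, x)))), 0)
  # 3 identical reads: one consensus equal to the read
  cons <- build_consensus(mk_umi_reads(c(x, x, x)))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$sequence, x)
  expect_equal(cons$read_count, 3L)
  # 3 + 3 conflicting: both variants meet min_reads, two consensus records
  cons2 <- build_consensus(mk_umi_reads(c(x, x, x, y, y, y)))
  expect_equal(nrow(cons2), 2)
  expect_setequal(cons2$sequence, c(x, y))
  expect_true(all(cons2$n_variants == 2))
  # 3 + 2: only the majority variant survives
  cons3 <- build_consensus(mk_umi_reads(c(x, x, x, y, y)))
  expect_equal(cons3$sequence, x)
})

test_that("majority vote corrects a minority substitution", {
  x <- strrep("ACGT", 15)
  x_err <- paste0("T", substr(x, 2, nchar(x)))
  cons <- build_consensus(mk_umi_reads(c(x, x, x_err)))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$sequence, x)
  expect_equal(cons$read_count, 3L)
})

test_that("low-quality UMIs are filtered by mean Phred", {
  x <- strrep("ACGT", 15)
  good <- mk_umi_reads(c(x, x, x), quality_char = "?")  # Phred 30
  bad <- mk_umi_reads(c(x, x, x), quality_char = "&")   # Phred 5
  expect_equal(nrow(build_consensus(good, min_quality = 10)), 1)
  expect_equal(nrow(build_consensus(bad, min_quality = 10)), 0)
})

test_that("annotation round-trips error-free synthetic consensus records", {
  co <- mk_small_cohort(n_donors = 1, richness = 100, seed = 29)
  tab <- simulate_repertoire(co$truth[[1]], "CD4_memory", "alpha",
                             n_cells = 150, seed = 9)
  ref <- tcr_reference()
  tags <- setNames(ref$tag, ref$gene)
  cons <- tibble::tibble(
    umi = sprintf("U%03d", seq_len(nrow(tab))),
    sequence = paste0(tags[tab$v_call], tab$junction, tags[tab$j_call]),
    read_count = 3L, n_variants = 1L
  )
  ann <- annotate_consensus(cons)
  expect_equal(attr(ann, "dropped"), 0L)
  expect_equal(ann$v_call, tab$v_call)
  expect_equal(ann$j_call, tab$j_call)
  expect_equal(ann$junction, tab$junction)
  expect_equal(ann$junction_aa, tab$junction_aa)
  expect_true(all(ann$chain == "alpha"))
})

test_that("annotation tolerates <=2 tag mismatches and drops worse", {
  ref <- tcr_reference()
  tags <- setNames(ref$tag, ref$gene)
  junction <- "TGTGCAGCAGCATTT"
  seq0 <- paste0(tags[["TRBV3"]], junction, tags[["TRBJ2"]])
  corrupt <- function(s, positions) {
    ch <- strsplit(s, "")[[1]]
    ch[positions] <- ifelse(ch[positions] == "A", "C", "A")
    paste(ch, collapse = "")
  }
  cons <- tibble::tibble(
    umi = c("U1", "U2"),
    sequence = c(corrupt(seq0, 1:2), corrupt(seq0, 1:5)),
    read_count = 3L, n_variants = 1L
  )
  ann <- annotate_consensus(cons)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$v_call, "TRBV3")
  expect_equal(attr(ann, "dropped"), 1L)
})

test_that("functional filter removes stop codons and weak support", {
  records <- tibble::tibble(
    umi = sprintf("U%02d", 1:10),
    read_count = c(rep(5L, 9), 2L),
    chain = "beta", v_call = "TRBV1", j_call = "TRBJ1",
    junction = strrep("AAA", 5),
    junction_aa = c("CASS*EQYF", "CAS*F", rep("CASSLEQYF", 8))
  )
  kept <- filter_functional(records, min_reads = 3)
  expect_equal(nrow(kept), 7)
  expect_false(any(grepl("*", kept$junction_aa, fixed = TRUE)))
  expect_true(all(kept$read_count >= 3))
})

test_that("collapse tallies distinct UMIs per clonotype key", {
  rec <- function(umi, junction) {
    tibble::tibble(umi = umi, read_count = 3L, chain = "beta",
                   v_call = "TRBV1", j_call = "TRBJ1", junction = junction,
                   junction_aa = tcrlong:::translate_nt(junction))
  }
  same <- dplyr::bind_rows(lapply(sprintf("U%d", 1:5), rec,
                                  junction = "TGTGCAGCATTT"))
  tab <- collapse_clonotypes(same, sample_id = "S1")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$duplicate_count, 5L)
  distinct <- dplyr::bind_rows(lapply(1:5, function(i) {
    rec(sprintf("U%d", i), paste0("TGT", strrep(c("GCA", "GCC", "GCG", "GCT", "AAA")[i], 2), "TTT"))
  }))
  tab2 <- collapse_clonotypes(distinct, sample_id = "S1")
  expect_equal(nrow(tab2), 5)
  expect_true(all(tab2$duplicate_count == 1L))
})

test_that("random UMI-to-clonotype assignment matches a brute-force tally", {
  set.seed(101)
  junctions <- vapply(1:10, function(i) {
    paste0("TGT", strrep(c("GCA", "GCC", "GCG", "GCT")[(i - 1) %% 4 + 1], 2),
           c("GCA", "GCC", "GCG")[((i - 1) %/% 4) + 1], "TTT")
  }, character(1))
  assignment <- sample(1:10, 100, replace = TRUE)
  records <- tibble::tibble(
    umi = sprintf("U%03d", 1:100), read_count = 3L, chain = "beta",
    v_call = "TRBV1", j_call = "TRBJ1",
    junction = junctions[assignment],
    junction_aa = tcrlong:::translate_nt(junctions[assignment])
  )
  tab <- collapse_clonotypes(records, sample_id = "S1")
  oracle <- table(junctions[assignment])
  expect_equal(total_umi(tab), 100)
  expect_equal(as.integer(oracle[tab$junction]), tab$duplicate_count)
})

test_that("end-to-end: error-free reads recover the truth table exactly", {
  co <- mk_small_cohort(n_donors = 1, richness = 60, seed = 37)
  tab <- simulate_repertoire(co$truth[[1]], "CD8_naive", "beta",
                             n_cells = 80, seed = 10)
  sim <- simulate_reads(tab, reads_per_umi = 3, error_rate = 0,
                        reads_dist = "fixed", barcode = "ACGTACGT", seed = 11)
  res <- preprocess_reads(sim$reads, c(S1 = "ACGTACGT"))
  got <- res$tables$S1
  ord_a <- order(clonotype_key(tab, "nt"))
  ord_b <- order(clonotype_key(got, "nt"))
  expect_identical(clonotype_key(tab, "nt")[ord_a],
                   clonotype_key(got, "nt")[ord_b])
  expect_identical(as.integer(tab$duplicate_count[ord_a]),
                   as.integer(got$duplicate_count[ord_b]))
  expect_equal(total_umi(got), nrow(res$records))
})
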