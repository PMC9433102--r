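#' Generative configuration for a synthetic longitudinal TCR cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults emulate the design of a longitudinal aging study: 30 donors
#' (half male, half female), two visits roughly 9 years apart (range 7-13),
#' first-visit ages spanning the late 20s to early 80s, UMI-tagged reads at
#' a mean depth of ~30 reads per UMI, and per-subset generative richness
#' slopes matching reported naive-subset declines (CD4 alpha -0.66, CD4
#' beta -2.27, CD8 alpha -2.19, CD8 beta -3.48 percent per year; memory
#' subsets flat).
#'
#' @param n_donors Number of donors.
#' @param visit_gap_years Named numeric `c(mean=, min=, max=)`; the gap
#'   between visits is drawn from a Beta distribution rescaled to
#'   `[min, max]` with the requested mean.
#' @param age_range First-visit age range (years).
#' @param clone_size_distribution List with `name` ("lognormal" or
#'   "powerlaw") and its parameter (`sigma` for log-normal clone sizes,
#'   `exponent` for the power law). Clone cell counts are drawn from this
#'   law, so repertoires are heavy-tailed (clonally expanded).
#' @param true_richness Baseline number of unique clonotypes per
#'   donor/subset/chain at the reference age of 50; scalar or named by
#'   subset.
#' @param annual_pct_change Generative richness slope in percent per year:
#'   a scalar applied everywhere, or a data frame with columns `subset`,
#'   `chain`, `pct_per_year` (see [default_slopes()]).
#' @param retention_fraction Probability that a visit-1 clone persists to
#'   visit 2.
#' @param reads_per_umi Mean sequencing reads per UMI.
#' @param error_rate Per-base substitution probability in simulated reads.
#' @param dual_alpha_fraction Probability that a T cell carries two distinct
#'   TCR alpha chains.
#' @param cdr3_stop_fraction Fraction of generated CDR3 junctions carrying
#'   an internal stop codon (exercises the functional filter).
#' @param intercept_sd SD (log10 units) of the per-donor random intercept
#'   on richness.
#' @param residual_sd Residual SD (log10 units) per observation.
#' @param subsets,chains Cell subsets and receptor chains simulated.
#' @param seed Integer seed; a fixed seed makes all outputs reproducible.
#' @return A validated list of class `generative_config`.
#' @examples
#' cfg <- generative_config(n_donors = 4, true_richness = 100, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' cohort$profiles
#' @export
generative_config <- function(n_donors = 30L,
                              visit_gap_years = c(mean = 9, min = 7, max = 13),
                              age_range = c(28, 76),
                              clone_size_distribution = list(name = "lognormal", sigma = 1.5),
                              true_richness = 2000,
                              annual_pct_change = default_slopes(),
                              retention_fraction = 0.5,
                              reads_per_umi = 30,
                              error_rate = 0.001,
                              dual_alpha_fraction = 0.13,
                              cdr3_stop_fraction = 0,
                              intercept_sd = 0.3,
                              residual_sd = 0.1,
                              subsets = c("CD4_naive", "CD4_memory",
                                          "CD8_naive", "CD8_memory"),
                              chains = c("alpha", "beta"),
                              seed = 1L) {
  config <- list(
    n_donors = as.integer(n_donors),
    visit_gap_years = visit_gap_years,
    age_range = age_range,
    clone_size_distribution = clone_size_distribution,
    true_richness = true_richness,
    annual_pct_change = annual_pct_change,
    retention_fraction = retention_fraction,
    reads_per_umi = reads_per_umi,
    error_rate = error_rate,
    dual_alpha_fraction = dual_alpha_fraction,
    cdr3_stop_fraction = cdr3_stop_fraction,
    intercept_sd = intercept_sd,
    residual_sd = residual_sd,
    subsets = subsets,
    chains = chains,
    seed = as.integer(seed)
  )
  validate_generative_config(config)
  class(config) <- "generative_config"
  config
}

validate_generative_config <- function(config) {
  probs <- c(retention = config$retention_fraction,
             error_rate = config$error_rate,
             dual_alpha = config$dual_alpha_fraction,
             stop_fraction = config$cdr3_stop_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(config$true_richness < 1)) {
    stop("configuration error: true_richness must be >= 1", call. = FALSE)
  }
  if (config$n_donors < 1) {
    stop("configuration error: n_donors must be >= 1", call. = FALSE)
  }
  dist <- config$clone_size_distribution
  if (!is.list(dist) || !dist$name %in% c("lognormal", "powerlaw")) {
    stop("configuration error: unknown clone_size_distribution '",
         if (is.list(dist)) dist$name else dist, "'", call. = FALSE)
  }
  gap <- config$visit_gap_years
  if (!all(c("mean", "min", "max") %in% names(gap)) ||
      gap[["min"]] > gap[["mean"]] || gap[["mean"]] > gap[["max"]]) {
    stop("configuration error: visit_gap_years needs min <= mean <= max",
         call. = FALSE)
  }
  invisible(config)
}

#' Default generative richness slopes
#'
#' Percent-per-year richness change used by the cohort generator: reported
#' naive-subset declines, with memory subsets flat (no significant decline
#' reported for memory richness).
#'
#' @return A tibble with columns `subset`, `chain`, `pct_per_year`.
#' @export
default_slopes <- function() {
  tibble::tibble(
    subset = rep(c("CD4_naive", "CD4_memory", "CD8_naive", "CD8_memory"), each = 2),
    chain = rep(c("alpha", "beta"), 4),
    pct_per_year = c(-0.66, -2.27, 0, 0, -2.19, -3.48, 0, 0)
  )
}

slope_lookup <- function(config) {
  spec <- config$annual_pct_change
  grid <- expand.grid(subset = config$subsets, chain = config$chains,
                      stringsAsFactors = FALSE)
  if (is.data.frame(spec)) {
    out <- merge(grid, spec, by = c("subset", "chain"), all.x = TRUE)
    out$pct_per_year[is.na(out$pct_per_year)] <- 0
    tibble::as_tibble(out)
  } else {
    grid$pct_per_year <- as.numeric(spec)
    tibble::as_tibble(grid)
  }
}

richness_lookup <- function(config) {
  r <- config$true_richness
  if (length(r) == 1L && is.null(names(r))) {
    stats::setNames(rep(r, length(config$subsets)), config$subsets)
  } else {
    missing <- setdiff(config$subsets, names(r))
    if (length(missing) > 0) {
      stop("configuration error: true_richness missing subsets: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    r[config$subsets]
  }
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_gap <- function(n, gap) {
  lo <- gap[["min"]]; hi <- gap[["max"]]; m <- gap[["mean"]]
  if (hi == lo) {
    return(rep(m, n))
  }
  mu <- (m - lo) / (hi - lo)
  a <- 2
  b <- a * (1 - mu) / mu
  lo + (hi - lo) * stats::rbeta(n, a, b)
}

draw_clone_cells <- function(n, dist) {
  if (dist$name == "lognormal") {
    pmax(1L, as.integer(round(stats::rlnorm(n, meanlog = 0, sdlog = dist$sigma))))
  } else {
    # Pareto tail: P(size >= s) ~ s^-(exponent - 1)
    pmax(1L, pmin(1000000L,
                  as.integer(floor(stats::runif(n)^(-1 / (dist$exponent - 1))))))
  }
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Generates donor profiles (anthropometrics, blood counts, subset
#' fractions at both visits) and, per donor, a truth record holding the
#' true per-subset/chain richness trajectory and the clone universe (cell
#' counts per clone at each visit, retention flags). Richness follows
#' `log10 R(age) = log10(baseline) + S_old * (age - 50) + donor intercept +
#' residual`, where `S_old = log10(1 + pct/100)`, so with zero noise
#' visit-2 richness equals visit-1 richness compounded by the configured
#' percent change over the visit gap.
#'
#' @param config A [generative_config()].
#' @param clones Build the per-donor clone universes (cell counts,
#'   retention flags)? Set `FALSE` for analyses that only need richness
#'   trajectories; the clone-level fields are then empty.
#' @return A list of class `synthetic_cohort` with elements `profiles` (a
#'   tibble, one row per donor x visit), `truth` (a list of truth records),
#'   and `config`.
#' @export
simulate_cohort <- function(config, clones = TRUE) {
  stopifnot(inherits(config, "generative_config"))
  with_seed(config$seed, {
    n <- config$n_donors
    donors <- sprintf("D%02d", seq_len(n))
    sex <- rep(c("male", "female"), length.out = n)[sample.int(n)]
    age1 <- stats::runif(n, config$age_range[1], config$age_range[2])
    gap <- draw_gap(n, config$visit_gap_years)
    age2 <- age1 + gap

    profiles <- lapply(seq_len(n), function(i) {
      ages <- c(age1[i], age2[i])
      male <- sex[i] == "male"
      height <- stats::rnorm(1, if (male) 1.77 else 1.63, if (male) 0.07 else 0.06)
      weight0 <- stats::rnorm(1, if (male) 82 else 70, 12)
      tibble::tibble(
        donor = donors[i],
        visit = 1:2,
        age = ages,
        sex = sex[i],
        height_m = height,
        weight_kg = clamp(weight0 + stats::rnorm(2, 0, 2), 40, 160),
        lymphocytes_per_ul = clamp(stats::rnorm(2, 2300 - 5 * ages, 300), 500, 6000),
        frac_CD4_naive = clamp(0.28 - 0.002 * (ages - 50) + stats::rnorm(2, 0, 0.03), 0.02, 0.6),
        frac_CD4_memory = clamp(0.17 + 0.001 * (ages - 50) + stats::rnorm(2, 0, 0.03), 0.02, 0.6),
        frac_CD8_naive = clamp(0.11 - 0.0015 * (ages - 50) + stats::rnorm(2, 0, 0.02), 0.01, 0.5),
        frac_CD8_memory = clamp(0.10 + 0.001 * (ages - 50) + stats::rnorm(2, 0, 0.02), 0.01, 0.5)
      )
    })
    profiles <- dplyr::bind_rows(profiles)

    slopes <- slope_lookup(config)
    base_richness <- richness_lookup(config)
    combos <- expand.grid(subset = config$subsets, chain = config$chains,
                          stringsAsFactors = FALSE)

    truth <- lapply(seq_len(n), function(i) {
      rich_rows <- list()
      clone_rows <- list()
      for (k in seq_len(nrow(combos))) {
        subset <- combos$subset[k]
        chain <- combos$chain[k]
        pct <- slopes$pct_per_year[slopes$subset == subset & slopes$chain == chain]
        s_old <- log10(1 + pct / 100)
        intercept <- stats::rnorm(1, 0, config$intercept_sd)
        log10_base <- log10(base_richness[[subset]])
        lr <- log10_base + s_old * (c(age1[i], age2[i]) - 50) + intercept +
          stats::rnorm(2, 0, config$residual_sd)
        r_true <- 10^lr
        n_clones <- pmax(1L, as.integer(round(r_true)))
        rich_rows[[k]] <- tibble::tibble(
          subset = subset, chain = chain, visit = 1:2,
          true_richness = r_true, n_clones = n_clones
        )
        if (!clones) {
          next
        }
        r1 <- n_clones[1]; r2 <- n_clones[2]
        n_ret <- min(stats::rbinom(1, r1, config$retention_fraction), r2)
        retained_ids <- sort(sample.int(r1, n_ret))
        v2_ids <- c(retained_ids,
                    if (r2 > n_ret) r1 + seq_len(r2 - n_ret) else integer(0))
        all_ids <- seq_len(max(r1, if (length(v2_ids)) max(v2_ids) else r1))
        cells_v1 <- integer(length(all_ids))
        cells_v1[seq_len(r1)] <- draw_clone_cells(r1, config$clone_size_distribution)
        cells_v2 <- integer(length(all_ids))
        cells_v2[v2_ids] <- draw_clone_cells(length(v2_ids), config$clone_size_distribution)
        clone_rows[[k]] <- tibble::tibble(
          subset = subset, chain = chain, clone_id = all_ids,
          cells_v1 = cells_v1, cells_v2 = cells_v2,
          retained = all_ids %in% retained_ids
        )
      }
      richness <- dplyr::bind_rows(rich_rows)
      if (clones) {
        clone_tbl <- dplyr::bind_rows(clone_rows)
        clone_tbl <- clone_tbl[clone_tbl$cells_v1 > 0 | clone_tbl$cells_v2 > 0, ]
        clone_tbl$freq_v1 <- stats::ave(clone_tbl$cells_v1,
                                        paste(clone_tbl$subset, clone_tbl$chain),
                                        FUN = function(x) if (sum(x) > 0) x / sum(x) else x)
        clone_tbl$freq_v2 <- stats::ave(clone_tbl$cells_v2,
                                        paste(clone_tbl$subset, clone_tbl$chain),
                                        FUN = function(x) if (sum(x) > 0) x / sum(x) else x)
      } else {
        clone_tbl <- tibble::tibble(
          subset = character(0), chain = character(0), clone_id = integer(0),
          cells_v1 = integer(0), cells_v2 = integer(0), retained = logical(0),
          freq_v1 = numeric(0), freq_v2 = numeric(0)
        )
      }
      paired <- paired_truth(richness)
      structure(
        list(donor = donors[i], donor_index = i, sex = sex[i],
             age_v1 = age1[i], age_v2 = age2[i], gap = gap[i],
             richness = richness, clones = clone_tbl, paired = paired,
             meta = list(seed = config$seed, subsets = config$subsets,
                         chains = config$chains,
                         stop_fraction = config$cdr3_stop_fraction)),
        class = "truth_record"
      )
    })

    structure(list(profiles = profiles, truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

# Generative convention: the donor's "true" paired alpha-beta richness is
# the default lineage pairing equation applied to the true chain richness.
paired_truth <- function(richness) {
  wide <- tidyr::pivot_wider(richness[, c("subset", "chain", "visit", "true_richness")],
                             names_from = "chain", values_from = "true_richness")
  wide$lineage <- ifelse(grepl("^CD4", wide$subset), "CD4", "CD8")
  wide$paired_richness <- ifelse(
    wide$lineage == "CD4",
    apply_pairing_equation(pairing_model_cd4(), wide$alpha, wide$beta),
    apply_pairing_equation(pairing_model_cd8(), wide$alpha, wide$beta)
  )
  tibble::as_tibble(wide[, c("subset", "visit", "lineage", "paired_richness")])
}

#' Deterministic clone sequences for one donor/subset/chain
#'
#' Clonotype sequences (V gene, J gene, in-frame CDR3 junction) for every
#' clone id in the donor's clone universe. Generation is keyed on the
#' cohort seed and the donor/subset/chain indices, so repeated calls —
#' and calls for different visits — return identical sequences, and
#' (V, J, junction) triples are unique within the universe.
#'
#' @param truth A truth record from [simulate_cohort()].
#' @param subset,chain Which repertoire.
#' @return A tibble with `clone_id`, `v_call`, `j_call`, `junction`,
#'   `junction_aa`.
#' @export
clone_sequences <- function(truth, subset, chain) {
  stopifnot(inherits(truth, "truth_record"))
  meta <- truth$meta
  si <- match(subset, meta$subsets)
  ci <- match(chain, meta$chains)
  if (is.na(si) || is.na(ci)) {
    stop("unknown subset or chain for this cohort", call. = FALSE)
  }
  ids <- truth$clones$clone_id[truth$clones$subset == subset &
                                 truth$clones$chain == chain]
  n <- length(ids)
  ref <- tcr_reference()
  v_genes <- ref$gene[ref$chain == chain & ref$segment == "V"]
  j_genes <- ref$gene[ref$chain == chain & ref$segment == "J"]
  stream <- truth$donor_index * 64L + si * 8L + ci
  with_seed(derive_seed(meta$seed, stream), {
    v_call <- sample(v_genes, n, replace = TRUE)
    j_call <- sample(j_genes, n, replace = TRUE)
    junction <- random_junctions(n, stop_fraction = meta$stop_fraction)
    key <- paste(v_call, j_call, junction)
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      junction[dup] <- random_junctions(sum(dup),
                                        stop_fraction = meta$stop_fraction)
      key <- paste(v_call, j_call, junction)
    }
    tibble::tibble(clone_id = ids, v_call = v_call, j_call = j_call,
                   junction = junction, junction_aa = translate_nt(junction))
  })
}

#' Sample a clonotype table from a donor's true repertoire
#'
#' Draws `n_cells` cells without replacement from the clone population of
#' one donor/visit/subset/chain (each clone contributes its true cell
#' count) and tallies the sampled cells per clonotype. One sampled cell
#' yields one UMI.
#'
#' @param truth A truth record from [simulate_cohort()].
#' @param subset,chain Which repertoire.
#' @param visit Visit number (1 or 2).
#' @param n_cells Number of cells to draw; must not exceed the population
#'   size. Drawing the full population returns every clone (a census).
#' @param seed Optional seed for the draw.
#' @return A `clonotype_table`.
#' @export
simulate_repertoire <- function(truth, subset, chain, visit = 1, n_cells,
                                seed = NULL) {
  stopifnot(inherits(truth, "truth_record"), n_cells >= 1)
  clones <- truth$clones[truth$clones$subset == subset &
                           truth$clones$chain == chain, ]
  cells <- if (visit == 1) clones$cells_v1 else clones$cells_v2
  present <- cells > 0
  pop <- rep(clones$clone_id[present], cells[present])
  if (n_cells > length(pop)) {
    stop("n_cells (", n_cells, ") exceeds population size (", length(pop), ")",
         call. = FALSE)
  }
  drawn <- with_seed(seed, {
    if (n_cells == length(pop)) pop else sample(pop, n_cells)
  })
  counts <- table(drawn)
  seqs <- clone_sequences(truth, subset, chain)
  idx <- match(as.integer(names(counts)), seqs$clone_id)
  clonotype_table(
    tibble::tibble(
      v_call = seqs$v_call[idx],
      j_call = seqs$j_call[idx],
      junction = seqs$junction[idx],
      junction_aa = seqs$junction_aa[idx],
      duplicate_count = as.integer(counts)
    ),
    sample_id = paste(truth$donor, paste0("v", visit), subset, chain, sep = "_"),
    donor = truth$donor, visit = visit, subset = subset, chain = chain
  )
}

#' Simulate UMI-tagged sequencing reads from a clonotype table
#'
#' Each UMI (one per `duplicate_count` unit) emits one or more reads laid
#' out as `[sample barcode][12-bp UMI][V tag][CDR3 junction][J tag]`, with
#' independent per-base substitution errors. A truth sidecar maps every
#' UMI to its source clonotype.
#'
#' @param table A `clonotype_table` (rows must carry `v_call`, `j_call`,
#'   `junction` present in the reference).
#' @param reads_per_umi Mean reads per UMI; with `reads_dist = "poisson"`
#'   each UMI emits `1 + Poisson(reads_per_umi - 1)` reads (always >= 1),
#'   with `"fixed"` exactly `reads_per_umi`.
#' @param error_rate Per-base substitution probability (applied over the
#'   whole read).
#' @param barcode Sample barcode prepended to every read.
#' @param seed Optional seed.
#' @param reads_dist Read-count law per UMI.
#' @param base_quality Constant Phred quality assigned to every base.
#' @param reference V/J reference supplying the tag sequences.
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `quality`),
#'   `truth` (tibble mapping `umi` to clonotype and read count), and
#'   `barcode`.
#' @export
simulate_reads <- function(table, reads_per_umi = 30, error_rate = 0.001,
                           barcode = "ACGTACGT", seed = NULL,
                           reads_dist = c("poisson", "fixed"),
                           base_quality = 30L,
                           reference = tcr_reference()) {
  reads_dist <- match.arg(reads_dist)
  stopifnot(reads_per_umi >= 1)
  tag_map <- stats::setNames(reference$tag, reference$gene)
  inserts <- paste0(tag_map[table$v_call], table$junction, tag_map[table$j_call])
  if (anyNA(tag_map[table$v_call]) || anyNA(tag_map[table$j_call])) {
    stop("table contains V/J calls absent from the reference", call. = FALSE)
  }
  with_seed(seed, {
    n_umi <- sum(table$duplicate_count)
    umis <- random_umis(n_umi)
    row_of_umi <- rep(seq_len(nrow(table)), table$duplicate_count)
    n_reads <- if (reads_dist == "fixed") {
      rep(as.integer(round(reads_per_umi)), n_umi)
    } else {
      1L + stats::rpois(n_umi, reads_per_umi - 1)
    }
    umi_of_read <- rep(seq_len(n_umi), n_reads)
    seqs <- paste0(barcode, umis[umi_of_read], inserts[row_of_umi][umi_of_read])
    if (error_rate > 0) {
      seqs <- mutate_sequences(seqs, error_rate)
    }
    qual_char <- rawToChar(as.raw(base_quality + 33L))
    reads <- tibble::tibble(
      read_id = sprintf("R%06d", seq_along(seqs)),
      sequence = seqs,
      quality = strrep(qual_char, nchar(seqs))
    )
    truth <- tibble::tibble(
      umi = umis,
      v_call = table$v_call[row_of_umi],
      j_call = table$j_call[row_of_umi],
      junction = table$junction[row_of_umi],
      junction_aa = table$junction_aa[row_of_umi],
      n_reads = n_reads
    )
    list(reads = reads, truth = truth, barcode = barcode)
  })
}

random_umis <- function(n) {
  umis <- character(0)
  need <- n
  while (need > 0) {
    new <- vapply(seq_len(need), function(i) {
      paste(sample(c("A", "C", "G", "T"), UMI_LENGTH, replace = TRUE),
            collapse = "")
    }, character(1))
    umis <- unique(c(umis, new))
    need <- n - length(umis)
  }
  umis[seq_len(n)]
}

# Apply independent per-base substitutions at the given rate.
mutate_sequences <- function(seqs, error_rate) {
  widths <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), widths, error_rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate single-cell paired alpha/beta clonotypes
#'
#' Every cell carries exactly one TCR beta chain and one or two distinct
#' TCR alpha chains; a fraction `dual_alpha_fraction` of cells are
#' dual-alpha.
#'
#' @param n_cells Number of cells.
#' @param dual_alpha_fraction Probability a cell carries two alphas.
#' @param n_clones Number of distinct clonotypes in each chain pool.
#' @param seed Optional seed.
#' @return A tibble with `cell_id`, `chain`, `v_call`, `j_call`,
#'   `junction`, `junction_aa` (long format, one row per chain per cell).
#' @export
simulate_paired_sc <- function(n_cells, dual_alpha_fraction = 0.13,
                               n_clones = max(2L, round(n_cells / 2)),
                               seed = NULL) {
  stopifnot(n_cells >= 1, n_clones >= 2)
  ref <- tcr_reference()
  with_seed(seed, {
    pools <- lapply(c("alpha", "beta"), function(chain) {
      v <- sample(ref$gene[ref$chain == chain & ref$segment == "V"],
                  n_clones, replace = TRUE)
      j <- sample(ref$gene[ref$chain == chain & ref$segment == "J"],
                  n_clones, replace = TRUE)
      junction <- random_junctions(n_clones)
      tibble::tibble(v_call = v, j_call = j, junction = junction,
                     junction_aa = translate_nt(junction))
    })
    names(pools) <- c("alpha", "beta")
    cell_ids <- sprintf("C%06d", seq_len(n_cells))
    beta_idx <- sample.int(n_clones, n_cells, replace = TRUE)
    alpha1_idx <- sample.int(n_clones, n_cells, replace = TRUE)
    dual <- stats::runif(n_cells) < dual_alpha_fraction
    alpha2_idx <- rep(NA_integer_, n_cells)
    if (any(dual)) {
      # second alpha must be a distinct clonotype
      alpha2_idx[dual] <- vapply(alpha1_idx[dual], function(a1) {
        repeat {
          a2 <- sample.int(n_clones, 1L)
          if (a2 != a1) return(a2)
        }
      }, integer(1))
    }
    rows <- dplyr::bind_rows(
      tibble::tibble(cell_id = cell_ids, chain = "beta",
                     pools$beta[beta_idx, ]),
      tibble::tibble(cell_id = cell_ids, chain = "alpha",
                     pools$alpha[alpha1_idx, ]),
      tibble::tibble(cell_id = cell_ids[dual], chain = "alpha",
                     pools$alpha[alpha2_idx[dual], ])
    )
    dplyr::arrange(rows, .data$cell_id, .data$chain)
  })
}

#' Simulate per-sample pairing summaries with a known slope
#'
#' Generates `(alpha_unique, beta_unique, paired_unique)` summaries obeying
#' `paired - max(f * alpha, beta) = M * (f * alpha + beta)` up to optional
#' multiplicative noise; used to validate the pairing-model fit.
#'
#' @param n_samples Number of samples.
#' @param M True through-origin slope.
#' @param f True single-alpha fraction.
#' @param richness_range Range of per-chain unique counts.
#' @param noise_sd Multiplicative noise SD on the linear term.
#' @param seed Optional seed.
#' @return A tibble with one row per sample.
#' @export
simulate_pairing_samples <- function(n_samples, M, f,
                                     richness_range = c(2000, 20000),
                                     noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    alpha <- stats::runif(n_samples, richness_range[1], richness_range[2])
    beta <- stats::runif(n_samples, richness_range[1], richness_range[2])
    x <- f * alpha + beta
    y <- M * x * (1 + stats::rnorm(n_samples, 0, noise_sd))
    tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      alpha_unique = alpha,
      beta_unique = beta,
      paired_unique = y + pmax(f * alpha, beta)
    )
  })
}
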