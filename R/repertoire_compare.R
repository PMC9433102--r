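# Repertoire overlap (unique- and total-sequence level), public/private
# TCR classification across donors, and publicity-abundance profiles.

#' Unique-sequence overlap between two repertoires
#'
#' Percent overlap of clonotype identities (richness level). The default
#' metric is the Jaccard percentage
#' `100 * |A intersect B| / |A union B|`; the Sorensen percentage
#' `100 * 2|A intersect B| / (|A| + |B|)` is selectable. Both are
#' symmetric, 100 for identical sets and 0 for disjoint ones. Clonotypes
#' are keyed on V + CDR3 amino acid + CDR3 nucleotide + J by default.
#'
#' @param a,b Clonotype tables of the same chain.
#' @param metric `"jaccard"` or `"sorensen"`.
#' @param key Clonotype key (see [clonotype_key()]).
#' @return Percent overlap in `[0, 100]`, with attributes `metric` and
#'   `key` recording the variant used.
#' @examples
#' a <- clonotype_table(data.frame(v_call = "V1", j_call = "J1",
#'   junction_aa = c("CAF", "CGF", "CHF"), junction = c("a", "b", "c"),
#'   duplicate_count = 1))
#' b <- clonotype_table(data.frame(v_call = "V1", j_call = "J1",
#'   junction_aa = c("CGF", "CHF", "CIF"), junction = c("b", "c", "d"),
#'   duplicate_count = 1))
#' unique_overlap(a, b)                       # Jaccard: 50
#' unique_overlap(a, b, metric = "sorensen")  # 66.67
#' @export
unique_overlap <- function(a, b, metric = c("jaccard", "sorensen"),
                           key = c("nt", "aa")) {
  metric <- match.arg(metric)
  key <- match.arg(key)
  check_comparable(a, b)
  ka <- unique(clonotype_key(a, key = key))
  kb <- unique(clonotype_key(b, key = key))
  shared <- length(intersect(ka, kb))
  pct <- if (metric == "jaccard") {
    100 * shared / (length(ka) + length(kb) - shared)
  } else {
    100 * 2 * shared / (length(ka) + length(kb))
  }
  structure(pct, metric = metric, key = key)
}

#' Total-sequence overlap between two repertoires
#'
#' Percent of UMI mass carried by shared clonotypes (cell-population
#' level, sensitive to clonal expansion). The default two-sided reading is
#' `100 * (UMI_A(shared) + UMI_B(shared)) / (UMI_A + UMI_B)`; the
#' one-sided reading `100 * UMI_A(shared) / UMI_A` is available via
#' `reading = "one_sided"`.
#'
#' @inheritParams unique_overlap
#' @param reading `"two_sided"` (default) or `"one_sided"` (relative to
#'   `a`).
#' @return Percent overlap in `[0, 100]`, with attributes `reading` and
#'   `key`.
#' @export
total_overlap <- function(a, b, key = c("nt", "aa"),
                          reading = c("two_sided", "one_sided")) {
  key <- match.arg(key)
  reading <- match.arg(reading)
  check_comparable(a, b)
  ka <- clonotype_key(a, key = key)
  kb <- clonotype_key(b, key = key)
  shared <- intersect(ka, kb)
  umi_a_shared <- sum(a$duplicate_count[ka %in% shared])
  umi_b_shared <- sum(b$duplicate_count[kb %in% shared])
  pct <- if (reading == "two_sided") {
    100 * (umi_a_shared + umi_b_shared) / (total_umi(a) + total_umi(b))
  } else {
    100 * umi_a_shared / total_umi(a)
  }
  structure(pct, reading = reading, key = key)
}

check_comparable <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("cannot compute overlap with an empty repertoire", call. = FALSE)
  }
  if ("chain" %in% names(a) && "chain" %in% names(b)) {
    ca <- unique(a$chain); cb <- unique(b$chain)
    if (length(ca) == 1 && length(cb) == 1 && ca != cb) {
      stop("overlap requires repertoires of the same chain", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Public/private classification of TCRs across donors
#'
#' Counts, for every unique TCR, the number of distinct donors carrying it
#' (pooling all of each donor's samples and visits). A TCR found in
#' exactly one donor is private; in two or more, public.
#'
#' @param tables A list of clonotype tables (each with a `donor` column),
#'   or a single combined data frame.
#' @param key Clonotype key; the amino-acid key (V + J + CDR3aa) by
#'   default.
#' @return A tibble with one row per unique TCR: the key columns,
#'   `publicity` (number of donors), and `status`
#'   (`"private"`/`"public"`).
#' @export
publicity <- function(tables, key = c("aa", "nt")) {
  key <- match.arg(key)
  combined <- if (is.data.frame(tables)) tables else dplyr::bind_rows(tables)
  if (!"donor" %in% names(combined)) {
    stop("publicity requires a 'donor' column", call. = FALSE)
  }
  if (length(unique(combined$donor)) < 2) {
    stop("publicity requires repertoires from at least 2 donors",
         call. = FALSE)
  }
  combined$.key <- clonotype_key(combined, key = key)
  out <- combined |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      v_call = dplyr::first(.data$v_call),
      j_call = dplyr::first(.data$j_call),
      junction_aa = dplyr::first(.data$junction_aa),
      publicity = dplyr::n_distinct(.data$donor),
      .groups = "drop"
    )
  out$status <- ifelse(out$publicity == 1L, "private", "public")
  dplyr::rename(out, key = ".key")
}

#' Abundance by publicity level
#'
#' For each donor, all samples are pooled (UMI counts cumulated) and each
#' TCR's UMI percentage within the donor is computed. For each unique TCR
#' the median UMI percentage across the donors carrying it is taken, and
#' TCRs are aggregated by publicity level (number of donors sharing
#' them); the per-level summary is reported on a log10 scale.
#'
#' @inheritParams publicity
#' @return A list with `tcr` (per-TCR tibble: key, publicity, status,
#'   `median_umi_pct`, `log10_median_umi_pct`) and `by_level` (per
#'   publicity level: number of TCRs and the median of the per-TCR
#'   medians, raw and log10).
#' @export
abundance_by_publicity <- function(tables, key = c("aa", "nt")) {
  key <- match.arg(key)
  combined <- if (is.data.frame(tables)) tables else dplyr::bind_rows(tables)
  if (!"donor" %in% names(combined)) {
    stop("abundance_by_publicity requires a 'donor' column", call. = FALSE)
  }
  combined$.key <- clonotype_key(combined, key = key)
  per_donor <- combined |>
    dplyr::group_by(.data$donor, .data$.key) |>
    dplyr::summarise(umi = sum(.data$duplicate_count), .groups = "drop_last") |>
    dplyr::mutate(umi_pct = 100 * .data$umi / sum(.data$umi)) |>
    dplyr::ungroup()
  per_tcr <- per_donor |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      publicity = dplyr::n_distinct(.data$donor),
      median_umi_pct = stats::median(.data$umi_pct),
      .groups = "drop"
    )
  per_tcr$status <- ifelse(per_tcr$publicity == 1L, "private", "public")
  per_tcr$log10_median_umi_pct <- log10(per_tcr$median_umi_pct)
  by_level <- per_tcr |>
    dplyr::group_by(.data$publicity) |>
    dplyr::summarise(
      n_tcrs = dplyr::n(),
      median_umi_pct = stats::median(.data$median_umi_pct),
      .groups = "drop"
    )
  by_level$log10_median_umi_pct <- log10(by_level$median_umi_pct)
  list(tcr = dplyr::rename(per_tcr, key = ".key"), by_level = by_level)
}
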