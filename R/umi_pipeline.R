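# UMI consensus pipeline: demultiplex -> UMI grouping -> consensus ->
# V/J annotation -> functional filter -> clonotype collapse.

#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the sample whose barcode exactly matches the read
#' prefix. Reads matching no barcode are routed to `"undetermined"`.
#'
#' @param reads A read tibble (`read_id`, `sequence`, `quality`).
#' @param barcodes Named character vector, sample id -> barcode. All
#'   barcodes must be distinct and the same length.
#' @return A named list of read tibbles (one per sample, plus
#'   `"undetermined"` when present), with an `assignment_counts` attribute.
#' @export
demultiplex <- function(reads, barcodes) {
  if (anyDuplicated(barcodes)) {
    stop("configuration error: duplicate barcodes", call. = FALSE)
  }
  if (length(unique(nchar(barcodes))) != 1) {
    stop("configuration error: barcodes must share one length", call. = FALSE)
  }
  bl <- nchar(barcodes[[1]])
  prefix <- substr(reads$sequence, 1L, bl)
  sample_of <- names(barcodes)[match(prefix, barcodes)]
  sample_of[is.na(sample_of)] <- "undetermined"
  out <- split(reads, factor(sample_of, levels = unique(c(names(barcodes), "undetermined"))))
  out <- out[vapply(out, nrow, integer(1)) > 0]
  counts <- vapply(out, nrow, integer(1))
  attr(out, "assignment_counts") <- counts
  out
}

# Mean Phred score over a substring region of a quality string.
mean_phred <- function(quality, from, to) {
  vapply(substr(quality, from, to), function(q) {
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Group reads by UMI and call consensus sequences
#'
#' Reads are laid out `[barcode][12-bp UMI][TCR insert]`. Reads whose mean
#' Phred over the UMI region falls below `min_quality` are discarded. The
#' remaining reads are grouped by UMI; within a UMI, reads are clustered by
#' sequence identity (identical length, <= `cluster_mismatch` mismatches
#' merges into the nearest existing cluster), so conflicting TCR sequences
#' under one UMI are separated. Each cluster supported by at least
#' `min_reads` reads yields one consensus by position-wise majority vote
#' (ties broken alphabetically, deterministically).
#'
#' @param reads A read tibble for one sample.
#' @param barcode_length Length of the sample barcode preceding the UMI.
#' @param min_reads Minimum supporting reads per consensus (UMIs or
#'   variants with fewer reads emit nothing).
#' @param min_quality Minimum mean Phred over the UMI region.
#' @param cluster_mismatch Maximum mismatches merged into one variant
#'   cluster.
#' @return A tibble with `umi`, `sequence` (consensus insert), `read_count`,
#'   `n_variants` (clusters meeting `min_reads` under that UMI).
#' @export
build_consensus <- function(reads, barcode_length = 8L, min_reads = 3L,
                            min_quality = 10, cluster_mismatch = 1L) {
  if (nrow(reads) == 0) {
    return(empty_consensus())
  }
  umi_from <- barcode_length + 1L
  umi_to <- barcode_length + UMI_LENGTH
  keep <- mean_phred(reads$quality, umi_from, umi_to) >= min_quality
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0) {
    return(empty_consensus())
  }
  umi <- substr(reads$sequence, umi_from, umi_to)
  insert <- substr(reads$sequence, umi_to + 1L, nchar(reads$sequence))
  groups <- split(insert, umi)
  out <- lapply(names(groups), function(u) {
    cons <- consensus_one_umi(groups[[u]], min_reads, cluster_mismatch)
    if (nrow(cons) == 0) {
      return(NULL)
    }
    cons$umi <- u
    cons$n_variants <- nrow(cons)
    cons
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(empty_consensus())
  }
  out[, c("umi", "sequence", "read_count", "n_variants")]
}

empty_consensus <- function() {
  tibble::tibble(umi = character(0), sequence = character(0),
                 read_count = integer(0), n_variants = integer(0))
}

# Cluster the reads of one UMI and majority-vote each qualifying cluster.
consensus_one_umi <- function(seqs, min_reads, cluster_mismatch) {
  tab <- sort(table(seqs), decreasing = TRUE)
  uniq <- names(tab)
  # stable order: frequency desc, then sequence, so clustering is
  # deterministic for a fixed input multiset
  uniq <- uniq[order(-as.integer(tab), uniq)]
  counts <- as.integer(tab[uniq])
  centroid <- character(0)
  assign <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    hit <- 0L
    for (k in seq_along(centroid)) {
      if (nchar(uniq[i]) == nchar(centroid[k]) &&
          hamming(uniq[i], centroid[k]) <= cluster_mismatch) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      centroid <- c(centroid, uniq[i])
      hit <- length(centroid)
    }
    assign[i] <- hit
  }
  rows <- lapply(seq_along(centroid), function(k) {
    members <- which(assign == k)
    n_reads <- sum(counts[members])
    if (n_reads < min_reads) {
      return(NULL)
    }
    tibble::tibble(
      sequence = majority_vote(uniq[members], counts[members]),
      read_count = n_reads
    )
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) empty_consensus()[, c("sequence", "read_count")] else out
}

majority_vote <- function(seqs, counts) {
  if (length(seqs) == 1L) {
    return(seqs)
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    votes <- tapply(counts, mat[, j], sum)
    names(votes)[order(-votes, names(votes))][1]
  }, character(1))
  paste(cons, collapse = "")
}

#' Annotate consensus sequences with V/J genes and CDR3
#'
#' Matches the leading and trailing tag regions of each consensus insert
#' against the V and J tags of the reference (allowing up to
#' `max_mismatch` substitutions), extracts the CDR3 nucleotide junction
#' between the anchors, and translates it. Records with no acceptable V or
#' J match, disagreeing chain calls, or an out-of-frame junction are
#' dropped; the number dropped is recorded in the `dropped` attribute.
#'
#' @param consensus A consensus tibble from [build_consensus()].
#' @param reference V/J reference (see [tcr_reference()]).
#' @param max_mismatch Tag-match tolerance in substitutions.
#' @return The annotated tibble (`umi`, `read_count`, `chain`, `v_call`,
#'   `j_call`, `junction`, `junction_aa`) with attribute `dropped`.
#' @export
annotate_consensus <- function(consensus, reference = tcr_reference(),
                               max_mismatch = 2L) {
  n <- nrow(consensus)
  if (n == 0) {
    out <- tibble::tibble(umi = character(0), read_count = integer(0),
                          chain = character(0), v_call = character(0),
                          j_call = character(0), junction = character(0),
                          junction_aa = character(0))
    attr(out, "dropped") <- 0L
    return(out)
  }
  wid <- nchar(consensus$sequence)
  long_enough <- wid >= 2L * TAG_LENGTH + 3L
  prefix <- substr(consensus$sequence, 1L, TAG_LENGTH)
  suffix <- substr(consensus$sequence, wid - TAG_LENGTH + 1L, wid)
  v_hit <- best_tag_match(prefix, reference[reference$segment == "V", ], max_mismatch)
  j_hit <- best_tag_match(suffix, reference[reference$segment == "J", ], max_mismatch)
  junction <- substr(consensus$sequence, TAG_LENGTH + 1L, wid - TAG_LENGTH)
  ok <- long_enough & !is.na(v_hit$gene) & !is.na(j_hit$gene) &
    v_hit$chain == j_hit$chain &
    nchar(junction) %% 3 == 0
  ok[is.na(ok)] <- FALSE
  out <- tibble::tibble(
    umi = consensus$umi[ok],
    read_count = consensus$read_count[ok],
    chain = v_hit$chain[ok],
    v_call = v_hit$gene[ok],
    j_call = j_hit$gene[ok],
    junction = junction[ok]
  )
  out$junction_aa <- translate_nt(out$junction)
  attr(out, "dropped") <- sum(!ok)
  out
}

# Best-matching tag per query (fixed-width); NA when the best exceeds
# max_mismatch. Ties go to the first gene in reference order.
best_tag_match <- function(queries, ref, max_mismatch) {
  qmat <- do.call(rbind, strsplit(queries, ""))
  best_d <- rep(Inf, length(queries))
  best_i <- rep(NA_integer_, length(queries))
  for (k in seq_len(nrow(ref))) {
    tag <- strsplit(ref$tag[k], "")[[1]]
    d <- rowSums(qmat != matrix(tag, nrow(qmat), length(tag), byrow = TRUE))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_i[upd] <- k
  }
  ok <- best_d <= max_mismatch
  list(gene = ifelse(ok, ref$gene[best_i], NA_character_),
       chain = ifelse(ok, ref$chain[best_i], NA_character_),
       mismatches = best_d)
}

#' Keep functional, well-supported records
#'
#' Removes records whose CDR3 amino-acid sequence contains a stop codon
#' (`*`) and records supported by fewer than `min_reads` reads.
#'
#' @param records Annotated consensus records.
#' @param min_reads Minimum supporting reads.
#' @return The filtered tibble.
#' @export
filter_functional <- function(records, min_reads = 3L) {
  keep <- !grepl("*", records$junction_aa, fixed = TRUE) &
    !is.na(records$junction_aa) &
    records$read_count >= min_reads
  records[keep, , drop = FALSE]
}

#' Collapse consensus records to a clonotype table
#'
#' One row per clonotype key (chain, V, J, CDR3 nucleotide and amino acid),
#' with `duplicate_count` = number of distinct UMIs supporting the key.
#'
#' @param records Annotated, filtered consensus records for one sample.
#' @param sample_id,donor,visit,subset Sample metadata for the table.
#' @return A `clonotype_table`.
#' @export
collapse_clonotypes <- function(records, sample_id = NULL, donor = NULL,
                                visit = NULL, subset = NULL) {
  if ("sample_id" %in% names(records) &&
      length(unique(records$sample_id)) > 1) {
    stop("collapse_clonotypes() expects records from a single sample",
         call. = FALSE)
  }
  tab <- records |>
    dplyr::group_by(.data$chain, .data$v_call, .data$j_call,
                    .data$junction, .data$junction_aa) |>
    dplyr::summarise(duplicate_count = dplyr::n_distinct(.data$umi),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$duplicate_count), .data$v_call,
                   .data$j_call, .data$junction)
  clonotype_table(tab, sample_id = sample_id, donor = donor, visit = visit,
                  subset = subset)
}

#' Run the full read-to-clonotype pipeline
#'
#' Demultiplexes, consensus-calls, annotates, filters, and collapses a read
#' stream into per-sample clonotype tables, keeping the per-UMI consensus
#' records (with sample metadata such as PCR amplification time) for
#' contamination analysis.
#'
#' @param reads A read tibble covering one or more samples.
#' @param barcodes Named character vector, sample id -> barcode.
#' @param meta Optional tibble of per-sample metadata joined onto the
#'   consensus records by `sample_id` (e.g. `pcr_time`, `donor`, `visit`,
#'   `subset`, `chain`).
#' @param min_reads,min_quality,max_mismatch Pipeline thresholds (see
#'   [build_consensus()] and [annotate_consensus()]).
#' @param reference V/J reference.
#' @return A list with `records` (all samples' annotated functional
#'   consensus records), `tables` (named list of `clonotype_table`), and
#'   `stats` (per-sample read/UMI accounting).
#' @export
preprocess_reads <- function(reads, barcodes, meta = NULL, min_reads = 3L,
                             min_quality = 10, max_mismatch = 2L,
                             reference = tcr_reference()) {
  streams <- demultiplex(reads, barcodes)
  bl <- nchar(barcodes[[1]])
  samples <- setdiff(names(streams), "undetermined")
  records <- list()
  stats <- list()
  for (s in samples) {
    cons <- build_consensus(streams[[s]], barcode_length = bl,
                            min_reads = min_reads, min_quality = min_quality)
    ann <- annotate_consensus(cons, reference = reference,
                              max_mismatch = max_mismatch)
    fun <- filter_functional(ann, min_reads = min_reads)
    if (nrow(fun) > 0) {
      fun$sample_id <- s
    }
    records[[s]] <- fun
    stats[[s]] <- tibble::tibble(
      sample_id = s, n_reads = nrow(streams[[s]]),
      n_consensus = nrow(cons), n_unannotated = attr(ann, "dropped"),
      n_functional = nrow(fun)
    )
  }
  records <- dplyr::bind_rows(records)
  if (!is.null(meta) && nrow(records) > 0) {
    records <- dplyr::left_join(records, meta, by = "sample_id")
  }
  tables <- lapply(samples, function(s) {
    recs <- records[records$sample_id == s, , drop = FALSE]
    if (nrow(recs) == 0) {
      return(NULL)
    }
    collapse_clonotypes(recs, sample_id = s)
  })
  names(tables) <- samples
  tables <- tables[!vapply(tables, is.null, logical(1))]
  list(records = records, tables = tables, stats = dplyr::bind_rows(stats))
}
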