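# Cross-sample contamination removal. A 12-bp UMI together with a TCR
# nucleotide sequence identifies one physical mRNA molecule; the chance of
# the same combination arising independently in two samples is ~1 in
# (UMI diversity x TCR diversity), so recurrence across samples marks
# carried-over material. Collisions are resolved by PCR amplification
# time: the earliest amplified record is the likely source and is kept;
# ties at the earliest time are unresolvable and all records are removed.

#' Find UMI + TCR collisions across samples
#'
#' Groups records sharing the same (UMI, TCR nucleotide key) across two or
#' more samples.
#'
#' @param records Consensus-level records across samples: columns
#'   `sample_id`, `umi`, `v_call`, `j_call`, `junction`, `pcr_time`
#'   (ordinal or sortable timestamp), plus any others.
#' @param key Clonotype key used for the collision test; nucleotide
#'   (`"nt"`) by default since contamination is physical molecules.
#' @return The colliding records, with a `collision_id` column; zero rows
#'   when there are no collisions.
#' @export
find_collisions <- function(records, key = c("nt", "aa")) {
  key <- match.arg(key)
  if (!"pcr_time" %in% names(records) || anyNA(records$pcr_time)) {
    stop("records must carry a complete 'pcr_time' column", call. = FALSE)
  }
  if (!"sample_id" %in% names(records)) {
    stop("records must carry 'sample_id'", call. = FALSE)
  }
  ckey <- paste(records$umi, clonotype_key(records, key = key), sep = "::")
  n_samples <- stats::ave(records$sample_id, ckey,
                          FUN = function(x) length(unique(x)))
  colliding <- as.integer(n_samples) > 1L
  out <- records[colliding, , drop = FALSE]
  if (nrow(out) > 0) {
    out$collision_id <- match(ckey[colliding], unique(ckey[colliding]))
  } else {
    out$collision_id <- integer(0)
  }
  out
}

#' Resolve one collision group by PCR amplification time
#'
#' Keeps only the record with the unique earliest PCR time; if several
#' records tie at the earliest time, all records in the group are removed.
#'
#' @param group Records of one collision group (same UMI + TCR across
#'   samples).
#' @return A logical vector, `TRUE` for records to keep.
#' @export
resolve_collision <- function(group) {
  t <- group$pcr_time
  r <- xtfrm(t)
  earliest <- r == min(r)
  if (sum(earliest) == 1L) earliest else rep(FALSE, length(t))
}

#' Remove contaminating records across samples
#'
#' Applies [find_collisions()] and [resolve_collision()] to a combined
#' record set. Records whose (UMI, TCR) occurs in a single sample are
#' never touched; the operation is idempotent.
#'
#' @inheritParams find_collisions
#' @return A list with `kept`, `removed`, and `report` (per-sample removed
#'   counts and the number of collision groups).
#' @export
decontaminate <- function(records, key = c("nt", "aa")) {
  key <- match.arg(key)
  collisions <- find_collisions(records, key = key)
  if (nrow(collisions) == 0) {
    return(list(kept = records,
                removed = records[0, , drop = FALSE],
                report = list(n_collision_groups = 0L,
                              removed_by_sample = integer(0))))
  }
  keep_flag <- rep(TRUE, nrow(collisions))
  for (g in unique(collisions$collision_id)) {
    idx <- which(collisions$collision_id == g)
    keep_flag[idx] <- resolve_collision(collisions[idx, , drop = FALSE])
  }
  removed <- collisions[!keep_flag, , drop = FALSE]
  rec_id <- do.call(paste, c(records[c("sample_id", "umi", "v_call",
                                       "j_call", "junction")], sep = "\r"))
  rem_id <- do.call(paste, c(removed[c("sample_id", "umi", "v_call",
                                       "j_call", "junction")], sep = "\r"))
  kept <- records[!rec_id %in% rem_id, , drop = FALSE]
  list(
    kept = kept,
    removed = removed[, setdiff(names(removed), "collision_id"), drop = FALSE],
    report = list(
      n_collision_groups = length(unique(collisions$collision_id)),
      removed_by_sample = table(removed$sample_id)
    )
  )
}

#' Probability of an independent UMI + TCR recurrence
#'
#' The chance that a specific UMI and TCR sequence combination recurs
#' independently in another sample: `1 / (umi_diversity * tcr_diversity)`.
#' With typical per-sample diversities of about 1e6 UMIs and 1e4 TCRs this
#' is below 1e-10, which justifies treating cross-sample recurrences as
#' contamination.
#'
#' @param umi_diversity,tcr_diversity Effective numbers of distinct UMIs
#'   and TCR sequences in a sample; both must be >= 1.
#' @return The collision probability.
#' @examples
#' collision_probability(1e6, 1e4)
#' @export
collision_probability <- function(umi_diversity, tcr_diversity) {
  if (any(umi_diversity < 1) || any(tcr_diversity < 1)) {
    stop("diversities must be >= 1", call. = FALSE)
  }
  1 / (umi_diversity * tcr_diversity)
}
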