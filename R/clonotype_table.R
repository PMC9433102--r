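#' Construct a clonotype table
#'
#' A clonotype table is the repertoire of one sample (one donor / visit /
#' subset / chain): one row per clonotype with its UMI count. Columns follow
#' the AIRR Rearrangement vocabulary where one exists (`v_call`, `j_call`,
#' `junction` for the CDR3 nucleotide sequence, `junction_aa`,
#' `duplicate_count` for the UMI count).
#'
#' @param data A data frame with columns `v_call`, `j_call`, `junction_aa`,
#'   `duplicate_count`, and optionally `junction` (CDR3 nucleotide sequence;
#'   required for nucleotide-keyed analyses).
#' @param sample_id,donor,visit,subset,chain Sample metadata; stored as
#'   columns (recycled across rows). Any already present in `data` are kept.
#' @return A tibble of class `clonotype_table`.
#' @examples
#' tab <- clonotype_table(
#'   data.frame(
#'     v_call = c("TRBV1", "TRBV2"), j_call = "TRBJ1",
#'     junction_aa = c("CASSF", "CATTF"), duplicate_count = c(5L, 1L)
#'   ),
#'   sample_id = "d1_v1", donor = "d1", visit = 1, subset = "CD4_naive",
#'   chain = "beta"
#' )
#' total_umi(tab)
#' @export
clonotype_table <- function(data, sample_id = NULL, donor = NULL,
                            visit = NULL, subset = NULL, chain = NULL) {
  tab <- tibble::as_tibble(data)
  meta <- list(sample_id = sample_id, donor = donor, visit = visit,
               subset = subset, chain = chain)
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]])) {
      tab[[nm]] <- meta[[nm]]
    }
  }
  validate_clonotype_table(tab)
  class(tab) <- unique(c("clonotype_table", class(tab)))
  tab
}

validate_clonotype_table <- function(tab) {
  required <- c("v_call", "j_call", "junction_aa", "duplicate_count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("clonotype table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$duplicate_count < 1)) {
    stop("all UMI counts (duplicate_count) must be >= 1", call. = FALSE)
  }
  key <- clonotype_key(tab, key = if ("junction" %in% names(tab)) "nt" else "aa")
  if (anyDuplicated(key)) {
    stop("clonotype keys must be unique within a table", call. = FALSE)
  }
  invisible(tab)
}

#' Total UMI count of a clonotype table
#'
#' @param table A `clonotype_table` (or any data frame with a
#'   `duplicate_count` column).
#' @return The sum of UMI counts.
#' @export
total_umi <- function(table) {
  sum(table$duplicate_count)
}

#' Clonotype keys
#'
#' Builds the identity key used to compare clonotypes. Diversity analyses
#' key on V + J + CDR3 amino acid sequence; overlap and contamination
#' analyses additionally include the CDR3 nucleotide sequence.
#'
#' @param table A clonotype table or compatible data frame.
#' @param key `"aa"` (V, J, CDR3 amino-acid) or `"nt"` (V, CDR3 amino-acid,
#'   CDR3 nucleotide, J).
#' @return A character vector of keys, one per row.
#' @export
clonotype_key <- function(table, key = c("aa", "nt")) {
  key <- match.arg(key)
  if (key == "aa") {
    paste(table$v_call, table$j_call, table$junction_aa, sep = "|")
  } else {
    if (!"junction" %in% names(table)) {
      stop("nucleotide key requires a 'junction' column", call. = FALSE)
    }
    paste(table$v_call, table$junction_aa, table$junction, table$j_call,
          sep = "|")
  }
}

#' Read / write AIRR-style clonotype TSV
#'
#' Plain tab-separated files with AIRR Rearrangement-style column names.
#'
#' @param path File path.
#' @return `read_airr()` returns a `clonotype_table`.
#' @export
read_airr <- function(path) {
  dat <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  clonotype_table(dat)
}

#' @rdname read_airr
#' @param table A clonotype table.
#' @export
write_airr <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
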