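#' Built-in miniature V/J reference
#'
#' The package ships a small synthetic germline reference: 20 V and 10 J
#' genes per chain (alpha and beta), each identified by a unique 20-nt tag.
#' Tags are generated deterministically and kept at pairwise Hamming
#' distance >= 6 within each chain/segment class, so tag matching with a
#' 2-mismatch tolerance is unambiguous. This stands in for a full germline
#' database: synthetic reads embed a V tag, a CDR3 junction, and a J tag,
#' and annotation recovers the gene calls by tag lookup.
#'
#' @return A tibble with columns `chain` ("alpha"/"beta"), `segment`
#'   ("V"/"J"), `gene` (e.g. "TRAV3"), and `tag` (20-nt sequence).
#' @examples
#' ref <- tcr_reference()
#' table(ref$chain, ref$segment)
#' @export
tcr_reference <- function() {
  if (!is.null(.tcrlong_cache$reference)) {
    return(.tcrlong_cache$reference)
  }
  ref <- with_seed(20220901L, build_reference())
  .tcrlong_cache$reference <- ref
  ref
}

.tcrlong_cache <- new.env(parent = emptyenv())

TAG_LENGTH <- 20L
UMI_LENGTH <- 12L

build_reference <- function(n_v = 20L, n_j = 10L, min_dist = 6L) {
  rows <- list()
  for (chain in c("alpha", "beta")) {
    prefix <- if (chain == "alpha") "TRA" else "TRB"
    for (segment in c("V", "J")) {
      n <- if (segment == "V") n_v else n_j
      tags <- spaced_tags(n, TAG_LENGTH, min_dist)
      rows[[paste(chain, segment)]] <- tibble::tibble(
        chain = chain,
        segment = segment,
        gene = paste0(prefix, segment, seq_len(n)),
        tag = tags
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Rejection-sample random tags until all pairwise Hamming distances meet
# min_dist. Tag space (4^20) dwarfs the class sizes, so this terminates
# almost immediately.
spaced_tags <- function(n, len, min_dist) {
  tags <- character(0)
  mat <- matrix(character(0), nrow = 0, ncol = len)
  while (length(tags) < n) {
    cand <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (nrow(mat) == 0 ||
        all(rowSums(mat != matrix(cand, nrow(mat), len, byrow = TRUE)) >= min_dist)) {
      mat <- rbind(mat, cand)
      tags <- c(tags, paste(cand, collapse = ""))
    }
  }
  tags
}

reference_tags <- function(reference, chain, segment) {
  sub <- reference[reference$chain == chain & reference$segment == segment, ]
  stats::setNames(sub$tag, sub$gene)
}

# Codons excluding the three stops; used for in-frame CDR3 generation.
non_stop_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

stop_codons <- function() c("TAA", "TAG", "TGA")

# Generate n random in-frame CDR3 nucleotide junctions. Lengths are drawn
# uniformly between min_codons and max_codons codons; junctions start with
# a cysteine codon (TGT) and end with a phenylalanine codon (TTT), the
# canonical CDR3 anchors. A fraction stop_fraction carry an internal stop
# codon to exercise the functional filter downstream.
random_junctions <- function(n, min_codons = 6L, max_codons = 15L,
                             stop_fraction = 0) {
  if (n == 0L) {
    return(character(0))
  }
  pool <- non_stop_codons()
  n_codons <- sample(seq(min_codons, max_codons), n, replace = TRUE)
  has_stop <- stats::runif(n) < stop_fraction
  vapply(seq_len(n), function(i) {
    k <- n_codons[i]
    inner <- sample(pool, k - 2L, replace = TRUE)
    if (has_stop[i] && k > 2L) {
      inner[sample.int(k - 2L, 1L)] <- sample(stop_codons(), 1L)
    }
    paste(c("TGT", inner, "TTT"), collapse = "")
  }, character(1))
}
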