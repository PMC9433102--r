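# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the session RNG.
#'
#' @param seed Integer seed, or NULL to leave the RNG alone.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and a stream index; keeps values
# inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483587L) + 1L
}

#' Geometric mean
#' @param x Positive numeric vector.
#' @return exp(mean(log(x))).
#' @keywords internal
#' @noRd
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    return(Inf)
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Translate nucleotide strings to amino acids; stop codons become "*".
# Sequences whose length is not a multiple of 3 yield NA.
translate_nt <- function(nt) {
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) %% 3 == 0 & nchar(nt) > 0
  if (any(ok)) {
    aa <- Biostrings::translate(
      Biostrings::DNAStringSet(nt[ok]),
      if.fuzzy.codon = "X",
      no.init.codon = TRUE
    )
    out[ok] <- as.character(aa)
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
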