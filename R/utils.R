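#' Derive a child seed from a master seed
#'
#' Deterministic stream-splitting used so that reference tables are
#' independent of chunking / worker count: every simulated row gets its own
#' seed derived from the master seed and the row's identity.
#'
#' @param master integer master seed.
#' @param ... further integer components (e.g. scenario index, row index).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  h <- 0
  for (p in parts) {
    # 32-bit mixing in double arithmetic (exact below 2^53)
    h <- (h * 1664525 + as.numeric(p) + 1013904223) %% 2147483647
  }
  as.integer(h)
}

nucleotides <- c("A", "C", "G", "T")

#' Encode a character nucleotide matrix as integers 1..4
#' @keywords internal
encode_nuc <- function(seqs) {
  m <- match(seqs, nucleotides)
  if (anyNA(m)) {
    bad <- unique(as.vector(seqs)[is.na(m)])
    abort(paste0("non-ACGT state(s) in alignment: ", paste(bad, collapse = ", ")))
  }
  matrix(m, nrow = nrow(seqs), dimnames = dimnames(seqs))
}

#' @keywords internal
decode_nuc <- function(int_mat) {
  matrix(nucleotides[int_mat], nrow = nrow(int_mat), dimnames = dimnames(int_mat))
}

round_half_up <- function(x) floor(x + 0.5)
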