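## Small shared helpers.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Derive a stream-specific seed from a base seed
#'
#' Deterministic small-integer seed for independent generator streams.
#' @param seed Base integer seed.
#' @param k Stream index.
#' @return Integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
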