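#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n rename count across
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# Strip an optional "chr" prefix so labels from mixed sources compare equal.
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Reverse complement of a DNA string (plain character in/out).
revcomp_dna <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_dna <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# RNA 5'->3' -> mRNA-sense DNA of the pairing site (reverse complement, T for U).
revcomp_rna_to_dna <- function(x) {
  dna <- chartr("Uu", "Tt", x)
  revcomp_dna(dna)
}

is_dna_string <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}
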