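#' @importFrom stats median quantile sd rnorm runif rexp rbinom p.adjust
#'   pt pchisq setNames aggregate complete.cases
#' @importFrom utils head read.delim write.table combn
NULL

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Collapse isoleucine to leucine in a peptide sequence
#'
#' Isoleucine and leucine are isobaric and cannot be distinguished by
#' conventional mass spectrometry, so peptide comparisons throughout the
#' package are performed on I/L-collapsed sequences. Every `I` is replaced
#' by `L`; the operation is idempotent.
#'
#' @param peptide Character vector of amino-acid sequences (20-letter
#'   alphabet, optionally containing `*`).
#' @return Character vector of the same length with all `I` replaced by `L`.
#' @examples
#' collapse_il("PEPTIDE")
#' @export
collapse_il <- function(peptide) {
  if (!is.character(peptide)) stop("peptide must be character")
  bad <- grepl(sprintf("[^%s*]", paste(AA_ALPHABET20, collapse = "")), peptide)
  if (any(bad)) {
    stop("non-amino-acid character in peptide(s): ",
         paste(utils::head(peptide[bad], 3), collapse = ", "))
  }
  chartr("I", "L", peptide)
}

# Translate a DNA coding sequence to amino acids using the standard
# genetic code table shipped with Biostrings. Trailing bases that do not
# fill a codon (possible after a frameshift) are dropped. Returns the full
# translation including any '*' characters. A plain vector lookup is used
# because per-sequence S4 dispatch dominates runtime when translating many
# short variant records.
translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n, 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Translation truncated at (exclusive of) the first stop codon.
translate_to_stop <- function(dna) {
  aa <- translate_dna(dna)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) substr(aa, 1L, stop_at - 1L) else aa
}

# All 61 sense codons, used by the synthetic reference generator.
sense_codons <- function() {
  nts <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

md5_hex <- function(x) {
  vapply(x, function(s) digest::digest(s, algo = "md5", serialize = FALSE),
         character(1), USE.NAMES = FALSE)
}
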