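#' Read a protein or DNA FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write per-sample variant calls as a plain-text VCF 4.2 file
#'
#' Coordinates are transcript-relative: `CHROM` holds the transcript id and
#' `POS` is the 1-based position of the first reference base on the coding
#' sequence. The 0-based offsets used internally are converted on write.
#'
#' @param variants Data frame with columns `transcript_id`, `pos` (0-based
#'   CDS offset), `ref_allele`, `alt_allele`, and optionally `variant_id`.
#' @param path Output file.
#' @param sample_id Sample name recorded in the header.
#' @export
write_vcf <- function(variants, path, sample_id = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=proteovar;sample=%s", sample_id),
    "##INFO=<ID=FE,Number=1,Type=String,Description=\"Frame effect\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(variants) > 0) {
    ids <- if ("variant_id" %in% names(variants)) variants$variant_id else "."
    fe <- classify_frame_effect(variants$ref_allele, variants$alt_allele)
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tFE=%s",
                    variants$transcript_id, variants$pos + 1L, ids,
                    variants$ref_allele, variants$alt_allele, fe)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF of transcript-relative variant calls
#'
#' Parses with \pkg{vcfR} and returns the package's 0-based representation.
#'
#' @param path VCF file.
#' @param sample_id Sample name to attach; defaults to the file basename
#'   stripped of extension.
#' @return Data frame with columns `sample_id`, `transcript_id`, `pos`
#'   (0-based), `ref_allele`, `alt_allele`, `variant_id`.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(sample_id = character(0), transcript_id = character(0),
                      pos = integer(0), ref_allele = character(0),
                      alt_allele = character(0), variant_id = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    sample_id = sample_id,
    transcript_id = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    stringsAsFactors = FALSE
  )
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a feature-by-sample TSV matrix
#'
#' First column holds feature ids, header row holds sample ids.
#'
#' @param path TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param mat Matrix with dimnames.
#' @param feature_col Name for the id column.
#' @export
write_matrix_tsv <- function(mat, path, feature_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
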