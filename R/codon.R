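# Genetic-code helpers shared by the codon projection and piN/piS code.
# Standard nuclear code, hard-coded via Biostrings::GENETIC_CODE; codons
# containing ambiguous bases (N) are untranslatable.

NUCS <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

is_stop_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  !is.na(aa) & aa == "*"
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

translate_cds <- function(seq) {
  codons <- split_codons(seq)
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) return(NULL)  # untranslatable codon (e.g. contains N)
  paste(aa, collapse = "")
}

#' Project a protein alignment onto codon sequences
#'
#' PAL2NAL-style back-translation: each amino-acid column of the protein
#' alignment becomes one codon column; a protein gap becomes `---`. For every
#' aligned protein its CDS must translate (standard code) to exactly the
#' ungapped protein; a terminal stop codon is allowed and trimmed, internal
#' stops and ambiguous codons are errors.
#'
#' @param protein_aln protein `nlr_alignment`.
#' @param cds named character vector (or unaligned `read_fasta` result) of
#'   CDS sequences covering every alignment id.
#' @return codon `nlr_alignment` of length `3 * protein_aln$length`.
#' @export
project_protein_alignment_to_codons <- function(protein_aln, cds) {
  stopifnot(inherits(protein_aln, "nlr_alignment"))
  if (protein_aln$alphabet != "protein") stop("expected a protein alignment")
  cds <- stats::setNames(toupper(as.character(cds)), names(cds))
  missing_cds <- setdiff(protein_aln$ids, names(cds))
  if (length(missing_cds)) {
    stop("missing CDS for id(s): ", paste(missing_cds, collapse = ", "))
  }
  out <- character(length(protein_aln$ids))
  for (i in seq_along(protein_aln$ids)) {
    id <- protein_aln$ids[i]
    prot <- gsub("-", "", protein_aln$seqs[i], fixed = TRUE)
    dna <- cds[[id]]
    if (nchar(dna) %% 3L != 0L) {
      stop("CDS length of ", id, " is not a multiple of 3")
    }
    codons <- split_codons(dna)
    if (length(codons) > 1L && isTRUE(is_stop_codon(codons[length(codons)]))) {
      codons <- codons[-length(codons)]  # trim terminal stop
    }
    if (length(codons) != nchar(prot)) {
      stop("CDS of ", id, " (", length(codons), " codons) does not match protein length (",
           nchar(prot), ")")
    }
    aa <- translate_codon(codons)
    res <- strsplit(prot, "", fixed = TRUE)[[1]]
    bad <- which(is.na(aa) | aa != res)
    if (length(bad)) {
      stop("translation mismatch for ", id, " at residue ", bad[1],
           " (codon ", codons[bad[1]], " vs residue ", res[bad[1]], ")")
    }
    cols <- strsplit(protein_aln$seqs[i], "", fixed = TRUE)[[1]]
    codon_cols <- character(length(cols))
    codon_cols[cols == "-"] <- "---"
    codon_cols[cols != "-"] <- codons
    out[i] <- paste(codon_cols, collapse = "")
  }
  new_alignment(protein_aln$ids, out, alphabet = "codon")
}
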