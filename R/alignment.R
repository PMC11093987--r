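#' Multiple sequence alignment container
#'
#' Light S3 container for a gapped alignment: parallel vectors of sequence
#' identifiers and equal-length sequence strings, plus an alphabet tag.
#' Codon alignments must have length divisible by 3; the gap character is "-".
#'
#' @param ids character vector of unique, non-empty identifiers.
#' @param seqs character vector of sequences (same length as `ids`).
#' @param alphabet one of "protein", "nucleotide", "codon".
#' @return An object of class `nlr_alignment` with elements `ids`, `seqs`,
#'   `alphabet`, `length` (columns).
#' @export
new_alignment <- function(ids, seqs, alphabet = c("protein", "nucleotide", "codon")) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs must have equal length")
  if (length(ids) == 0L) stop("alignment must contain at least one sequence")
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")
  len <- unique(nchar(seqs))
  if (length(len) != 1L) {
    stop("alignment rows have unequal lengths: ", paste(sort(len), collapse = ", "))
  }
  if (alphabet == "codon" && len %% 3L != 0L) {
    stop("codon alignment length (", len, ") is not a multiple of 3")
  }
  structure(list(ids = ids, seqs = seqs, alphabet = alphabet, length = len),
            class = "nlr_alignment")
}

#' @export
print.nlr_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment: %d sequences x %d columns>\n",
              x$alphabet, length(x$ids), x$length))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln an `nlr_alignment`.
#' @return integer count of rows.
#' @export
aln_n <- function(aln) length(aln$ids)

#' Alignment as a character matrix
#'
#' @param aln an `nlr_alignment`.
#' @return character matrix, one row per sequence (rownames = ids), one
#'   column per alignment column.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

# detect alphabet from observed letters; N is ambiguous in both alphabets but
# sequences made only of ACGTN- are treated as nucleotide
detect_alphabet <- function(seqs) {
  chars <- unique(unlist(strsplit(toupper(seqs), "", fixed = TRUE)))
  chars <- setdiff(chars, "-")
  if (length(chars) && all(chars %in% c("A", "C", "G", "T", "N"))) "nucleotide" else "protein"
}

#' Read FASTA sequences
#'
#' Reads FASTA via Biostrings. With `aligned = TRUE` all records must have
#' equal length and an alignment object is returned; otherwise a named
#' character vector of (possibly ragged) sequences is returned. Identifiers
#' are the header up to the first whitespace and must be unique.
#'
#' @param path FASTA file.
#' @param aligned logical; interpret the file as an alignment (default TRUE).
#' @param alphabet force an alphabet; default auto-detects.
#' @return `nlr_alignment` (aligned) or named character vector.
#' @export
read_fasta <- function(path, aligned = TRUE, alphabet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (!aligned) return(seqs)
  if (is.null(alphabet)) alphabet <- detect_alphabet(seqs)
  new_alignment(ids, seqs, alphabet)
}

#' Write FASTA
#'
#' Writes records as 60-column wrapped FASTA. Accepts an alignment or a named
#' character vector; an empty vector yields an empty file.
#'
#' @param x `nlr_alignment` or named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "nlr_alignment")) {
    seqs <- x$seqs
    names(seqs) <- x$ids
  } else {
    seqs <- as.character(x)
    if (length(seqs) && (is.null(names(x)) || any(!nzchar(names(x))))) {
      stop("sequences must be named")
    }
    names(seqs) <- names(x)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
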