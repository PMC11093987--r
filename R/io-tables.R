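#' Read gene / transposable-element annotations
#'
#' Two dialects are supported: `"gff3"` (via rtracklayer; rows of type
#' `gene` or `transposable_element` are kept, 1-based inclusive coordinates
#' passed through) and `"tair_te_table"`, the tab-delimited TAIR-style TE
#' table with columns name, orientation, start, end, family, superfamily.
#' In the TE table, rows with start > end have their coordinates swapped and
#' strand set to "-" (with a warning); orientation `true`/`false` maps to
#' `+`/`-`; the chromosome is derived from the AT<chrom>TE<number> name.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"tair_te_table"`.
#' @return An `annotation_set`: data.frame with columns `chrom`, `start`,
#'   `end`, `strand`, `kind`, `id`.
#' @export
read_annotations <- function(path, dialect = c("gff3", "tair_te_table")) {
  if (!is.character(dialect) || !all(dialect %in% c("gff3", "tair_te_table"))) {
    stop("unknown annotation dialect: ", paste(dialect, collapse = ", "))
  }
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% c("gene", "transposable_element")
    gr <- gr[keep]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene rows must carry an ID attribute")
    ann <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      kind = ifelse(as.character(gr$type) == "gene", "gene", "transposable_element"),
      id = ids,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("TE table needs name/orientation/start/end columns")
    names(tab)[1:4] <- c("name", "orientation", "start", "end")
    start <- suppressWarnings(as.numeric(tab$start))
    end <- suppressWarnings(as.numeric(tab$end))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) {
      stop("malformed TE table row at line ", bad[1] + 1L, " of ", path)
    }
    strand <- ifelse(tolower(tab$orientation) %in% c("true", "+", "1"), "+", "-")
    swapped <- start > end
    if (any(swapped)) {
      warning(sum(swapped), " TE row(s) with start > end: coordinates swapped, strand set '-'")
      tmp <- start[swapped]
      start[swapped] <- end[swapped]
      end[swapped] <- tmp
      strand[swapped] <- "-"
    }
    chrom <- sub("^AT([0-9CM])TE.*$", "Chr\\1", tab$name)
    ann <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                      kind = "transposable_element", id = tab$name,
                      stringsAsFactors = FALSE)
  }
  validate_annotation_set(ann)
}

validate_annotation_set <- function(ann) {
  stopifnot(all(c("chrom", "start", "end", "strand", "kind", "id") %in% names(ann)))
  if (any(ann$start > ann$end)) stop("annotation with start > end")
  if (any(ann$start < 1)) stop("annotation coordinates must be positive")
  for (k in unique(ann$kind)) {
    ids <- ann$id[ann$kind == k]
    dup <- ids[duplicated(ids)]
    if (length(dup)) stop("duplicate ", k, " id(s): ", paste(unique(dup), collapse = ", "))
  }
  class(ann) <- c("annotation_set", "data.frame")
  ann
}

#' Build an annotation set from vectors
#'
#' @param chrom,start,end,strand,kind,id feature fields (1-based inclusive
#'   coordinates; strand in `+`, `-`, `.`).
#' @return An `annotation_set` data.frame.
#' @export
annotation_set <- function(chrom, start, end, id, kind = "gene", strand = ".") {
  validate_annotation_set(data.frame(
    chrom = as.character(chrom), start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, length(chrom)), kind = rep_len(kind, length(chrom)),
    id = as.character(id), stringsAsFactors = FALSE))
}

as_granges <- function(ann) {
  GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end),
                         strand = sub("\\.", "*", ann$strand), id = ann$id)
}

#' Read per-cytosine methylation calls
#'
#' Tab-separated table with header columns `chrom`, `pos`, `strand`,
#' `context` (CG/CHG/CHH), `count_methylated`, `count_total`. No coverage
#' filter is applied at read time.
#'
#' @param path TSV file.
#' @return data.frame of class `methylation_calls`.
#' @export
read_methylation_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  need <- c("chrom", "pos", "strand", "context", "count_methylated", "count_total")
  if (!all(need %in% names(tab))) {
    stop("methylation table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[need]
  if (any(tab$count_methylated < 0) || any(tab$count_total < 0)) {
    stop("negative read counts in methylation table")
  }
  if (any(tab$count_methylated > tab$count_total)) {
    stop("count_methylated exceeds count_total at row ",
         which(tab$count_methylated > tab$count_total)[1])
  }
  if (!all(tab$context %in% c("CG", "CHG", "CHH"))) {
    stop("context must be one of CG, CHG, CHH")
  }
  message(nrow(tab), " methylation call rows read")
  class(tab) <- c("methylation_calls", "data.frame")
  tab
}

#' Read a gene-level count matrix
#'
#' TSV with header: `gene_id`, optionally `length` (bp), then one column per
#' sample. Gene lengths may instead be supplied via `lengths` (named vector).
#'
#' @param path TSV file.
#' @param lengths optional named numeric vector of gene lengths (bp).
#' @return list of class `count_matrix`: `counts` (genes x samples integer
#'   matrix), `lengths` (bp, named), `samples`.
#' @export
read_counts <- function(path, lengths = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("count table must have a gene_id column")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene ids in count table")
  if ("length" %in% names(tab)) {
    lens <- stats::setNames(as.numeric(tab$length), tab$gene_id)
  } else if (!is.null(lengths)) {
    if (!all(tab$gene_id %in% names(lengths))) stop("lengths missing for some genes")
    lens <- lengths[tab$gene_id]
  } else {
    stop("no length column in count table and no lengths supplied")
  }
  samp <- setdiff(names(tab), c("gene_id", "length"))
  if (!length(samp)) stop("count table has no sample columns")
  cnt <- as.matrix(tab[samp])
  rownames(cnt) <- tab$gene_id
  storage.mode(cnt) <- "numeric"
  if (any(cnt < 0, na.rm = TRUE)) stop("negative counts in count table")
  count_matrix(cnt, lens)
}

#' Construct a count matrix container
#' @param counts genes x samples non-negative matrix with rownames.
#' @param lengths gene lengths in bp, named or in row order.
#' @return list of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(names(lengths))) names(lengths) <- rownames(counts)
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) stop("every gene needs a positive length")
  structure(list(counts = counts, lengths = lengths, samples = colnames(counts)),
            class = "count_matrix")
}

#' Read biallelic SNP haplotypes from a VCF region
#'
#' Retains biallelic SNPs in `[start, end]` on `chrom`; sites that are not
#' biallelic SNPs, or that have any missing genotype among the retained
#' samples, are dropped and counted. Diploid genotypes (phased or unphased)
#' expand to two haplotypes per sample; heterozygous sites are retained
#' as-is and their count reported.
#'
#' @param path VCF file (plain or gzipped), GT field required.
#' @param chrom chromosome name; must exist in the file.
#' @param start,end 1-based inclusive region bounds.
#' @param samples optional character vector restricting the accession set.
#' @return list of class `haplotype_matrix`: `mat` (haplotypes x sites 0/1),
#'   `positions`, `sample_ids`, and counters `n_records`, `n_dropped_nonbiallelic`,
#'   `n_dropped_missing`, `n_het_sites`.
#' @export
read_vcf_region <- function(path, chrom, start, end, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L || !chrom %in% fix[, "CHROM"]) {
    stop("chromosome not present in VCF: ", chrom)
  }
  pos <- as.numeric(fix[, "POS"])
  in_region <- fix[, "CHROM"] == chrom & pos >= start & pos <= end
  n_records <- sum(in_region)
  gt <- v@gt[in_region, -1, drop = FALSE]
  fix <- fix[in_region, , drop = FALSE]
  pos <- pos[in_region]
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s)) stop("samples absent from VCF: ", paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  snp <- fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_nonbi <- sum(!snp)
  gt <- gt[snp, , drop = FALSE]
  pos <- pos[snp]
  # strip any trailing FORMAT fields, keep GT
  gt[] <- sub(":.*$", "", gt)
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^[^/|]*[/|]", "", gt)
  haploid <- !grepl("[/|]", gt)
  a2[haploid] <- a1[haploid]
  miss <- a1 == "." | a2 == "." | is.na(gt)
  drop_missing <- if (nrow(gt)) apply(miss, 1, any) else logical(0)
  n_missing <- sum(drop_missing)
  keep <- !drop_missing
  a1 <- a1[keep, , drop = FALSE]
  a2 <- a2[keep, , drop = FALSE]
  pos <- pos[keep]
  n_het <- if (nrow(a1)) sum(apply(a1 != a2, 1, any)) else 0L
  nsamp <- ncol(gt)
  mat <- matrix(0L, nrow = 2L * nsamp, ncol = length(pos))
  if (length(pos)) {
    m1 <- matrix(as.integer(a1), nrow = nrow(a1))
    m2 <- matrix(as.integer(a2), nrow = nrow(a2))
    if (any(c(m1, m2) > 1L)) stop("non-biallelic genotype index encountered")
    mat[seq_len(nsamp) * 2L - 1L, ] <- t(m1)
    mat[seq_len(nsamp) * 2L, ] <- t(m2)
  }
  hap_ids <- if (nsamp) paste(rep(colnames(gt), each = 2L), c("1", "2"), sep = "_")
             else character(0)
  rownames(mat) <- hap_ids
  structure(list(mat = mat, positions = pos, sample_ids = hap_ids,
                 n_records = n_records, n_dropped_nonbiallelic = n_nonbi,
                 n_dropped_missing = n_missing, n_het_sites = n_het),
            class = "haplotype_matrix")
}
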