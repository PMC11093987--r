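#' Shannon entropy of one alignment column
#'
#' Plug-in (maximum-likelihood) Shannon entropy in bits,
#' H = -sum_a p_a log2 p_a with p_a = count_a / sum(counts). Gap and
#' ambiguous-residue counts must already be excluded by the caller.
#'
#' @param counts named numeric vector of residue counts (at least one > 0).
#' @return entropy in bits.
#' @export
column_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-gap column: entropy undefined")
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Per-position entropy profile in focal-sequence coordinates
#'
#' Scores only alignment columns where the focal (reference-accession)
#' sequence is non-gap; position k of the profile is the k-th non-gap focal
#' residue. Gaps and ambiguous residues (`X`) are excluded from the column
#' counts; columns with fewer than 2 informative residues get entropy 0 and
#' are flagged `low_support`.
#'
#' @param aln protein `nlr_alignment`.
#' @param focal_id id of the focal sequence (must be present, not all-gap).
#' @param gene_id optional gene label (defaults to `focal_id`).
#' @return data.frame of class `entropy_profile` with columns `position`
#'   (1-based focal residue index), `entropy` (bits), `n_effective`,
#'   `low_support`; attributes `gene_id` and `focal_id`.
#' @export
entropy_profile <- function(aln, focal_id, gene_id = focal_id) {
  stopifnot(inherits(aln, "nlr_alignment"))
  if (!focal_id %in% aln$ids) stop("focal id not in alignment: ", focal_id)
  m <- aln_matrix(aln)
  focal <- m[focal_id, ]
  keep <- which(focal != "-")
  if (!length(keep)) stop("focal sequence is all gaps: ", focal_id)
  ent <- numeric(length(keep))
  neff <- integer(length(keep))
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    col <- col[col != "-" & col != "X"]
    neff[k] <- length(col)
    ent[k] <- if (length(col) < 2L) 0 else column_entropy(table(col))
  }
  out <- data.frame(position = seq_along(keep), entropy = ent,
                    n_effective = neff, low_support = neff < 2L)
  attr(out, "gene_id") <- gene_id
  attr(out, "focal_id") <- focal_id
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Classify a gene as hvNLR or non-hvNLR
#'
#' A gene is highly variable (hv) when at least `min_positions` focal
#' positions have entropy strictly greater than `threshold` bits.
#'
#' @param profile an `entropy_profile`.
#' @param threshold entropy cutoff in bits (default 1.5).
#' @param min_positions minimum count of high-entropy positions (default 10).
#' @return one-row data.frame: `gene_id`, `focal_id`, `n_high`, `threshold`,
#'   `min_positions`, `mean_entropy`, `label` ("hv" or "non-hv").
#' @export
classify_hv <- function(profile, threshold = 1.5, min_positions = 10L) {
  stopifnot(inherits(profile, "entropy_profile"))
  n_high <- sum(profile$entropy > threshold)
  data.frame(
    gene_id = attr(profile, "gene_id"), focal_id = attr(profile, "focal_id"),
    n_high = n_high, threshold = threshold, min_positions = min_positions,
    mean_entropy = mean(profile$entropy),
    label = if (n_high >= min_positions) "hv" else "non-hv",
    stringsAsFactors = FALSE
  )
}

#' Mean entropy per gene
#'
#' Unweighted mean over focal positions, one row per gene.
#'
#' @param profiles list of `entropy_profile` objects.
#' @return data.frame `gene_id`, `mean_entropy`.
#' @export
mean_entropy_per_gene <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  ids <- vapply(profiles, function(p) attr(p, "gene_id"), character(1))
  if (anyDuplicated(ids)) stop("duplicate gene_id in profiles: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(gene_id = ids,
             mean_entropy = vapply(profiles, function(p) mean(p$entropy), numeric(1)),
             stringsAsFactors = FALSE)
}
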