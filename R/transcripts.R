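#' Transcript model tables
#'
#' utrkit represents transcript models as a tibble with one row per
#' transcript ("tx table"). All genomic coordinates are 0-based
#' half-open; GTF input/output converts at the boundary. Columns:
#'
#' * `transcript_id`, `gene_id`, `chrom` — character identifiers.
#' * `strand` — `"+"` or `"-"`.
#' * `exons` — list column; each element a data frame with integer
#'   columns `start`, `end` (0-based half-open), non-overlapping and in
#'   ascending genomic order.
#' * `cds_start`, `cds_end` — 0-based half-open genomic span of the
#'   coding region including the stop codon (`NA` for non-coding).
#' * `tags` — list column of character vectors (e.g. `"mRNA_end_NF"`).
#' * `source` — provenance of the model: `"gencode"` for annotated
#'   transcripts, `"upstream"`/`"downstream"` for isoforms created at
#'   atlas cleavage sites.
#' * `is_ipa` — logical; `TRUE` when the 3' end lies in an annotated
#'   intron of the gene (intronic polyadenylation).
#'
#' @param transcript_id,gene_id,chrom Character vectors.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param exons List of data frames with `start`/`end` columns.
#' @param cds_start,cds_end Optional CDS span per transcript.
#' @param tags Optional list of character vectors.
#' @param source Provenance label, recycled.
#' @param is_ipa Logical, recycled.
#' @return A validated tx table (tibble).
#' @examples
#' tx_table("T1", "G1", "chr1", "+", list(data.frame(start = 100, end = 300)))
#' @export
tx_table <- function(transcript_id, gene_id, chrom, strand, exons,
                     cds_start = NA_integer_, cds_end = NA_integer_,
                     tags = NULL, source = "gencode", is_ipa = FALSE) {
  n <- length(transcript_id)
  if (is.null(tags)) tags <- rep(list(character()), n)
  tx <- tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    exons = lapply(exons, normalize_exons),
    cds_start = as.integer(rep_len(cds_start, n)),
    cds_end = as.integer(rep_len(cds_end, n)),
    tags = tags,
    source = rep_len(as.character(source), n),
    is_ipa = rep_len(as.logical(is_ipa), n)
  )
  validate_tx_table(tx)
}

normalize_exons <- function(ex) {
  ex <- as.data.frame(ex)[, c("start", "end")]
  ex$start <- as.integer(ex$start)
  ex$end <- as.integer(ex$end)
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

validate_tx_table <- function(tx) {
  stopifnot(all(tx$strand %in% c("+", "-")))
  bad <- vapply(tx$exons, function(ex) {
    nrow(ex) == 0 || any(ex$end <= ex$start) ||
      (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
  }, logical(1))
  if (any(bad)) {
    stop("invalid exon structure for transcript(s): ",
         paste(tx$transcript_id[bad], collapse = ", "))
  }
  tx
}

#' Transcript geometry helpers
#'
#' `tx_three_prime_end()` returns the 0-based genomic coordinate of the
#' last transcribed nucleotide (the cleavage-site position under the
#' package's convention): the last base of the last exon on `+`, the
#' first base of the first exon on `-`. `tx_five_prime_end()` is the
#' symmetric 5' coordinate and `tx_spliced_length()` the summed exon
#' length.
#'
#' @param tx A tx table.
#' @return An integer vector, one value per transcript.
#' @examples
#' tx <- tx_table("T1", "G1", "chr1", "+",
#'                list(data.frame(start = c(100, 400), end = c(300, 600))))
#' tx_three_prime_end(tx)  # 599
#' tx_spliced_length(tx)   # 400
#' @export
tx_three_prime_end <- function(tx) {
  mapply(function(ex, s) {
    if (s == "+") as.integer(ex$end[nrow(ex)] - 1L) else as.integer(ex$start[1])
  }, tx$exons, tx$strand)
}

#' @rdname tx_three_prime_end
#' @export
tx_five_prime_end <- function(tx) {
  mapply(function(ex, s) {
    if (s == "+") as.integer(ex$start[1]) else as.integer(ex$end[nrow(ex)] - 1L)
  }, tx$exons, tx$strand)
}

#' @rdname tx_three_prime_end
#' @export
tx_spliced_length <- function(tx) {
  vapply(tx$exons, function(ex) sum(ex$end - ex$start), numeric(1))
}

# Keep the 3'-most `length` spliced nucleotides of an exon structure.
# Walks exons from the 3' end accumulating spliced length; the 3' end
# itself is always preserved exactly.
truncate_exons <- function(ex, strand, length) {
  widths <- ex$end - ex$start
  total <- sum(widths)
  if (total <= length) return(ex)
  if (strand == "+") {
    cum <- rev(cumsum(rev(widths)))          # spliced nt from exon i to 3' end
    keep <- which(cum - widths < length)     # exon not fully beyond the cut
    out <- ex[keep, , drop = FALSE]
    excess <- cum[keep[1]] - length
    out$start[1] <- out$start[1] + excess
  } else {
    cum <- cumsum(widths)                    # spliced nt from 3' end (leftmost)
    keep <- which(cum - widths < length)
    out <- ex[keep, , drop = FALSE]
    excess <- cum[keep[length(keep)]] - length
    out$end[nrow(out)] <- out$end[nrow(out)] - excess
  }
  rownames(out) <- NULL
  out
}

# Cut an exon structure so transcription ends at genomic position `pos`
# (0-based, inclusive; strand-aware). Returns NULL if pos lies outside
# the exonic span in the 3' direction.
clip_exons_at <- function(ex, strand, pos) {
  if (strand == "+") {
    keep <- ex$start <= pos
    if (!any(keep)) return(NULL)
    out <- ex[keep, , drop = FALSE]
    out$end[nrow(out)] <- min(out$end[nrow(out)], pos + 1L)
  } else {
    keep <- ex$end > pos
    if (!any(keep)) return(NULL)
    out <- ex[keep, , drop = FALSE]
    out$start[1] <- max(out$start[1], pos)
  }
  rownames(out) <- NULL
  out
}

# Introns of an exon structure as a data frame of 0-based half-open
# intervals (empty for single-exon models).
exon_gaps <- function(ex) {
  if (nrow(ex) < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}
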