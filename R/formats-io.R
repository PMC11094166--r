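#' Read a GTF transcript annotation into a tx table
#'
#' Imports a GENCODE-dialect GTF and returns one row per transcript with
#' exon structures converted from the GTF's 1-based closed coordinates
#' to the package-internal 0-based half-open convention. The CDS span
#' (including the stop codon, when annotated) is recorded per
#' transcript. Because GENCODE repeats the `tag` attribute and generic
#' importers keep only one value, all `tag "..."` occurrences are
#' collected per transcript.
#'
#' @param path Path to a GTF file (may be gzipped).
#' @param exclude_tags Transcripts carrying any of these tags are
#'   dropped (default `"mRNA_end_NF"`, i.e. unvalidated 3' ends are
#'   excluded).
#' @param biotypes If non-`NULL`, keep only transcripts whose
#'   `transcript_type`/`transcript_biotype` is in this set (e.g.
#'   `"protein_coding"`).
#' @return A tx table (see [tx_table()]). Transcript records without
#'   exons are dropped with a warning.
#' @export
read_transcript_annotation <- function(path, exclude_tags = "mRNA_end_NF",
                                       biotypes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id)) stop("GTF has no transcript_id attribute")
  ex <- gr[mc$type == "exon" & !is.na(mc$transcript_id)]
  if (length(ex) == 0) stop("GTF contains no exon features")

  # collect repeated tag attributes per transcript from the raw lines
  tag_map <- collect_gtf_tags(path)

  exdf <- tibble(
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    gene_id = S4Vectors::mcols(ex)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex)
  )
  if (!is.null(biotypes)) {
    bt <- mc$transcript_type
    if (is.null(bt)) bt <- mc$transcript_biotype
    keep_tx <- unique(mc$transcript_id[!is.na(mc$transcript_id) &
                                         !is.na(bt) & bt %in% biotypes])
    exdf <- exdf[exdf$transcript_id %in% keep_tx, ]
  }

  cds <- gr[mc$type %in% c("CDS", "stop_codon") & !is.na(mc$transcript_id)]
  cds_span <- if (length(cds) > 0) {
    tibble(transcript_id = S4Vectors::mcols(cds)$transcript_id,
           s = GenomicRanges::start(cds) - 1L,
           e = GenomicRanges::end(cds)) |>
      group_by(.data$transcript_id) |>
      summarise(cds_start = min(.data$s), cds_end = max(.data$e))
  } else {
    tibble(transcript_id = character(), cds_start = integer(),
           cds_end = integer())
  }

  nested <- exdf |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(exons = list(normalize_exons(
      data.frame(start = .data$start, end = .data$end))), .groups = "drop") |>
    left_join(cds_span, by = "transcript_id")

  nested$tags <- unname(lapply(nested$transcript_id, function(id) {
    t <- tag_map[[id]]
    if (is.null(t)) character() else t
  }))
  if (length(exclude_tags) > 0) {
    drop <- vapply(nested$tags, function(t) any(t %in% exclude_tags),
                   logical(1))
    nested <- nested[!drop, ]
  }
  tx_table(nested$transcript_id, nested$gene_id, nested$chrom, nested$strand,
           nested$exons, cds_start = nested$cds_start,
           cds_end = nested$cds_end, tags = nested$tags)
}

# GENCODE repeats `tag "x"; tag "y";`; pull every occurrence per
# transcript id from the attribute column.
collect_gtf_tags <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  attrs <- vapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) >= 9) f[9] else ""
  }, character(1))
  ids <- sub('.*transcript_id "([^"]+)".*', "\\1", attrs)
  ids[!grepl('transcript_id "', attrs, fixed = TRUE)] <- NA
  tags <- lapply(regmatches(attrs, gregexpr('tag "[^"]+"', attrs)), function(m) {
    unique(sub('tag "([^"]+)"', "\\1", m))
  })
  keep <- !is.na(ids)
  out <- tapply(tags[keep], ids[keep],
                function(l) sort(unique(unlist(l))), simplify = FALSE)
  # split any comma-joined tags written by write_utrome_annotation
  lapply(out, function(t) unique(unlist(strsplit(t, ",", fixed = TRUE))))
}

#' Write a tx table as GTF (and optionally spliced FASTA)
#'
#' Emits one `transcript` feature plus its `exon` features per row,
#' converting internal 0-based half-open coordinates back to the GTF's
#' 1-based closed convention. When `genome` and `fasta_path` are given,
#' spliced, strand-oriented (reverse-complemented on `-`) sequences are
#' written with identifiers matching the GTF 1:1.
#'
#' @param tx A tx table.
#' @param gtf_path Output GTF path.
#' @param genome A named [Biostrings::DNAStringSet] (or path to a FASTA
#'   file) covering every chromosome referenced.
#' @param fasta_path Output FASTA path (requires `genome`).
#' @return `gtf_path`, invisibly.
#' @export
write_utrome_annotation <- function(tx, gtf_path, genome = NULL,
                                    fasta_path = NULL) {
  fmt_attr <- function(i) {
    a <- sprintf('gene_id "%s"; transcript_id "%s";',
                 tx$gene_id[i], tx$transcript_id[i])
    if (length(tx$tags[[i]]) > 0) {
      a <- paste0(a, sprintf(' tag "%s";',
                             paste(tx$tags[[i]], collapse = ",")))
    }
    paste0(a, sprintf(' source_class "%s";', tx$source[i]))
  }
  lines <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]
    attr <- fmt_attr(i)
    c(sprintf("%s\tutrkit\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom[i], min(ex$start) + 1L, max(ex$end), tx$strand[i], attr),
      sprintf("%s\tutrkit\texon\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom[i], ex$start + 1L, ex$end, tx$strand[i], attr))
  }))
  writeLines(lines, gtf_path)
  if (!is.null(fasta_path)) {
    if (is.null(genome)) stop("fasta_path requires a genome")
    seqs <- tx_spliced_sequence(tx, genome)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(gtf_path)
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) return(Biostrings::DNAStringSet(genome))
  genome
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' on the `-` strand, so each returned sequence reads 5' to 3' and its
#' length equals the spliced transcript length.
#'
#' @param tx A tx table.
#' @param genome Named [Biostrings::DNAStringSet], named character
#'   vector, or FASTA path.
#' @return A `DNAStringSet` named by `transcript_id`.
#' @export
tx_spliced_sequence <- function(tx, genome) {
  genome <- as_genome(genome)
  missing <- setdiff(unique(tx$chrom), names(genome))
  if (length(missing) > 0) {
    stop("genome is missing chromosome(s): ", paste(missing, collapse = ", "))
  }
  seqs <- vapply(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]
    s <- paste(vapply(seq_len(nrow(ex)), function(j) {
      as.character(Biostrings::subseq(genome[[tx$chrom[i]]],
                                      ex$start[j] + 1L, ex$end[j]))
    }, character(1)), collapse = "")
    if (tx$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tx$transcript_id
  out
}

# Strand-oriented genomic window [start0, end0) clipped to the contig;
# used by the internal-priming filter and motif scans.
genomic_window <- function(genome, chrom, strand, start0, end0) {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome)) stop("genome is missing chromosome: ", chrom)
  len <- length(genome[[chrom]])
  s <- max(0L, start0)
  e <- min(len, end0)
  if (e <= s) return("")
  seq <- as.character(Biostrings::subseq(genome[[chrom]], s + 1L, e))
  if (strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  seq
}

#' Sparse cell-by-isoform count container
#'
#' A light S3 container for UMI counts: a sparse non-negative integer
#' matrix (cells in rows, isoforms in columns) plus a `cells` tibble
#' (`barcode`, `group`) and an `isoforms` tibble (`isoform_id`,
#' `gene_id`). `group` carries the cell-type or perturbation label used
#' by the statistics layer.
#'
#' @param counts Matrix or sparse Matrix, cells x isoforms.
#' @param cells Tibble with columns `barcode` and `group` (or a
#'   character vector of barcodes).
#' @param isoforms Tibble with columns `isoform_id` and `gene_id`.
#' @return An object of class `cell_counts`.
#' @export
cell_counts <- function(counts, cells, isoforms) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.character(cells)) cells <- tibble(barcode = cells, group = NA_character_)
  cells <- as_tibble(cells)
  isoforms <- as_tibble(isoforms)
  stopifnot(nrow(counts) == nrow(cells), ncol(counts) == nrow(isoforms))
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers")
  }
  rownames(counts) <- cells$barcode
  colnames(counts) <- isoforms$isoform_id
  structure(list(counts = counts, cells = cells, isoforms = isoforms),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d cells x %d isoforms (%d genes), %s UMIs\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$isoforms$gene_id)),
              format(sum(x$counts), big.mark = ",")))
  groups <- table(x$cells$group, useNA = "ifany")
  cat("groups:", paste(sprintf("%s=%d", names(groups), groups),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Read/write UMI counts in MTX-triplet form
#'
#' `read_umi_counts()` reads a MatrixMarket triplet file plus barcode
#' and feature TSVs (the matrix is stored isoforms x cells, the usual
#' on-disk convention, and transposed on read). If an annotation table
#' is supplied, cells without an annotation row are dropped and the
#' annotation's `group` column becomes the cell group label.
#'
#' @param mtx Path to the `.mtx` file.
#' @param barcodes Path to a headerless single-column barcode TSV.
#' @param features Path to a headerless two-column TSV
#'   (isoform id, gene id).
#' @param annotations Optional path to a TSV with header columns
#'   `barcode` and `group`.
#' @return A [cell_counts()] object.
#' @export
read_umi_counts <- function(mtx, barcodes, features, annotations = NULL) {
  m <- Matrix::readMM(mtx)
  m <- methods::as(methods::as(methods::as(m, "CsparseMatrix"),
                               "generalMatrix"), "dMatrix")
  if (any(m@x != round(m@x))) stop("MTX contains non-integer entries")
  bc <- readr::read_tsv(barcodes, col_names = "barcode",
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  ft <- readr::read_tsv(features, col_names = c("isoform_id", "gene_id"),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(m) != nrow(ft) || ncol(m) != nrow(bc)) {
    stop(sprintf("MTX dimensions %dx%d do not match %d features x %d barcodes",
                 nrow(m), ncol(m), nrow(ft), nrow(bc)))
  }
  cells <- tibble(barcode = bc$barcode, group = NA_character_)
  counts <- Matrix::t(m)
  if (!is.null(annotations)) {
    ann <- readr::read_tsv(annotations, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    keep <- cells$barcode %in% ann$barcode
    counts <- counts[keep, , drop = FALSE]
    cells <- cells[keep, ]
    cells$group <- ann$group[match(cells$barcode, ann$barcode)]
  }
  cell_counts(counts, cells, ft)
}

#' @param x A [cell_counts()] object.
#' @param dir Output directory; files `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` and `annotations.tsv` are written there.
#' @rdname read_umi_counts
#' @export
write_umi_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$cells$barcode, file.path(dir, "barcodes.tsv"))
  readr::write_tsv(x$isoforms[, c("isoform_id", "gene_id")],
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(x$cells[, c("barcode", "group")],
                   file.path(dir, "annotations.tsv"))
  invisible(dir)
}

#' Read/write the proximal-to-distal merge table
#'
#' The merge table is a 3-column TSV (`isoform_id`, `representative_id`,
#' `gene_id`) mapping each isoform to the distal representative whose
#' counts absorb it during quantification.
#'
#' @param path TSV path.
#' @return A tibble with the three columns above.
#' @export
read_merge_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' @param merge_table Tibble as returned by [build_merge_table()].
#' @rdname read_merge_table
#' @export
write_merge_table <- function(merge_table, path) {
  readr::write_tsv(merge_table[, c("isoform_id", "representative_id",
                                   "gene_id")], path)
  invisible(path)
}

#' Read strand-specific 3'-end coverage
#'
#' Coverage rows give the number of read 5' ends observed at a single
#' 0-based genomic position, per cell type — the direct product of
#' strand-specific single-nucleotide coverage of aligned 3'-end reads.
#'
#' @param path TSV with columns `chrom`, `position`, `strand`, `count`,
#'   `group` (header required).
#' @return A tibble with those columns; `position`/`count` integer.
#' @export
read_site_coverage <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", position = "i", strand = "c", count = "i", group = "c"
  ), progress = FALSE)
}
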