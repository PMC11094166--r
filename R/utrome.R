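# Truncated-UTRome construction: augment an annotation with atlas
# cleavage sites, truncate to a fixed 3' length, deduplicate near-equal
# ends, and build the proximal-to-distal merge table used at counting.

#' Augment transcript models with atlas cleavage sites
#'
#' For every retained atlas site labeled `three_prime_UTR`, a new
#' isoform truncated at the site ("upstream") is created for each
#' transcript of the gene whose 3'UTR contains the site downstream of
#' the stop codon. For every site labeled `extended_three_prime_UTR`
#' within `three_ext` nt downstream of a transcript 3' end, a new
#' isoform extending the last exon to the site ("downstream") is
#' created. Original models are retained. Sites labeled
#' `three_prime_UTR` that fall upstream of the stop codon of every
#' transcript of their gene are rejected and reported in the
#' `rejected_sites` attribute.
#'
#' @param transcripts A tx table (typically protein-coding transcripts
#'   with validated 3' ends).
#' @param atlas_sites Data frame with `chrom`, `strand`, `position`,
#'   `region_label`, `gene_id` (from [annotate_region()]).
#' @param three_ext Maximum downstream extension in nt (default 5000).
#' @return The augmented tx table; new isoform ids are
#'   `<transcript_id>.u<pos>` / `<transcript_id>.d<pos>`.
#' @export
augment_transcripts <- function(transcripts, atlas_sites, three_ext = 5000) {
  tx <- transcripts
  ends <- tx_three_prime_end(tx)
  new_rows <- list()
  rejected <- list()

  utr_sites <- atlas_sites[atlas_sites$region_label == "three_prime_UTR", ,
                           drop = FALSE]
  for (i in seq_len(nrow(utr_sites))) {
    s <- utr_sites[i, ]
    cand <- which(tx$gene_id == s$gene_id & tx$chrom == s$chrom &
                    tx$strand == s$strand & tx$source == "gencode")
    made <- FALSE
    for (j in cand) {
      ex <- tx$exons[[j]]
      exonic <- any(s$position >= ex$start & s$position < ex$end)
      if (!exonic || s$position == ends[j]) next
      post_stop <- if (is.na(tx$cds_end[j])) TRUE
        else if (tx$strand[j] == "+") s$position >= tx$cds_end[j]
        else s$position < tx$cds_start[j]
      in_3dir <- if (tx$strand[j] == "+") s$position < ends[j]
                 else s$position > ends[j]
      if (!post_stop || !in_3dir) next
      clipped <- clip_exons_at(ex, tx$strand[j], s$position)
      if (is.null(clipped)) next
      row <- tx[j, ]
      row$transcript_id <- sprintf("%s.u%d", tx$transcript_id[j], s$position)
      row$exons <- list(clipped)
      row$source <- "upstream"
      new_rows[[length(new_rows) + 1]] <- row
      made <- TRUE
    }
    if (!made) rejected[[length(rejected) + 1]] <- s
  }

  ext_sites <- atlas_sites[atlas_sites$region_label ==
                             "extended_three_prime_UTR", , drop = FALSE]
  for (i in seq_len(nrow(ext_sites))) {
    s <- ext_sites[i, ]
    cand <- which(tx$gene_id == s$gene_id & tx$chrom == s$chrom &
                    tx$strand == s$strand & tx$source == "gencode")
    for (j in cand) {
      d <- if (tx$strand[j] == "+") s$position - ends[j]
           else ends[j] - s$position
      if (d < 1 || d > three_ext) next
      ex <- tx$exons[[j]]
      if (tx$strand[j] == "+") {
        ex$end[nrow(ex)] <- s$position + 1L
      } else {
        ex$start[1] <- s$position
      }
      row <- tx[j, ]
      row$transcript_id <- sprintf("%s.d%d", tx$transcript_id[j], s$position)
      row$exons <- list(ex)
      row$source <- "downstream"
      new_rows[[length(new_rows) + 1]] <- row
    }
  }

  out <- if (length(new_rows) > 0) {
    bind_rows(tx, bind_rows(new_rows)) |> distinct(.data$transcript_id,
                                                   .keep_all = TRUE)
  } else tx
  if (length(rejected) > 0) {
    rej <- bind_rows(rejected)
    warning(nrow(rej), " three_prime_UTR site(s) matched no transcript ",
            "3'UTR downstream of a stop codon; rejected")
    attr(out, "rejected_sites") <- rej
  }
  out
}

#' Flag intronic-polyadenylation isoforms
#'
#' Marks an isoform `is_ipa` when its 3' end lies inside an intron of
#' any annotated (`source == "gencode"`) transcript model of the same
#' gene in `annotation`.
#'
#' @param tx Tx table to flag.
#' @param annotation Tx table supplying the annotated intron structures
#'   (defaults to the gencode-source rows of `tx`).
#' @return `tx` with `is_ipa` updated.
#' @export
flag_ipa_isoforms <- function(tx, annotation = NULL) {
  if (is.null(annotation)) annotation <- tx[tx$source == "gencode", ]
  ends <- tx_three_prime_end(tx)
  introns_by_gene <- split(annotation, annotation$gene_id)
  tx$is_ipa <- vapply(seq_len(nrow(tx)), function(i) {
    ann <- introns_by_gene[[tx$gene_id[i]]]
    if (is.null(ann)) return(FALSE)
    for (j in seq_len(nrow(ann))) {
      g <- exon_gaps(ann$exons[[j]])
      if (any(ends[i] >= g$start & ends[i] < g$end)) return(TRUE)
    }
    FALSE
  }, logical(1))
  tx
}

#' Truncate a transcriptome to a fixed 3' length
#'
#' Each isoform keeps its 3'-most `length` spliced nucleotides; the
#' exon structure is intersected accordingly and the 3' end is
#' preserved exactly. Transcripts already at or below `length` are
#' unchanged.
#'
#' @param tx A tx table.
#' @param length Truncation length in spliced nt (default 500).
#' @return The truncated tx table.
#' @export
truncate_transcriptome <- function(tx, length = 500) {
  tx$exons <- lapply(seq_len(nrow(tx)), function(i) {
    truncate_exons(tx$exons[[i]], tx$strand[i], length)
  })
  tx
}

# Signed coordinate increasing in the 3' direction.
three_prime_coord <- function(ends, strand) {
  ifelse(strand == "+", ends, -ends)
}

#' Deduplicate truncated isoforms with near-identical 3' ends
#'
#' Within a gene, isoforms whose 3' ends are fewer than `min_distinct`
#' nt apart (transitively chained in genomic order) collapse to one
#' representative: the most 3' member, with `downstream`-sourced
#' isoforms outranking annotation-derived ones at the same position.
#' The surviving model keeps the lexicographically smallest transcript
#' id among the collapsed set.
#'
#' @param tx A truncated tx table.
#' @param min_distinct Minimum distinct 3'-end distance in nt
#'   (default 50; exactly 50 apart is kept distinct).
#' @return The deduplicated tx table.
#' @export
deduplicate_truncated <- function(tx, min_distinct = 50) {
  keep <- lapply(split(seq_len(nrow(tx)),
                       paste(tx$gene_id, tx$chrom, tx$strand)), function(idx) {
    sub <- tx[idx, ]
    ends <- tx_three_prime_end(sub)
    d3 <- three_prime_coord(ends, sub$strand)
    o <- order(d3)
    grp <- cumsum(c(1, diff(d3[o]) >= min_distinct))
    lapply(split(o, grp), function(members) {
      # survivor: most 3' end; downstream source wins ties; then lexical id
      pr <- ifelse(sub$source[members] == "downstream", 0L, 1L)
      surv <- members[order(-d3[members], pr[members],
                            sub$transcript_id[members])][1]
      row <- sub[surv, ]
      row$transcript_id <- min(sub$transcript_id[members])
      row
    })
  })
  bind_rows(unlist(keep, recursive = FALSE)) |>
    arrange(.data$gene_id, .data$transcript_id)
}

#' Build the proximal-to-distal merge table
#'
#' Within a gene, each isoform is pointed at the most 3' isoform whose
#' 3' end lies strictly closer than `merge_distance` nt, and pointer
#' chains are resolved to a fixed point so every isoform maps directly
#' to its final distal representative (representatives map to
#' themselves). Isoform pairs this close cannot be discriminated by 3'
#' end reads, so their counts are merged onto the distal site at
#' quantification.
#'
#' @param tx A deduplicated tx table.
#' @param merge_distance Merge distance in nt (default 200; exactly 200
#'   apart is not merged).
#' @return Tibble `isoform_id`, `representative_id`, `gene_id`.
#' @export
build_merge_table <- function(tx, merge_distance = 200) {
  res <- lapply(split(seq_len(nrow(tx)),
                      paste(tx$gene_id, tx$chrom, tx$strand)), function(idx) {
    sub <- tx[idx, ]
    ends <- tx_three_prime_end(sub)
    d3 <- three_prime_coord(ends, sub$strand)
    o <- order(d3, sub$transcript_id)
    d3s <- d3[o]
    n <- length(o)
    ptr <- vapply(seq_len(n), function(i) {
      within <- which(d3s - d3s[i] >= 0 & d3s - d3s[i] < merge_distance)
      max(within)
    }, integer(1))
    # fixed-point resolution; pointers never decrease, so this terminates
    repeat {
      nxt <- ptr[ptr]
      if (identical(nxt, ptr)) break
      ptr <- nxt
    }
    tibble(isoform_id = sub$transcript_id[o],
           representative_id = sub$transcript_id[o][ptr],
           gene_id = sub$gene_id[o])
  })
  bind_rows(res) |> arrange(.data$gene_id, .data$isoform_id)
}

#' Apply a merge table to a count matrix
#'
#' Sums the counts of each isoform into its distal representative.
#' Total counts are conserved exactly.
#'
#' @param x A [cell_counts()] object.
#' @param merge_table Tibble from [build_merge_table()]; isoforms of
#'   `x` absent from the table map to themselves.
#' @return A [cell_counts()] with one column per representative.
#' @export
apply_merge_table <- function(x, merge_table) {
  rep_of <- setNames(merge_table$representative_id, merge_table$isoform_id)
  iso <- x$isoforms$isoform_id
  target <- ifelse(iso %in% names(rep_of), rep_of[iso], iso)
  reps <- unique(target)
  map <- Matrix::sparseMatrix(i = seq_along(iso),
                              j = match(target, reps),
                              x = 1, dims = c(length(iso), length(reps)))
  merged <- x$counts %*% map
  iso_tbl <- tibble(isoform_id = reps,
                    gene_id = x$isoforms$gene_id[match(reps, iso)])
  cell_counts(merged, x$cells, iso_tbl)
}
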