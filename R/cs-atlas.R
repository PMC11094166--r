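# Cleavage-site (CS) atlas construction: peak calling on 3'-end read
# coverage, cross-group harmonization, classification against an
# annotation and an external polyA-site atlas, internal-priming
# filtering, region labeling, and usage scoring.

# Iterative greedy local-mode merge: the highest-count position becomes
# the mode and absorbs every position within +/- radius; repeat on the
# remainder. Ties on count go to the leftmost (5'-most on +) position.
# Returns, for each input row, the index of the row chosen as its mode.
greedy_local_mode <- function(position, count, radius) {
  n <- length(position)
  assign <- integer(n)
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    idx <- which(remaining)
    best <- idx[order(-count[idx], position[idx])][1]
    absorbed <- idx[abs(position[idx] - position[best]) <= radius]
    assign[absorbed] <- best
    remaining[absorbed] <- FALSE
  }
  assign
}

#' Call cleavage-site peaks from single-group 3'-end coverage
#'
#' Merges single-nucleotide 3'-end coverage to local modes within a
#' fixed radius (iteratively: the highest-count position absorbs all
#' positions within the radius, then the next highest among the
#' remainder, and so on) and retains peaks exceeding a strict
#' reads-per-million threshold.
#'
#' @param coverage Data frame with columns `chrom`, `position` (0-based),
#'   `strand`, `count`; one cell type at a time.
#' @param radius Merge radius in nt (default 30).
#' @param rpm_threshold Peaks are retained iff support/library_size*1e6
#'   is strictly greater than this (default 5).
#' @param library_size Total reads for RPM normalization; defaults to
#'   the sum of `count` in `coverage` (per-group totals).
#' @return Tibble of retained peaks: `chrom`, `strand`, `position` (the
#'   local mode), `support` (summed reads), `rpm`.
#' @export
call_peaks <- function(coverage, radius = 30, rpm_threshold = 5,
                       library_size = NULL) {
  coverage <- as_tibble(coverage)
  if (nrow(coverage) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  position = integer(), support = numeric(), rpm = numeric()))
  }
  if (is.null(library_size)) library_size <- sum(coverage$count)
  if (library_size <= 0) stop("library_size must be positive")
  peaks <- coverage |>
    group_by(.data$chrom, .data$strand) |>
    group_modify(function(d, key) {
      mode <- greedy_local_mode(d$position, d$count, radius)
      tibble(position = d$position[mode], count = d$count) |>
        group_by(.data$position) |>
        summarise(support = sum(.data$count), .groups = "drop")
    }) |>
    ungroup() |>
    mutate(rpm = .data$support / library_size * 1e6) |>
    filter(.data$rpm > rpm_threshold) |>
    arrange(.data$chrom, .data$strand, .data$position)
  peaks
}

#' Harmonize per-group peaks into pooled cleavage-site candidates
#'
#' Sums peak support across cell types at identical positions, then
#' applies a final local-mode merge pass so minor positional variation
#' between cell types collapses to a single candidate site. Tracks how
#' many groups contributed reads to each harmonized site.
#'
#' @param per_group_peaks Data frame of [call_peaks()] outputs stacked
#'   with a `group` column.
#' @param radius Merge radius in nt (default 30).
#' @return Tibble: `chrom`, `strand`, `position`, `support` (reads
#'   summed over groups), `n_celltypes_used`.
#' @export
harmonize_peaks <- function(per_group_peaks, radius = 30) {
  pk <- as_tibble(per_group_peaks)
  if (nrow(pk) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  position = integer(), support = numeric(),
                  n_celltypes_used = integer()))
  }
  pk |>
    group_by(.data$chrom, .data$strand) |>
    group_modify(function(d, key) {
      summed <- d |>
        group_by(.data$position) |>
        summarise(support = sum(.data$support),
                  groups = list(unique(.data$group)), .groups = "drop")
      mode <- greedy_local_mode(summed$position, summed$support, radius)
      tibble(final = summed$position[mode], support = summed$support,
             groups = summed$groups) |>
        group_by(position = .data$final) |>
        summarise(support = sum(.data$support),
                  n_celltypes_used = length(unique(unlist(.data$groups))),
                  .groups = "drop")
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$strand, .data$position)
}

#' Internal-priming filter
#'
#' Oligo(dT) priming at genomic A-rich stretches produces spurious 3'
#' ends. A candidate site fails when its downstream genomic context
#' (strand-aware, the `window_down` nt immediately 3' of the site) is
#' A-rich: A-fraction at least `a_frac` or any run of `a_run` or more
#' consecutive A. Windows extending past the contig end are truncated.
#'
#' @param sites Data frame with `chrom`, `strand`, `position`.
#' @param genome Named `DNAStringSet`/character vector or FASTA path.
#' @param window_down Downstream window size in nt (default 20).
#' @param a_frac A-fraction threshold (default 0.65, inclusive fail).
#' @param a_run Consecutive-A run-length threshold (default 8).
#' @return Logical vector: `TRUE` where the site passes (is kept).
#' @export
internal_priming_filter <- function(sites, genome, window_down = 20,
                                    a_frac = 0.65, a_run = 8) {
  genome <- as_genome(genome)
  vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$position[i]
    seq <- if (sites$strand[i] == "+") {
      genomic_window(genome, sites$chrom[i], "+", p + 1L, p + 1L + window_down)
    } else {
      genomic_window(genome, sites$chrom[i], "-", p - window_down, p)
    }
    if (nchar(seq) == 0) return(TRUE)
    chars <- strsplit(seq, "")[[1]]
    frac_a <- mean(chars == "A")
    runs <- rle(chars == "A")
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
    !(frac_a >= a_frac || max_run >= a_run)
  }, logical(1))
}

#' Classify cleavage-site candidates
#'
#' Applies the three-tier classification: a candidate within
#' `window/2` nt of an annotated transcript 3' end (same strand) is
#' `validated`; otherwise, within `window/2` nt of an external
#' polyA-site cluster center with TPM at or above `cluster_tpm_min` is
#' `supported`; otherwise, a candidate passing the internal-priming
#' filter is `likely`; everything else is `discarded`. The retained
#' atlas is the union of `supported` and `likely` sites (validated
#' sites already have annotated ends and are tracked separately).
#'
#' @param candidates Tibble from [harmonize_peaks()].
#' @param gencode_ends Data frame `chrom`, `strand`, `position` of
#'   annotated 3' ends (transcripts with unvalidated ends excluded).
#' @param external_clusters Data frame `chrom`, `strand`, `position`,
#'   `tpm` of external atlas cluster centers.
#' @param genome Genome for the internal-priming check.
#' @param window Total window size centered on 3' ends / cluster
#'   centers (default 40, i.e. +/-20 nt, center-to-center, same strand).
#' @param cluster_tpm_min Minimum external-cluster TPM (default 3).
#' @inheritParams internal_priming_filter
#' @return `candidates` with a `class_label` column
#'   (`validated`/`supported`/`likely`/`discarded`) and a `retained`
#'   logical column marking the supported-union-likely atlas.
#' @export
classify_sites <- function(candidates, gencode_ends, external_clusters,
                           genome, window = 40, cluster_tpm_min = 3,
                           window_down = 20, a_frac = 0.65, a_run = 8) {
  half <- window / 2
  near_any <- function(sites, ref) {
    if (is.null(ref) || nrow(ref) == 0) return(rep(FALSE, nrow(sites)))
    vapply(seq_len(nrow(sites)), function(i) {
      sel <- ref$chrom == sites$chrom[i] & ref$strand == sites$strand[i]
      any(abs(ref$position[sel] - sites$position[i]) <= half)
    }, logical(1))
  }
  out <- as_tibble(candidates)
  validated <- near_any(out, gencode_ends)
  ext <- external_clusters[external_clusters$tpm >= cluster_tpm_min, ,
                           drop = FALSE]
  supported <- !validated & near_any(out, ext)
  todo <- !validated & !supported
  likely <- rep(FALSE, nrow(out))
  if (any(todo)) {
    likely[todo] <- internal_priming_filter(out[todo, , drop = FALSE], genome,
                                            window_down = window_down,
                                            a_frac = a_frac, a_run = a_run)
  }
  out$class_label <- dplyr::case_when(
    validated ~ "validated",
    supported ~ "supported",
    likely ~ "likely",
    TRUE ~ "discarded"
  )
  out$retained <- out$class_label %in% c("supported", "likely")
  out
}

#' Assign genomic region labels to cleavage sites
#'
#' Each site receives the first matching label, across all same-strand
#' overlapping transcripts, in the fixed precedence order
#' `three_prime_UTR` > `five_prime_UTR` > `exon` > `intron` >
#' `extended_five_prime_UTR` > `extended_three_prime_UTR` >
#' `intergenic`. 5' ends are extended `five_ext` nt upstream and 3'
#' ends `three_ext` nt downstream for the extended labels. The matched
#' transcript's gene id is attached.
#'
#' @param sites Data frame with `chrom`, `strand`, `position`.
#' @param transcripts A tx table carrying CDS bounds where available.
#' @param five_ext Upstream extension in nt (default 1000).
#' @param three_ext Downstream extension in nt (default 5000).
#' @return `sites` with `region_label` and `gene_id` columns.
#' @export
annotate_region <- function(sites, transcripts, five_ext = 1000,
                            three_ext = 5000) {
  labels <- c("three_prime_UTR", "five_prime_UTR", "exon", "intron",
              "extended_five_prime_UTR", "extended_three_prime_UTR")
  site_label <- character(nrow(sites))
  site_gene <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    cand <- transcripts[transcripts$chrom == sites$chrom[i] &
                          transcripts$strand == sites$strand[i], , drop = FALSE]
    best <- 7L  # intergenic
    best_gene <- NA_character_
    for (j in seq_len(nrow(cand))) {
      lab <- region_for_tx(p, cand$exons[[j]], cand$strand[j],
                           cand$cds_start[j], cand$cds_end[j],
                           five_ext, three_ext)
      if (lab < best) {
        best <- lab
        best_gene <- cand$gene_id[j]
        if (best == 1L) break
      }
    }
    site_label[i] <- if (best <= 6L) labels[best] else "intergenic"
    site_gene[i] <- if (best <= 6L) best_gene else NA_character_
  }
  out <- as_tibble(sites)
  out$region_label <- site_label
  out$gene_id <- site_gene
  out
}

# Precedence rank (1..6) of a position within one transcript, 7 if no
# overlap. Coordinates 0-based; cds span is half-open and includes the
# stop codon, so on + the 3'UTR is exonic sequence at pos >= cds_end.
region_for_tx <- function(p, ex, strand, cds_start, cds_end,
                          five_ext, three_ext) {
  span_start <- ex$start[1]
  span_end <- ex$end[nrow(ex)]
  exonic <- any(p >= ex$start & p < ex$end)
  coding <- !is.na(cds_start) && !is.na(cds_end)
  if (exonic) {
    if (coding) {
      in_3utr <- if (strand == "+") p >= cds_end else p < cds_start
      in_5utr <- if (strand == "+") p < cds_start else p >= cds_end
      if (in_3utr) return(1L)
      if (in_5utr) return(2L)
    }
    return(3L)
  }
  if (p >= span_start && p < span_end) return(4L)
  if (strand == "+") {
    if (p >= span_start - five_ext && p < span_start) return(5L)
    if (p >= span_end && p < span_end + three_ext) return(6L)
  } else {
    if (p >= span_end && p < span_end + five_ext) return(5L)
    if (p >= span_start - three_ext && p < span_start) return(6L)
  }
  7L
}

#' Cleavage-site usage score and major/minor classification
#'
#' The usage score of a site is the number of cell types using the site
#' divided by the number of cell types expressing its gene. A site used
#' in fewer than `min_celltypes` expressing cell types is classified
#' `minor` (the default rule); `rule = "fraction"` instead calls a site
#' minor when it is used in less than `min_fraction` of expressing cell
#' types.
#'
#' @param n_used Integer vector: cell types in which the site was
#'   called (post RPM filter).
#' @param n_expressing Integer vector: cell types expressing the gene
#'   (at least one UMI in the cell type's pseudobulk).
#' @param min_celltypes Count threshold for the `"count"` rule
#'   (default 10).
#' @param min_fraction Fraction threshold for the `"fraction"` rule
#'   (default 0.10).
#' @param rule `"count"` (default) or `"fraction"`.
#' @return Tibble with `usage_score` (in `[0,1]`, `NA` when the gene is
#'   expressed nowhere) and `usage_class` (`major`/`minor`, `NA` when
#'   undefined).
#' @export
usage_score <- function(n_used, n_expressing, min_celltypes = 10,
                        min_fraction = 0.10, rule = c("count", "fraction")) {
  rule <- match.arg(rule)
  if (any(n_used > n_expressing)) {
    stop("a site cannot be used in more cell types than express its gene")
  }
  score <- ifelse(n_expressing > 0, n_used / n_expressing, NA_real_)
  minor <- if (rule == "count") n_used < min_celltypes
           else score < min_fraction
  tibble(usage_score = score,
         usage_class = ifelse(is.na(score), NA_character_,
                              ifelse(minor, "minor", "major")))
}

#' Positional density of sequence motifs around cleavage sites
#'
#' Extracts a strand-oriented window centered at each site, scans for
#' every occurrence of each IUPAC motif (e.g. the PAS `AWTAAA`), and
#' pools motif-center offsets (site at offset 0, negative = upstream)
#' into a per-motif histogram with the global mode scaled to 1.
#'
#' @param sites Data frame with `chrom`, `strand`, `position`.
#' @param genome Genome sequences.
#' @param motifs Character vector of IUPAC motifs (optionally named).
#' @param flank Half-window in nt (default 500: a 1001-nt window).
#' @param search_windows Optional named list of `c(min, max)` offset
#'   ranges restricting where each motif's occurrences are counted.
#' @return Tibble `motif`, `offset`, `count`, `density` covering every
#'   offset in the (possibly restricted) window.
#' @export
motif_positional_density <- function(sites, genome, motifs, flank = 500,
                                     search_windows = NULL) {
  bad <- unique(unlist(strsplit(toupper(motifs), "")))
  bad <- setdiff(bad, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) stop("invalid IUPAC symbol(s): ",
                            paste(bad, collapse = ", "))
  genome <- as_genome(genome)
  if (is.null(names(motifs))) names(motifs) <- motifs
  # windows are clipped at contig boundaries; remember each window's
  # offset origin so occurrence positions map back to CS-relative offsets
  wins <- lapply(seq_len(nrow(sites)), function(i) {
    p <- sites$position[i]
    s0 <- max(0L, p - flank)
    e0 <- min(length(genome[[sites$chrom[i]]]), p + flank + 1L)
    seq <- genomic_window(genome, sites$chrom[i], sites$strand[i], s0, e0)
    left <- if (sites$strand[i] == "+") p - s0 else e0 - 1L - p
    list(seq = seq, left = left)  # CS is at string position left+1
  })
  seqs <- Biostrings::DNAStringSet(vapply(wins, `[[`, character(1), "seq"))
  purrr::map_dfr(names(motifs), function(mn) {
    motif <- toupper(motifs[[mn]])
    hits <- Biostrings::vmatchPattern(motif, seqs, fixed = FALSE)
    offs <- unlist(lapply(seq_along(hits), function(i) {
      st <- Biostrings::startIndex(hits)[[i]]
      if (is.null(st) || length(st) == 0) return(integer())
      first <- st - 1L - wins[[i]]$left            # offset of motif start
      floor(first + (nchar(motif) - 1) / 2)        # motif-center offset
    }))
    rng <- if (!is.null(search_windows) && mn %in% names(search_windows)) {
      search_windows[[mn]]
    } else c(-flank, flank)
    offs <- offs[offs >= rng[1] & offs <= rng[2]]
    all_off <- seq.int(rng[1], rng[2])
    count <- as.integer(table(factor(offs, levels = all_off)))
    dens <- if (max(count) > 0) count / max(count) else rep(0, length(count))
    tibble(motif = mn, offset = all_off, count = count, density = dens)
  })
}
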