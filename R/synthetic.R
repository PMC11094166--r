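# Seeded synthetic-data generators: toy annotations, 3'-end reads with
# gamma-distributed distances, Dirichlet-multinomial cell count
# matrices with planted usage shifts, planted-module effect matrices,
# and first-order decay curves. These are first-class, tested
# components — every statistics layer in the package is exercised
# against data they generate.

# Dirichlet sample via independent gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) {
    out <- numeric(length(alpha))
    out[which.max(alpha)] <- 1
    return(out)
  }
  g / sum(g)
}

#' Generate a toy multi-gene, multi-isoform annotation
#'
#' Lays out `n_genes` genes (alternating strands) on one chromosome,
#' each with `isoforms_per_gene` single-gene isoforms sharing a 5' end
#' and CDS but ending at cleavage sites spaced `cs_spacing` nt apart,
#' so isoform ranks from 5' to 3' are well defined. Also returns a
#' random genome covering the layout.
#'
#' @param n_genes,isoforms_per_gene Layout (defaults 3 genes x 2).
#' @param cs_spacing Distance between consecutive cleavage sites
#'   (default 300 nt).
#' @param utr_length 3'UTR length of the shortest isoform (default 400).
#' @param chrom Chromosome name.
#' @param seed Optional seed for the random genome sequence.
#' @return List: `transcripts` (tx table), `genome` (DNAStringSet),
#'   `isoforms` tibble (`isoform_id`, `gene_id`, `rank`, `cs_position`).
#' @export
generate_toy_annotation <- function(n_genes = 3, isoforms_per_gene = 2,
                                    cs_spacing = 300, utr_length = 400,
                                    chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_span <- 2000 + isoforms_per_gene * cs_spacing
  pitch <- gene_span + 1000
  rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
    g_start <- (g - 1) * pitch + 500
    strand <- if (g %% 2 == 1) "+" else "-"
    purrr::map_dfr(seq_len(isoforms_per_gene), function(i) {
      len <- 600 + utr_length + (i - 1) * cs_spacing  # 5'UTR+CDS 600 nt
      tibble(transcript_id = sprintf("G%d.T%d", g, i),
             gene_id = sprintf("G%d", g), chrom = chrom, strand = strand,
             start = if (strand == "+") g_start else g_start + gene_span - len,
             end = if (strand == "+") g_start + len else g_start + gene_span,
             cds_start = if (strand == "+") g_start + 100 else
               g_start + gene_span - 600 + 100,
             cds_end = if (strand == "+") g_start + 600 else
               g_start + gene_span - 100,
             rank = i)
    })
  })
  tx <- tx_table(rows$transcript_id, rows$gene_id, rows$chrom, rows$strand,
                 exons = lapply(seq_len(nrow(rows)), function(i) {
                   data.frame(start = rows$start[i], end = rows$end[i])
                 }),
                 cds_start = rows$cds_start, cds_end = rows$cds_end)
  genome_len <- n_genes * pitch + 1000
  genome <- Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
          collapse = ""), chrom))
  iso <- tibble(isoform_id = rows$transcript_id, gene_id = rows$gene_id,
                rank = rows$rank, cs_position = tx_three_prime_end(tx))
  list(transcripts = tx, genome = genome, isoforms = iso)
}

#' Generate 3'-end reads around cleavage sites
#'
#' Draws read 5'-end distances from each isoform's cleavage site from
#' the discretized gamma model (rounded, floored at `read_length`) and
#' converts them to genomic 3'-end read positions, assuming the
#' distances fall within the isoform's last exon (true for the toy
#' annotations generated here).
#'
#' @param counts Tibble `barcode`, `isoform_id`, `n` reads.
#' @param annotation Output of [generate_toy_annotation()] (or a list
#'   with `transcripts` and `isoforms`).
#' @param read_length,dist_mean,dist_sd Read model (defaults 100/300/100).
#' @param seed Optional seed.
#' @return Tibble `barcode`, `umi`, `chrom`, `strand`, `position` (the
#'   read 3' end, 0-based).
#' @export
generate_reads <- function(counts, annotation, read_length = 100,
                           dist_mean = 300, dist_sd = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tx <- annotation$transcripts
  shape <- (dist_mean / dist_sd)^2
  scale <- dist_sd^2 / dist_mean
  ends <- setNames(tx_three_prime_end(tx), tx$transcript_id)
  strands <- setNames(tx$strand, tx$transcript_id)
  chroms <- setNames(tx$chrom, tx$transcript_id)
  purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]
    if (n == 0) return(NULL)
    iso <- counts$isoform_id[i]
    dist <- pmax(round(rgamma(n, shape = shape, scale = scale)), read_length)
    offset <- dist - read_length  # read 3' end this far upstream of CS
    pos <- if (strands[iso] == "+") ends[iso] - offset else ends[iso] + offset
    tibble(barcode = counts$barcode[i],
           umi = sprintf("%s-%s-%06d", counts$barcode[i], iso, seq_len(n)),
           chrom = chroms[iso], strand = strands[iso],
           position = as.integer(pos))
  })
}

#' Generate a cell count matrix with planted usage and expression
#'
#' Draws per-cell isoform counts from a Dirichlet-multinomial around
#' planted per-group isoform fractions: for each gene and group, a
#' target weighted UTR index `wui` is planted by putting fraction
#' `wui` on the longest isoform and `1 - wui` on the shortest; each
#' cell's gene total is Poisson around `mean_count` (scaled by the
#' group's `fc` fold change), and its isoform split is multinomial with
#' probabilities drawn from `Dirichlet(overdispersion * fractions)`
#' (`overdispersion = Inf` gives a pure multinomial).
#'
#' @param genes Tibble with one row per gene and group:
#'   `gene_id`, `group`, `wui`, `mean_count` (expected UMIs per cell),
#'   optional `fc` multiplier. Alternatively pass `n_genes` and
#'   scalar/vector `wui`, `mean_count`, `fc` via the shortcut arguments.
#' @param cells_per_group Named integer vector: cells per group label.
#' @param isoforms_per_gene Isoforms per gene (default 2).
#' @param overdispersion Dirichlet concentration (default `Inf`,
#'   i.e. multinomial; smaller = more cell-to-cell variability).
#' @param n_genes,wui,mean_count,fc Shortcut spec used when `genes` is
#'   `NULL`: every group gets the same `wui`/`mean_count` unless a
#'   named list keyed by group is given.
#' @param seed Optional seed.
#' @return List: `counts` (a [cell_counts()] with `rank`ed isoforms),
#'   `truth` (tibble `gene_id`, `group`, `wui`, `mean_count`,
#'   `fractions` list column).
#' @export
generate_fixture <- function(genes = NULL, cells_per_group = c(A = 100),
                             isoforms_per_gene = 2, overdispersion = Inf,
                             n_genes = 10, wui = 0.5, mean_count = 5,
                             fc = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- names(cells_per_group)
  if (is.null(groups)) stop("cells_per_group must be named by group")
  if (is.null(genes)) {
    get_par <- function(par, g) {
      if (is.list(par)) rep_len(par[[g]], n_genes) else rep_len(par, n_genes)
    }
    genes <- purrr::map_dfr(groups, function(g) {
      tibble(gene_id = sprintf("gene%03d", seq_len(n_genes)), group = g,
             wui = get_par(wui, g), mean_count = get_par(mean_count, g),
             fc = get_par(fc, g))
    })
  }
  if (!"fc" %in% names(genes)) genes$fc <- 1
  if (any(genes$wui < 0 | genes$wui > 1)) stop("wui targets must be in [0,1]")
  gene_ids <- unique(genes$gene_id)
  k <- isoforms_per_gene
  iso_tbl <- tidyr::expand_grid(gene_id = gene_ids, rank = seq_len(k)) |>
    mutate(isoform_id = sprintf("%s.%d", .data$gene_id, .data$rank)) |>
    select("isoform_id", "gene_id", "rank")
  frac_of <- function(w) {
    f <- numeric(k)
    f[1] <- 1 - w
    f[k] <- f[k] + w
    f
  }
  barcodes <- unlist(lapply(groups, function(g) {
    sprintf("%s-%04d", g, seq_len(cells_per_group[[g]]))
  }))
  cell_groups <- rep(groups, cells_per_group[groups])
  mat <- matrix(0L, length(barcodes), nrow(iso_tbl))
  truth <- genes |>
    mutate(fractions = lapply(.data$wui, frac_of))
  for (g in groups) {
    rows <- which(cell_groups == g)
    sub <- truth[truth$group == g, ]
    for (j in seq_len(nrow(sub))) {
      cols <- which(iso_tbl$gene_id == sub$gene_id[j])
      f <- sub$fractions[[j]]
      tot <- rpois(length(rows), sub$mean_count[j] * sub$fc[j])
      for (ci in seq_along(rows)) {
        if (tot[ci] == 0) next
        p <- if (is.finite(overdispersion)) {
          a <- overdispersion * f
          pos <- a > 0
          pp <- numeric(k)
          pp[pos] <- rdirichlet1(a[pos])
          pp
        } else f
        mat[rows[ci], cols] <- rmultinom(1, tot[ci], p)[, 1]
      }
    }
  }
  cc <- cell_counts(mat, tibble(barcode = barcodes, group = cell_groups),
                    iso_tbl)
  list(counts = cc, truth = truth)
}

#' Generate a perturbation effect matrix with planted modules
#'
#' Plants `n_modules` blocks of perturbations sharing a sign structure
#' over matching gene blocks (`signal` magnitude with random signs per
#' module/gene-block pair), plus Gaussian noise, emulating groups of
#' regulators that shift the same response genes.
#'
#' @param n_perturbations,n_genes Matrix size (defaults 60 x 300).
#' @param n_modules Planted modules (default 3).
#' @param signal Block effect magnitude (default 1).
#' @param noise_sd Gaussian noise sd (default 0.3).
#' @param seed Optional seed.
#' @return List: `z` (matrix with dimnames), `modules` tibble
#'   (`perturbation`, `module`), `gene_modules` tibble.
#' @export
generate_effect_matrix <- function(n_perturbations = 60, n_genes = 300,
                                   n_modules = 3, signal = 1,
                                   noise_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pm <- sort(rep_len(seq_len(n_modules), n_perturbations))
  gm <- sort(rep_len(seq_len(n_modules), n_genes))
  signs <- matrix(sample(c(-1, 1), n_modules * n_modules, replace = TRUE),
                  n_modules, n_modules)
  mean_mat <- signal * signs[pm, gm] *
    (outer(pm, gm, "==") * 1)                 # block-diagonal signal
  z <- mean_mat + matrix(rnorm(n_perturbations * n_genes, sd = noise_sd),
                         n_perturbations, n_genes)
  dimnames(z) <- list(sprintf("pert%03d", seq_len(n_perturbations)),
                      sprintf("gene%03d", seq_len(n_genes)))
  list(z = z,
       modules = tibble(perturbation = rownames(z), module = pm),
       gene_modules = tibble(gene_id = colnames(z), module = gm))
}

#' Generate a first-order decay conversion time course
#'
#' Evaluates `c(t) = c_max (1 - exp(-k t))` at the given timepoints,
#' optionally adding Gaussian noise, with read-count weights.
#'
#' @param k Decay rate per minute.
#' @param c_max Plateau conversion rate (default 0.1).
#' @param timepoints Minutes (default `c(0, 120, 240, 360)`).
#' @param noise_sd Gaussian noise on rates (default 0).
#' @param weights Read counts per timepoint (default 1000).
#' @param seed Optional seed.
#' @return Tibble `time`, `rate`, `weight`.
#' @export
generate_decay_curve <- function(k, c_max = 0.1,
                                 timepoints = c(0, 120, 240, 360),
                                 noise_sd = 0, weights = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- c_max * (1 - exp(-k * timepoints))
  if (noise_sd > 0) rate <- pmax(rate + rnorm(length(rate), sd = noise_sd), 0)
  tibble(time = timepoints, rate = rate,
         weight = rep_len(weights, length(timepoints)))
}
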