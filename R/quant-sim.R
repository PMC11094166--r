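# Toy 3'-end quantifier: positional read-to-isoform compatibility,
# equivalence classes for ambiguous reads, EM abundance estimation, and
# the two-isoform resolution simulation used to calibrate the merge
# distance.

#' Assign 3'-end reads to UTRome isoforms
#'
#' Reads are deduplicated on (barcode, UMI, gene) and assigned by
#' position: a read is compatible with an isoform iff its 3'-end
#' genomic position lies within the isoform's truncated body (same
#' chromosome and strand). Uniquely compatible reads are counted
#' directly; reads compatible with several isoforms that share a merge
#' table representative are counted to that representative; remaining
#' multi-compatible reads are recorded as equivalence classes for
#' [em_abundance()]. Reads matching no isoform land in the
#' `unassigned` count.
#'
#' @param reads Data frame with columns `barcode`, `umi`, `chrom`,
#'   `strand`, `position` (the read 3' end, 0-based).
#' @param utrome A truncated tx table.
#' @param merge_table Optional tibble from [build_merge_table()].
#' @return List with `counts` (a [cell_counts()] of unique+merged
#'   assignments), `eq_classes` (tibble `barcode`, `gene_id`, `class`
#'   (isoform ids collapsed with `,`), `count`) and `unassigned`
#'   (number of reads).
#' @export
assign_reads <- function(reads, utrome, merge_table = NULL) {
  reads <- as_tibble(reads)
  rep_of <- if (!is.null(merge_table)) {
    setNames(merge_table$representative_id, merge_table$isoform_id)
  } else setNames(utrome$transcript_id, utrome$transcript_id)
  compat <- lapply(seq_len(nrow(reads)), function(i) {
    hits <- which(utrome$chrom == reads$chrom[i] &
                    utrome$strand == reads$strand[i])
    hits[vapply(hits, function(j) {
      ex <- utrome$exons[[j]]
      any(reads$position[i] >= ex$start & reads$position[i] < ex$end)
    }, logical(1))]
  })
  gene_of <- vapply(compat, function(h) {
    if (length(h) == 0) NA_character_ else utrome$gene_id[h[1]]
  }, character(1))
  # UMI deduplication: one record per (barcode, UMI, gene)
  key <- paste(reads$barcode, reads$umi, gene_of)
  dedup <- !duplicated(key) | is.na(gene_of)
  reads <- reads[dedup, ]
  compat <- compat[dedup]
  gene_of <- gene_of[dedup]

  unassigned <- sum(lengths(compat) == 0)
  keep <- lengths(compat) > 0
  assigned_iso <- vapply(compat[keep], function(h) {
    reps <- unique(unname(rep_of[utrome$transcript_id[h]]))
    if (length(reps) == 1) reps else NA_character_
  }, character(1))
  bc <- reads$barcode[keep]
  gene <- gene_of[keep]
  uniq <- !is.na(assigned_iso)

  barcodes <- sort(unique(reads$barcode))
  iso_tbl <- tibble(isoform_id = utrome$transcript_id,
                    gene_id = utrome$gene_id)
  mat <- Matrix::sparseMatrix(
    i = match(bc[uniq], barcodes),
    j = match(assigned_iso[uniq], iso_tbl$isoform_id),
    x = 1, dims = c(length(barcodes), nrow(iso_tbl)))
  counts <- cell_counts(mat, tibble(barcode = barcodes,
                                    group = NA_character_), iso_tbl)
  eq <- if (any(!uniq)) {
    tibble(barcode = bc[!uniq], gene_id = gene[!uniq],
           class = vapply(compat[keep][!uniq], function(h) {
             paste(sort(utrome$transcript_id[h]), collapse = ",")
           }, character(1))) |>
      dplyr::count(.data$barcode, .data$gene_id, .data$class, name = "count")
  } else {
    tibble(barcode = character(), gene_id = character(),
           class = character(), count = integer())
  }
  list(counts = counts, eq_classes = eq, unassigned = unassigned)
}

#' EM abundance estimation over equivalence classes
#'
#' Standard expectation maximization on a categorical mixture for one
#' gene: the likelihood of a read in class `c` is the sum of the
#' abundances of the class members (uniform within-class read model; no
#' effective-length weighting, since 3'-end tags violate the
#' uniform-coverage assumption length weights encode). Iterates until
#' the largest abundance change falls below `tol` or `max_iter`
#' rounds. The observed-data log-likelihood is non-decreasing across
#' iterations.
#'
#' @param class_counts Named numeric vector: names are isoform ids
#'   collapsed with `","`, values are read counts.
#' @param isoforms Optional character vector fixing the isoform order;
#'   defaults to the sorted union of class members.
#' @param tol Convergence tolerance on abundances (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return Tibble `isoform_id`, `abundance`, `est_count`, plus
#'   attributes `iterations`, `loglik` (trace) and `identifiable`
#'   (`FALSE` when no class pins any isoform down, in which case the
#'   uniform point is returned).
#' @export
em_abundance <- function(class_counts, isoforms = NULL, tol = 1e-8,
                         max_iter = 1000) {
  members <- strsplit(names(class_counts), ",", fixed = TRUE)
  if (is.null(isoforms)) isoforms <- sort(unique(unlist(members)))
  # zero-count classes carry no information and would produce 0/0
  # responsibilities once their members' abundances vanish
  nonzero <- class_counts > 0
  if (any(nonzero)) {
    class_counts <- class_counts[nonzero]
    members <- members[nonzero]
  }
  k <- length(isoforms)
  n <- unname(as.numeric(class_counts))
  total <- sum(n)
  A <- vapply(members, function(m) as.numeric(isoforms %in% m), numeric(k))
  A <- matrix(A, nrow = k)  # k x classes membership
  if (total == 0) {
    warning("all class counts are zero; returning uniform abundances")
    return(structure(tibble(isoform_id = isoforms, abundance = rep(1 / k, k),
                            est_count = rep(0, k)),
                     iterations = 0L, loglik = numeric(),
                     identifiable = FALSE))
  }
  alpha <- rep(1 / k, k)
  ll <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    class_prob <- as.numeric(crossprod(A, alpha))     # sum of member alphas
    ll <- c(ll, sum(n * log(class_prob)))
    resp <- A * alpha                                  # k x classes
    resp <- sweep(resp, 2, class_prob, "/")
    expected <- as.numeric(resp %*% n)
    new_alpha <- expected / total
    delta <- max(abs(new_alpha - alpha))
    alpha <- new_alpha
    if (delta < tol || iter >= max_iter) break
  }
  identifiable <- qr(t(A))$rank == k
  if (!identifiable && all(colSums(A) > 1)) alpha <- rep(1 / k, k)
  structure(tibble(isoform_id = isoforms, abundance = alpha,
                   est_count = alpha * total),
            iterations = iter, loglik = ll, identifiable = identifiable)
}

#' Two-isoform 3'-end quantification resolution simulation
#'
#' Simulates a gene with a proximal and a distal cleavage site
#' `cs_distance` nt apart. Read 5'-end distances from each site follow
#' a discretized gamma distribution (`dist_mean`, `dist_sd`; shape
#' `(mean/sd)^2`, rounded to integers and floored at `read_length`, as
#' a read cannot end downstream of its site). Both isoforms are
#' truncated to `truncation_length` nt; reads are assigned by the
#' position of their 3' end (5' position minus `read_length` toward
#' the site), ambiguous reads resolved by [em_abundance()], and the
#' relative estimation error `(estimated - true)/true` returned per
#' isoform per replicate.
#'
#' @param cs_distance Proximal-to-distal 3'-end distance in nt (> 0).
#' @param truncation_length Truncated isoform length in nt (default 500).
#' @param proximal_count,distal_count Reads generated per isoform.
#' @param read_length Read length in nt (default 100).
#' @param dist_mean,dist_sd Gamma distance model (defaults 300/100).
#' @param replicates Number of replicates (default 10).
#' @param seed Optional RNG seed.
#' @return Tibble `replicate`, `isoform` (`proximal`/`distal`),
#'   `true_count`, `est_count`, `rel_error`.
#' @export
simulate_two_isoform <- function(cs_distance, truncation_length = 500,
                                 proximal_count = 100, distal_count = 100,
                                 read_length = 100, dist_mean = 300,
                                 dist_sd = 100, replicates = 10, seed = NULL) {
  if (cs_distance <= 0) stop("cs_distance must be positive (identical ",
                             "isoforms are degenerate)")
  if (!is.null(seed)) set.seed(seed)
  shape <- (dist_mean / dist_sd)^2
  scale <- dist_sd^2 / dist_mean
  draw_dist <- function(n) pmax(round(rgamma(n, shape = shape, scale = scale)),
                                read_length)
  purrr::map_dfr(seq_len(replicates), function(r) {
    # coordinates on the distal isoform: distal CS at 0, proximal at
    # -cs_distance; a read's 3' end sits read_length nt downstream of
    # its sampled 5' start, i.e. at cs - dist + read_length
    p3 <- -cs_distance - draw_dist(proximal_count) + read_length
    d3 <- -draw_dist(distal_count) + read_length
    ends <- c(p3, d3)
    in_p <- ends >= -cs_distance - truncation_length & ends <= -cs_distance
    in_d <- ends >= -truncation_length & ends <= 0
    class <- dplyr::case_when(
      in_p & in_d ~ "distal,proximal",
      in_p ~ "proximal",
      in_d ~ "distal",
      TRUE ~ NA_character_
    )
    cc <- table(class[!is.na(class)])
    est <- em_abundance(setNames(as.numeric(cc), names(cc)),
                        isoforms = c("distal", "proximal"))
    truth <- c(distal = distal_count, proximal = proximal_count)
    tibble(replicate = r,
           isoform = c("proximal", "distal"),
           true_count = unname(truth[c("proximal", "distal")]),
           est_count = est$est_count[match(c("proximal", "distal"),
                                           est$isoform_id)],
           rel_error = (.data$est_count - .data$true_count) / .data$true_count)
  })
}

#' Sweep quantification error over the resolution grid
#'
#' Runs [simulate_two_isoform()] over every combination of cleavage-site
#' distance, truncation length, and proximal/distal read counts, and
#' summarises the mean and sd of the relative error per isoform. The
#' default grid covers distances 50-700 nt in 50-nt steps, truncation
#' lengths 350-600 nt in 50-nt steps, and counts of 50 and 100 reads
#' per isoform.
#'
#' @param distances,truncations,proximal_counts,distal_counts Grid axes.
#' @param replicates Replicates per grid cell (default 10).
#' @param seed RNG seed; each cell derives its own substream.
#' @return Long tibble: one row per grid cell and isoform with
#'   `mean_rel_error`, `sd_rel_error`, `mean_abs_rel_error`.
#' @export
resolution_sweep <- function(distances = seq(50, 700, by = 50),
                             truncations = seq(350, 600, by = 50),
                             proximal_counts = c(50, 100),
                             distal_counts = c(50, 100),
                             replicates = 10, seed = 1) {
  grid <- tidyr::expand_grid(cs_distance = distances,
                             truncation_length = truncations,
                             proximal_count = proximal_counts,
                             distal_count = distal_counts)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sim <- simulate_two_isoform(g$cs_distance, g$truncation_length,
                                g$proximal_count, g$distal_count,
                                replicates = replicates,
                                seed = seed + i)
    sim |>
      group_by(.data$isoform) |>
      summarise(mean_rel_error = mean(.data$rel_error),
                sd_rel_error = sd(.data$rel_error),
                mean_abs_rel_error = mean(abs(.data$rel_error)),
                .groups = "drop") |>
      bind_cols(g[rep(1, 2), ])
  })
}

#' Smallest reliably resolved cleavage-site distance
#'
#' Flags, from a [resolution_sweep()] table, the smallest distance at
#' which the mean absolute relative error stays below `tolerance` for
#' every truncation/count combination at that distance and beyond.
#'
#' @param sweep Output of [resolution_sweep()].
#' @param tolerance Mean absolute relative error bound (default 0.05).
#' @return The distance in nt (`NA` if none qualifies).
#' @export
resolved_distance <- function(sweep, tolerance = 0.05) {
  per_dist <- sweep |>
    group_by(.data$cs_distance) |>
    summarise(worst = max(.data$mean_abs_rel_error), .groups = "drop") |>
    arrange(.data$cs_distance)
  ok <- rev(cumprod(rev(per_dist$worst < tolerance))) > 0
  if (!any(ok)) return(NA_real_)
  min(per_dist$cs_distance[ok])
}

#' Nearest-rank 95th percentiles of read distances
#'
#' Computes empirical percentiles (nearest-rank, `type = 1`) of read
#' 5'-end distances from the annotated 3' end, per sample and per gene
#' — the diagnostic used to choose the truncation window.
#'
#' @param distances Data frame with columns `gene`, `sample`,
#'   `distance` (nt, >= 0).
#' @param prob Percentile (default 0.95).
#' @return List of two tibbles: `per_sample` (percentile across all
#'   genes of a sample) and `per_gene` (percentile across all samples
#'   of a gene).
#' @export
peak_width_percentiles <- function(distances, prob = 0.95) {
  distances <- as_tibble(distances)
  if (nrow(distances) == 0) stop("no distances supplied")
  if (any(distances$distance < 0)) stop("distances must be non-negative")
  q1 <- function(x) unname(quantile(x, prob, type = 1))
  list(
    per_sample = distances |> group_by(sample = .data$sample) |>
      summarise(percentile = q1(.data$distance), .groups = "drop"),
    per_gene = distances |> group_by(gene = .data$gene) |>
      summarise(percentile = q1(.data$distance), .groups = "drop")
  )
}
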