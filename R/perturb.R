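# Perturbation-screen analysis: per-perturbation dWUI/dIPA effects,
# z-scaling with imputation, iterative PCA/kNN/walktrap clustering,
# per-cluster differential tests, compensation classification, overlap
# and replicate-validation statistics, and feature correlations.

#' Per-perturbation usage profiles
#'
#' Convenience pseudobulk for screens: per (perturbation, gene), the
#' pseudobulk WUI (and IPA fraction when IPA isoforms are flagged),
#' gene TPM, cell count, and the fraction of the perturbation's cells
#' detecting the gene.
#'
#' @param x A [cell_counts()] whose `group` labels are perturbations.
#' @return Tibble `perturbation`, `gene_id`, `wui`, `ipa`, `tpm`,
#'   `n_cells`, `detect_rate`. `wui` is `NA` for unexpressed or
#'   single-isoform genes.
#' @export
perturbation_profiles <- function(x) {
  st <- iso_structure(x)
  ipa <- if ("is_ipa" %in% names(x$isoforms)) x$isoforms$is_ipa
         else rep(FALSE, ncol(x$counts))
  groups <- sort(unique(x$cells$group))
  E <- Matrix::Matrix((x$counts %*% st$G) > 0) * 1
  purrr::map_dfr(groups, function(g) {
    rows <- x$cells$group == g
    cnt <- Matrix::colSums(x$counts[rows, , drop = FALSE])
    tot_g <- as.numeric(cnt %*% st$G)
    w_g <- as.numeric(cnt %*% (st$G * st$w))
    ipa_g <- as.numeric((cnt * ipa) %*% st$G)
    tibble(perturbation = g, gene_id = st$genes,
           wui = ifelse(tot_g > 0 & st$n_iso >= 2, w_g / tot_g, NA_real_),
           ipa = ifelse(tot_g > 0, ipa_g / tot_g, NA_real_),
           tpm = tot_g / sum(cnt) * 1e6,
           n_cells = sum(rows),
           detect_rate = as.numeric(Matrix::colSums(
             E[rows, , drop = FALSE])) / sum(rows))
  })
}

#' Perturbation effect matrix (dWUI / dIPA)
#'
#' Computes, per gene, a baseline value over the non-targeting
#' perturbations (cell-count-weighted mean of `value_col`) and, per
#' targeting perturbation with at least `min_cells` cells, the
#' deviation from that baseline (dWUI when `value_col = "wui"`, dIPA
#' when `"ipa"`). The per-perturbation average effect summarizes genes
#' whose control mean expression exceeds `tpm_min` TPM and whose
#' baseline value lies inside `band` (degenerate near-0/near-1 genes
#' cannot move much and are excluded). As a plain average it is most
#' sensitive to unidirectional shifts; opposite shifts cancel.
#'
#' @param profiles Tibble from [perturbation_profiles()] (columns
#'   `perturbation`, `gene_id`, the value column, `tpm`, `n_cells`,
#'   optionally `detect_rate`).
#' @param non_targeting Perturbation labels of the non-targeting
#'   controls (at least one required).
#' @param value_col `"wui"` (default) or `"ipa"`.
#' @param tpm_min,band,min_cells Filters (defaults 5 TPM, `[0.1, 0.9]`,
#'   30 cells).
#' @return A `utr_effects` object: list with `effects` (perturbation x
#'   gene matrix of deviations, `NA` where the perturbation does not
#'   detect the gene), `baseline` tibble (`gene_id`, `baseline`,
#'   `control_tpm`, `control_detect_rate`, `in_band`),
#'   `perturbations` tibble (`perturbation`, `n_cells`,
#'   `avg_effect`), and `value_col`.
#' @export
compute_effects <- function(profiles, non_targeting, value_col = "wui",
                            tpm_min = 5, band = c(0.1, 0.9),
                            min_cells = 30) {
  pr <- as_tibble(profiles)
  pr$value <- pr[[value_col]]
  nt <- pr |> filter(.data$perturbation %in% non_targeting)
  if (nrow(nt) == 0) stop("no non-targeting perturbations found")
  baseline <- nt |>
    group_by(.data$gene_id) |>
    summarise(
      baseline = {
        ok <- !is.na(.data$value)
        if (!any(ok)) NA_real_
        else sum(.data$value[ok] * .data$n_cells[ok]) / sum(.data$n_cells[ok])
      },
      control_tpm = sum(.data$tpm * .data$n_cells) / sum(.data$n_cells),
      control_detect_rate = if ("detect_rate" %in% names(nt)) {
        sum(.data$detect_rate * .data$n_cells) / sum(.data$n_cells)
      } else NA_real_,
      .groups = "drop") |>
    mutate(in_band = !is.na(.data$baseline) &
             .data$baseline >= band[1] & .data$baseline <= band[2] &
             .data$control_tpm > tpm_min)

  targ <- pr |>
    filter(!.data$perturbation %in% non_targeting) |>
    group_by(.data$perturbation) |>
    filter(first(.data$n_cells) >= min_cells) |>
    ungroup()
  genes <- baseline$gene_id
  perts <- sort(unique(targ$perturbation))
  eff <- matrix(NA_real_, length(perts), length(genes),
                dimnames = list(perts, genes))
  eff[cbind(match(targ$perturbation, perts), match(targ$gene_id, genes))] <-
    targ$value - baseline$baseline[match(targ$gene_id, genes)]
  avg <- vapply(seq_along(perts), function(i) {
    v <- eff[i, baseline$in_band]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  pert_info <- targ |> distinct(.data$perturbation, .data$n_cells) |>
    arrange(.data$perturbation) |>
    mutate(avg_effect = avg[match(.data$perturbation, perts)])
  structure(list(effects = eff, baseline = baseline,
                 perturbations = pert_info, value_col = value_col),
            class = "utr_effects")
}

#' @export
print.utr_effects <- function(x, ...) {
  cat(sprintf("<utr_effects> %d perturbations x %d genes (d%s)\n",
              nrow(x$effects), ncol(x$effects), toupper(x$value_col)))
  if (!is.null(x$z)) cat("z-scaled matrix present\n")
  invisible(x)
}

#' @method tidy utr_effects
#' @export
tidy.utr_effects <- function(x, ...) {
  m <- if (!is.null(x$z)) x$z else x$effects
  as_tibble(as.data.frame.table(m, responseName = "value",
                                stringsAsFactors = FALSE)) |>
    rlang::set_names(c("perturbation", "gene_id", "value"))
}

#' Z-scale an effect matrix with zero imputation
#'
#' Restricts the effect matrix to well-measured response genes (control
#' detection rate of at least `1 - max_nondetect` and control TPM of at
#' least `min_control_tpm`, when those baseline columns are available),
#' imputes missing perturbation/gene effects as 0 (identical to
#' baseline), and scales each perturbation row to unit variance
#' *without centering* — the center is already fixed by the
#' non-targeting baseline, and scaling preserves the sign pattern.
#' Zero-variance rows are left as zeros and flagged.
#'
#' @param x A `utr_effects` object.
#' @param max_nondetect Maximum fraction of control cells not detecting
#'   the gene (default 0.2).
#' @param min_control_tpm Minimum control TPM (default 20).
#' @return `x` with a `z` matrix and a `zero_variance` attribute on it.
#' @export
zscale_impute <- function(x, max_nondetect = 0.2, min_control_tpm = 20) {
  b <- x$baseline
  keep <- rep(TRUE, nrow(b))
  if (!all(is.na(b$control_detect_rate))) {
    keep <- keep & b$control_detect_rate >= 1 - max_nondetect
  }
  keep <- keep & b$control_tpm >= min_control_tpm & !is.na(b$baseline)
  m <- x$effects[, keep, drop = FALSE]
  m[is.na(m)] <- 0
  # uncentered row scale: divide by sqrt(mean square), the sd about the
  # baseline-determined center 0
  rms <- sqrt(rowMeans(m^2))
  zero <- rms == 0
  z <- m
  z[!zero, ] <- m[!zero, , drop = FALSE] / rms[!zero]
  attr(z, "zero_variance") <- rownames(m)[zero]
  x$z <- z
  x
}

# k nearest neighbors graph on rows of a score matrix
knn_graph <- function(scores, k, symmetrize = c("union", "mutual")) {
  symmetrize <- match.arg(symmetrize)
  n <- nrow(scores)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(scores))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[2:(k + 1)]
    adj[i, nn] <- TRUE
  }
  adj <- if (symmetrize == "mutual") adj & t(adj) else adj | t(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# one clustering round: PCA -> kNN -> walktrap (4-step random walks,
# modularity-optimal cut)
cluster_round <- function(m, n_pcs, k, symmetrize = "union") {
  n_pcs <- min(n_pcs, nrow(m) - 1, ncol(m))
  pcs <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  g <- knn_graph(pcs, k, symmetrize)
  wt <- igraph::cluster_walktrap(g, steps = 4)
  igraph::membership(wt)
}

#' Iterative clustering of a perturbation effect matrix
#'
#' Runs a sequence of PCA / k-nearest-neighbor / walktrap community
#' detection rounds on a z-scaled effect matrix. Each round clusters
#' one axis (`"perturbations"` = rows or `"genes"` = columns); rounds
#' flagged `drop_patternless` then remove the clusters with the weakest
#' regulation pattern, quantified as the cluster mean absolute z below
#' the `dispersion_quantile` of cluster dispersions (a quantitative
#' stand-in for flagging visually patternless blocks). The final round
#' reports cluster labels for both axes of the remaining matrix.
#'
#' @param z Numeric matrix (perturbations x genes), e.g.
#'   `zscale_impute(x)$z`, or a `utr_effects` object carrying one.
#' @param rounds List of round specs `list(axis=, n_pcs=, k=,
#'   drop_patternless=)`. The default mirrors a three-round screen
#'   analysis: perturbations at k = 5, genes at k = 4 (both dropping
#'   patternless clusters), then a final joint round at k = 3.
#' @param dispersion_quantile Fraction of clusters dropped per
#'   patternless round (default 0.25: the bottom quartile).
#' @param symmetrize kNN graph symmetrization: `"union"` (default;
#'   an edge when either point lists the other as a neighbor) or
#'   `"mutual"` (both must).
#' @return A `utr_clusters` object: list with `perturbation_clusters`
#'   and `gene_clusters` tibbles (`id`, `cluster`), `rounds` (per-round
#'   label tibbles with a `kept` flag), and the retained matrix `z`.
#' @export
cluster_perturbations <- function(z,
                                  rounds = list(
                                    list(axis = "perturbations", n_pcs = 30,
                                         k = 5, drop_patternless = TRUE),
                                    list(axis = "genes", n_pcs = 30, k = 4,
                                         drop_patternless = TRUE),
                                    list(axis = "perturbations", n_pcs = 30,
                                         k = 3, drop_patternless = FALSE)),
                                  dispersion_quantile = 0.25,
                                  symmetrize = c("union", "mutual")) {
  symmetrize <- match.arg(symmetrize)
  if (inherits(z, "utr_effects")) {
    if (is.null(z$z)) z <- zscale_impute(z)
    z <- z$z
  }
  m <- z
  round_logs <- list()
  pert_clusters <- NULL
  gene_clusters <- NULL
  for (r in seq_along(rounds)) {
    spec <- rounds[[r]]
    byrow <- spec$axis == "perturbations"
    mm <- if (byrow) m else t(m)
    lab <- cluster_round(mm, spec$n_pcs, spec$k, symmetrize)
    log <- tibble(axis = spec$axis, id = rownames(mm),
                  cluster = as.integer(lab), round = r, kept = TRUE)
    if (isTRUE(spec$drop_patternless)) {
      disp <- vapply(split(seq_len(nrow(mm)), lab), function(idx) {
        mean(abs(mm[idx, , drop = FALSE]))
      }, numeric(1))
      cut <- quantile(disp, dispersion_quantile, type = 1)
      dropped <- as.integer(names(disp)[disp <= cut])
      log$kept <- !(log$cluster %in% dropped)
      keep_ids <- log$id[log$kept]
      m <- if (byrow) m[keep_ids, , drop = FALSE]
           else m[, keep_ids, drop = FALSE]
    } else {
      if (byrow) {
        pert_clusters <- tibble(id = rownames(mm),
                                cluster = as.integer(lab))
      } else {
        gene_clusters <- tibble(id = rownames(mm),
                                cluster = as.integer(lab))
      }
    }
    round_logs[[r]] <- log
  }
  final <- rounds[[length(rounds)]]
  if (is.null(pert_clusters)) {
    lab <- cluster_round(m, final$n_pcs, final$k, symmetrize)
    pert_clusters <- tibble(id = rownames(m), cluster = as.integer(lab))
  }
  if (is.null(gene_clusters)) {
    lab <- cluster_round(t(m), final$n_pcs, final$k, symmetrize)
    gene_clusters <- tibble(id = colnames(m), cluster = as.integer(lab))
  }
  structure(list(perturbation_clusters = pert_clusters,
                 gene_clusters = gene_clusters,
                 rounds = bind_rows(round_logs), z = m),
            class = "utr_clusters")
}

#' @export
print.utr_clusters <- function(x, ...) {
  cat(sprintf("<utr_clusters> %d perturbations in %d clusters; %d genes in %d clusters\n",
              nrow(x$perturbation_clusters),
              length(unique(x$perturbation_clusters$cluster)),
              nrow(x$gene_clusters),
              length(unique(x$gene_clusters$cluster))))
  invisible(x)
}

#' @method tidy utr_clusters
#' @export
tidy.utr_clusters <- function(x, ...) {
  bind_rows(
    x$perturbation_clusters |> mutate(axis = "perturbation"),
    x$gene_clusters |> mutate(axis = "gene")
  )
}

#' @method glance utr_clusters
#' @export
glance.utr_clusters <- function(x, ...) {
  tibble(n_perturbations = nrow(x$perturbation_clusters),
         n_perturbation_clusters =
           length(unique(x$perturbation_clusters$cluster)),
         n_genes = nrow(x$gene_clusters),
         n_gene_clusters = length(unique(x$gene_clusters$cluster)))
}

#' Per-cluster differential usage and expression tests
#'
#' For each perturbation cluster and gene, compares the per-perturbation
#' WUI (or TPM) values of the cluster members against the non-targeting
#' perturbations with a two-sided Mann-Whitney test, adjusting p-values
#' per cluster (BH). Direction is the sign of the mean difference; for
#' expression the fold change `mean(cluster)/mean(control)` must also
#' exceed `fc_threshold` in either direction.
#'
#' @param profiles Tibble from [perturbation_profiles()].
#' @param clusters Tibble `id`, `cluster`
#'   (e.g. `cluster_perturbations(...)$perturbation_clusters`).
#' @param non_targeting Non-targeting perturbation labels.
#' @param tpm_min Gene tested when either side's mean TPM exceeds this
#'   (default 5).
#' @param q_threshold Significance threshold (default 0.05).
#' @param fc_threshold Expression fold-change rule (default 1.5).
#' @return Tibble `cluster`, `gene_id`, `test` (`dul`/`dge`), `effect`
#'   (mean dWUI or log2 fold change), `direction`
#'   (shortening/lengthening, down/up), `p`, `q`, `significant`.
#' @export
cluster_diff_tests <- function(profiles, clusters, non_targeting,
                               tpm_min = 5, q_threshold = 0.05,
                               fc_threshold = 1.5) {
  pr <- as_tibble(profiles)
  nt <- pr |> filter(.data$perturbation %in% non_targeting)
  purrr::map_dfr(sort(unique(clusters$cluster)), function(cl) {
    members <- clusters$id[clusters$cluster == cl]
    cp <- pr |> filter(.data$perturbation %in% members)
    genes <- intersect(unique(cp$gene_id), unique(nt$gene_id))
    res <- purrr::map_dfr(genes, function(g) {
      a <- cp |> filter(.data$gene_id == g)
      b <- nt |> filter(.data$gene_id == g)
      if (mean(a$tpm) <= tpm_min && mean(b$tpm) <= tpm_min) return(NULL)
      out <- list()
      wa <- a$wui[!is.na(a$wui)]; wb <- b$wui[!is.na(b$wui)]
      if (length(wa) >= 2 && length(wb) >= 2) {
        p <- if (length(unique(c(wa, wb))) == 1) 1 else
          suppressWarnings(wilcox.test(wa, wb)$p.value)
        out$dul <- tibble(test = "dul", effect = mean(wa) - mean(wb),
                          p = p)
      }
      p2 <- if (length(unique(c(a$tpm, b$tpm))) == 1) 1 else
        suppressWarnings(wilcox.test(a$tpm, b$tpm)$p.value)
      out$dge <- tibble(test = "dge",
                        effect = log2(mean(a$tpm) / mean(b$tpm)), p = p2)
      bind_rows(out) |> mutate(gene_id = g)
    })
    if (nrow(res) == 0) return(NULL)
    res |>
      mutate(cluster = cl) |>
      group_by(.data$test) |>
      mutate(q = bh_adjust(.data$p)) |>
      ungroup() |>
      mutate(
        direction = ifelse(.data$test == "dul",
                           ifelse(.data$effect < 0, "shortening",
                                  "lengthening"),
                           ifelse(.data$effect < 0, "down", "up")),
        significant = .data$q < q_threshold &
          (.data$test == "dul" |
             abs(.data$effect) > log2(fc_threshold))) |>
      select("cluster", "gene_id", "test", "effect", "direction",
             "p", "q", "significant")
  })
}

#' Classify compensation between two 3'UTR isoforms
#'
#' For two-isoform genes with significant differential UTR length in a
#' cluster, splits gene expression into short-UTR (SU) and long-UTR
#' (LU) isoform TPMs — `TPM_SU = mean(TPM) * (1 - mean(WUI))`,
#' `TPM_LU = mean(TPM) * mean(WUI)` — computes the cluster-vs-control
#' TPM change per isoform, and calls the regulation *coordinated*
#' (compensatory) when at least half of the expression gained by one
#' isoform is lost by the other:
#' `-shift_threshold >= dTPM_LU / dTPM_SU >= -1/shift_threshold`
#' (with the default 0.5: `-0.5 >= ratio >= -2`, bounds inclusive).
#' Otherwise the gene is SU-specific or LU-specific, whichever isoform
#' has the larger absolute TPM change.
#'
#' @param records Tibble with columns `gene_id`, `tpm_cluster`,
#'   `wui_cluster`, `tpm_control`, `wui_control` (means over
#'   perturbations), and optionally `cluster`.
#' @param shift_threshold Minimum compensated fraction (default 0.5).
#' @return `records` plus `tpm_su_cluster`, `tpm_lu_cluster`,
#'   `tpm_su_control`, `tpm_lu_control`, `dtpm_su`, `dtpm_lu`, `ratio`,
#'   `category` (`coordinated`/`SU-specific`/`LU-specific`; `NA` when
#'   both changes are zero).
#' @export
compensation_classify <- function(records, shift_threshold = 0.5) {
  lo <- -1 / shift_threshold
  hi <- -shift_threshold
  as_tibble(records) |>
    mutate(
      tpm_su_cluster = .data$tpm_cluster * (1 - .data$wui_cluster),
      tpm_lu_cluster = .data$tpm_cluster * .data$wui_cluster,
      tpm_su_control = .data$tpm_control * (1 - .data$wui_control),
      tpm_lu_control = .data$tpm_control * .data$wui_control,
      dtpm_su = .data$tpm_su_cluster - .data$tpm_su_control,
      dtpm_lu = .data$tpm_lu_cluster - .data$tpm_lu_control,
      ratio = ifelse(.data$dtpm_su == 0, NA_real_,
                     .data$dtpm_lu / .data$dtpm_su),
      category = dplyr::case_when(
        .data$dtpm_su == 0 & .data$dtpm_lu == 0 ~ NA_character_,
        .data$dtpm_su == 0 ~ "LU-specific",
        .data$ratio >= lo & .data$ratio <= hi ~ "coordinated",
        abs(.data$dtpm_su) >= abs(.data$dtpm_lu) ~ "SU-specific",
        TRUE ~ "LU-specific"
      )
    )
}

#' Overlap of differentially regulated gene sets between clusters
#'
#' Tests every ordered pair of (cluster, direction) gene sets for
#' enrichment of their overlap with a one-sided Fisher / hypergeometric
#' tail against a common gene universe. Same-direction pairs
#' (shortening with shortening, lengthening with lengthening) are
#' `synergistic`; opposite-direction pairs are `antagonistic`.
#'
#' @param gene_sets Tibble `cluster`, `direction`, `gene_id`.
#' @param universe Character vector of all testable genes.
#' @return Tibble `cluster1`, `direction1`, `cluster2`, `direction2`,
#'   `type`, `n1`, `n2`, `overlap`, `p`, `neg_log10_p` (one row per
#'   unordered pair of distinct sets).
#' @export
cluster_overlap <- function(gene_sets, universe) {
  sets <- gene_sets |>
    group_by(.data$cluster, .data$direction) |>
    summarise(genes = list(intersect(unique(.data$gene_id), universe)),
              .groups = "drop")
  n_u <- length(universe)
  if (nrow(sets) < 2) {
    return(tibble(cluster1 = character(), direction1 = character(),
                  cluster2 = character(), direction2 = character(),
                  type = character(), n1 = integer(), n2 = integer(),
                  overlap = integer(), p = numeric(),
                  neg_log10_p = numeric()))
  }
  pairs <- utils::combn(nrow(sets), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    g1 <- sets$genes[[i1]]; g2 <- sets$genes[[i2]]
    ov <- length(intersect(g1, g2))
    p <- if (length(g1) == 0 || length(g2) == 0) 1 else
      phyper(ov - 1, length(g1), n_u - length(g1), length(g2),
             lower.tail = FALSE)
    tibble(cluster1 = as.character(sets$cluster[i1]),
           direction1 = sets$direction[i1],
           cluster2 = as.character(sets$cluster[i2]),
           direction2 = sets$direction[i2],
           type = ifelse(sets$direction[i1] == sets$direction[i2],
                         "synergistic", "antagonistic"),
           n1 = length(g1), n2 = length(g2), overlap = ov, p = p,
           neg_log10_p = -log10(p))
  })
}

#' Validate perturbation clusters with replicate data
#'
#' Correlates each cluster's average z-scaled effect profile with the
#' profiles of replicating perturbations from an independent dataset,
#' using non-targeting perturbations from that dataset as a control
#' correlation distribution, and tests per cluster (one-sided
#' Mann-Whitney, alternative: replicate correlations greater) with BH
#' adjustment across clusters.
#'
#' @param cluster_avg Matrix clusters x genes of cluster-average
#'   z-scaled effects (rownames = cluster ids).
#' @param replicate_z Matrix replicate perturbations x genes.
#' @param replicate_clusters Tibble `id`, `cluster` mapping each
#'   replicate perturbation to the cluster it replicates.
#' @param control_z Matrix of non-targeting replicate profiles.
#' @param genes Optional gene subset (e.g. significant response genes)
#'   used for the correlations; defaults to the shared columns.
#' @return List: `per_cluster` tibble (`cluster`, `n_replicates`,
#'   `median_r`, `median_r_control`, `p`, `q`) and `correlations`
#'   tibble (`cluster`, `id`, `role`, `r`).
#' @export
validate_replicates <- function(cluster_avg, replicate_z,
                                replicate_clusters, control_z,
                                genes = NULL) {
  if (is.null(genes)) {
    genes <- Reduce(intersect, list(colnames(cluster_avg),
                                    colnames(replicate_z),
                                    colnames(control_z)))
  }
  if (length(genes) < 2) stop("fewer than 2 shared genes")
  cors <- purrr::map_dfr(rownames(cluster_avg), function(cl) {
    avg <- cluster_avg[cl, genes]
    reps <- replicate_clusters$id[replicate_clusters$cluster == cl]
    reps <- intersect(reps, rownames(replicate_z))
    bind_rows(
      tibble(cluster = cl, id = reps, role = "replicate",
             r = unname(vapply(reps, function(i)
               stats::cor(avg, replicate_z[i, genes]), numeric(1)))),
      tibble(cluster = cl, id = rownames(control_z), role = "control",
             r = unname(apply(control_z[, genes, drop = FALSE], 1,
                              function(v) stats::cor(avg, v))))
    )
  })
  per_cluster <- cors |>
    group_by(.data$cluster) |>
    summarise(
      n_replicates = sum(.data$role == "replicate"),
      median_r = stats::median(.data$r[.data$role == "replicate"]),
      median_r_control = stats::median(.data$r[.data$role == "control"]),
      p = if (sum(.data$role == "replicate") == 0) NA_real_ else
        suppressWarnings(wilcox.test(
          .data$r[.data$role == "replicate"],
          .data$r[.data$role == "control"],
          alternative = "greater")$p.value),
      .groups = "drop") |>
    mutate(q = bh_adjust(.data$p))
  list(per_cluster = per_cluster, correlations = cors)
}

#' Correlate per-gene effects with gene features
#'
#' Pearson-correlates the mean per-gene effect (e.g. mean dWUI) of each
#' cluster with numeric gene features, with BH adjustment within each
#' feature across clusters.
#'
#' @param gene_effects Tibble `cluster`, `gene_id`, `effect`.
#' @param features Tibble with `gene_id` plus one numeric column per
#'   feature; any numeric table is accepted.
#' @param min_genes Minimum genes with both values (default 3).
#' @return Tibble `cluster`, `feature`, `n`, `r`, `p`, `q`,
#'   `significant` (`q < 0.05`). Constant features give `NA`.
#' @export
feature_correlation <- function(gene_effects, features, min_genes = 3) {
  feat_cols <- setdiff(names(features), "gene_id")
  res <- purrr::map_dfr(sort(unique(gene_effects$cluster)), function(cl) {
    eff <- gene_effects |> filter(.data$cluster == cl)
    purrr::map_dfr(feat_cols, function(fc) {
      d <- inner_join(eff, features[, c("gene_id", fc)], by = "gene_id")
      v <- d[[fc]]
      ok <- !is.na(v) & !is.na(d$effect)
      if (sum(ok) < min_genes || sd(v[ok]) == 0 || sd(d$effect[ok]) == 0) {
        return(tibble(cluster = cl, feature = fc, n = sum(ok),
                      r = NA_real_, p = NA_real_))
      }
      ct <- cor.test(d$effect[ok], v[ok])
      tibble(cluster = cl, feature = fc, n = sum(ok),
             r = unname(ct$estimate), p = ct$p.value)
    })
  })
  res |>
    group_by(.data$feature) |>
    mutate(q = bh_adjust(.data$p)) |>
    ungroup() |>
    mutate(significant = !is.na(.data$q) & .data$q < 0.05)
}
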