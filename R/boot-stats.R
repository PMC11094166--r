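# Isoform-usage statistics (UI, weighted UTR index, Wasserstein
# distance) and the two-sample cell-level bootstrap test, vectorized so
# one resampling of cells serves every gene.

#' Positional rank weights for the weighted UTR index
#'
#' Weights are the positional rank of each cleavage site from 5' to 3'
#' scaled to the unit interval: a two-isoform gene has weights
#' `{0, 1}`, a three-isoform gene `{0, 1/2, 1}`, a four-isoform gene
#' `{0, 1/3, 2/3, 1}`, and so forth. With these weights the WUI of a
#' two-isoform gene is the expression fraction of the longest isoform.
#'
#' @param n_isoforms Number of isoforms (>= 2).
#' @return Numeric weight vector of length `n_isoforms`.
#' @export
positional_weights <- function(n_isoforms) {
  if (n_isoforms < 2) stop("positional weights require at least 2 isoforms")
  (seq_len(n_isoforms) - 1) / (n_isoforms - 1)
}

#' Per-gene isoform-usage statistics between two expression profiles
#'
#' Computes, per gene, the difference in isoform usage between two
#' profiles: `UI`, the difference in the expression fraction of a
#' flagged isoform; `WUI`, the difference in the positional-rank
#' weighted mean of isoform fractions; or `WD`, half the total absolute
#' difference in isoform fractions (the Wasserstein / earth-mover
#' distance on the discrete isoform set). For two-isoform genes the
#' three statistics agree in magnitude.
#'
#' @param profiles Tibble with columns `gene_id`, `isoform_id`,
#'   `count_a`, `count_b`; rows ordered 5' to 3' within each gene.
#' @param mode One of `"wui"`, `"ui"`, `"wd"`.
#' @param feature_index For `"ui"`: logical vector (aligned to
#'   `profiles` rows) or character vector of flagged isoform ids.
#' @param weights Optional custom weight vector aligned to rows;
#'   defaults to [positional_weights()] per gene.
#' @return Tibble `gene_id`, `statistic` (A minus B; genes with a zero
#'   total on either side are returned as `NA` with `tested = FALSE`).
#' @export
isoform_statistic <- function(profiles, mode = c("wui", "ui", "wd"),
                              feature_index = NULL, weights = NULL) {
  mode <- match.arg(mode)
  pr <- as_tibble(profiles)
  if (mode == "ui") {
    if (is.null(feature_index)) stop("UI mode requires feature_index")
    flag <- if (is.character(feature_index)) {
      pr$isoform_id %in% feature_index
    } else as.logical(feature_index)
  }
  if (is.null(weights)) {
    weights <- numeric(nrow(pr))
    for (idx in split(seq_len(nrow(pr)), pr$gene_id)) {
      weights[idx] <- if (length(idx) < 2) 0
                      else positional_weights(length(idx))
    }
  }
  pr$w <- weights
  if (mode == "ui") pr$flag <- flag
  pr |>
    group_by(.data$gene_id) |>
    summarise(statistic = {
      ta <- sum(.data$count_a); tb <- sum(.data$count_b)
      if (ta == 0 || tb == 0) NA_real_ else {
        fa <- .data$count_a / ta; fb <- .data$count_b / tb
        switch(mode,
               wui = sum(.data$w * fa) - sum(.data$w * fb),
               wd = 0.5 * sum(abs(fa - fb)),
               ui = sum(fa[.data$flag]) - sum(fb[.data$flag]))
      }
    }, .groups = "drop") |>
    mutate(tested = !is.na(.data$statistic))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `p.adjust(..., method = "BH")`, kept as a named
#' step so every q-value in the package flows through one place.
#'
#' @param p Numeric vector of p-values (`NA`s preserved).
#' @return Step-up BH q-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

# --- internal machinery shared by the bootstrap test and CIs ---------

# isoform-level gene structure of a cell_counts object: gene indicator
# (isoforms x genes, sparse), per-isoform positional weights, gene ids
iso_structure <- function(x, weights = NULL) {
  iso <- x$isoforms
  rank_col <- if ("rank" %in% names(iso)) iso$rank else seq_len(nrow(iso))
  genes <- unique(iso$gene_id)
  gi <- match(iso$gene_id, genes)
  w <- numeric(nrow(iso))
  for (idx in split(seq_len(nrow(iso)), gi)) {
    o <- order(rank_col[idx])
    w[idx[o]] <- if (length(idx) >= 2) positional_weights(length(idx)) else 0
  }
  if (!is.null(weights)) w <- weights
  G <- Matrix::sparseMatrix(i = seq_len(nrow(iso)), j = gi, x = 1,
                            dims = c(nrow(iso), length(genes)))
  list(genes = genes, gi = gi, w = w, G = G,
       n_iso = as.integer(Matrix::colSums(G)))
}

# per-gene statistic rows from pseudobulk matrices PA, PB (B x isoforms)
boot_statistics <- function(PA, PB, st, mode, flag = NULL) {
  TA <- as.matrix(PA %*% st$G)
  TB <- as.matrix(PB %*% st$G)
  if (mode == "wui") {
    WA <- as.matrix(PA %*% (st$G * st$w))
    WB <- as.matrix(PB %*% (st$G * st$w))
    stat <- WA / TA - WB / TB
  } else {
    FA <- as.matrix(PA) / TA[, st$gi, drop = FALSE]
    FB <- as.matrix(PB) / TB[, st$gi, drop = FALSE]
    if (mode == "wd") {
      stat <- 0.5 * as.matrix(abs(FA - FB) %*% st$G)
    } else {
      D <- FA - FB
      D[, !flag] <- 0
      stat <- as.matrix(D %*% st$G)
    }
  }
  stat[!is.finite(stat)] <- NA
  list(stat = stat, TA = TA, TB = TB)
}

# B x n multiplicity matrix of bootstrap draws from 1..n
boot_indicator <- function(n_draw, n_pool, B) {
  s <- sample.int(n_pool, n_draw * B, replace = TRUE)
  Matrix::sparseMatrix(i = rep(seq_len(B), each = n_draw), j = s, x = 1,
                       dims = c(B, n_pool))
}

#' Two-sample bootstrap test for differential isoform usage
#'
#' Tests, per gene, whether isoform usage differs between two groups of
#' cells. The statistic (`WUI` difference by default; `UI` or `WD`
#' alternatively) is computed on pseudobulk counts summed within each
#' group. Under the null that both groups are draws from one
#' population, cells are resampled with replacement from the union of
#' the two groups, preserving the original group sizes; the same
#' resampled cell sets serve every gene. The two-sided p-value is the
#' fraction of bootstrap statistics at least as extreme (in absolute
#' value) as the observed one, with a pseudocount of 1, so p is never
#' zero:
#' `p = (1 + #\{|T_b| >= |T_obs|\}) / (1 + B_valid)`.
#'
#' Genes must have at least `min_cells_per_gene` expressing cells
#' (>= 1 UMI) in each observed group to be tested at all; bootstrap
#' samples violating the same minimum for a gene are discarded for that
#' gene, and its p-value uses only the retained samples
#' (`n_bootstraps_retained`). Genes for which every bootstrap sample is
#' discarded get `NA`.
#'
#' @param x A [cell_counts()] object.
#' @param group_a,group_b Group labels in `x$cells$group`.
#' @param mode `"wui"` (default), `"ui"` or `"wd"`.
#' @param feature_index For `"ui"`: flagged isoform ids (character) or
#'   logical per isoform.
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param min_cells_per_gene Coexpression minimum (default 50).
#' @param weights Optional custom isoform weights (WUI mode).
#' @param seed Optional RNG seed.
#' @return A `utr_boot_test` object; [tidy()] (or the object itself,
#'   a tibble subclass) has columns `gene_id`, `statistic` (mode),
#'   `observed` (A minus B), `p`, `q` (BH), `n_bootstraps_retained`.
#' @export
two_sample_bootstrap_test <- function(x, group_a, group_b,
                                      mode = c("wui", "ui", "wd"),
                                      feature_index = NULL, n_boot = 1000,
                                      min_cells_per_gene = 50, weights = NULL,
                                      seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ia <- which(x$cells$group %in% group_a)
  ib <- which(x$cells$group %in% group_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty cell group")
  st <- iso_structure(x, weights)
  flag <- if (mode == "ui") {
    if (is.null(feature_index)) stop("UI mode requires feature_index")
    if (is.character(feature_index)) x$isoforms$isoform_id %in% feature_index
    else as.logical(feature_index)
  }
  testable <- st$n_iso >= 2 | (mode == "ui" & st$n_iso >= 1)

  U <- x$counts[c(ia, ib), , drop = FALSE]
  nA <- length(ia); nB <- length(ib); n <- nA + nB
  E <- Matrix::Matrix((U %*% st$G) > 0) * 1   # cell expresses gene

  obs_a <- Matrix::Matrix(Matrix::colSums(U[seq_len(nA), , drop = FALSE]),
                          nrow = 1, sparse = TRUE)
  obs_b <- Matrix::Matrix(Matrix::colSums(U[nA + seq_len(nB), , drop = FALSE]),
                          nrow = 1, sparse = TRUE)
  obs <- boot_statistics(obs_a, obs_b, st, mode, flag)
  expr_a <- Matrix::colSums(E[seq_len(nA), , drop = FALSE])
  expr_b <- Matrix::colSums(E[nA + seq_len(nB), , drop = FALSE])
  tested <- testable & expr_a >= min_cells_per_gene &
    expr_b >= min_cells_per_gene & is.finite(obs$stat[1, ])

  SA <- boot_indicator(nA, n, n_boot)
  SB <- boot_indicator(nB, n, n_boot)
  PA <- SA %*% U
  PB <- SB %*% U
  bs <- boot_statistics(PA, PB, st, mode, flag)
  valid <- as.matrix(SA %*% E) >= min_cells_per_gene &
    as.matrix(SB %*% E) >= min_cells_per_gene &
    !is.na(bs$stat)

  t_obs <- obs$stat[1, ]
  extreme <- sweep(abs(bs$stat), 2, abs(t_obs), ">=")
  n_valid <- colSums(valid)
  p <- (1 + colSums(extreme & valid, na.rm = TRUE)) / (1 + n_valid)
  p[n_valid == 0] <- NA

  res <- tibble(gene_id = st$genes, statistic = toupper(mode),
                observed = t_obs, p = p,
                n_bootstraps_retained = as.integer(n_valid))[tested, ]
  res$q <- bh_adjust(res$p)
  res <- res[, c("gene_id", "statistic", "observed", "p", "q",
                 "n_bootstraps_retained")]
  class(res) <- c("utr_boot_test", class(res))
  attr(res, "groups") <- c(paste(group_a, collapse = "+"),
                           paste(group_b, collapse = "+"))
  attr(res, "n_boot") <- n_boot
  attr(res, "min_cells_per_gene") <- min_cells_per_gene
  res
}

#' @method tidy utr_boot_test
#' @export
tidy.utr_boot_test <- function(x, ...) as_tibble(unclass_tbl(x))

#' @method glance utr_boot_test
#' @export
glance.utr_boot_test <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_significant = sum(x$q < 0.05, na.rm = TRUE),
         n_boot = attr(x, "n_boot"),
         min_cells_per_gene = attr(x, "min_cells_per_gene"),
         group_a = attr(x, "groups")[1], group_b = attr(x, "groups")[2])
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("utr_boot_test"))
  x
}

#' Bootstrap percentile confidence intervals per gene
#'
#' For one set of cells, resamples cells with replacement `n_boot`
#' times and computes either the mean per-cell TPM per gene (TPM here
#' means UMIs per million cell UMIs, no length normalization) or the
#' pseudobulk WUI per gene, returning the percentile interval of the
#' bootstrap distribution.
#'
#' @param x A [cell_counts()] object.
#' @param cells Cell selector: group label(s) or integer indices
#'   (default: all cells).
#' @param statistic `"tpm"` or `"wui"`.
#' @param n_boot Bootstrap samples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return Tibble `gene_id`, `estimate` (statistic on the original
#'   cells), `lower`, `upper`. Genes never expressed are `NA`.
#' @export
bootstrap_percentile_ci <- function(x, cells = NULL,
                                    statistic = c("tpm", "wui"),
                                    n_boot = 2000, level = 0.95,
                                    seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  idx <- if (is.null(cells)) seq_len(nrow(x$counts))
         else if (is.numeric(cells)) cells
         else which(x$cells$group %in% cells)
  U <- x$counts[idx, , drop = FALSE]
  st <- iso_structure(x)
  n <- nrow(U)
  S <- boot_indicator(n, n, n_boot)
  if (statistic == "tpm") {
    lib <- Matrix::rowSums(U)
    tpm_cells <- U / pmax(lib, 1) * 1e6
    gene_tpm <- as.matrix(tpm_cells %*% st$G)
    est <- colMeans(gene_tpm)
    boot <- as.matrix(S %*% gene_tpm) / n
  } else {
    P <- S %*% U
    tot_b <- as.matrix(P %*% st$G)
    W <- as.matrix(P %*% (st$G * st$w))
    boot <- W / tot_b
    tot <- Matrix::colSums(U)
    est <- as.numeric((tot %*% (st$G * st$w)) / (tot %*% st$G))
  }
  boot[!is.finite(boot)] <- NA
  a <- (1 - level) / 2
  ci <- apply(boot, 2, function(b) {
    b <- b[!is.na(b)]
    if (length(b) == 0) c(NA_real_, NA_real_)
    else unname(quantile(b, c(a, 1 - a)))
  })
  tibble(gene_id = st$genes, estimate = est,
         lower = ci[1, ], upper = ci[2, ])
}
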