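# Gene classification (single/multi-UTR, IPA), dominant-isoform
# switching, and the differential-expression vs differential-UTR-length
# independence analysis.

#' Pseudobulk isoform profiles per group
#'
#' Sums UMI counts over the cells of each group and returns a long
#' table of per-(group, gene, isoform) counts and within-gene fractions,
#' plus gene TPM (UMIs per million group UMIs). Fractions are computed
#' both over all isoforms of the gene and excluding IPA isoforms
#' (`frac_no_ipa`), the denominator used for 3'UTR isoform
#' classification.
#'
#' @param x A [cell_counts()] object with group labels.
#' @return Tibble `group`, `gene_id`, `isoform_id`, `rank`, `is_ipa`,
#'   `count`, `frac`, `frac_no_ipa`, `gene_tpm`, `n_cells`.
#' @export
pseudobulk_profiles <- function(x) {
  groups <- sort(unique(x$cells$group))
  iso <- x$isoforms
  if (!"is_ipa" %in% names(iso)) iso$is_ipa <- FALSE
  if (!"rank" %in% names(iso)) {
    iso$rank <- stats::ave(seq_len(nrow(iso)), iso$gene_id,
                           FUN = seq_along)
  }
  purrr::map_dfr(groups, function(g) {
    rows <- x$cells$group == g
    cnt <- Matrix::colSums(x$counts[rows, , drop = FALSE])
    tot <- sum(cnt)
    d <- tibble(group = g, gene_id = iso$gene_id,
                isoform_id = iso$isoform_id, rank = iso$rank,
                is_ipa = iso$is_ipa, count = cnt, n_cells = sum(rows))
    d |>
      group_by(.data$gene_id) |>
      mutate(frac = if (sum(.data$count) > 0) .data$count / sum(.data$count)
                    else NA_real_,
             frac_no_ipa = {
               tot_ni <- sum(.data$count[!.data$is_ipa])
               ifelse(.data$is_ipa, NA_real_,
                      if (tot_ni > 0) .data$count / tot_ni else NA_real_)
             },
             gene_tpm = sum(.data$count[!.data$is_ipa]) / tot * 1e6) |>
      ungroup()
  })
}

#' Classify genes as single- or multi-UTR
#'
#' A 3'UTR isoform qualifies when it reaches at least `threshold`
#' (default 10 percent) of the gene's non-IPA expression in at least
#' one cell type; genes with two or more qualifying isoforms are
#' multi-UTR, all others single-UTR. Isoforms whose 3' ends lie in
#' annotated introns (IPA) are excluded from both numerator and
#' denominator.
#'
#' @param profiles Output of [pseudobulk_profiles()] (or any tibble
#'   with `group`, `gene_id`, `isoform_id`, `is_ipa`, `frac_no_ipa`).
#' @param threshold Qualifying expression fraction (default 0.10,
#'   inclusive).
#' @return Tibble `gene_id`, `n_qualifying_isoforms`, `utr_class`
#'   (`single`/`multi`), `qualifying_isoforms` (list column).
#' @export
classify_utr_genes <- function(profiles, threshold = 0.10) {
  profiles |>
    filter(!.data$is_ipa) |>
    group_by(.data$gene_id, .data$isoform_id) |>
    summarise(qualifies = any(!is.na(.data$frac_no_ipa) &
                                .data$frac_no_ipa >= threshold),
              .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(n_qualifying_isoforms = sum(.data$qualifies),
              qualifying_isoforms = list(.data$isoform_id[.data$qualifies]),
              .groups = "drop") |>
    mutate(utr_class = ifelse(.data$n_qualifying_isoforms >= 2,
                              "multi", "single"))
}

#' Flag genes with expressed intronic-polyadenylation isoforms
#'
#' A gene is an IPA gene when any of its IPA isoforms carries at least
#' `threshold` of the gene's total reads (all 3' ends of the
#' transcription unit included) in at least one cell type.
#'
#' @inheritParams classify_utr_genes
#' @return Tibble `gene_id`, `is_ipa_gene`.
#' @export
classify_ipa_genes <- function(profiles, threshold = 0.10) {
  profiles |>
    group_by(.data$gene_id) |>
    summarise(is_ipa_gene = any(.data$is_ipa & !is.na(.data$frac) &
                                  .data$frac >= threshold), .groups = "drop")
}

#' Dominant-isoform switching across cell types
#'
#' For each multi-UTR gene, identifies the dominant (highest expression
#' fraction) non-IPA isoform in every qualifying cell type — cell types
#' with at least `min_cells` cells where the gene exceeds `min_tpm`
#' (excluding IPA) — and flags the gene as switching when the dominant
#' isoform differs across qualifying cell types. Ties within a cell
#' type resolve to the more 3' (higher rank) isoform.
#'
#' @param profiles Output of [pseudobulk_profiles()].
#' @param genes Optional vector restricting to (multi-UTR) genes.
#' @param min_cells Minimum cells per qualifying cell type (default 200).
#' @param min_tpm Minimum gene TPM per qualifying cell type (default 5).
#' @return Tibble `gene_id`, `n_celltypes`, `switching` (`NA` when
#'   fewer than 2 qualifying cell types), `dominant` (list column of
#'   per-cell-type dominant isoform ids).
#' @export
dominant_switching <- function(profiles, genes = NULL, min_cells = 200,
                               min_tpm = 5) {
  pr <- profiles |> filter(!.data$is_ipa, .data$n_cells >= min_cells,
                           .data$gene_tpm > min_tpm)
  if (!is.null(genes)) pr <- pr |> filter(.data$gene_id %in% genes)
  pr |>
    group_by(.data$gene_id, .data$group) |>
    summarise(dominant = {
      o <- order(-.data$frac_no_ipa, -.data$rank)
      .data$isoform_id[o][1]
    }, .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(n_celltypes = dplyr::n(),
              switching = if (dplyr::n() < 2) NA
                          else length(unique(.data$dominant)) > 1,
              dominant = list(setNames(.data$dominant, .data$group)),
              .groups = "drop")
}

# Vectorized Welch t statistics over the columns of two matrices
# (cells x genes); cross-checked against stats::t.test in the suite.
welch_cols <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, var); vB <- apply(B, 2, var)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(-abs(t), df)
  # equal means with zero variance on both sides: no evidence, p = 1
  degenerate <- se2 == 0
  t[degenerate] <- 0
  p[degenerate] <- 1
  list(t = t, df = df, p = p, mean_a = mA, mean_b = mB)
}

#' Welch differential gene expression on log-normalized counts
#'
#' Gene-level UMI counts are normalized by per-cell size factors,
#' log2-transformed with a pseudocount of 1, and compared between two
#' groups with a per-gene Welch t-test. Fold changes come from the
#' de-logged group means, q-values from Benjamini-Hochberg; a gene is
#' significant when its fold change exceeds `fc_threshold` in either
#' direction and `q < q_threshold`.
#'
#' @param x A [cell_counts()] object (isoform counts are summed to the
#'   gene level).
#' @param group_a,group_b Group labels.
#' @param size_factors Optional per-cell size factors (aligned to
#'   `x$cells`); defaults to library size scaled to mean 1. A hook for
#'   externally computed factors (e.g. pooling-based).
#' @param fc_threshold,q_threshold Significance rule (defaults 1.5 and
#'   0.05).
#' @return Tibble `gene_id`, `log2FC` (A over B), `t`, `df`, `dge_p`,
#'   `dge_q`, `dge_sig`.
#' @export
dge_welch <- function(x, group_a, group_b, size_factors = NULL,
                      fc_threshold = 1.5, q_threshold = 0.05) {
  st <- iso_structure(x)
  gene_counts <- x$counts %*% st$G
  if (is.null(size_factors)) {
    lib <- Matrix::rowSums(x$counts)
    size_factors <- lib / mean(lib)
  }
  norm <- log2(as.matrix(gene_counts / size_factors) + 1)
  ia <- x$cells$group %in% group_a
  ib <- x$cells$group %in% group_b
  if (sum(ia) < 2 || sum(ib) < 2) stop("need >= 2 cells per group")
  w <- welch_cols(norm[ia, , drop = FALSE], norm[ib, , drop = FALSE])
  res <- tibble(gene_id = st$genes, log2FC = w$mean_a - w$mean_b,
                t = w$t, df = w$df, dge_p = w$p)
  res$dge_q <- bh_adjust(res$dge_p)
  res$dge_sig <- abs(res$log2FC) > log2(fc_threshold) &
    !is.na(res$dge_q) & res$dge_q < q_threshold
  res
}

#' Cross-classify genes by DGE and DUL significance
#'
#' Joins Welch differential-expression results with bootstrap
#' differential-UTR-length results and assigns every gene to exactly
#' one of `none`, `DGE-only`, `DUL-only`, `both`. DUL significance
#' follows the effect-size rule `|dWUI| > dwui_threshold` and
#' `q < q_threshold`.
#'
#' @param dge Output of [dge_welch()].
#' @param dul A `utr_boot_test` (WUI mode) or tibble with `gene_id`,
#'   `observed`, `q`.
#' @param dwui_threshold Minimum absolute WUI difference (default 0.10).
#' @param q_threshold FDR threshold for DUL (default 0.05).
#' @return Tibble `gene_id`, `log2FC`, `dge_q`, `dge_sig`, `dWUI`,
#'   `dul_q`, `dul_sig`, `category`; one row per gene present in both
#'   inputs (the coexpressed genes).
#' @export
dge_dul_categories <- function(dge, dul, dwui_threshold = 0.10,
                               q_threshold = 0.05) {
  dul_tbl <- as_tibble(unclass(dul)[c("gene_id", "observed", "q")]) |>
    rename(dWUI = "observed", dul_q = "q") |>
    mutate(dul_sig = abs(.data$dWUI) > dwui_threshold &
             !is.na(.data$dul_q) & .data$dul_q < q_threshold)
  inner_join(dge[, c("gene_id", "log2FC", "dge_q", "dge_sig")], dul_tbl,
             by = "gene_id") |>
    mutate(category = dplyr::case_when(
      .data$dge_sig & .data$dul_sig ~ "both",
      .data$dge_sig ~ "DGE-only",
      .data$dul_sig ~ "DUL-only",
      TRUE ~ "none"
    ))
}

#' Chi-square test of DGE/DUL independence
#'
#' Tabulates DGE significance against DUL significance over coexpressed
#' multi-UTR genes and tests independence with a chi-square test. The
#' Yates-corrected test (the standard 2x2 default) is reported as
#' primary; the uncorrected statistic `n(ad-bc)^2/(r1 r2 c1 c2)` is
#' returned alongside.
#'
#' @param categories Output of [dge_dul_categories()] (or any tibble
#'   with logical `dge_sig`, `dul_sig`).
#' @return One-row tibble: `statistic`, `p_value` (Yates),
#'   `statistic_uncorrected`, `p_uncorrected`, `df`, the four cell
#'   counts, and `flag` (`"degenerate"` when a margin is empty, with
#'   `NA` statistics).
#' @export
dge_dul_independence <- function(categories) {
  tab <- table(factor(categories$dge_sig, levels = c(FALSE, TRUE)),
               factor(categories$dul_sig, levels = c(FALSE, TRUE)))
  cells <- tibble(n_none = tab[1, 1], n_dge_only = tab[2, 1],
                  n_dul_only = tab[1, 2], n_both = tab[2, 2])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(bind_cols(tibble(statistic = NA_real_, p_value = NA_real_,
                            statistic_uncorrected = NA_real_,
                            p_uncorrected = NA_real_, df = 1L,
                            flag = "degenerate"), cells))
  }
  yates <- suppressWarnings(chisq.test(tab, correct = TRUE))
  plain <- suppressWarnings(chisq.test(tab, correct = FALSE))
  bind_cols(tibble(statistic = unname(yates$statistic),
                   p_value = yates$p.value,
                   statistic_uncorrected = unname(plain$statistic),
                   p_uncorrected = plain$p.value,
                   df = unname(yates$parameter), flag = NA_character_),
            cells)
}

#' Fraction of DUL genes driven by the lower-abundance isoform
#'
#' For significant two-UTR genes, identifies the isoform with the
#' largest absolute log fold change (in the cell type of lower gene
#' expression) and asks whether that isoform is the lower-abundance one
#' there. Genes whose isoforms tie in abundance are excluded.
#'
#' @param iso_changes Tibble with one row per isoform of each
#'   qualifying two-UTR gene: `gene_id`, `isoform_id`, `abundance`
#'   (expression fraction in the lower-expression cell type), `log2fc`.
#' @return List: `fraction` (of genes where the larger change falls on
#'   the lower-abundance isoform; `NA` when no gene qualifies) and
#'   `per_gene` tibble (`gene_id`, `top_isoform`, `counted`,
#'   `excluded_tie`).
#' @export
minor_isoform_dominance <- function(iso_changes) {
  per_gene <- iso_changes |>
    group_by(.data$gene_id) |>
    dplyr::reframe({
      tie <- length(unique(.data$abundance)) == 1
      top <- .data$isoform_id[which.max(abs(.data$log2fc))]
      ab <- setNames(.data$abundance, .data$isoform_id)
      tibble(top_isoform = top, excluded_tie = tie,
             counted = if (tie) NA else unname(ab[top] == min(ab)))
    })
  qualifying <- per_gene$counted[!per_gene$excluded_tie]
  list(fraction = if (length(qualifying) == 0) NA_real_
                  else mean(qualifying),
       per_gene = per_gene)
}
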