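# Gene classification, isoform switching, Welch DGE and the DGE/DUL
# independence machinery.

profiles_from <- function(fracs_by_group, ipa = NULL) {
  # fracs_by_group: named list group -> numeric isoform fractions
  k <- length(fracs_by_group[[1]])
  iso <- tibble::tibble(isoform_id = paste0("i", seq_len(k)),
                        gene_id = "g1", rank = seq_len(k),
                        is_ipa = if (is.null(ipa)) rep(FALSE, k) else ipa)
  purrr::map_dfr(names(fracs_by_group), function(g) {
    f <- fracs_by_group[[g]]
    no_ipa_tot <- sum(f[!iso$is_ipa])
    tibble::tibble(group = g, gene_id = "g1", isoform_id = iso$isoform_id,
                   rank = iso$rank, is_ipa = iso$is_ipa,
                   count = f * 1000, n_cells = 300,
                   frac = f / sum(f),
                   frac_no_ipa = ifelse(iso$is_ipa, NA, f / no_ipa_tot),
                   gene_tpm = 50)
  })
}

test_that("multi-UTR classification uses the inclusive 10% rule", {
  multi <- classify_utr_genes(profiles_from(list(A = c(0.90, 0.10))))
  expect_equal(multi$utr_class, "multi")
  expect_equal(multi$n_qualifying_isoforms, 2L)

  single <- classify_utr_genes(profiles_from(list(A = c(0.95, 0.05),
                                                  B = c(0.95, 0.05))))
  expect_equal(single$utr_class, "single")

  one <- classify_utr_genes(profiles_from(list(A = 1)))
  expect_equal(one$utr_class, "single")

  # monotone: adding a cell type can only raise the qualifying count
  base <- classify_utr_genes(profiles_from(list(A = c(0.95, 0.05))))
  more <- classify_utr_genes(profiles_from(list(A = c(0.95, 0.05),
                                                B = c(0.85, 0.15))))
  expect_gte(more$n_qualifying_isoforms, base$n_qualifying_isoforms)
})

test_that("IPA genes are flagged from total-gene fractions", {
  pr <- profiles_from(list(A = c(0.88, 0.12)), ipa = c(FALSE, TRUE))
  expect_true(classify_ipa_genes(pr)$is_ipa_gene)
  pr2 <- profiles_from(list(A = c(0.91, 0.09)), ipa = c(FALSE, TRUE))
  expect_false(classify_ipa_genes(pr2)$is_ipa_gene)
  pr3 <- profiles_from(list(A = c(0.5, 0.5)))
  expect_false(classify_ipa_genes(pr3)$is_ipa_gene)
})

test_that("pseudobulk profiles sum cells and exclude IPA from the
          classification denominator", {
  counts <- rbind(c(4, 6, 2), c(0, 2, 2))
  cc <- cell_counts(counts,
                    tibble::tibble(barcode = c("c1", "c2"), group = "A"),
                    tibble::tibble(isoform_id = c("i1", "i2", "ipa"),
                                   gene_id = "g1", rank = c(1, 2, 3),
                                   is_ipa = c(FALSE, FALSE, TRUE)))
  pr <- pseudobulk_profiles(cc)
  expect_equal(pr$count, c(4, 8, 4), ignore_attr = TRUE)
  expect_equal(pr$frac, c(0.25, 0.5, 0.25), ignore_attr = TRUE)
  expect_equal(pr$frac_no_ipa, c(4 / 12, 8 / 12, NA), ignore_attr = TRUE)
  expect_equal(unique(pr$gene_tpm), 12 / 16 * 1e6)
})

test_that("switching requires a different dominant isoform somewhere", {
  mk <- function(fr) profiles_from(fr)
  sw <- dominant_switching(mk(list(A = c(0.8, 0.2), B = c(0.7, 0.3),
                                   C = c(0.2, 0.8))),
                           min_cells = 200, min_tpm = 5)
  expect_true(sw$switching)
  ns <- dominant_switching(mk(list(A = c(0.8, 0.2), B = c(0.7, 0.3))))
  expect_false(ns$switching)
  # tie resolves to the more 3' isoform, deterministically
  tie <- dominant_switching(mk(list(A = c(0.5, 0.5), B = c(0.2, 0.8))))
  expect_false(tie$switching)
  expect_equal(unname(tie$dominant[[1]]), c("i2", "i2"))
  # fewer than 2 qualifying cell types: NA
  na <- dominant_switching(mk(list(A = c(0.8, 0.2))))
  expect_true(is.na(na$switching))
})

test_that("Welch DGE matches the textbook example and t.test oracle", {
  # per-cell gene counts chosen so log2(count + 1) = (1,2,3) vs (2,3,4)
  counts <- matrix(c(1, 3, 7, 3, 7, 15), ncol = 1)
  cc <- cell_counts(counts,
                    tibble::tibble(barcode = sprintf("c%d", 1:6),
                                   group = rep(c("A", "B"), each = 3)),
                    tibble::tibble(isoform_id = "i1", gene_id = "g1"))
  res <- dge_welch(cc, "A", "B", size_factors = rep(1, 6))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  orc <- oracle_welch(log2(c(1, 3, 7) + 1), log2(c(3, 7, 15) + 1))
  expect_equal(res$t, orc$t)
  expect_equal(res$dge_p, orc$p, tolerance = 1e-12)
  expect_equal(res$dge_p, 0.2878641, tolerance = 1e-6)

  # identical groups: p = 1, FC = 1
  same <- cell_counts(matrix(c(2, 2, 2, 2), ncol = 1),
                      tibble::tibble(barcode = sprintf("c%d", 1:4),
                                     group = rep(c("A", "B"), each = 2)),
                      tibble::tibble(isoform_id = "i", gene_id = "g"))
  rs <- dge_welch(same, "A", "B", size_factors = rep(1, 4))
  expect_equal(rs$dge_p, 1)
  expect_equal(rs$log2FC, 0)
})

test_that("vectorized Welch agrees with per-gene t.test on a fixture", {
  fx <- generate_fixture(cells_per_group = c(A = 30, B = 30), n_genes = 12,
                         wui = 0.5, mean_count = 10,
                         fc = list(A = 1, B = 1.6), seed = 13)
  res <- dge_welch(fx$counts, "A", "B")
  st <- fx$counts$counts %*% Matrix::sparseMatrix(
    i = seq_len(ncol(fx$counts$counts)),
    j = match(fx$counts$isoforms$gene_id, unique(fx$counts$isoforms$gene_id)),
    x = 1)
  lib <- Matrix::rowSums(fx$counts$counts)
  norm <- log2(as.matrix(st / (lib / mean(lib))) + 1)
  grp <- fx$counts$cells$group
  for (j in sample(ncol(norm), 5)) {
    orc <- oracle_welch(norm[grp == "A", j], norm[grp == "B", j])
    expect_equal(res$dge_p[j], orc$p, tolerance = 1e-10)
    expect_equal(res$t[j], orc$t, tolerance = 1e-10)
  }
})

test_that("planted fold changes are detected with high power", {
  # 2-fold change planted in a quarter of the genes, the rest null, so
  # library-size factors do not absorb the shift
  fx <- generate_fixture(cells_per_group = c(A = 300, B = 300), n_genes = 40,
                         wui = 0.5, mean_count = 8,
                         fc = list(A = 1, B = rep(c(2, 1), c(10, 30))),
                         seed = 17)
  res <- dge_welch(fx$counts, "A", "B")
  planted <- res$gene_id %in% sprintf("gene%03d", 1:10)
  expect_gt(mean(res$dge_sig[planted]), 0.95)
  expect_lt(mean(res$dge_sig[!planted]), 0.2)
})

test_that("DGE/DUL categories partition genes and feed the chi-square", {
  cats <- tibble::tibble(
    dge_sig = rep(c(FALSE, TRUE, FALSE, TRUE), c(10, 30, 20, 40)),
    dul_sig = rep(c(FALSE, FALSE, TRUE, TRUE), c(10, 30, 20, 40)))
  res <- dge_dul_independence(cats)
  # closed form n(ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$statistic_uncorrected, 0.7936508, tolerance = 1e-6)
  expect_equal(res$df, 1L)
  expect_lt(res$statistic, res$statistic_uncorrected)  # Yates shrinks

  # perfectly proportional table: chi-square 0, p 1
  prop <- tibble::tibble(dge_sig = rep(c(TRUE, FALSE), c(50, 50)),
                         dul_sig = rep(c(TRUE, FALSE, TRUE, FALSE),
                                       c(20, 30, 20, 30)))
  rp <- dge_dul_independence(prop)
  expect_equal(rp$statistic_uncorrected, 0)
  expect_equal(rp$p_uncorrected, 1)
  # degenerate margin flagged
  deg <- dge_dul_independence(tibble::tibble(dge_sig = c(TRUE, TRUE),
                                             dul_sig = c(TRUE, FALSE)))
  expect_equal(deg$flag, "degenerate")
  expect_true(is.na(deg$statistic))
})

test_that("category assignment is a single-label partition", {
  dge <- tibble::tibble(gene_id = paste0("g", 1:4),
                        log2FC = c(2, 0, 2, 0),
                        dge_q = c(0.01, 0.5, 0.01, 0.5),
                        dge_sig = c(TRUE, FALSE, TRUE, FALSE))
  dul <- tibble::tibble(gene_id = paste0("g", 1:4),
                        observed = c(0.3, 0.3, 0.01, 0.01),
                        q = c(0.01, 0.01, 0.5, 0.5))
  cats <- dge_dul_categories(dge, dul)
  expect_equal(cats$category, c("both", "DUL-only", "DGE-only", "none"))
  expect_equal(nrow(cats), 4L)
})

test_that("minor-isoform dominance counts the lower-abundance isoform", {
  iso <- tibble::tibble(gene_id = c("g1", "g1"),
                        isoform_id = c("a", "b"),
                        abundance = c(0.8, 0.2), log2fc = c(0.3, 1.5))
  res <- minor_isoform_dominance(iso)
  expect_equal(res$fraction, 1)
  expect_true(res$per_gene$counted)
  # equal abundance: tie excluded
  tie <- tibble::tibble(gene_id = "g2", isoform_id = c("a", "b"),
                        abundance = c(0.5, 0.5), log2fc = c(1, 2))
  rt <- minor_isoform_dominance(tie)
  expect_true(is.na(rt$fraction))
  # larger change on the abundant isoform is not counted
  maj <- tibble::tibble(gene_id = "g3", isoform_id = c("a", "b"),
                        abundance = c(0.8, 0.2), log2fc = c(1.5, 0.3))
  expect_equal(minor_isoform_dominance(maj)$fraction, 0)
})
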