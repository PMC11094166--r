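# Effect matrices, z-scaling, clustering, cluster tests, compensation,
# overlap, replicate validation, feature correlations, and decay fits.

mk_profiles <- function(df) {
  # fill in optional columns with sensible defaults
  if (!"tpm" %in% names(df)) df$tpm <- 50
  if (!"n_cells" %in% names(df)) df$n_cells <- 100
  if (!"detect_rate" %in% names(df)) df$detect_rate <- 1
  if (!"ipa" %in% names(df)) df$ipa <- NA_real_
  df
}

test_that("dWUI effects subtract the cell-weighted baseline", {
  pr <- mk_profiles(tibble::tibble(
    perturbation = c("nt1", "nt2", "p1"),
    gene_id = "g1",
    wui = c(0.55, 0.65, 0.45),
    n_cells = c(100, 100, 40)))
  eff <- compute_effects(pr, non_targeting = c("nt1", "nt2"))
  expect_equal(eff$baseline$baseline, 0.60)
  expect_equal(unname(eff$effects["p1", "g1"]), -0.15)
  expect_equal(eff$perturbations$avg_effect, -0.15)
})

test_that("effect averages respect TPM, band and cell-count filters", {
  pr <- mk_profiles(tibble::tibble(
    perturbation = rep(c("nt1", "p1", "p2"), each = 3),
    gene_id = rep(c("g_ok", "g_lowtpm", "g_extreme"), 3),
    wui = c(0.5, 0.5, 0.95, 0.3, 0.3, 0.80, 0.4, 0.4, 0.90),
    tpm = rep(c(50, 4, 50), 3),
    n_cells = rep(c(100, 50, 10), each = 3)))
  eff <- compute_effects(pr, "nt1")
  # p2 has < 30 cells: absent entirely
  expect_equal(rownames(eff$effects), "p1")
  # averages use only g_ok (low TPM and out-of-band genes excluded)
  expect_equal(eff$baseline$in_band,
               c(c(g_extreme = FALSE, g_lowtpm = FALSE, g_ok = TRUE)),
               ignore_attr = TRUE)
  expect_equal(eff$perturbations$avg_effect, -0.2)
  expect_error(compute_effects(pr, "nope"), "non-targeting")
})

test_that("z-scaling is uncentered, sign-preserving and idempotent", {
  pr <- mk_profiles(tidyr::expand_grid(
    perturbation = c("nt1", "p1", "p2"),
    gene_id = paste0("g", 1:4)))
  pr$wui <- 0.5
  pr$tpm <- 50
  pr <- dplyr::mutate(pr, wui = ifelse(perturbation == "p1",
                                       0.5 + c(0.1, -0.1, 0.2, -0.2), wui))
  eff <- compute_effects(pr, "nt1", min_cells = 1)
  z <- zscale_impute(eff, min_control_tpm = 5)$z
  expect_equal(mean(z["p1", ]^2), 1)
  expect_equal(sign(z["p1", ]), sign(eff$effects["p1", ]))
  # all-baseline row has zero variance: left as zeros and flagged
  expect_equal(unname(z["p2", ]), rep(0, 4))
  expect_equal(attr(z, "zero_variance"), "p2")
  # scaling an already unit-variance row changes nothing
  eff2 <- eff
  eff2$effects <- rbind(z)
  z2 <- zscale_impute(eff2, min_control_tpm = 5)$z
  expect_equal(z2["p1", ], z["p1", ])
})

test_that("missing effects impute to zero and gene filters apply", {
  pr <- mk_profiles(tibble::tibble(
    perturbation = c("nt1", "nt1", "p1", "p1"),
    gene_id = c("g1", "g2", "g1", "g2"),
    wui = c(0.5, 0.5, NA, 0.7),
    tpm = c(50, 50, 50, 50),
    detect_rate = c(1, 1, 1, 1)))
  eff <- compute_effects(pr, "nt1", min_cells = 1)
  expect_true(is.na(eff$effects["p1", "g1"]))
  z <- zscale_impute(eff, min_control_tpm = 5)$z
  expect_equal(unname(z["p1", "g1"]), 0)
  # low-TPM gene dropped before scaling
  pr2 <- dplyr::mutate(pr, tpm = ifelse(gene_id == "g2", 10, 50))
  z2 <- zscale_impute(compute_effects(pr2, "nt1", min_cells = 1),
                      min_control_tpm = 20)$z
  expect_equal(colnames(z2), "g1")
})

test_that("planted perturbation modules are recovered", {
  em <- generate_effect_matrix(60, 300, 3, noise_sd = 0.3, seed = 5)
  cl <- cluster_perturbations(em$z, rounds = list(
    list(axis = "perturbations", n_pcs = 30, k = 5,
         drop_patternless = FALSE)))
  lab <- cl$perturbation_clusters
  ari <- adjusted_rand_index(
    lab$cluster[match(em$modules$perturbation, lab$id)], em$modules$module)
  expect_gt(ari, 0.9)
})

test_that("clustering handles trivial and permuted inputs", {
  set.seed(4)
  z <- matrix(rep(c(1, -1), c(8, 8)), 16, 10)   # rows 1-8 vs rows 9-16
  z <- z + matrix(rnorm(160, sd = 0.05), 16, 10)
  rownames(z) <- sprintf("p%02d", 1:16)
  colnames(z) <- sprintf("g%02d", 1:10)
  cl <- cluster_perturbations(z, rounds = list(
    list(axis = "perturbations", n_pcs = 5, k = 3,
         drop_patternless = FALSE)))
  expect_equal(length(unique(cl$perturbation_clusters$cluster)), 2L)

  # permuting rows permutes labels consistently
  perm <- sample(16)
  cl2 <- cluster_perturbations(z[perm, ], rounds = list(
    list(axis = "perturbations", n_pcs = 5, k = 3,
         drop_patternless = FALSE)))
  m1 <- cl$perturbation_clusters
  m2 <- cl2$perturbation_clusters
  expect_equal(adjusted_rand_index(m1$cluster[match(m2$id, m1$id)],
                                   m2$cluster), 1)
})

test_that("patternless rounds drop weak clusters before the final round", {
  set.seed(8)
  strong <- generate_effect_matrix(40, 100, 2, signal = 2, noise_sd = 0.2,
                                   seed = 3)
  weak <- matrix(rnorm(20 * 100, sd = 0.05), 20, 100,
                 dimnames = list(sprintf("weak%02d", 1:20),
                                 colnames(strong$z)))
  z <- rbind(strong$z, weak)
  cl <- cluster_perturbations(z, rounds = list(
    list(axis = "perturbations", n_pcs = 10, k = 5,
         drop_patternless = TRUE),
    list(axis = "perturbations", n_pcs = 10, k = 5,
         drop_patternless = FALSE)),
    dispersion_quantile = 0.4)
  kept <- cl$perturbation_clusters$id
  expect_lt(mean(startsWith(kept, "weak")), 0.2)
  expect_gt(mean(startsWith(kept, "pert")), 0.9)
})

test_that("cluster Mann-Whitney tests match exact enumeration", {
  pr <- mk_profiles(tibble::tibble(
    perturbation = c(paste0("nt", 1:3), paste0("p", 1:3)),
    gene_id = "g1",
    wui = c(0.6, 0.65, 0.7, 0.2, 0.25, 0.3),
    tpm = 50))
  res <- cluster_diff_tests(pr, tibble::tibble(id = paste0("p", 1:3),
                                               cluster = 1),
                            non_targeting = paste0("nt", 1:3))
  dul <- res[res$test == "dul", ]
  # U = 0 with n = m = 3: exact two-sided p = 2 * 1/C(6,3) = 0.1
  expect_equal(dul$p, 0.1)
  expect_equal(dul$direction, "shortening")
  expect_equal(dul$effect, -0.4, tolerance = 1e-9)
  # identical distributions: p ~ 1
  pr2 <- dplyr::mutate(pr, wui = rep(c(0.6, 0.65, 0.7), 2), tpm = 50)
  res2 <- cluster_diff_tests(pr2, tibble::tibble(id = paste0("p", 1:3),
                                                 cluster = 1),
                             non_targeting = paste0("nt", 1:3))
  expect_gte(res2$p[res2$test == "dul"], 1)
})

test_that("planted shortening is detected across many genes", {
  set.seed(10)
  genes <- paste0("g", sprintf("%02d", 1:50))
  mk <- function(ids, shift) {
    purrr::map_dfr(ids, function(p) {
      tibble::tibble(perturbation = p, gene_id = genes,
                     wui = pmin(pmax(rnorm(50, 0.6 + shift, 0.03), 0), 1),
                     tpm = 50, n_cells = 100, detect_rate = 1,
                     ipa = NA_real_)
    })
  }
  pr <- dplyr::bind_rows(mk(paste0("nt", 1:20), 0),
                         mk(paste0("p", 1:20), -0.15))
  res <- cluster_diff_tests(pr, tibble::tibble(id = paste0("p", 1:20),
                                               cluster = 1),
                            non_targeting = paste0("nt", 1:20))
  dul <- res[res$test == "dul", ]
  expect_gte(sum(dul$q < 0.05 & dul$direction == "shortening"), 45)
})

test_that("compensation classification reproduces the worked examples", {
  rec <- tibble::tibble(
    gene_id = c("coord", "su", "boundary"),
    tpm_control = 100, wui_control = 0.5,
    tpm_cluster = c(100, 120, 100),
    wui_cluster = c(0.3, 5 / 12, NA))
  # boundary case: engineer ratio exactly -2 (dSU = +10, dLU = -20)
  rec$tpm_cluster[3] <- 90
  rec$wui_cluster[3] <- 30 / 90
  out <- compensation_classify(rec)
  expect_equal(out$dtpm_su[1], 20)
  expect_equal(out$dtpm_lu[1], -20)
  expect_equal(out$category[1], "coordinated")    # ratio -1
  expect_equal(out$dtpm_su[2], 20)
  expect_equal(out$dtpm_lu[2], 0)
  expect_equal(out$category[2], "SU-specific")    # ratio 0
  expect_equal(out$ratio[3], -2)
  expect_equal(out$category[3], "coordinated")    # inclusive bound
  # degenerate cases
  none <- compensation_classify(tibble::tibble(
    gene_id = "x", tpm_control = 100, wui_control = 0.5,
    tpm_cluster = 100, wui_cluster = 0.5))
  expect_true(is.na(none$category))
  lu <- compensation_classify(tibble::tibble(
    gene_id = "x", tpm_control = 100, wui_control = 0.5,
    tpm_cluster = 110, wui_cluster = 60 / 110))
  expect_equal(lu$category, "LU-specific")        # dSU = 0 alone
})

test_that("swapping SU/LU maps the specific categories onto each other", {
  set.seed(14)
  rec <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000),
                        tpm_control = runif(1000, 20, 200),
                        wui_control = runif(1000, 0.1, 0.9),
                        tpm_cluster = runif(1000, 20, 200),
                        wui_cluster = runif(1000, 0.1, 0.9))
  a <- compensation_classify(rec)
  swapped <- dplyr::mutate(rec, wui_control = 1 - wui_control,
                           wui_cluster = 1 - wui_cluster)
  b <- compensation_classify(swapped)
  map <- c(`SU-specific` = "LU-specific", `LU-specific` = "SU-specific",
           coordinated = "coordinated")
  expect_equal(unname(map[a$category]), b$category)
  # categories partition all classified genes
  expect_true(all(a$category %in% names(map) | is.na(a$category)))
})

test_that("cluster overlap uses the one-sided hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  sets <- tibble::tibble(
    cluster = c(rep("c1", 10), rep("c2", 10)),
    direction = "shortening",
    gene_id = c(universe[1:10], universe[1:10]))
  ov <- cluster_overlap(sets, universe)
  expect_equal(ov$overlap, 10)
  expect_equal(ov$p, 1 / choose(100, 10), tolerance = 1e-9)
  expect_gt(ov$neg_log10_p, 10)
  expect_equal(ov$type, "synergistic")
  # zero overlap: p = 1
  disj <- tibble::tibble(cluster = c(rep("c1", 5), rep("c2", 5)),
                         direction = c(rep("shortening", 5),
                                       rep("lengthening", 5)),
                         gene_id = c(universe[1:5], universe[6:10]))
  od <- cluster_overlap(disj, universe)
  expect_equal(od$p, 1)
  expect_equal(od$type, "antagonistic")
})

test_that("replicate validation recovers perfect and planted correlations", {
  genes <- sprintf("g%03d", 1:200)
  avg <- matrix(rnorm(2 * 200), 2, 200,
                dimnames = list(c("c1", "c2"), genes))
  reps <- rbind(r1 = avg["c1", ], r2 = -avg["c1", ])
  colnames(reps) <- genes
  nt <- matrix(rnorm(10 * 200), 10, 200,
               dimnames = list(paste0("nt", 1:10), genes))
  v <- validate_replicates(avg, reps, tibble::tibble(id = c("r1", "r2"),
                                                     cluster = c("c1", "c1")),
                           nt)
  cors <- v$correlations
  expect_equal(cors$r[cors$id == "r1"][1], 1)
  expect_equal(cors$r[cors$id == "r2"][1], -1)

  # planted shared signal, equal noise: r concentrates near
  # 1/sqrt(1 + noise^2/signal^2) = 0.71
  set.seed(20)
  signal <- rnorm(200)
  reps2 <- t(replicate(30, signal + rnorm(200)))
  dimnames(reps2) <- list(paste0("r", 1:30), genes)
  avg2 <- matrix(signal, 1, 200, dimnames = list("c1", genes))
  v2 <- validate_replicates(avg2, reps2,
                            tibble::tibble(id = paste0("r", 1:30),
                                           cluster = "c1"), nt)
  expect_equal(v2$per_cluster$median_r, sqrt(0.5), tolerance = 0.1)
  expect_lt(abs(v2$per_cluster$median_r_control), 0.2)
  expect_lt(v2$per_cluster$q, 0.01)
  expect_error(validate_replicates(avg[, 1, drop = FALSE],
                                   reps[, 1, drop = FALSE],
                                   tibble::tibble(id = "r1",
                                                  cluster = "c1"),
                                   nt[, 1, drop = FALSE]), "shared genes")
})

test_that("feature correlations flag constructed relationships", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:100)
  eff <- tibble::tibble(cluster = "c1", gene_id = genes,
                        effect = rnorm(100))
  feats <- tibble::tibble(gene_id = genes,
                          self = eff$effect,
                          anti = -eff$effect + rnorm(100, sd = 0.3),
                          noise = rnorm(100),
                          constant = 1)
  fc <- feature_correlation(eff, feats)
  expect_equal(fc$r[fc$feature == "self"], 1)
  expect_lt(fc$r[fc$feature == "anti"], -0.8)
  expect_true(fc$significant[fc$feature == "anti"])
  expect_true(is.na(fc$r[fc$feature == "constant"]))
  expect_false(isTRUE(fc$significant[fc$feature == "noise"]))
})

test_that("half-life fits invert noiseless first-order curves", {
  for (k in c(0.002, 0.005, 0.01)) {
    fit <- fit_half_life(generate_decay_curve(k, c_max = 0.08))
    expect_equal(fit$k, k, tolerance = 0.05 * k)
    expect_equal(fit$half_life, log(2) / k, tolerance = 0.05 * log(2) / k)
    expect_true(fit$converged)
  }
  # worked half-life: k = 0.005 -> 138.63 min
  f <- fit_half_life(generate_decay_curve(0.005))
  expect_equal(f$half_life, 138.6294, tolerance = 1e-3)
})

test_that("half-life flags degenerate time courses", {
  z <- fit_half_life(tibble::tibble(time = c(0, 120, 240, 360), rate = 0))
  expect_equal(z$flag, "no_conversion")
  expect_equal(z$half_life, Inf)
  fast <- fit_half_life(generate_decay_curve(0.05))  # saturates by t = 120
  expect_equal(fast$flag, "low_confidence")
  expect_lt(fast$half_life, 120)
  # weighted timepoint means: rates (0.1, 0.3) with weights (1, 3) -> 0.25
  mixed <- tibble::tibble(time = c(120, 120, 0, 240),
                          rate = c(0.1, 0.3, 0, 0.26),
                          weight = c(1, 3, 1, 1))
  ft <- fit_half_life(mixed)
  expect_true(is.finite(ft$k))
  agg <- 0.25  # the weighted mean feeding the fit at t = 120
  expect_equal(sum(c(0.1, 0.3) * c(1, 3)) / 4, agg)
})
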