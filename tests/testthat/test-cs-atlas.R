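# Peak calling, harmonization, site classification, region labels,
# usage scores and motif densities.

test_that("peak calling merges to local modes and applies strict RPM", {
  cov <- tibble::tibble(chrom = "chr1", strand = "+",
                        position = c(100L, 115L, 180L),
                        count = c(10L, 4L, 7L))
  pk <- call_peaks(cov, radius = 30, rpm_threshold = 5, library_size = 1e6)
  expect_equal(pk$position, c(100L, 180L))
  expect_equal(pk$support, c(14L, 7L))

  one <- call_peaks(tibble::tibble(chrom = "chr1", strand = "+",
                                   position = 500L, count = 6L),
                    library_size = 1e6)
  expect_equal(nrow(one), 1L)  # 6 RPM > 5: retained
  none <- call_peaks(tibble::tibble(chrom = "chr1", strand = "+",
                                    position = 500L, count = 5L),
                     library_size = 1e6)
  expect_equal(nrow(none), 0L)  # 5 RPM is not > 5: dropped

  expect_equal(nrow(call_peaks(tibble::tibble(chrom = character(),
                                              strand = character(),
                                              position = integer(),
                                              count = integer()))), 0L)
  expect_error(call_peaks(cov, library_size = 0), "positive")
})

test_that("greedy merge equals the exhaustive oracle on random inputs", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:12, 1)
    pos <- sort(sample(1:400, n))
    cnt <- sample(1:50, n, replace = TRUE)
    pk <- call_peaks(tibble::tibble(chrom = "c", strand = "+",
                                    position = pos, count = cnt),
                     rpm_threshold = 0, library_size = 1e6)
    or <- oracle_local_mode(pos, cnt, 30)
    expect_equal(pk$position, or$position)
    expect_equal(pk$support, or$support)
    # retained peaks pairwise farther than the radius
    if (nrow(pk) > 1) expect_true(all(diff(pk$position) > 30))
  }
})

test_that("harmonization pools groups and counts contributing cell types", {
  pk <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", strand = "+", position = 100L,
                   support = 14, rpm = 14, group = "A"),
    tibble::tibble(chrom = "chr1", strand = "+", position = 110L,
                   support = 9, rpm = 9, group = "B"))
  h <- harmonize_peaks(pk)
  expect_equal(h$position, 100L)  # higher summed local mode wins
  expect_equal(h$support, 23)
  expect_equal(h$n_celltypes_used, 2L)

  # idempotent on isolated peaks
  single <- tibble::tibble(chrom = "chr1", strand = "+", position = 100L,
                           support = 14, rpm = 14, group = "A")
  expect_equal(harmonize_peaks(single)$position, 100L)

  far <- dplyr::bind_rows(single,
                          dplyr::mutate(single, position = 161L, group = "B"))
  expect_equal(nrow(harmonize_peaks(far)), 2L)  # 61 nt > radius
})

test_that("site classification follows the validated/supported/likely tiers", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(paste(rep("ACGT", 500), collapse = ""),
                  strrep("A", 30),
                  paste(rep("ACGT", 500), collapse = ""))))
  cands <- tibble::tibble(chrom = "chr1", strand = "+",
                          position = c(1015L, 1200L, 1990L, 300L),
                          support = 10, n_celltypes_used = 1L)
  gencode <- tibble::tibble(chrom = "chr1", strand = "+", position = 1000L)
  ext <- tibble::tibble(chrom = "chr1", strand = "+",
                        position = c(1195L, 330L), tpm = c(10, 2))
  cl <- classify_sites(cands, gencode, ext, genome)
  expect_equal(cl$class_label,
               c("validated",   # |1015-1000| = 15 <= 20
                 "supported",   # 5 nt from a 10-TPM cluster
                 "discarded",   # A-run downstream (internal priming)
                 "likely"))     # 2-TPM cluster below threshold, passes priming
  expect_equal(cl$retained, c(FALSE, TRUE, FALSE, TRUE))
  # 21 nt beyond the window is not validated
  edge <- classify_sites(tibble::tibble(chrom = "chr1", strand = "+",
                                        position = 1021L, support = 1,
                                        n_celltypes_used = 1L),
                         gencode, ext[2, ], genome)
  expect_equal(edge$class_label, "likely")
})

test_that("internal priming fails on A-rich or A-run downstream context", {
  mk <- function(down) Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 100), down, strrep("C", 50))))
  site <- tibble::tibble(chrom = "chr1", strand = "+", position = 99L)
  expect_true(internal_priming_filter(site, mk("ACGTACGTACGTACGTACGT")))
  expect_false(internal_priming_filter(site, mk("AAAAAAAACGTACGTACGTA")))
  expect_false(internal_priming_filter(site, mk("AAGAAGAAAGAAAGAAGAAA")))

  # minus strand reads the reverse complement: genomic T-run upstream
  mseq <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 80), strrep("T", 20), strrep("C", 50))))
  msite <- tibble::tibble(chrom = "chr1", strand = "-", position = 100L)
  expect_false(internal_priming_filter(msite, mseq))
  # truncated window at the contig edge passes on short context
  edge <- tibble::tibble(chrom = "chr1", strand = "+", position = 149L)
  expect_true(internal_priming_filter(edge, mseq))
})

test_that("region labels follow the precedence order", {
  tx <- single_exon_tx(c("T1", "T2"), c("G1", "G2"), "chr1", "+",
                       start = c(1000, 500), end = c(2000, 3000),
                       cds_start = c(1100, 600), cds_end = c(1500, 2800))
  tx2 <- tx_table("T3", "G3", "chr1", "+",
                  exons = list(data.frame(start = c(1000, 1800),
                                          end = c(1400, 2000))),
                  cds_start = 1100, cds_end = 1300)
  # site in T1's 3'UTR and T3's intron: 3'UTR wins
  both <- dplyr::bind_rows(tx, tx2)
  r <- annotate_region(tibble::tibble(chrom = "chr1", strand = "+",
                                      position = 1600L), both)
  expect_equal(r$region_label, "three_prime_UTR")
  expect_equal(r$gene_id, "G1")
  # 300 nt downstream of T1's end (and beyond G2)
  r2 <- annotate_region(tibble::tibble(chrom = "chr1", strand = "+",
                                       position = 3300L), both)
  expect_equal(r2$region_label, "extended_three_prime_UTR")
  # far beyond every extension
  r3 <- annotate_region(tibble::tibble(chrom = "chr1", strand = "+",
                                       position = 9000L), both)
  expect_equal(r3$region_label, "intergenic")
  # upstream extension and 5'UTR
  r4 <- annotate_region(tibble::tibble(chrom = "chr1", strand = "+",
                                       position = c(950L, 1050L)), tx[1, ])
  expect_equal(r4$region_label, c("extended_five_prime_UTR",
                                  "five_prime_UTR"))
  # opposite strand never matches
  r5 <- annotate_region(tibble::tibble(chrom = "chr1", strand = "-",
                                       position = 1600L), both)
  expect_equal(r5$region_label, "intergenic")
})

test_that("usage scores and the minor rule behave as specified", {
  u <- usage_score(c(5L, 50L, 9L), c(50L, 50L, 9L))
  expect_equal(u$usage_score, c(0.1, 1, 1))
  expect_equal(u$usage_class, c("minor", "major", "minor"))  # 9 < 10
  expect_true(all(u$usage_score >= 0 & u$usage_score <= 1))
  # fraction rule variant
  uf <- usage_score(5L, 50L, rule = "fraction")
  expect_equal(uf$usage_class, "major")  # 0.1 not < 0.10
  # undefined when gene expressed nowhere
  u0 <- usage_score(0L, 0L)
  expect_true(is.na(u0$usage_score))
  expect_error(usage_score(5L, 3L), "cannot")
  # monotone in site usage
  sc <- usage_score(0:20, rep(20L, 21))$usage_score
  expect_true(all(diff(sc) >= 0))
})

test_that("motif positional density finds centers and scales mode to 1", {
  # AATAAA ends 21 nt upstream of the CS: occupies offsets [-26, -21]
  left <- strrep("C", 174)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    left, "AATAAA", strrep("C", 220))))
  sites <- tibble::tibble(chrom = "chr1", strand = "+",
                          position = c(200L, 200L))
  d <- motif_positional_density(sites, genome, c(PAS = "AWTAAA"),
                                flank = 50)
  spike <- d[d$count > 0, ]
  expect_equal(spike$offset, -24L)
  expect_equal(spike$density, 1)
  expect_equal(spike$count, 2L)
  # absent motif: all-zero histogram
  d0 <- motif_positional_density(sites, genome, "GGGGGGGG", flank = 50)
  expect_true(all(d0$count == 0) && all(d0$density == 0))
  # IUPAC expansion counts both AATAAA and ATTAAA
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 100), "AATAAA", strrep("C", 20), "ATTAAA", strrep("C", 100))))
  s2 <- tibble::tibble(chrom = "chr1", strand = "+", position = 130L)
  d2 <- motif_positional_density(s2, g2, "AWTAAA", flank = 40)
  expect_equal(sum(d2$count), 2L)
  expect_error(motif_positional_density(s2, g2, "AXTAAA"), "IUPAC")
})
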