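# Independent oracles and tiny fixture builders shared across tests.

# Plain recursive local-mode merge, written independently of the
# package implementation: repeatedly take the highest-count position
# (ties to the leftmost), absorb everything within +/- radius.
oracle_local_mode <- function(position, count, radius) {
  out <- list()
  while (length(position) > 0) {
    best <- which(count == max(count))
    best <- best[which.min(position[best])]
    near <- abs(position - position[best]) <= radius
    out[[length(out) + 1]] <- c(position = position[best],
                                support = sum(count[near]))
    position <- position[!near]
    count <- count[!near]
  }
  d <- as.data.frame(do.call(rbind, out))
  d[order(d$position), , drop = FALSE]
}

# Brute-force merge-table oracle over pairwise 3'-end distances: each
# isoform points at the 3'-most isoform (in strand direction) closer
# than merge_distance; pointers chased until stable.
oracle_merge_table <- function(ids, ends, strand, merge_distance) {
  d3 <- if (strand == "+") ends else -ends
  target <- vapply(seq_along(ids), function(i) {
    cand <- which(d3 >= d3[i] & d3 - d3[i] < merge_distance)
    cand[which.max(d3[cand])]
  }, integer(1))
  for (iter in seq_along(ids)) target <- target[target]
  setNames(ids[target], ids)
}

# Brute-force dedup oracle: union-find over all pairs with end distance
# < min_distinct; survivor is the most 3' member of each component.
oracle_dedup <- function(ids, ends, strand, min_distinct) {
  d3 <- if (strand == "+") ends else -ends
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j && abs(d3[i] - d3[j]) < min_distinct) {
      parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  vapply(split(seq_along(ids), comp), function(m) {
    d3[m[which.max(d3[m])]]
  }, numeric(1))
}

# Welch t oracle via stats::t.test on log values.
oracle_welch <- function(a, b) {
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# single-exon tx table builder
single_exon_tx <- function(id, gene, chrom, strand, start, end,
                           cds_start = NA, cds_end = NA, source = "gencode") {
  tx_table(id, gene, chrom, strand,
           exons = lapply(seq_along(id), function(i) {
             data.frame(start = start[i], end = end[i])
           }),
           cds_start = cds_start, cds_end = cds_end, source = source)
}

# deterministic random genome
random_genome <- function(len, chrom = "chr1", seed = 1) {
  set.seed(seed)
  Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    chrom))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
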