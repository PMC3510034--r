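# small shared fixtures, built in code

small_cfg <- function(...) {
  sim_config(n_genes = 60, n_targets = 8, seed = 42, ...)
}

# a tiny read table builder for dedup tests
make_reads <- function(start, strand = "+", exp_bc = "ACGT",
                       rand_bc = "AAAAA", chrom = "chrS1",
                       genotype = "wildtype", replicate = 1L) {
  n <- max(length(start), length(strand), length(rand_bc))
  data.table::data.table(
    chrom = chrom,
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(start, n) + 1L),
    strand = rep_len(strand, n),
    exp_bc = rep_len(exp_bc, n),
    rand_bc = rep_len(rand_bc, n),
    genotype = rep_len(genotype, n),
    replicate = rep_len(replicate, n))
}

# rank-sum AUC of target recovery from a ranking table
target_auc <- function(ranking, targets) {
  lab <- ranking$gene_id %in% targets
  r <- rank(ranking$score)
  (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) / (sum(lab) * sum(!lab))
}

# independent brute-force pentamer counter: explicit loops over all 1024
# pentamers and all window offsets, no Biostrings
brute_pentamer_counts <- function(windows) {
  bases <- c("A", "C", "G", "T")
  all5 <- apply(expand.grid(bases, bases, bases, bases, bases,
                            stringsAsFactors = FALSE)[, 5:1],
                1, paste, collapse = "")
  cnt <- stats::setNames(numeric(1024), all5)
  for (w in windows) {
    n <- nchar(w)
    if (n < 5) next
    for (i in 1:(n - 4)) {
      p <- substr(w, i, i + 4)
      cnt[p] <- cnt[p] + 1
    }
  }
  cnt
}

# independent two-sided Fisher exact p by exhaustive enumeration over all
# tables with the observed margins (conditional point-probability rule)
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  a <- lo:hi
  d <- stats::dhyper(a, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  sum(d[d <= p_obs * (1 + 1e-7)])
}
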