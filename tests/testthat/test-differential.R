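test_that("upper-quartile normalization removes sample scale", {
  set.seed(1)
  a <- rpois(40, 50)
  m <- cbind(s1 = a, s2 = 2 * a)
  nm <- quartile_normalize(m)
  expect_equal(nm[, "s1"], nm[, "s2"], ignore_attr = TRUE)

  # single sample: identity up to the global rescale (which is identity)
  one <- matrix(a, ncol = 1, dimnames = list(NULL, "s"))
  expect_equal(quartile_normalize(one), one)

  # hand-computed upper quartile of a 4-gene sample (linear interpolation):
  # nonzero values 2, 4, 10, 20 -> Q3 = 10 + 0.25 * (20 - 10) = 12.5
  toy <- matrix(c(2, 4, 10, 20), ncol = 1)
  expect_equal(quartile_normalize(toy), toy / 12.5 * 12.5)
  toy2 <- cbind(toy, c(0, 1, 2, 3))   # zeros excluded from the quartile
  uq2 <- stats::quantile(c(1, 2, 3), 0.75, names = FALSE)  # 2.5
  expect_equal(uq2, 2.5)
  nm2 <- quartile_normalize(toy2)
  expect_equal(nm2[, 2], c(0, 1, 2, 3) / 2.5 * mean(c(12.5, 2.5)))
  expect_error(quartile_normalize(cbind(toy, 0)), "all-zero")
})

test_that("normal-quantile transform matches the quantile table", {
  # n = 4 distinct values -> scores at (r - 0.5)/4
  x <- c(3, 1, 4, 2)
  s <- quantile_transform(x)
  expect_equal(sort(s), qnorm(c(0.125, 0.375, 0.625, 0.875)))
  expect_equal(s[order(x)], sort(s))

  # odd n: the median observation scores 0; mean is 0 without ties
  s5 <- quantile_transform(c(10, 30, 20, 50, 40))
  expect_equal(s5[2], 0)   # 30 is the median observation
  expect_equal(mean(s5), 0)

  # ties share the averaged-rank score; constant input maps to zeros
  st <- quantile_transform(c(1, 1, 2, 3))
  expect_equal(st[1], st[2])
  expect_equal(quantile_transform(rep(7, 6)), rep(0, 6))
  expect_error(quantile_transform(c(1, 2)), "3 samples")

  # sd approaches 1 as n grows
  expect_equal(sd(quantile_transform(seq_len(500))), 1, tolerance = 0.01)
})

test_that("interaction ANOVA reproduces a hand-worked two-way table", {
  # balanced 2x2 with 2 replicates per cell; sums of squares by hand
  d <- make_design(n_rep = 2)
  y <- c(10, 12, 20, 22, 11, 13, 35, 37)   # wtA wtA wtB wtB nullA nullA nullB nullB
  names(y) <- d$sample
  # cell means: wtA 11, wtB 21, nullA 12, nullB 36; grand 20
  # SS_treatment = 4 * ((16-20)^2 + (24-20)^2) applied to treatment means:
  # A mean 11.5, B mean 28.5 -> SS_t = 4*((11.5-20)^2+(28.5-20)^2) = 578
  # genotype means: wt 16, null 24 -> SS_g = 4*(16-20)^2*2 = 128
  # interaction: cell - row - col + grand: wtA 11-16-11.5+20 = 3.5 (abs)
  # SS_i = 2 * sum over cells (3.5^2) = 2*4*12.25 = 98
  # residual: each cell +-1 -> SS_e = 8
  m <- matrix(y, 1, 8, dimnames = list("g", d$sample))
  r <- interaction_anova(m, d, n_perm = 10, seed = 1, transform = FALSE)
  expect_equal(r$F_experiment, 578 / (8 / 4))
  expect_equal(r$F_genotype, 128 / 2)
  expect_equal(r$F_interaction, 98 / 2)

  # and agrees with anova(lm()) on random data
  set.seed(4)
  y2 <- rnorm(8)
  m2 <- matrix(y2, 1, 8, dimnames = list("g", d$sample))
  r2 <- interaction_anova(m2, d, n_perm = 5, seed = 1, transform = FALSE)
  a2 <- anova(lm(y2 ~ factor(d$treatment) * factor(d$genotype)))
  expect_equal(c(r2$F_experiment, r2$F_genotype, r2$F_interaction),
               a2$`F value`[1:3])

  # unreplicated cell: interaction inestimable
  d1 <- make_design(n_rep = 1)
  m1 <- matrix(rnorm(4), 1, 4, dimnames = list("g", d1$sample))
  expect_error(interaction_anova(m1, d1), "replicates")
})

test_that("noise-free crossover yields the top interaction F", {
  d <- make_design(n_rep = 3)
  set.seed(8)
  base <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), d$sample))
  cross <- d$genotype == "null" & d$treatment == "B" |
    d$genotype == "wt" & d$treatment == "A"
  base[1, ] <- ifelse(cross, 100, 0) + rnorm(12, 0, 1e-3)
  r <- interaction_anova(base, d, n_perm = 20, seed = 2)
  expect_equal(r$rank_F[r$gene_id == "g01"], 1L)
})

test_that("type-I error is nominal on null genes", {
  cfg <- sim_config(n_genes = 400, n_targets = 40, interaction_effect = 0,
                    seed = 31)
  ann <- generate_annotation(cfg)
  ex <- generate_counts_experiment(ann, cfg, make_design(n_rep = 3))
  ia <- interaction_anova(quartile_normalize(ex$counts), ex$design,
                          n_perm = 100, seed = 1)
  expect_gt(mean(ia$p_interaction < 0.05), 0.02)
  expect_lt(mean(ia$p_interaction < 0.05), 0.08)
})

test_that("rank association links interaction strength to iCLIP rank", {
  # F ranks identical to iCLIP ranks: association maximal
  n <- 100
  rk <- data.table::data.table(gene_id = sprintf("g%03d", 1:n),
                               score = seq(1, 0, length.out = n), rank = 1:n)
  it <- data.table::data.table(gene_id = rk$gene_id,
                               F_interaction = seq(100, 1, length.out = n))
  ra <- rank_association(it, rk, top_k = 40)
  expect_equal(ra$spearman, 1)
  expect_lt(ra$p_assoc, 1e-10)
  expect_equal(length(ra$high), 20L)
  expect_equal(length(ra$low), 20L)
  expect_true(all(ra$high %in% head(rk$gene_id, 40)))
  # high set holds the largest F values among the top_k
  expect_true(min(it$F_interaction[match(ra$high, it$gene_id)]) >=
                max(it$F_interaction[match(ra$low, it$gene_id)]))

  # odd top_k: extra gene goes to the low half
  ra_odd <- rank_association(it, rk, top_k = 41)
  expect_equal(length(ra_odd$high), 20L)
  expect_equal(length(ra_odd$low), 21L)
  expect_error(rank_association(it, rk, top_k = 1000), "top_k")

  # independent ranks: association non-significant over seeds
  ps <- vapply(1:20, function(s) {
    set.seed(s)
    it_r <- data.table::data.table(gene_id = rk$gene_id,
                                   F_interaction = sample(100))
    rank_association(it_r, rk, top_k = 40)$p_assoc
  }, 0)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("delta log p composes two enrichment calls", {
  u <- sprintf("g%03d", 1:60)
  terms <- list(t_hi = u[1:10], t_even = c(u[1:5], u[31:35]))
  high <- u[1:20]; low <- u[31:50]
  # equal representation in equally sized sets: delta = 0
  r_even <- delta_log_p("t_even", high, low, u, terms)
  expect_equal(r_even$delta_log_p, 0)
  # term concentrated in the high set: more significant there, delta < 0
  r_hi <- delta_log_p("t_hi", high, low, u, terms)
  expect_lt(r_hi$delta_log_p, 0)
  # compositional oracle: matches the two direct enrich() calls
  expect_equal(r_hi$delta_log_p,
               log10(enrich(high, u, terms["t_hi"])$table$p) -
                 log10(enrich(low, u, terms["t_hi"])$table$p))
  expect_error(delta_log_p("t_hi", high, c(high[1], low), u, terms),
               "disjoint")
  expect_error(delta_log_p("missing", high, low, u, terms), "unknown")
})

test_that("direction tables match the Fisher enumeration oracle", {
  # printed counts from the neuronal-axis synaptic-plasticity category
  tab <- matrix(c(19L, 7L, 2L, 14L), 2,
                dimnames = list(c("null", "wt"), c(">1", "<1")))
  r <- fisher_direction(tab)
  expect_equal(r$fisher_p, fisher_enum_p(tab))
  expect_equal(r$fisher_p, fisher.test(tab)$p.value)
  expect_equal(r$odds_ratio, 19 * 14 / (2 * 7))

  # no association and degenerate diagonal
  expect_equal(fisher_direction(matrix(c(5L, 5L, 5L, 5L), 2))$fisher_p, 1)
  expect_equal(fisher_direction(matrix(c(5L, 5L, 5L, 5L), 2))$odds_ratio, 1)
  expect_true(is.infinite(
    fisher_direction(matrix(c(6L, 0L, 0L, 4L), 2))$odds_ratio))

  # enumeration agreement across a grid of margins
  set.seed(6)
  for (i in 1:40) {
    r1 <- sample.int(30, 1); r2 <- sample.int(30, 1)
    c1 <- sample.int(r1 + r2, 1)
    a <- sample(max(0, c1 - r2):min(r1, c1), 1)
    tb <- matrix(c(a, c1 - a, r1 - a, r2 - (c1 - a)), 2)
    expect_equal(fisher_direction(tb)$fisher_p, fisher_enum_p(tb))
  }
})

test_that("direction_table classifies genes by treatment ratio per genotype", {
  d <- make_design(treatments = c("A", "B"), n_rep = 2)
  genes <- c("up_null", "down_wt", "flat")
  m <- matrix(10, 3, 8, dimnames = list(genes, d$sample))
  m["up_null", d$genotype == "null" & d$treatment == "B"] <- 30
  m["down_wt", d$genotype == "wt" & d$treatment == "B"] <- 2
  r <- direction_table(genes, m, d, label = "toy")
  # null genotype: up_null >1; down_wt and flat are excluded/counted by sign
  expect_equal(unname(r$counts["null", ">1"]), 1L)
  expect_equal(unname(r$counts["wt", "<1"]), 1L)
  expect_equal(r$n_excluded, 4L)   # 'flat' has ratio 1 in both genotypes,
                                   # down_wt ratio 1 in null, up_null in wt
  expect_error(direction_table("absent", m, d), "absent")
})

test_that("ddCt fold changes follow the 2^ddCt rule", {
  # identical dCt in both genotypes -> fold change 1
  r0 <- ddct_fold_change(list(control = c(20, 20, 20),
                              experimental = c(20, 20, 20)),
                         list(control = c(15, 15, 15),
                              experimental = c(15, 15, 15)))
  expect_equal(r0$ddct, 0)
  expect_equal(r0$fold_change, 1)

  # ddCt of +1 doubles, -1 halves
  up <- ddct_fold_change(list(control = c(21, 21, 21),
                              experimental = c(20, 20, 20)),
                         list(control = c(15, 15, 15),
                              experimental = c(15, 15, 15)))
  expect_equal(up$fold_change, 2)
  dn <- ddct_fold_change(list(control = c(20, 20, 20),
                              experimental = c(21, 21, 21)),
                         list(control = c(15, 15, 15),
                              experimental = c(15, 15, 15)))
  expect_equal(dn$fold_change, 0.5)

  # triplicates average; a missing replicate warns but still averages
  expect_warning(
    rm <- ddct_fold_change(list(control = c(20, NA, 20),
                                experimental = c(20, 20, 20)),
                           list(control = c(15, 15, 15),
                                experimental = c(15, 15, 15))),
    "missing")
  expect_equal(rm$fold_change, 1)
})

test_that("planted interaction genes drive the rank association end to end", {
  cfg <- sim_config(n_genes = 500, n_targets = 60, n_interaction_genes = 30,
                    interaction_effect = 2, seed = 37)
  ann <- generate_annotation(cfg)
  ex <- generate_counts_experiment(ann, cfg, make_design(n_rep = 3))
  ia <- interaction_anova(quartile_normalize(ex$counts), ex$design,
                          n_perm = 100, seed = 1)
  # a synthetic occupancy ranking that puts targets on top, as the iCLIP
  # arm of the study would
  targets <- sort(ann$genes$gene_id[ann$genes$is_target])
  genes <- rownames(ex$counts)
  set.seed(2)
  ord <- c(sample(targets), sample(setdiff(genes, targets)))
  rk <- data.table::data.table(gene_id = ord,
                               score = seq(1, 0, length.out = length(ord)),
                               rank = seq_along(ord))
  ra <- rank_association(ia, rk, top_k = 60)
  expect_lt(ra$p_assoc, 0.01)
  # the high half of the top-60 is enriched for planted interaction genes
  k <- length(intersect(ra$high, ex$interaction_genes))
  p_hyper <- phyper(k - 1, length(ex$interaction_genes),
                    length(genes) - length(ex$interaction_genes),
                    length(ra$high), lower.tail = FALSE)
  expect_lt(p_hyper, 0.01)

  # parameter recovery: planted effect within +-25% from cell means
  d <- ex$design
  nm <- quartile_normalize(ex$counts)
  cm <- function(g, gt, tr)
    mean(nm[g, d$sample[d$genotype == gt & d$treatment == tr]])
  est <- vapply(ex$interaction_genes, function(g)
    log2(cm(g, "null", "B") / cm(g, "null", "A")) -
      log2(cm(g, "wt", "B") / cm(g, "wt", "A")), 0)
  expect_lt(abs(mean(est) - cfg$interaction_effect),
            0.25 * cfg$interaction_effect)
})
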