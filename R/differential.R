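#' Upper-quartile normalization
#'
#' Divides each sample by the 75th percentile of its nonzero values
#' (linear-interpolation quantile), then rescales all samples by the
#' mean upper quartile so the output stays on the input's magnitude.
#'
#' @param mat genes x samples numeric matrix.
#' @return normalized matrix of the same shape.
#' @export
quartile_normalize <- function(mat) {
  uq <- apply(mat, 2L, function(x) {
    x <- x[x > 0]
    if (length(x) == 0L) stop("all-zero sample", call. = FALSE)
    stats::quantile(x, 0.75, names = FALSE)
  })
  sweep(mat, 2L, uq, "/") * mean(uq)
}

#' Rank-based normal-quantile transform
#'
#' Replaces values by standard-normal scores of their mid-ranks:
#' `qnorm((r - 0.5) / n)` with ties given the average rank. A constant
#' vector maps to all zeros.
#'
#' @param x numeric vector (one gene across samples; `length(x) >= 3`).
#' @return numeric vector of normal scores.
#' @export
quantile_transform <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(unique(x)) == 1L) return(rep(0, n))
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / n)
}

# residual sums of squares of Y (samples x genes) under design matrix X
rss_under <- function(X, Y) {
  r <- stats::lm.fit(X, Y)$residuals
  if (is.null(dim(r))) r <- matrix(r, ncol = 1L)
  colSums(r^2)
}

# sequential two-way ANOVA F statistics for every gene at once.
# Y: samples x genes matrix of (transformed) values.
interaction_f <- function(Y, treatment, genotype) {
  t_f <- factor(treatment); g_f <- factor(genotype)
  X0 <- stats::model.matrix(~1, data.frame(t = t_f))
  X1 <- stats::model.matrix(~t_f)
  X2 <- stats::model.matrix(~t_f + g_f)
  X3 <- stats::model.matrix(~t_f * g_f)
  df_res <- nrow(Y) - ncol(X3)
  if (df_res < 1L)
    stop("interaction inestimable: no residual degrees of freedom",
         call. = FALSE)
  r0 <- rss_under(X0, Y); r1 <- rss_under(X1, Y)
  r2 <- rss_under(X2, Y); r3 <- rss_under(X3, Y)
  ms_res <- r3 / df_res
  list(F_experiment = ((r0 - r1) / (ncol(X1) - ncol(X0))) / ms_res,
       F_genotype = ((r1 - r2) / (ncol(X2) - ncol(X1))) / ms_res,
       F_interaction = ((r2 - r3) / (ncol(X3) - ncol(X2))) / ms_res,
       df_res = df_res)
}

#' Per-gene genotype-by-treatment interaction ANOVA
#'
#' For every gene, fits a two-way fixed-effects ANOVA (treatment
#' "experiment" + genotype + interaction) to rank-based normal scores of
#' the normalized expression values, reporting sequential F statistics.
#' The interaction p-value is permutation-adjusted: the sample labels
#' are shuffled within the design `n_perm` times, interaction F values
#' are recomputed for every gene, and all permuted F values are pooled
#' into one null distribution against which each observed F is compared
#' (`p = (1 + #null >= F) / (1 + n_null)`).
#'
#' Genes whose design leaves no residual degrees of freedom (unreplicated
#' cells) cause an error, matching the 2x2-with-replication contract.
#'
#' @param mat genes x samples matrix (normalized expression or counts).
#' @param design design table (sample, genotype, treatment); rows must
#'   match `colnames(mat)`.
#' @param n_perm number of label permutations for the pooled null.
#' @param seed integer seed.
#' @param transform apply [quantile_transform()] per gene first
#'   (default), as the models operate on ranked normal-quantile data.
#' @return data.table: gene_id, F_experiment, F_genotype, F_interaction,
#'   p_interaction, rank_F (1 = largest interaction F).
#' @export
interaction_anova <- function(mat, design, n_perm = 100L, seed = 1L,
                              transform = TRUE) {
  stopifnot(nrow(design) == ncol(mat))
  if (!is.null(design$sample) && !is.null(colnames(mat)))
    mat <- mat[, design$sample, drop = FALSE]
  cells <- table(design$genotype, design$treatment)
  if (any(cells < 2L))
    stop("each genotype x treatment cell needs >= 2 replicates",
         call. = FALSE)
  Y <- t(mat)
  if (transform) Y <- apply(Y, 2L, quantile_transform)
  obs <- interaction_f(Y, design$treatment, design$genotype)

  set.seed(seed)
  null_f <- unlist(lapply(seq_len(n_perm), function(b) {
    idx <- sample.int(nrow(Y))
    interaction_f(Y[idx, , drop = FALSE], design$treatment,
                  design$genotype)$F_interaction
  }), use.names = FALSE)
  null_sorted <- sort(null_f)
  n_null <- length(null_sorted)
  n_ge <- n_null - findInterval(obs$F_interaction - 1e-12, null_sorted)
  p <- (1 + n_ge) / (1 + n_null)

  out <- data.table::data.table(
    gene_id = rownames(mat),
    F_experiment = obs$F_experiment,
    F_genotype = obs$F_genotype,
    F_interaction = obs$F_interaction,
    p_interaction = p)
  out[, rank_F := rank(-F_interaction, ties.method = "first")]
  out[]
}

#' Relate interaction strength to the iCLIP target ranking
#'
#' Two complementary summaries over the common gene universe: (a) a
#' rank-regression of the interaction-F rank on top-`top_k` target
#' status (F and p of the regression, with a Spearman correlation
#' between iCLIP rank and F rank alongside); (b) a median split of the
#' top-`top_k` targets by interaction F into equally sized high/low
#' sets (odd counts give the extra gene to the low set).
#'
#' @param interaction result of [interaction_anova()].
#' @param ranking ranked gene table from [rank_genes()].
#' @param top_k number of top-ranked genes treated as targets.
#' @return list: F_assoc, p_assoc, spearman, high, low (character
#'   vectors of gene ids), universe.
#' @export
rank_association <- function(interaction, ranking, top_k = 2000L) {
  common <- intersect(interaction$gene_id, ranking$gene_id)
  if (top_k > length(common))
    stop("top_k exceeds the common gene universe", call. = FALSE)
  it <- interaction[match(common, interaction$gene_id), ]
  rk <- ranking[match(common, ranking$gene_id), ]
  f_rank <- rank(-it$F_interaction, ties.method = "average")
  i_rank <- rank(rk$rank, ties.method = "average")
  is_target <- as.integer(rk$rank <= sort(rk$rank)[top_k])
  fit <- stats::anova(stats::lm(f_rank ~ is_target))
  top <- common[is_target == 1L]
  top_f <- it$F_interaction[match(top, it$gene_id)]
  o <- order(-top_f, top)
  n_high <- length(top) %/% 2L
  list(F_assoc = fit[["F value"]][1L],
       p_assoc = fit[["Pr(>F)"]][1L],
       spearman = stats::cor(i_rank, f_rank, method = "spearman"),
       high = top[o][seq_len(n_high)],
       low = top[o][(n_high + 1L):length(top)],
       universe = common)
}

#' Difference of log enrichment p between two gene sets
#'
#' `delta_log_p = log10 p(term | high vs universe) - log10 p(term | low
#' vs universe)`, with hypergeometric p from [enrich()]. Negative values
#' mean the term is more significantly enriched in the high set.
#'
#' @param term term name (must exist in `terms`).
#' @param high,low disjoint gene sets (e.g. from [rank_association()]).
#' @param universe background gene set.
#' @param terms named list of term gene sets.
#' @return list: term, p_high, p_low, delta_log_p.
#' @export
delta_log_p <- function(term, high, low, universe, terms) {
  if (!term %in% names(terms)) stop("unknown term", call. = FALSE)
  if (length(intersect(high, low)) > 0L)
    stop("high and low sets must be disjoint", call. = FALSE)
  if (length(intersect(terms[[term]], universe)) == 0L)
    stop("term absent from universe", call. = FALSE)
  one <- terms[term]
  p_high <- enrich(high, universe, one)$table$p
  p_low <- enrich(low, universe, one)$table$p
  list(term = term, p_high = p_high, p_low = p_low,
       delta_log_p = log10(p_high) - log10(p_low))
}

#' Direction-of-effect contingency table for a gene category
#'
#' Classifies each category gene, per genotype, by whether the ratio of
#' mean normalized expression (second treatment / first treatment)
#' exceeds 1; ratios exactly 1 are excluded. The resulting 2x2 table
#' (genotype x direction) is tested with a two-sided Fisher exact test
#' (conditional point-probability method) and summarized by the sample
#' odds ratio, flagged infinite for a zero off-diagonal cell.
#'
#' @param category character vector of category gene ids.
#' @param mat genes x samples normalized expression matrix.
#' @param design design table (sample, genotype, treatment).
#' @param label optional category label carried into the result.
#' @return list of class `direction_table`: label, counts (2x2 matrix,
#'   rows null/wt, columns ">1"/"<1"), fisher_p, odds_ratio, n_excluded.
#' @export
direction_table <- function(category, mat, design, label = NULL) {
  category <- intersect(category, rownames(mat))
  if (length(category) == 0L)
    stop("category genes absent from matrix", call. = FALSE)
  treatments <- unique(design$treatment)
  stopifnot(length(treatments) == 2L)
  ratio_for <- function(gt) {
    a <- design$sample[design$genotype == gt &
                         design$treatment == treatments[1L]]
    b <- design$sample[design$genotype == gt &
                         design$treatment == treatments[2L]]
    den <- rowMeans(mat[category, a, drop = FALSE])
    num <- rowMeans(mat[category, b, drop = FALSE])
    ifelse(den == 0, NA_real_, num / den)
  }
  r_null <- ratio_for("null"); r_wt <- ratio_for("wt")
  excl <- sum(is.na(r_null)) + sum(is.na(r_wt)) +
    sum(r_null == 1, na.rm = TRUE) + sum(r_wt == 1, na.rm = TRUE)
  counts <- rbind(null = c(sum(r_null > 1, na.rm = TRUE),
                           sum(r_null < 1, na.rm = TRUE)),
                  wt = c(sum(r_wt > 1, na.rm = TRUE),
                         sum(r_wt < 1, na.rm = TRUE)))
  colnames(counts) <- c(">1", "<1")
  fisher_direction(counts, label = label, n_excluded = excl)
}

#' Fisher test on a prebuilt direction table
#'
#' @param counts 2x2 integer matrix (rows: genotypes, columns: ratio
#'   greater / less than 1).
#' @param label optional category label.
#' @param n_excluded number of genes excluded upstream.
#' @return list of class `direction_table` (see [direction_table()]).
#' @export
fisher_direction <- function(counts, label = NULL, n_excluded = 0L) {
  stopifnot(all(dim(counts) == c(2L, 2L)), all(counts >= 0))
  ft <- stats::fisher.test(counts, alternative = "two.sided")
  or <- (counts[1L, 1L] * counts[2L, 2L]) /
    (counts[1L, 2L] * counts[2L, 1L])
  out <- list(label = label, counts = counts,
              fisher_p = ft$p.value,
              odds_ratio = or, n_excluded = n_excluded)
  class(out) <- "direction_table"
  out
}

#' @export
print.direction_table <- function(x, ...) {
  if (!is.null(x$label)) cat(x$label, "\n")
  print(x$counts)
  cat("Fisher exact p =", format(x$fisher_p, digits = 4),
      "| odds ratio =", format(x$odds_ratio, digits = 4), "\n")
  invisible(x)
}

#' qPCR 2^ddCt fold change
#'
#' Averages the triplicate Ct values of the target and reference
#' (actin) amplicons within each genotype, forms
#' `dCt = mean(Ct_target) - mean(Ct_ref)` per genotype, then
#' `ddCt = dCt_control - dCt_experimental` so positive values mean the
#' target is up in the experimental genotype, and reports
#' `fold_change = 2^ddCt`.
#'
#' @param ct_target,ct_ref lists with numeric components `control` and
#'   `experimental` holding the replicate Ct values (typically
#'   triplicates; missing replicates are averaged over with a warning).
#' @return list: dct_control, dct_experimental, ddct, fold_change.
#' @examples
#' ddct_fold_change(list(control = c(25, 25, 25), experimental = c(24, 24, 24)),
#'                  list(control = c(15, 15, 15), experimental = c(15, 15, 15)))
#' @export
ddct_fold_change <- function(ct_target, ct_ref) {
  m <- function(x, what) {
    if (anyNA(x)) warning("missing ", what, " replicate; mean of available")
    mean(x, na.rm = TRUE)
  }
  dct_c <- m(ct_target$control, "target control") -
    m(ct_ref$control, "reference control")
  dct_e <- m(ct_target$experimental, "target experimental") -
    m(ct_ref$experimental, "reference experimental")
  ddct <- dct_c - dct_e
  list(dct_control = dct_c, dct_experimental = dct_e,
       ddct = ddct, fold_change = 2^ddct)
}
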