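#' Hypergeometric term over-representation
#'
#' One-sided hypergeometric over-representation test of a gene query
#' against every term of an annotation set, with Benjamini-Hochberg
#' correction across terms. Term sizes are taken after intersection with
#' the universe.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param universe character vector of background genes.
#' @param terms named list of character vectors (term -> gene set).
#' @param alpha adjusted-p significance level defining `n_clusters`.
#' @return list with `table` (data.table: term, k, n, K, N, p, p_adj),
#'   `n_clusters` (terms with adjusted p < alpha) and `min_p` (smallest
#'   raw p).
#' @examples
#' u <- paste0("g", 1:20)
#' enrich(u[1:5], u, list(t1 = u[1:5]))$table$p  # 1 / choose(20, 5)
#' @export
enrich <- function(query, universe, terms, alpha = 0.05) {
  if (length(query) == 0L || length(universe) == 0L)
    stop("empty query or universe", call. = FALSE)
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe", call. = FALSE)
  N <- length(universe); n <- length(query)
  K <- vapply(terms, function(g) length(intersect(g, universe)), 0L)
  k <- vapply(terms, function(g) length(intersect(g, query)), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  tab <- data.table::data.table(term = names(terms), k = k, n = n, K = K,
                                N = N, p = p,
                                p_adj = stats::p.adjust(p, "BH"))
  list(table = tab[],
       n_clusters = sum(tab$p_adj < alpha),
       min_p = if (nrow(tab) > 0L) min(tab$p) else NA_real_)
}

# serial split of N ranks into floor(N/g) groups, remainder to the last
walkdown_groups <- function(n_genes, group_size) {
  if (group_size < 1L) stop("group_size must be >= 1", call. = FALSE)
  if (group_size > n_genes)
    stop("group_size exceeds the ranking length", call. = FALSE)
  n_groups <- n_genes %/% group_size
  g <- pmin(ceiling(seq_len(n_genes) / group_size), n_groups)
  split(seq_len(n_genes), g)
}

#' Walk-down functional-annotation scoring of a ranked gene list
#'
#' Splits the ranking serially into `floor(N / group_size)` groups of
#' `group_size` genes (the remainder is appended to the last group),
#' scores each group's term over-representation independently against
#' the full ranking universe, and accumulates two curves over groups:
#' the number of significant terms (`cum_clusters`) and
#' `-log10` of the smallest raw p (`cum_neglog_minp`).
#'
#' @param ranking a ranked gene table (data.table with gene_id ordered
#'   by rank, see [rank_genes()]) or a character vector already in rank
#'   order.
#' @param group_size genes per group (e.g. 357 or 204).
#' @param terms named list of term gene sets.
#' @param alpha adjusted-p level passed to [enrich()].
#' @return object of class `walkdown_curve`: data.table with group,
#'   rank_end, n_clusters, min_p, cum_clusters, cum_neglog_minp; the
#'   group size is kept as attribute `group_size`.
#' @export
walk_down <- function(ranking, group_size, terms, alpha = 0.05) {
  genes <- if (is.character(ranking)) ranking else ranking$gene_id
  groups <- walkdown_groups(length(genes), as.integer(group_size))
  res <- lapply(groups, function(idx) enrich(genes[idx], genes, terms, alpha))
  out <- data.table::data.table(
    group = seq_along(groups),
    rank_end = vapply(groups, max, 0L),
    n_clusters = vapply(res, `[[`, 0, "n_clusters"),
    min_p = vapply(res, `[[`, 0, "min_p"))
  out[, cum_clusters := cumsum(n_clusters)]
  out[, cum_neglog_minp := cumsum(-log10(pmax(min_p, .Machine$double.xmin)))]
  data.table::setattr(out, "group_size", as.integer(group_size))
  data.table::setattr(out, "class",
                      c("walkdown_curve", class(out)))
  out[]
}

#' Permuted-ranking control curves for the walk-down
#'
#' Shuffles the gene order uniformly `n_perm` times, applies
#' [walk_down()] to each permuted ranking, and returns the pointwise
#' mean (and sd) of the cumulative curves.
#'
#' @inheritParams walk_down
#' @param n_perm number of ranking permutations.
#' @param seed integer seed.
#' @return data.table: group, perm_cum_clusters, perm_cum_neglog_minp,
#'   sd_cum_clusters, sd_cum_neglog_minp.
#' @export
permute_walkdown <- function(ranking, n_perm = 100L, seed = 1L,
                             group_size, terms, alpha = 0.05) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  genes <- if (is.character(ranking)) ranking else ranking$gene_id
  set.seed(seed)
  curves <- lapply(seq_len(n_perm), function(b)
    walk_down(sample(genes), group_size, terms, alpha))
  cc <- vapply(curves, `[[`, numeric(nrow(curves[[1L]])), "cum_clusters")
  cc <- matrix(cc, ncol = n_perm)
  cm <- vapply(curves, `[[`, numeric(nrow(curves[[1L]])), "cum_neglog_minp")
  cm <- matrix(cm, ncol = n_perm)
  data.table::data.table(
    group = curves[[1L]]$group,
    perm_cum_clusters = rowMeans(cc),
    perm_cum_neglog_minp = rowMeans(cm),
    sd_cum_clusters = apply(cc, 1L, stats::sd),
    sd_cum_neglog_minp = apply(cm, 1L, stats::sd))
}

#' Locate the inflection of a cumulative walk-down curve
#'
#' Fits a two-segment piecewise-linear model at every candidate
#' breakpoint (each segment needs at least two groups) and selects the
#' breakpoint minimizing the total squared error, provided the second
#' slope is smaller than the first (the curve "flattens"). The returned
#' threshold is `breakpoint group x group_size` in rank units; `NA` when
#' no flattening exists (e.g. a strictly linear curve).
#'
#' @param curve a `walkdown_curve` from [walk_down()].
#' @param measure which cumulative series to use.
#' @return list: group (breakpoint group), threshold_rank, slope1,
#'   slope2, sse; or NULL when no slope decrease is found.
#' @export
detect_inflection <- function(curve,
                              measure = c("clusters", "minp")) {
  measure <- match.arg(measure)
  y <- if (!is.null(curve[["cum_stat"]])) curve$cum_stat
       else if (measure == "clusters") curve$cum_clusters
       else curve$cum_neglog_minp
  x <- curve$group
  G <- length(x)
  if (G < 4L) stop("need at least 4 groups", call. = FALSE)
  group_size <- attr(curve, "group_size")
  best <- NULL
  sse_tol <- 1e-9 * (sum(y^2) / G + 1)   # fp-noise guard for SSE ties
  # scan right-to-left so that an exact kink (zero error on both sides
  # of the breakpoint, the boundary point lying on both lines) resolves
  # to the kink group itself
  for (b in (G - 2L):2L) {
    i1 <- 1:b; i2 <- (b + 1L):G
    f1 <- stats::lm.fit(cbind(1, x[i1]), y[i1])
    f2 <- stats::lm.fit(cbind(1, x[i2]), y[i2])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    s1 <- f1$coefficients[2L]; s2 <- f2$coefficients[2L]
    flattens <- (s1 - s2) > 1e-8 * max(1, abs(s1))
    better <- is.null(best) || sse < best$sse - sse_tol
    if (flattens && better)
      best <- list(group = b, threshold_rank = b * group_size,
                   slope1 = unname(s1), slope2 = unname(s2), sse = sse)
  }
  best
}

#' Restrict a ranking to a keep-list
#'
#' Filters the ranked gene list to the supplied gene set, preserving the
#' original order and renumbering ranks 1..M.
#'
#' @param ranking ranked gene table (see [rank_genes()]).
#' @param keep character vector of genes to retain.
#' @return filtered ranking with renumbered `rank`.
#' @export
apply_list_filter <- function(ranking, keep) {
  out <- data.table::as.data.table(ranking)[gene_id %in% keep]
  if (nrow(out) == 0L)
    stop("keep-list does not intersect the ranking", call. = FALSE)
  out[, rank := seq_len(.N)]
  out[]
}

#' Walk-down corroboration by differential expression
#'
#' Replaces the enrichment statistic with a per-gene differential
#' expression indicator (e.g. |fold change| or an interaction F): each
#' group's statistic is the mean indicator over its genes, accumulated
#' down the ranking, with a permuted-ranking mean curve as control.
#'
#' @inheritParams walk_down
#' @param diff_expr named numeric indicator per gene; genes with missing
#'   values are dropped with a message.
#' @param n_perm permutations for the control curve.
#' @param seed integer seed.
#' @return object of class `walkdown_curve`: data.table with group,
#'   rank_end, stat (group mean), cum_stat, perm_cum_stat.
#' @export
expression_corroboration <- function(ranking, diff_expr, group_size,
                                     n_perm = 100L, seed = 1L) {
  genes <- if (is.character(ranking)) ranking else ranking$gene_id
  v <- diff_expr[genes]
  drop <- is.na(v)
  if (any(drop)) {
    message(sum(drop), " gene(s) dropped: no differential-expression value")
    genes <- genes[!drop]; v <- v[!drop]
  }
  groups <- walkdown_groups(length(genes), as.integer(group_size))
  stat <- vapply(groups, function(idx) mean(v[idx]), 0)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    pv <- sample(v)
    cumsum(vapply(groups, function(idx) mean(pv[idx]), 0))
  }, numeric(length(groups)))
  perm <- matrix(perm, ncol = n_perm)
  out <- data.table::data.table(
    group = seq_along(groups),
    rank_end = vapply(groups, max, 0L),
    stat = stat,
    cum_stat = cumsum(stat),
    perm_cum_stat = rowMeans(perm))
  data.table::setattr(out, "group_size", as.integer(group_size))
  data.table::setattr(out, "class", c("walkdown_curve", class(out)))
  out[]
}
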