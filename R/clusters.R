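#' Call significant crosslink clusters within one gene
#'
#' Crosslink sites are tested against a within-gene permutation null:
#' the gene's cDNAs (each site contributes `count` of them) are placed
#' uniformly at random across the gene span and per-position heights are
#' re-tabulated, `n_perm` times. For a candidate height h the false
#' discovery proportion is
#' `FDR(h) = mean permuted sites with height >= h / observed sites with height >= h`,
#' and the count threshold is the smallest h with `FDR(h) <= fdr_level`.
#' Significant sites within `merge_dist` nt of each other merge into one
#' cluster; each cluster is summarized by its count-weighted centre of
#' mass (rounded half up) and a 31-nt window extending 15 nt on each
#' side, whose `window_sum` is the summed cDNA count of all events
#' (significant or not) inside the window.
#'
#' @param events crosslink events of a single gene and strand (columns
#'   pos, count; chrom/strand carried through if present).
#' @param gene_start,gene_end gene span (0-based half-open) defining the
#'   permutation space; defaults to the observed event span.
#' @param fdr_level target false-discovery level for site heights.
#' @param n_perm number of permutations (>= 1).
#' @param merge_dist maximum distance (nt) between significant sites in
#'   one cluster.
#' @param seed integer seed for the permutation stream.
#' @return data.table of clusters: com, window_start, window_end,
#'   window_sum, n_sites, threshold, fdr (achieved at threshold). Empty
#'   when no site passes.
#' @export
call_clusters <- function(events, gene_start = NULL, gene_end = NULL,
                          fdr_level = 0.05, n_perm = 100L,
                          merge_dist = 15L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  empty <- data.table::data.table(com = integer(0), window_start = integer(0),
                                  window_end = integer(0),
                                  window_sum = integer(0),
                                  n_sites = integer(0),
                                  threshold = integer(0), fdr = numeric(0))
  if (is.null(events) || nrow(events) == 0L) return(empty)
  pos <- as.integer(events$pos)
  cnt <- as.integer(events$count)
  if (is.null(gene_start)) gene_start <- min(pos)
  if (is.null(gene_end)) gene_end <- max(pos) + 1L
  L <- as.integer(gene_end - gene_start)
  n_cdna <- sum(cnt)
  max_h <- max(cnt)

  thr <- NA_integer_; fdr_at <- NA_real_
  if (max_h >= 2L) {
    obs_ge <- vapply(2:max_h, function(h) sum(cnt >= h), 0L)
    set.seed(seed)
    # all permutations in one draw: heights arise from position collisions
    key <- sample.int(L, n_cdna * n_perm, replace = TRUE) +
      rep.int((seq_len(n_perm) - 1L) * L, rep.int(n_cdna, n_perm))
    heights <- rle(sort.int(key, method = "radix"))$lengths
    perm_ge <- vapply(2:max_h, function(h) sum(heights >= h), 0L) / n_perm
    fdr_h <- pmin(1, perm_ge / obs_ge)
    ok <- which(fdr_h <= fdr_level)
    if (length(ok) > 0L) {
      thr <- (2:max_h)[ok[1L]]
      fdr_at <- fdr_h[ok[1L]]
    }
  }
  if (is.na(thr)) return(empty)

  sig <- which(cnt >= thr)
  o <- order(pos[sig])
  sp <- pos[sig][o]; sc <- cnt[sig][o]
  grp <- cumsum(c(1L, as.integer(diff(sp) > merge_dist)))
  out <- data.table::rbindlist(lapply(split(seq_along(sp), grp), function(i) {
    com <- floor(sum(as.numeric(sp[i]) * sc[i]) / sum(sc[i]) + 0.5)
    ws <- as.integer(com - 15L); we <- as.integer(com + 16L)
    data.table::data.table(
      com = as.integer(com), window_start = ws, window_end = we,
      window_sum = sum(cnt[pos >= ws & pos < we]),
      n_sites = length(i), threshold = thr, fdr = fdr_at)
  }))
  data.table::setorderv(out, "com")
  out[]
}

#' Call clusters for every gene of a genotype library
#'
#' Assigns events to genes by same-strand overlap with the gene span and
#' runs [call_clusters()] per gene. Events outside any gene are ignored.
#'
#' @param events crosslink events (one genotype) from [deduplicate()].
#' @param ann a `genome_annotation`.
#' @inheritParams call_clusters
#' @return data.table of clusters with a gene_id column.
#' @export
call_clusters_all <- function(events, ann, fdr_level = 0.05,
                              n_perm = 100L, merge_dist = 15L, seed = 1L) {
  genes <- ann$genes
  ev_gr <- GenomicRanges::GRanges(events$chrom,
                                  IRanges::IRanges(events$pos + 1L, width = 1L),
                                  strand = events$strand)
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end),
                                 strand = genes$strand)
  hits <- GenomicRanges::findOverlaps(ev_gr, g_gr)
  ev <- data.table::as.data.table(events)[S4Vectors::queryHits(hits)]
  ev[, gene_idx := S4Vectors::subjectHits(hits)]
  res <- ev[, call_clusters(.SD, gene_start = genes$start[gene_idx[1L]],
                            gene_end = genes$end[gene_idx[1L]],
                            fdr_level = fdr_level, n_perm = n_perm,
                            merge_dist = merge_dist,
                            seed = seed + gene_idx[1L]),
            by = gene_idx]
  if (nrow(res) == 0L)
    return(data.table::data.table(gene_id = character(0), com = integer(0),
                                  window_start = integer(0),
                                  window_end = integer(0),
                                  window_sum = integer(0),
                                  n_sites = integer(0),
                                  threshold = integer(0), fdr = numeric(0)))
  res[, gene_id := genes$gene_id[gene_idx]]
  res[, gene_idx := NULL]
  data.table::setcolorder(res, "gene_id")
  res[]
}

#' Normalized cluster occupancy
#'
#' Occupancy of a cluster window is its summed cDNA count divided by the
#' total cDNA count of the library, further divided by the gene's
#' expression (FPKM), approximating the bound fraction of transcripts.
#'
#' @param clusters cluster table from [call_clusters_all()] (needs
#'   gene_id and window_sum).
#' @param library_total total cDNA count of the library (sum of event
#'   counts); must be positive.
#' @param fpkm named per-gene expression vector; genes with missing or
#'   non-positive FPKM are excluded with a message.
#' @return `clusters` with an `occupancy` column added.
#' @export
occupancy <- function(clusters, library_total, fpkm) {
  if (library_total <= 0) stop("library_total must be > 0", call. = FALSE)
  out <- data.table::as.data.table(clusters)
  f <- fpkm[out$gene_id]
  bad <- is.na(f) | f <= 0
  if (any(bad)) {
    message(sum(bad), " cluster(s) dropped: gene FPKM missing or <= 0")
    out <- out[!bad]; f <- f[!bad]
  }
  out[, occupancy := (out$window_sum / library_total) / f]
  out[]
}

#' Expressed-gene filter
#'
#' @param expr named numeric vector of normalized read counts per gene.
#' @param min_reads inclusion threshold (default 10 normalized reads).
#' @return character vector of expressed gene ids.
#' @export
expressed_genes <- function(expr, min_reads = 10) {
  names(expr)[!is.na(expr) & expr >= min_reads]
}

#' Rank genes as RBP targets by background-corrected occupancy
#'
#' For each expressed gene, the wildtype occupancy is that of the
#' wildtype cluster with the highest cDNA count (`window_sum`, ties to
#' the leftmost window; 0 when the gene has no wildtype cluster), from
#' which the highest cluster occupancy of the same gene in the null
#' libraries is subtracted. Genes are ranked by this difference score,
#' descending; ties break by wildtype occupancy descending, then gene id.
#'
#' @param wt,null occupancy tables from [occupancy()] for the wildtype
#'   and null libraries.
#' @param expressed character vector of expressed gene ids (the ranking
#'   universe); see [expressed_genes()].
#' @return data.table: gene_id, wt_occ, null_occ, score, rank.
#' @export
rank_genes <- function(wt, null, expressed) {
  if (length(expressed) == 0L) stop("empty expressed set", call. = FALSE)
  expressed <- unique(expressed)
  wt <- data.table::as.data.table(wt)[gene_id %in% expressed]
  null <- data.table::as.data.table(null)[gene_id %in% expressed]
  wt_best <- if (nrow(wt) > 0L) {
    data.table::setorderv(wt, c("gene_id", "window_sum", "window_start"),
                          c(1L, -1L, 1L))
    wt[, list(wt_occ = occupancy[1L]), by = "gene_id"]
  } else data.table::data.table(gene_id = character(0), wt_occ = numeric(0))
  null_best <- if (nrow(null) > 0L) {
    null[, list(null_occ = max(occupancy)), by = "gene_id"]
  } else data.table::data.table(gene_id = character(0), null_occ = numeric(0))
  out <- data.table::data.table(gene_id = sort(expressed))
  out <- merge(out, wt_best, by = "gene_id", all.x = TRUE)
  out <- merge(out, null_best, by = "gene_id", all.x = TRUE)
  out[is.na(wt_occ), wt_occ := 0]
  out[is.na(null_occ), null_occ := 0]
  out[, score := wt_occ - null_occ]
  data.table::setorderv(out, c("score", "wt_occ", "gene_id"),
                        c(-1L, -1L, 1L))
  out[, rank := seq_len(.N)]
  out[]
}
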