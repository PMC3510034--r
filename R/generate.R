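#' Generate a synthetic genome annotation
#'
#' Lays out `n_genes` genes along a single synthetic chromosome, each
#' with 5'UTR, ORF, intron and 3'UTR segments in transcription order and
#' separated by intergenic gaps. A random subset of genes is flagged as
#' planted RBP targets and receives `sites_per_target` motif site
#' positions inside the 3'UTR; a `decoy_rate` fraction of genes gains an
#' overlapping antisense ncRNA decoy so the full segment priority
#' hierarchy is exercised. Coordinates are 0-based half-open (BED
#' convention) throughout.
#'
#' @param cfg a [sim_config()] object.
#' @return An object of class `genome_annotation`: a list with
#'   data.tables `genes` (gene_id, chrom, strand, start, end, is_target),
#'   `segments` (gene_id, chrom, strand, type, start, end),
#'   `planted_sites` (gene_id, chrom, strand, pos), and named integer
#'   vector `chrom_len`.
#' @examples
#' ann <- generate_annotation(sim_config(n_genes = 20, n_targets = 4, seed = 1))
#' table(ann$segments$type)
#' @export
generate_annotation <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, 0L))
  n <- cfg$n_genes
  seg_types <- c("5UTR", "ORF", "intron", "3UTR")
  means <- c(cfg$utr5_len, cfg$orf_len, cfg$intron_len, cfg$utr3_len)
  motif_len <- nchar(cfg$motif)

  # per-gene segment lengths around the configured means (10% cv)
  len <- matrix(pmax(motif_len + 10L,
                     round(stats::rnorm(n * 4L, rep(means, each = n),
                                        rep(0.1 * means, each = n)))),
                nrow = n)
  gaps <- pmax(50L, stats::rpois(n, cfg$intergenic_len))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_len <- rowSums(len)
  start <- cumsum(c(gaps[1L], gene_len[-n] + gaps[-1L]))
  end <- start + gene_len
  gene_id <- sprintf("G%05d", seq_len(n))
  chrom <- "chrS1"
  is_target <- rep(FALSE, n)
  is_target[sample.int(n, cfg$n_targets)] <- TRUE

  # genomic order of segments follows the strand
  seg <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    ord <- if (strand[i] == "+") 1:4 else 4:1
    w <- len[i, ord]
    s <- start[i] + cumsum(c(0L, w[-4L]))
    data.table::data.table(gene_id = gene_id[i], chrom = chrom,
                           strand = strand[i], type = seg_types[ord],
                           start = as.integer(s), end = as.integer(s + w))
  }))

  genes <- data.table::data.table(gene_id = gene_id, chrom = chrom,
                                  strand = strand,
                                  start = as.integer(start),
                                  end = as.integer(end),
                                  is_target = is_target)

  # antisense ncRNA decoys overlapping the middle third of some genes
  n_decoy <- round(cfg$decoy_rate * n)
  if (n_decoy > 0L) {
    idx <- sample.int(n, n_decoy)
    d_start <- as.integer(start[idx] + gene_len[idx] %/% 3L)
    d_end <- as.integer(start[idx] + 2L * (gene_len[idx] %/% 3L))
    d_strand <- ifelse(strand[idx] == "+", "-", "+")
    d_id <- sprintf("NC%05d", seq_len(n_decoy))
    genes <- rbind(genes,
                   data.table::data.table(gene_id = d_id, chrom = chrom,
                                          strand = d_strand, start = d_start,
                                          end = d_end, is_target = FALSE))
    seg <- rbind(seg,
                 data.table::data.table(gene_id = d_id, chrom = chrom,
                                        strand = d_strand, type = "ncRNA",
                                        start = d_start, end = d_end))
  }

  # motif site positions inside target 3'UTRs, non-overlapping
  target_ids <- gene_id[is_target]
  utr3 <- as.data.frame(seg)[seg$type == "3UTR" &
                               seg$gene_id %in% target_ids, ]
  planted <- data.table::rbindlist(lapply(seq_len(nrow(utr3)), function(i) {
    lo <- utr3$start[i]
    hi <- utr3$end[i] - motif_len
    k <- cfg$sites_per_target
    cand <- seq.int(lo, hi, by = max(motif_len, 2L * motif_len))
    pos <- sort(sample(cand, min(k, length(cand))))
    data.table::data.table(gene_id = utr3$gene_id[i], chrom = chrom,
                           strand = utr3$strand[i], pos = as.integer(pos))
  }))

  chrom_len <- c(chrS1 = as.integer(max(genes$end) + cfg$intergenic_len))
  ann <- list(genes = genes, segments = seg, planted_sites = planted,
              chrom_len = chrom_len)
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", sum(!startsWith(x$genes$gene_id, "NC")),
      "genes (+", sum(startsWith(x$genes$gene_id, "NC")), "ncRNA decoys ),",
      sum(x$genes$is_target), "planted targets,",
      "chromosome length", unname(x$chrom_len[1L]), "nt\n")
  invisible(x)
}

#' Simulate log-normal gene expression (FPKM)
#'
#' @param ann a `genome_annotation`.
#' @param cfg a [sim_config()]; `fpkm_log_mean`/`fpkm_log_sd` are the
#'   `meanlog`/`sdlog` of the log-normal.
#' @return Named numeric vector of FPKM values, one per annotated gene.
#' @export
generate_fpkm <- function(ann, cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, 1L))
  ids <- ann$genes$gene_id
  stats::setNames(stats::rlnorm(length(ids), cfg$fpkm_log_mean,
                                cfg$fpkm_log_sd), ids)
}

#' Simulate the chromosome sequence with planted motif sites
#'
#' Draws a uniform random DNA sequence for each chromosome and writes the
#' configured motif at every planted site so that reading the gene strand
#' 5'->3' from the site position yields the motif.
#'
#' @inheritParams generate_fpkm
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
generate_genome <- function(ann, cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, 2L))
  motif <- cfg$motif
  k <- nchar(motif)
  seqs <- lapply(names(ann$chrom_len), function(ch) {
    L <- ann$chrom_len[[ch]]
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ps <- ann$planted_sites[ann$planted_sites$chrom == ch, ]
    if (nrow(ps) > 0L) {
      fwd <- strsplit(motif, "")[[1L]]
      rev <- strsplit(as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(motif))), "")[[1L]]
      for (i in seq_len(nrow(ps))) {
        p <- ps$pos[i]
        if (ps$strand[i] == "+") {
          s[(p + 1L):(p + k)] <- fwd          # genome [p, p+k)
        } else {
          s[(p - k + 2L):(p + 1L)] <- rev     # genome [p-k+1, p+1)
        }
      }
    }
    paste(s, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(ann$chrom_len)
  out
}

# fixed 4-nt experimental barcodes, one per (genotype, replicate)
exp_barcode <- function(genotype, replicate) {
  tab <- c("ACGT", "CATG", "GTAC", "TGCA", "AAGG", "CCTT", "GGAA", "TTCC")
  i <- (as.integer(replicate) - 1L) * 2L + ifelse(genotype == "wildtype", 1L, 2L)
  tab[((i - 1L) %% length(tab)) + 1L]
}

random_barcodes <- function(n) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), 5L * n, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate iCLIP reads for one genotype
#'
#' Emits single-nucleotide read-start records mimicking deduplicable
#' iCLIP libraries. All libraries receive uniform genome-wide background
#' plus expression-coupled background along gene bodies; wildtype
#' libraries additionally receive signal crosslinks at the planted motif
#' sites of target 3'UTRs at `wt_target_rate` per 3'UTR nt, scaled by
#' relative gene expression. Each read carries a fixed 4-nt experimental
#' barcode (library identity) and a random 5-nt barcode; PCR duplicates
#' (identical position and barcodes) are injected at `pcr_dup_rate`.
#'
#' The crosslink nucleotide sits one nt 5' of the read start, so a
#' crosslink at x is emitted as BED start x+1 on the plus strand and as
#' BED end x on the minus strand.
#'
#' @param ann a `genome_annotation`.
#' @param fpkm named per-gene expression vector (see [generate_fpkm()]).
#' @param cfg a [sim_config()].
#' @param genotype `"wildtype"` or `"null"`.
#' @return data.table with columns chrom, start, end, name
#'   (`exp_barcode:random_barcode`), score, strand, genotype, replicate
#'   and an attribute `n_duplicates` (number of injected PCR copies).
#' @export
generate_iclip_reads <- function(ann, fpkm, cfg, genotype) {
  validate_sim_config(cfg)
  if (!genotype %in% c("wildtype", "null"))
    stop("genotype must be 'wildtype' or 'null'", call. = FALSE)
  set.seed(sim_seed(cfg, if (genotype == "wildtype") 3L else 4L))

  genes <- ann$genes
  scale <- fpkm[genes$gene_id] / mean(fpkm)
  chrom_len <- ann$chrom_len
  utr3 <- ann$segments[ann$segments$type == "3UTR", ]
  utr3_len <- stats::setNames(utr3$end - utr3$start, utr3$gene_id)

  one_replicate <- function(rep_i) {
    # genome-wide uniform background
    xs <- list(); strands <- list()
    for (ch in names(chrom_len)) {
      n_bg <- stats::rpois(1L, cfg$background_rate * chrom_len[[ch]])
      xs[[ch]] <- sample.int(chrom_len[[ch]], n_bg, replace = TRUE) - 1L
      strands[[ch]] <- sample(c("+", "-"), n_bg, replace = TRUE)
    }
    pos <- unlist(xs, use.names = FALSE)
    chrom <- rep(names(chrom_len), lengths(xs))
    strand <- unlist(strands, use.names = FALSE)

    # expression-coupled background over gene bodies
    n_gb <- stats::rpois(nrow(genes),
                         cfg$background_rate * (genes$end - genes$start) * scale)
    gb_pos <- unlist(lapply(which(n_gb > 0L), function(i) {
      genes$start[i] + sample.int(genes$end[i] - genes$start[i],
                                  n_gb[i], replace = TRUE) - 1L
    }), use.names = FALSE)
    if (length(gb_pos) > 0L) {
      pos <- c(pos, gb_pos)
      chrom <- c(chrom, rep(genes$chrom, n_gb))
      strand <- c(strand, rep(genes$strand, n_gb))
    }

    # planted signal at motif sites, wildtype only
    if (genotype == "wildtype" && cfg$wt_target_rate > 0 &&
        nrow(ann$planted_sites) > 0L) {
      tg <- genes[genes$is_target, ]
      lam <- cfg$wt_target_rate * utr3_len[tg$gene_id] *
        scale[match(tg$gene_id, genes$gene_id)]
      n_sig <- stats::rpois(nrow(tg), lam)
      sig <- lapply(which(n_sig > 0L), function(i) {
        st <- ann$planted_sites[ann$planted_sites$gene_id == tg$gene_id[i], ]
        j <- sample.int(nrow(st), n_sig[i], replace = TRUE)
        st[j, c("chrom", "strand", "pos")]
      })
      if (length(sig) > 0L) {
        sig <- data.table::rbindlist(sig)
        pos <- c(pos, sig$pos)
        chrom <- c(chrom, sig$chrom)
        strand <- c(strand, sig$strand)
      }
    }

    n <- length(pos)
    bed_start <- ifelse(strand == "+", pos + 1L, pos - 1L)
    keep <- bed_start >= 0L
    dt <- data.table::data.table(
      chrom = chrom[keep],
      start = as.integer(bed_start[keep]),
      end = as.integer(bed_start[keep] + 1L),
      exp_bc = exp_barcode(genotype, rep_i),
      rand_bc = random_barcodes(sum(keep)),
      strand = strand[keep],
      genotype = genotype,
      replicate = rep_i)

    n_sampled <- nrow(dt)
    dup <- which(stats::runif(nrow(dt)) < cfg$pcr_dup_rate)
    if (length(dup) > 0L) dt <- rbind(dt, dt[dup, ])
    attr(dt, "n_duplicates") <- length(dup)
    attr(dt, "n_sampled") <- n_sampled
    dt
  }

  reps <- lapply(seq_len(cfg$n_replicates), one_replicate)
  out <- data.table::rbindlist(reps)
  out[, `:=`(name = paste(out$exp_bc, out$rand_bc, sep = ":"), score = 1L)]
  data.table::setcolorder(out, c("chrom", "start", "end", "name", "score",
                                 "strand", "genotype", "replicate",
                                 "exp_bc", "rand_bc"))
  attr(out, "n_duplicates") <- sum(vapply(reps, attr, 0L, "n_duplicates"))
  attr(out, "n_sampled") <- sum(vapply(reps, attr, 0L, "n_sampled"))
  out[]
}

#' Build a 2x2 genotype-by-treatment design table
#'
#' @param treatments two treatment labels (e.g. monosome/polysome or
#'   cell_body/neuropil).
#' @param n_rep replicates per genotype x treatment cell.
#' @return data.frame with columns sample, genotype, treatment, replicate.
#' @export
make_design <- function(treatments = c("A", "B"), n_rep = 3L) {
  stopifnot(length(treatments) == 2L, n_rep >= 1L)
  d <- expand.grid(replicate = seq_len(n_rep),
                   treatment = treatments,
                   genotype = c("wt", "null"),
                   stringsAsFactors = FALSE)
  d$sample <- sprintf("%s_%s_r%d", d$genotype, d$treatment, d$replicate)
  d[, c("sample", "genotype", "treatment", "replicate")]
}

#' Simulate a genotype-by-treatment count experiment
#'
#' Draws negative-binomial counts around log-normal per-gene baselines.
#' The planted interaction genes (the first `n_interaction_genes` of the
#' planted targets, in ranking-independent id order) receive a
#' `interaction_effect` log2 shift only in the null-genotype x
#' second-treatment cell, so a genotype-by-treatment interaction exists
#' for exactly those genes.
#'
#' @param ann a `genome_annotation`.
#' @param cfg a [sim_config()].
#' @param design a design table from [make_design()].
#' @return list with `counts` (genes x samples integer matrix), `design`,
#'   `baseline` (per-gene mean), and `interaction_genes`.
#' @export
generate_counts_experiment <- function(ann, cfg, design = make_design()) {
  validate_sim_config(cfg)
  if (is.null(design) || nrow(design) == 0L)
    stop("design must be non-empty", call. = FALSE)
  set.seed(sim_seed(cfg, 10L))
  ids <- ann$genes$gene_id[!startsWith(ann$genes$gene_id, "NC")]
  mu <- stats::setNames(stats::rlnorm(length(ids), cfg$count_log_mean,
                                      cfg$count_log_sd), ids)
  targets <- sort(ann$genes$gene_id[ann$genes$is_target])
  planted <- targets[seq_len(min(cfg$n_interaction_genes, length(targets)))]
  trtB <- unique(design$treatment)[2L]

  counts <- matrix(0L, nrow = length(ids), ncol = nrow(design),
                   dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    m <- mu
    if (design$genotype[j] == "null" && design$treatment[j] == trtB)
      m[planted] <- m[planted] * 2^cfg$interaction_effect
    counts[, j] <- if (cfg$dispersion > 0)
      stats::rnbinom(length(m), mu = m, size = 1 / cfg$dispersion)
    else stats::rpois(length(m), m)
  }
  list(counts = counts, design = design, baseline = mu,
       interaction_genes = planted)
}

#' Simulate functional annotation term sets
#'
#' Generates `n_terms` gene sets over the annotated (non-decoy) genes. A
#' `target_term_fraction` of terms draws its members preferentially from
#' the planted targets (padded from non-targets when `term_size` exceeds
#' the target count), so top-of-ranking enrichment exists by
#' construction; the remaining terms are uniform draws.
#'
#' @inheritParams generate_counts_experiment
#' @return Named list of character vectors with a logical attribute
#'   `enriched` marking the target-concentrated terms.
#' @export
generate_term_sets <- function(ann, cfg) {
  validate_sim_config(cfg)
  if (cfg$term_size <= 0L) stop("term_size must be positive", call. = FALSE)
  genes <- ann$genes$gene_id[!startsWith(ann$genes$gene_id, "NC")]
  if (cfg$term_size > length(genes))
    stop("term_size must not exceed the number of genes", call. = FALSE)
  set.seed(sim_seed(cfg, 20L))
  targets <- ann$genes$gene_id[ann$genes$is_target]
  nontargets <- setdiff(genes, targets)
  n_enr <- round(cfg$target_term_fraction * cfg$n_terms)
  enriched <- seq_len(cfg$n_terms) <= n_enr
  terms <- lapply(seq_len(cfg$n_terms), function(i) {
    if (enriched[i]) {
      k_t <- min(cfg$term_size, length(targets))
      members <- sample(targets, k_t)
      if (k_t < cfg$term_size)
        members <- c(members, sample(nontargets, cfg$term_size - k_t))
      members
    } else {
      sample(genes, cfg$term_size)
    }
  })
  names(terms) <- sprintf("TERM%04d", seq_len(cfg$n_terms))
  attr(terms, "enriched") <- enriched
  terms
}

#' Run every generator and optionally write the files
#'
#' Convenience wrapper producing all inputs the downstream modules
#' consume: annotation, FPKM, wildtype and null read sets, a count
#' experiment, term sets, and (optionally) the chromosome FASTA.
#'
#' @param cfg a [sim_config()].
#' @param outdir if non-NULL, directory into which the standard text
#'   formats are written (annotation TSV, reads BED, expression + design
#'   TSV, GMT, FASTA).
#' @param genome logical; also simulate the chromosome sequence.
#' @return list with elements ann, fpkm, reads_wt, reads_null, experiment,
#'   terms, and genome (NULL unless requested).
#' @export
simulate_study <- function(cfg = sim_config(), outdir = NULL, genome = FALSE) {
  ann <- generate_annotation(cfg)
  fpkm <- generate_fpkm(ann, cfg)
  reads_wt <- generate_iclip_reads(ann, fpkm, cfg, "wildtype")
  reads_null <- generate_iclip_reads(ann, fpkm, cfg, "null")
  expt <- generate_counts_experiment(ann, cfg)
  terms <- generate_term_sets(ann, cfg)
  gen <- if (genome) generate_genome(ann, cfg) else NULL
  out <- list(ann = ann, fpkm = fpkm, reads_wt = reads_wt,
              reads_null = reads_null, experiment = expt, terms = terms,
              genome = gen)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_annotation(ann, file.path(outdir, "annotation.tsv"))
    write_reads_bed(reads_wt, file.path(outdir, "reads_wildtype.bed"))
    write_reads_bed(reads_null, file.path(outdir, "reads_null.bed"))
    utils::write.table(data.frame(gene_id = names(fpkm), fpkm = fpkm),
                       file.path(outdir, "fpkm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = rownames(expt$counts),
                                  expt$counts, check.names = FALSE),
                       file.path(outdir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expt$design, file.path(outdir, "design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(terms, file.path(outdir, "terms.gmt"))
    if (!is.null(gen))
      Biostrings::writeXStringSet(gen, file.path(outdir, "genome.fa"))
  }
  invisible(out)
}
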