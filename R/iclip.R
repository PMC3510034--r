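SEGMENT_PRIORITY <- c("ncRNA", "3UTR", "5UTR", "ORF", "intron",
                      "antisense", "intergenic")

#' Collapse PCR duplicates into crosslink events
#'
#' Reads sharing (chrom, start, strand, experimental barcode, random
#' barcode) collapse to a single cDNA; the per-position event count is
#' the number of distinct barcode combinations observed there. The
#' crosslink nucleotide lies one nt 5' of the read start: position
#' `start - 1` on the plus strand and position `end` on the minus strand
#' (0-based).
#'
#' Replicate libraries of a genotype are pooled by default, since the
#' experimental barcode remains part of the deduplication key.
#'
#' @param reads extended-BED read table with columns chrom, start, end,
#'   strand, exp_bc, rand_bc, genotype (see [read_reads_bed()]).
#' @param per_replicate keep replicates separate instead of pooling.
#' @return data.table of crosslink events: chrom, pos, strand, genotype
#'   (and replicate when `per_replicate`), count.
#' @examples
#' r <- data.table::data.table(chrom = "c", start = 100L, end = 101L,
#'   strand = "+", exp_bc = "ACGT", rand_bc = c("AAAAA", "AAAAA", "CCCCC"),
#'   genotype = "wildtype", replicate = 1L)
#' deduplicate(r)  # one event at position 99 with count 2
#' @export
deduplicate <- function(reads, per_replicate = FALSE) {
  stopifnot(all(c("chrom", "start", "end", "strand", "exp_bc", "rand_bc",
                  "genotype") %in% names(reads)))
  if (any(nchar(reads$exp_bc) != 4L) || any(nchar(reads$rand_bc) != 5L))
    stop("malformed barcode length (expect 4-nt experimental, 5-nt random)",
         call. = FALSE)
  dt <- data.table::as.data.table(reads)
  key <- c("chrom", "start", "strand", "exp_bc", "rand_bc", "genotype",
           if (per_replicate) "replicate")
  cdna <- unique(dt, by = key)
  cdna[, pos := data.table::fifelse(cdna$strand == "+",
                                    cdna$start - 1L, cdna$end)]
  grp <- c("chrom", "pos", "strand", "genotype",
           if (per_replicate) "replicate")
  ev <- cdna[, list(count = .N), by = grp]
  data.table::setorderv(ev, grp)
  ev[]
}

# stranded label map of the annotation: for each (strand, position) the
# winning label under ncRNA > 3UTR > 5UTR > ORF > intron > antisense,
# with everything else intergenic. Returns a GRangesList by label.
segment_label_ranges <- function(ann) {
  seg <- ann$segments
  gr <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$start + 1L, seg$end),
                               strand = seg$strand, type = seg$type)
  genes <- ann$genes
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end),
                                    strand = genes$strand)
  out <- list()
  claimed_plus <- GenomicRanges::GRanges()
  claimed_minus <- GenomicRanges::GRanges()
  for (lab in c("ncRNA", "3UTR", "5UTR", "ORF", "intron")) {
    r <- GenomicRanges::reduce(gr[gr$type == lab])
    p <- r[BiocGenerics::strand(r) == "+"]
    m <- r[BiocGenerics::strand(r) == "-"]
    p <- GenomicRanges::setdiff(p, claimed_plus)
    m <- GenomicRanges::setdiff(m, claimed_minus)
    claimed_plus <- GenomicRanges::union(claimed_plus, p)
    claimed_minus <- GenomicRanges::union(claimed_minus, m)
    out[[lab]] <- c(p, m)
  }
  # antisense: opposite-strand gene extent not claimed by same-strand features
  flip <- gene_gr
  BiocGenerics::strand(flip) <- ifelse(
    as.character(BiocGenerics::strand(gene_gr)) == "+", "-", "+")
  fp <- GenomicRanges::reduce(flip[BiocGenerics::strand(flip) == "+"])
  fm <- GenomicRanges::reduce(flip[BiocGenerics::strand(flip) == "-"])
  out[["antisense"]] <- c(GenomicRanges::setdiff(fp, claimed_plus),
                          GenomicRanges::setdiff(fm, claimed_minus))
  out
}

#' Assign each crosslink event to a genomic segment class
#'
#' Among all annotation features overlapping the crosslink nucleotide,
#' the highest-priority label wins, under the fixed hierarchy
#' ncRNA > 3'UTR > 5'UTR > ORF (exon) > intron > antisense > intergenic.
#' Same-strand features are considered first; a position covered only by
#' an opposite-strand gene is antisense; positions overlapping nothing
#' are intergenic.
#'
#' @param events crosslink-event table from [deduplicate()].
#' @param ann a `genome_annotation`.
#' @return `events` with an added factor column `label`.
#' @export
assign_segment <- function(events, ann) {
  labs <- segment_label_ranges(ann)
  ev_gr <- GenomicRanges::GRanges(events$chrom,
                                  IRanges::IRanges(events$pos + 1L, width = 1L),
                                  strand = events$strand)
  label <- rep("intergenic", nrow(events))
  for (lab in rev(names(labs))) {     # low priority first, overwritten by high
    hit <- IRanges::overlapsAny(ev_gr, labs[[lab]])
    label[hit] <- lab
  }
  out <- data.table::as.data.table(events)
  out[, label := factor(label, levels = SEGMENT_PRIORITY)]
  out[]
}

#' Segment enrichment of crosslink events
#'
#' For each segment class, the fraction of events carrying that label is
#' divided by the fraction of the (stranded) genome covered by the
#' class, so a ratio of 1 means no enrichment over genomic abundance.
#'
#' @param calls labelled events from [assign_segment()].
#' @param ann a `genome_annotation`.
#' @return data.table with label, n_events, event_fraction,
#'   genome_fraction, enrichment. Labels with zero genomic coverage get
#'   `NA` enrichment and a warning.
#' @export
segment_enrichment <- function(calls, ann) {
  if (nrow(calls) == 0L) stop("no events", call. = FALSE)
  labs <- segment_label_ranges(ann)
  total_space <- 2 * sum(as.numeric(ann$chrom_len))   # both strands
  cov <- vapply(labs, function(r) sum(as.numeric(BiocGenerics::width(r))),
                0)
  cov <- c(cov, intergenic = total_space - sum(cov))
  # one event = one unique cDNA, so positions weigh in with their counts
  w <- if (!is.null(calls[["count"]])) as.numeric(calls$count)
       else rep(1, nrow(calls))
  n <- vapply(SEGMENT_PRIORITY, function(l) sum(w[calls$label == l]), 0)
  out <- data.table::data.table(
    label = SEGMENT_PRIORITY,
    n_events = n,
    event_fraction = n / sum(w),
    genome_fraction = cov[SEGMENT_PRIORITY] / total_space)
  out[, enrichment := out$event_fraction / out$genome_fraction]
  if (any(out$genome_fraction == 0 & out$n_events > 0)) {
    warning("label with zero genomic coverage; enrichment undefined")
    out[out$genome_fraction == 0, "enrichment"] <- NA_real_
  }
  out[]
}
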