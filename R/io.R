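#' Read and write the package's plain-text formats
#'
#' All tabular interchange uses TSV; reads use a 6+ column extended BED
#' (chrom, start, end, name = `exp_barcode:random_barcode`, score,
#' strand, genotype, replicate); term sets use GMT. Coordinates are
#' 0-based half-open.
#'
#' @param ann a `genome_annotation`.
#' @param path file path.
#' @name clipwalk-io
NULL

#' @rdname clipwalk-io
#' @export
write_annotation <- function(ann, path) {
  seg <- data.table::copy(ann$segments)
  seg[, is_target := seg$gene_id %in% ann$genes$gene_id[ann$genes$is_target]]
  data.table::fwrite(seg, path, sep = "\t")
  invisible(path)
}

#' @rdname clipwalk-io
#' @export
read_annotation <- function(path) {
  seg <- data.table::fread(path, sep = "\t")
  genes <- seg[, list(chrom = chrom[1L], strand = strand[1L],
                      start = min(start), end = max(end),
                      is_target = is_target[1L]),
               by = "gene_id"]
  ann <- list(genes = genes,
              segments = seg[, c("gene_id", "chrom", "strand", "type",
                                 "start", "end")],
              planted_sites = data.table::data.table(
                gene_id = character(0), chrom = character(0),
                strand = character(0), pos = integer(0)),
              chrom_len = vapply(split(seg$end, seg$chrom), max, 0L))
  class(ann) <- "genome_annotation"
  ann
}

#' @param reads a read-set data.table (see [generate_iclip_reads()]).
#' @rdname clipwalk-io
#' @export
write_reads_bed <- function(reads, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "genotype", "replicate")
  data.table::fwrite(reads[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname clipwalk-io
#' @export
read_reads_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "genotype",
                                        "replicate"))
  bc <- data.table::tstrsplit(dt$name, ":", fixed = TRUE)
  dt[, `:=`(exp_bc = bc[[1L]], rand_bc = bc[[2L]])]
  dt[]
}

#' @param terms named list of character vectors.
#' @rdname clipwalk-io
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(nm) {
    paste(c(nm, "synthetic", terms[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname clipwalk-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- vapply(parts, `[[`, "", 1L)
  terms
}

#' @rdname clipwalk-io
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}

#' @rdname clipwalk-io
#' @export
read_design <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
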