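#' Extract strand-aware sequence windows around crosslink sites
#'
#' Returns the `2 * half_width + 1` nt window centred on each crosslink
#' nucleotide, reverse-complemented for minus-strand events so windows
#' read 5'->3' on the bound strand. Events whose window would run past a
#' sequence end are dropped with a message. Typical half-widths are 10
#' and 30 nt.
#'
#' @param events crosslink events (chrom, pos, strand); usually the
#'   member sites of significant clusters.
#' @param genome a [Biostrings::DNAStringSet] named by chromosome, or a
#'   FASTA path.
#' @param half_width window half-width in nt.
#' @return character vector of windows (one per retained event).
#' @export
extract_flanks <- function(events, genome, half_width = 10L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!all(events$chrom %in% names(genome)))
    stop("event chromosome missing from genome", call. = FALSE)
  len <- Biostrings::width(genome)[match(events$chrom, names(genome))]
  start1 <- events$pos - half_width + 1L          # 1-based
  end1 <- events$pos + half_width + 1L
  keep <- start1 >= 1L & end1 <= len
  if (any(!keep))
    message(sum(!keep), " event(s) dropped at sequence ends")
  if (sum(keep) == 0L) return(character(0))
  v <- Biostrings::DNAStringSet(genome[events$chrom[keep]],
                                start = start1[keep], end = end1[keep])
  minus <- events$strand[keep] == "-"
  if (any(minus)) v[minus] <- Biostrings::reverseComplement(v[minus])
  as.character(unname(v))
}

ALL_PENTAMERS <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 5L),
                                             stringsAsFactors = FALSE)[, 5:1])

count_pentamers <- function(windows) {
  ss <- Biostrings::DNAStringSet(windows)
  cnt <- colSums(Biostrings::oligonucleotideFrequency(ss, width = 5L))
  cnt[ALL_PENTAMERS]
}

shuffle_windows <- function(windows) {
  vapply(strsplit(windows, "", fixed = TRUE),
         function(ch) paste(sample(ch), collapse = ""), "")
}

#' Pentamer z-scores against shuffled-sequence controls
#'
#' Counts overlapping 5-mer occurrences over the supplied windows, then
#' builds `n_random` control sets in which each window is independently
#' mononucleotide-shuffled (preserving its exact base composition), and
#' reports per pentamer `z = (obs - mean_control) / sd_control`. When
#' the control sd is 0, z is 0 if the observation equals the control
#' mean and +/-Inf otherwise.
#'
#' @param windows character vector of equal-purpose sequence windows
#'   (see [extract_flanks()]).
#' @param n_random number of shuffled control sets (>= 2).
#' @param seed integer seed for the shuffles.
#' @return data.table: pentamer, obs, mean, sd, z, sorted by z
#'   descending.
#' @export
pentamer_zscores <- function(windows, n_random = 100L, seed = 1L) {
  if (length(windows) == 0L) stop("empty window set", call. = FALSE)
  if (n_random < 2L) stop("n_random must be >= 2", call. = FALSE)
  obs <- count_pentamers(windows)
  set.seed(seed)
  ctrl <- matrix(0, nrow = length(ALL_PENTAMERS), ncol = n_random,
                 dimnames = list(ALL_PENTAMERS, NULL))
  for (b in seq_len(n_random))
    ctrl[, b] <- count_pentamers(shuffle_windows(windows))
  mu <- rowMeans(ctrl)
  sd <- apply(ctrl, 1L, stats::sd)
  z <- ifelse(sd > 0, (obs - mu) / sd,
              ifelse(obs == mu, 0, ifelse(obs > mu, Inf, -Inf)))
  out <- data.table::data.table(pentamer = ALL_PENTAMERS,
                                obs = as.numeric(obs), mean = mu,
                                sd = sd, z = z)
  data.table::setorderv(out, c("z", "pentamer"), c(-1L, 1L))
  out[]
}

#' Contrast pentamer z-scores between genotypes
#'
#' @param z_wt,z_null pentamer z tables from [pentamer_zscores()] over
#'   the same pentamer universe.
#' @return data.table: pentamer, z_wt, z_null, dz = z_wt - z_null,
#'   ranked by dz descending.
#' @export
genotype_contrast <- function(z_wt, z_null) {
  if (!setequal(z_wt$pentamer, z_null$pentamer))
    stop("mismatched pentamer universes", call. = FALSE)
  m <- merge(z_wt[, c("pentamer", "z")], z_null[, c("pentamer", "z")],
             by = "pentamer", suffixes = c("_wt", "_null"))
  m[, dz := z_wt - z_null]
  data.table::setorderv(m, c("dz", "pentamer"), c(-1L, 1L))
  m[]
}
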