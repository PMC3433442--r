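# Strand-resolved exact mapping and coverage over a single reference
# (e.g. an organelle genome).

#' Map tags exactly to a genome on both strands
#'
#' Exact matches of each tag (and its reverse complement) against a single
#' reference sequence. Multi-locus tags contribute full read weight at
#' every locus by default (a plastid inverted repeat is counted twice, as
#' in genome-wide coverage plots); `weight = "fractional"` divides each
#' tag's count evenly across its loci. Coverage increments at every
#' covered position, count-weighted.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @param genome single reference sequence (character scalar).
#' @param max_loci drop tags with more than this many loci (default Inf).
#' @param weight "full" (default) or "fractional".
#' @return list with `loci` (data.frame: `sequence`, `count`, `strand`,
#'   `start`, `end`, 0-based half-open forward coordinates), `coverage`
#'   (data.frame: `position` 1-based, `sense`, `antisense`; antisense
#'   stored as non-negative, negated only in exports), `starts` (per-strand
#'   read-start count vectors) and `totals` (unique tags mapped, reads
#'   mapped once per tag, and multi-locus read total).
#' @export
map_genome <- function(tags, genome, max_loci = Inf,
                       weight = c("full", "fractional")) {
  weight <- match.arg(weight)
  genome <- rna_norm(genome)
  L <- nchar(genome)
  sense <- numeric(L)
  anti <- numeric(L)
  s_start <- numeric(L)
  a_start <- numeric(L)
  loci <- list()
  n_unique <- 0L
  reads_once <- 0
  reads_multi <- 0
  for (i in seq_len(nrow(tags))) {
    tag <- rna_norm(tags$sequence[i])
    cnt <- tags$count[i]
    hit_rows <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else revcomp_rna(tag)
      for (pos in find_fixed_matches(pat, genome)) {
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          sequence = tag, count = cnt, strand = strand,
          start = pos, end = pos + nchar(tag), stringsAsFactors = FALSE)
      }
    }
    if (length(hit_rows) == 0 || length(hit_rows) > max_loci) next
    n_unique <- n_unique + 1L
    reads_once <- reads_once + cnt
    w <- if (weight == "full") cnt else cnt / length(hit_rows)
    for (h in hit_rows) {
      reads_multi <- reads_multi + w
      span <- seq(h$start + 1, h$end)
      if (h$strand == "+") {
        sense[span] <- sense[span] + w
        s_start[h$start + 1] <- s_start[h$start + 1] + w
      } else {
        anti[span] <- anti[span] + w
        a_start[h$start + 1] <- a_start[h$start + 1] + w
      }
      loci[[length(loci) + 1L]] <- h
    }
  }
  loci_df <- if (length(loci)) do.call(rbind, loci) else
    data.frame(sequence = character(), count = integer(),
               strand = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  rownames(loci_df) <- NULL
  list(loci = loci_df,
       coverage = data.frame(position = seq_len(L), sense = sense,
                             antisense = anti),
       starts = list(sense = s_start, antisense = a_start),
       totals = list(unique_tags = n_unique, reads = reads_once,
                     reads_multi_locus = reads_multi))
}

#' Size distribution of the mapped tag subset
#'
#' @param tags full tag set.
#' @param mapping [map_genome()] result.
#' @return [size_distribution()] of the tags with at least one locus.
#' @export
size_stats_of_mapped <- function(tags, mapping) {
  mapped <- tags[rna_norm(tags$sequence) %in% mapping$loci$sequence, ,
                 drop = FALSE]
  size_distribution(mapped)
}

#' Coverage clusters along the reference
#'
#' Maximal runs of positions with non-zero coverage on one strand, merged
#' across zero-coverage gaps shorter than `gap_nt`, kept when the total
#' read starts in the interval reach `min_reads`.
#'
#' @param mapping [map_genome()] result.
#' @param min_reads minimum total reads per cluster (default 50).
#' @param gap_nt gaps below this length are bridged (default 100).
#' @return data.frame with `strand`, `start`, `end` (0-based half-open),
#'   `total_reads`.
#' @export
coverage_clusters <- function(mapping, min_reads = 50, gap_nt = 100) {
  res <- list()
  for (strand in c("+", "-")) {
    cov <- if (strand == "+") mapping$coverage$sense else
      mapping$coverage$antisense
    starts <- if (strand == "+") mapping$starts$sense else
      mapping$starts$antisense
    nz <- which(cov > 0)
    if (length(nz) == 0) next
    brk <- which(diff(nz) > gap_nt)
    run_start <- nz[c(1, brk + 1)]
    run_end <- nz[c(brk, length(nz))]
    for (k in seq_along(run_start)) {
      tot <- sum(starts[run_start[k]:run_end[k]])
      if (tot >= min_reads) {
        res[[length(res) + 1L]] <- data.frame(
          strand = strand, start = run_start[k] - 1L, end = run_end[k],
          total_reads = tot, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), total_reads = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export strand coverage as a wiggle-style TSV
#'
#' Positions are 1-based; antisense counts are written as negative numbers,
#' the convention used in strand-resolved coverage plots.
#'
#' @param mapping [map_genome()] result.
#' @param path output TSV.
#' @param drop_zero omit positions with no coverage (default TRUE).
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(mapping, path, drop_zero = TRUE) {
  cov <- mapping$coverage
  out <- data.frame(position = cov$position, sense = cov$sense,
                    antisense = -cov$antisense)
  if (drop_zero) out <- out[out$sense != 0 | out$antisense != 0, ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
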