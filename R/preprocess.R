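# Raw FASTQ -> clean collapsed unique tags and population summaries.

#' Clean raw small RNA reads
#'
#' Locates the 3' adapter by best ungapped prefix match (at least
#' `min_overlap` nt of the adapter aligned, at most one mismatch), trims it,
#' then applies quality, N-content and length filters and converts the
#' surviving inserts to the RNA alphabet. "Low quality" is defined as mean
#' Phred below `min_mean_q` (the upstream publication pipeline left its
#' threshold unstated; this default is documented and configurable). Reads
#' in which no adapter is found are kept when they already fall inside the
#' length window, unless `require_adapter` is set.
#'
#' @param raw data.frame of raw reads (`id`, `sequence`, `quality`), e.g.
#'   from [read_fastq_records()].
#' @param adapter 3' adapter sequence (DNA or RNA alphabet), length >= 6.
#' @param min_len,max_len insert length bounds (default 18-30 nt).
#' @param min_mean_q minimum mean Phred quality (default 20).
#' @param max_N maximum number of N bases tolerated (default 0).
#' @param min_overlap minimum adapter prefix overlap (default 6).
#' @param require_adapter drop reads with no adapter match (default FALSE).
#' @return character vector of clean insert sequences (RNA alphabet).
#' @export
clean_reads <- function(raw, adapter, min_len = 18, max_len = 30,
                        min_mean_q = 20, max_N = 0, min_overlap = 6,
                        require_adapter = FALSE) {
  if (nchar(adapter) < 6) stop("adapter must be at least 6 nt")
  adapter <- dna_norm(adapter)
  n <- nrow(raw)
  if (n == 0) return(character(0))
  out <- character(0)
  for (i in seq_len(n)) {
    s <- dna_norm(raw$sequence[i])
    q <- raw$quality[i]
    pos <- find_adapter(s, adapter, min_overlap = min_overlap,
                        max_mismatch = 1)
    if (is.na(pos)) {
      if (require_adapter) next
      insert <- s
      insq <- q
    } else {
      insert <- substr(s, 1, pos - 1)
      insq <- substr(q, 1, pos - 1)
    }
    len <- nchar(insert)
    if (len < min_len || len > max_len) next
    if (nchar(gsub("[^N]", "", insert)) > max_N) next
    if (nchar(insq) > 0 && mean_phred(insq) < min_mean_q) next
    out <- c(out, rna_norm(insert))
  }
  out
}

# best ungapped match of the adapter prefix starting at each position of the
# read 3' end; returns the 1-based start of the adapter or NA.  Earliest
# (longest-insert... no: leftmost) full-criteria match wins so that a
# complete adapter occurrence beats a chance suffix hit.
find_adapter <- function(seq, adapter, min_overlap = 6, max_mismatch = 1) {
  L <- nchar(seq)
  A <- nchar(adapter)
  if (L < min_overlap) return(NA_integer_)
  sv <- seq_chars(seq)
  av <- seq_chars(adapter)
  for (start in seq_len(L - min_overlap + 1)) {
    ov <- min(A, L - start + 1)
    mm <- sum(sv[start:(start + ov - 1)] != av[seq_len(ov)])
    if (mm <= max_mismatch) return(start)
  }
  NA_integer_
}

#' Collapse clean sequences into unique tags
#'
#' One tag per distinct sequence with its read multiplicity, ordered by
#' count (descending) then sequence (lexicographic). The sum of tag counts
#' always equals the number of input sequences.
#'
#' @param sequences character vector of clean sequences.
#' @return data.frame with columns `sequence`, `count`.
#' @export
collapse_tags <- function(sequences) {
  if (length(sequences) == 0) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tb <- table(sequences)
  df <- data.frame(sequence = names(tb), count = as.integer(tb),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the `tag<N>_x<count>` convention used by collapsed small
#' RNA libraries.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path) {
  seqs <- tags$sequence
  names(seqs) <- sprintf("tag%d_x%d", seq_along(seqs), tags$count)
  write_fasta_seqs(seqs, path)
}

#' Size distribution of a tag set
#'
#' Read-weighted and unique-weighted length histograms with one-decimal
#' percentages over lengths present in the data.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @param lengths lengths to report (default: those observed).
#' @return data.frame with `length`, `read_count`, `unique_count`,
#'   `read_percent`, `unique_percent`.
#' @export
size_distribution <- function(tags, lengths = NULL) {
  len <- nchar(tags$sequence)
  if (is.null(lengths)) lengths <- sort(unique(len))
  if (length(lengths) == 0) {
    return(data.frame(length = integer(), read_count = integer(),
                      unique_count = integer(), read_percent = numeric(),
                      unique_percent = numeric()))
  }
  rc <- vapply(lengths, function(l) sum(tags$count[len == l]), numeric(1))
  uc <- vapply(lengths, function(l) sum(len == l), numeric(1))
  data.frame(length = as.integer(lengths),
             read_count = as.integer(rc),
             unique_count = as.integer(uc),
             read_percent = percent(rc, sum(rc)),
             unique_percent = percent(uc, sum(uc)))
}

#' 5'-base composition per length
#'
#' Fraction of unique tags starting with each of A, C, G, U in every size
#' group; lengths absent from the data are omitted.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @return data.frame with `length`, `A`, `C`, `G`, `U` (fractions summing
#'   to 1 per row).
#' @export
first_base_profile <- function(tags) {
  if (nrow(tags) == 0) {
    return(data.frame(length = integer(), A = numeric(), C = numeric(),
                      G = numeric(), U = numeric()))
  }
  len <- nchar(tags$sequence)
  fb <- substr(tags$sequence, 1, 1)
  lengths <- sort(unique(len))
  rows <- lapply(lengths, function(l) {
    sel <- fb[len == l]
    n <- length(sel)
    data.frame(length = l, A = sum(sel == "A") / n, C = sum(sel == "C") / n,
               G = sum(sel == "G") / n, U = sum(sel == "U") / n)
  })
  do.call(rbind, rows)
}
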