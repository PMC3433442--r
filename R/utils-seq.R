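#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' The package works internally in RNA space (A/C/G/U). Input may use T or U,
#' any case; `N` is preserved.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector in uppercase RNA alphabet.
#' @export
rna_norm <- function(x) {
  chartr("acgtuT", "ACGUUU", x)
}

#' Normalize to DNA alphabet (A/C/G/T)
#' @param x character vector of nucleotide strings.
#' @return character vector in uppercase DNA alphabet.
#' @export
dna_norm <- function(x) {
  chartr("acgtuU", "ACGTTT", x)
}

#' Reverse complement in RNA space
#' @param x character vector (RNA or DNA; T treated as U).
#' @return reverse complement, RNA alphabet.
#' @export
revcomp_rna <- function(x) {
  x <- rna_norm(x)
  vapply(x, function(s) {
    v <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(chartr("ACGUN", "UGCAN", v), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of a sequence
#' @param x character vector of nucleotide strings.
#' @return numeric vector in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  x <- rna_norm(x)
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n == 0, NA_real_, gc / n)
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Round half-up at a decimal position
#'
#' Decimal (not binary) half-up rounding, matching how one-decimal
#' percentages are conventionally printed. A tiny epsilon absorbs binary
#' floating-point representation error.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sgn <- sign(x)
  sgn * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @param alphabet "rna" (default) converts T to U; "dna" converts U to T;
#'   "as-is" leaves sequences untouched apart from uppercasing.
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(path, alphabet = c("rna", "dna", "as-is")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  v <- as.character(ss)
  names(v) <- sub("\\s.*$", "", names(ss))
  switch(alphabet, rna = rna_norm(v), dna = dna_norm(v), toupper(v))
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Parse a FASTQ file (Sanger Phred+33)
#'
#' Minimal strict 4-line-record parser. Malformed records raise an error
#' naming the record index.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: line count ", length(lines),
         " is not a multiple of 4 in ", path)
  }
  n <- length(lines) / 4
  if (n == 0) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  hd <- lines[seq(1, by = 4, length.out = n)]
  sq <- lines[seq(2, by = 4, length.out = n)]
  pl <- lines[seq(3, by = 4, length.out = n)]
  qu <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(qu))
  if (length(bad) > 0) {
    stop("malformed FASTQ record at index ", bad[1], " in ", path)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hd)),
             sequence = toupper(sq), quality = qu, stringsAsFactors = FALSE)
}

#' Write FASTQ records
#' @param records data.frame with `id`, `sequence`, `quality`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq_records <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", records$id), records$sequence, "+",
               records$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

# all (possibly overlapping) exact occurrences of pat in subj; 0-based starts
find_fixed_matches <- function(pat, subj) {
  if (nchar(pat) == 0 || nchar(pat) > nchar(subj)) return(integer(0))
  m <- Biostrings::matchPattern(pat, subj)
  BiocGenerics::start(m) - 1L
}

# mean Phred quality (Sanger +33 offset) of one quality string
mean_phred <- function(q) {
  if (nchar(q) == 0) return(NA_real_)
  mean(as.integer(charToRaw(q)) - 33L)
}
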