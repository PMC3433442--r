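# Penalty-score miRNA target prediction in sliding complementary windows.

#' Target-prediction scoring scheme
#'
#' The classic plant weighting: mismatch 1.0, G:U wobble 0.5, gap 2.0,
#' every penalty doubled when the miRNA position lies in the seed region
#' (positions 2-13, 1-based from the miRNA 5' end), at most one gap, and
#' an inclusive cutoff of 3.0.
#'
#' @param mismatch_penalty,gu_penalty,gap_penalty per-event penalties.
#' @param seed_start,seed_end seed region bounds (1-based miRNA positions).
#' @param seed_multiplier penalty multiplier inside the seed.
#' @param max_gaps maximum gaps in the duplex (0 or 1).
#' @param cutoff inclusive penalty cutoff for reported sites.
#' @return `scoring_scheme` list.
#' @export
scoring_scheme <- function(mismatch_penalty = 1.0, gu_penalty = 0.5,
                           gap_penalty = 2.0, seed_start = 2, seed_end = 13,
                           seed_multiplier = 2.0, max_gaps = 1,
                           cutoff = 3.0) {
  stopifnot(mismatch_penalty >= 0, gu_penalty >= 0, gap_penalty >= 0,
            cutoff >= 0, max_gaps %in% c(0, 1))
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty, gap_penalty = gap_penalty,
                 seed_start = seed_start, seed_end = seed_end,
                 seed_multiplier = seed_multiplier, max_gaps = max_gaps,
                 cutoff = cutoff), class = "scoring_scheme")
}

# per-position penalty of miRNA base X against the revcomp-transformed
# site base t: 0 = Watson-Crick, gu = wobble, mismatch otherwise.
# On the transformed site, wobble G:U pairs become (G, A) and (U, C).
.pair_penalty <- function(x, t, scheme) {
  p <- ifelse(x == t, 0,
              ifelse((x == "G" & t == "A") | (x == "U" & t == "C"),
                     scheme$gu_penalty, scheme$mismatch_penalty))
  p
}

.seed_weight <- function(pos, scheme) {
  ifelse(pos >= scheme$seed_start & pos <= scheme$seed_end,
         scheme$seed_multiplier, 1)
}

# optimal-alignment scorer shared by score_duplex and scan_targets.
# Returns list(penalty, type, gap_pos): type is "none", "mir" (unopposed
# miRNA base = bulge in the site) or "site" (unopposed site base).
.align_duplex <- function(mx, tx, scheme) {
  m <- length(mx)
  n <- length(tx)
  best <- list(penalty = Inf, type = "none", gap_pos = NA_integer_)
  if (n == m) {
    w <- .seed_weight(seq_len(m), scheme)
    pen <- sum(.pair_penalty(mx, tx, scheme) * w)
    best <- list(penalty = pen, type = "none", gap_pos = NA_integer_)
    if (scheme$max_gaps < 1 || m < 2) return(best)
    return(best)
  }
  if (scheme$max_gaps < 1) return(best)
  if (n == m - 1) {
    # one miRNA base unopposed: gap column at miRNA position g
    w <- .seed_weight(seq_len(m), scheme)
    pre <- cumsum(c(0, .pair_penalty(mx[seq_len(n)], tx, scheme) *
                      w[seq_len(n)]))
    suf <- rev(cumsum(rev(c(.pair_penalty(mx[-1], tx, scheme) * w[-1], 0))))
    for (g in seq_len(m)) {
      pen <- pre[g] + scheme$gap_penalty * w[g] + suf[g]
      if (pen < best$penalty) {
        best <- list(penalty = pen, type = "mir", gap_pos = g)
      }
    }
  } else if (n == m + 1) {
    # one site base unopposed: gap column between miRNA positions g-1 and g
    w <- .seed_weight(seq_len(m), scheme)
    pre <- cumsum(c(0, .pair_penalty(mx, tx[seq_len(m)], scheme) * w))
    suf <- rev(cumsum(rev(c(.pair_penalty(mx, tx[-1], scheme) * w, 0))))
    for (g in seq_len(m + 1)) {
      gw <- .seed_weight(min(g, m), scheme)
      pen <- pre[g] + scheme$gap_penalty * gw + suf[g]
      if (pen < best$penalty) {
        best <- list(penalty = pen, type = "site", gap_pos = g)
      }
    }
  }
  best
}

#' Penalty score of a miRNA against one site window
#'
#' Optimal gapped alignment (at most `scheme$max_gaps` gaps) of the miRNA
#' against the window, minimizing the weighted sum of mismatch, G:U and gap
#' penalties with seed doubling. Window and miRNA are both given 5' to 3';
#' the duplex is antiparallel.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet).
#' @param window candidate site, length within `max_gaps` of the miRNA.
#' @param scheme [scoring_scheme()].
#' @param detail also return the alignment rendering (default FALSE).
#' @return penalty (numeric), or with `detail = TRUE` a list with
#'   `penalty`, `pairing` (site-oriented string: `|` Watson-Crick, `o`
#'   wobble, space mismatch, `-` gap) and `gap` info.
#' @export
score_duplex <- function(mirna, window, scheme = scoring_scheme(),
                         detail = FALSE) {
  mirna <- rna_norm(mirna)
  window <- rna_norm(window)
  if (grepl("[^ACGU]", mirna) || grepl("[^ACGU]", window)) {
    stop("score_duplex(): sequences must be A/C/G/U (or T)")
  }
  m <- nchar(mirna)
  n <- nchar(window)
  if (abs(m - n) > scheme$max_gaps) {
    stop("score_duplex(): window length must be within max_gaps of miRNA")
  }
  mx <- seq_chars(mirna)
  tx <- seq_chars(revcomp_rna(window))
  al <- .align_duplex(mx, tx, scheme)
  if (!detail) return(al$penalty)
  # build alignment columns in miRNA order, then flip to site orientation
  cols <- character(0)
  sym <- function(x, t) {
    if (x == t) "|"
    else if ((x == "G" && t == "A") || (x == "U" && t == "C")) "o"
    else " "
  }
  if (al$type == "none") {
    cols <- mapply(sym, mx, tx)
  } else if (al$type == "mir") {
    ti <- 1L
    for (g in seq_len(m)) {
      if (g == al$gap_pos) { cols <- c(cols, "-") }
      else { cols <- c(cols, sym(mx[g], tx[ti])); ti <- ti + 1L }
    }
  } else if (al$type == "site") {
    mi <- 1L
    for (g in seq_len(n)) {
      if (g == al$gap_pos) { cols <- c(cols, "-") }
      else { cols <- c(cols, sym(mx[mi], tx[g])); mi <- mi + 1L }
    }
  }
  list(penalty = al$penalty,
       pairing = paste(rev(cols), collapse = ""),
       gap = list(type = al$type, mir_pos = al$gap_pos))
}

#' Scan transcripts for target sites of one miRNA
#'
#' Every window of length `len(mirna) +/- max_gaps` at every position is
#' scored; for each start the best window length is kept and sites with
#' penalty at or below the cutoff (inclusive) are reported, sorted by
#' penalty, transcript and position. The predicted cleavage coordinate is
#' the transcript base opposite miRNA position 10 (1-based), the standard
#' plant slicing register.
#'
#' @param mirna miRNA sequence.
#' @param transcripts named character vector.
#' @param scheme [scoring_scheme()].
#' @param mirna_id identifier carried into the output.
#' @param both_strands also scan the reverse strand and flag such sites
#'   (for transcripts of unknown orientation; default FALSE).
#' @return data.frame with `mirna`, `transcript_id`, `strand`, `start`
#'   (0-based), `penalty`, `pairing`, `cleavage_pos` (1-based).
#' @export
scan_targets <- function(mirna, transcripts, scheme = scoring_scheme(),
                         mirna_id = "mirna", both_strands = FALSE) {
  if (length(transcripts) == 0) stop("scan_targets(): no transcripts")
  mirna <- rna_norm(mirna)
  m <- nchar(mirna)
  mx <- seq_chars(mirna)
  lens <- unique(pmax(1, m + (-scheme$max_gaps):(scheme$max_gaps)))
  out <- list()
  scan_one <- function(seqs, tx_id, strand) {
    L <- nchar(seqs)
    tv <- seq_chars(seqs)
    # complement-transformed site characters for direct comparison
    for (start in 0:(L - min(lens))) {
      best <- list(penalty = Inf)
      best_len <- NA_integer_
      for (wl in lens) {
        if (start + wl > L) next
        window <- substr(seqs, start + 1, start + wl)
        tx <- seq_chars(revcomp_rna(window))
        al <- .align_duplex(mx, tx, scheme)
        if (al$penalty < best$penalty) {
          best <- al
          best_len <- wl
        }
      }
      if (is.finite(best$penalty) && best$penalty <= scheme$cutoff) {
        window <- substr(seqs, start + 1, start + best_len)
        det <- score_duplex(mirna, window, scheme, detail = TRUE)
        # miRNA position 10 sits 10 columns from the window 3' end
        cleav <- start + best_len - 10 + 1
        out[[length(out) + 1L]] <<- data.frame(
          mirna = mirna_id, transcript_id = tx_id, strand = strand,
          start = start, penalty = det$penalty, pairing = det$pairing,
          cleavage_pos = cleav, stringsAsFactors = FALSE)
      }
    }
  }
  for (t in seq_along(transcripts)) {
    if (nchar(transcripts[[t]]) < min(lens)) next
    scan_one(rna_norm(transcripts[[t]]), names(transcripts)[t], "+")
    if (both_strands) {
      scan_one(revcomp_rna(transcripts[[t]]), names(transcripts)[t], "-")
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna = character(), transcript_id = character(),
                      strand = character(), start = integer(),
                      penalty = numeric(), pairing = character(),
                      cleavage_pos = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$penalty, res$transcript_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Transcripts targeted by multiple miRNAs
#'
#' @param site_lists named list (miRNA id -> [scan_targets()] output) with
#'   at least two distinct miRNAs.
#' @return data.frame with `transcript_id` and `mirnas` (comma-joined ids),
#'   one row per transcript hit by two or more distinct miRNAs.
#' @export
shared_targets <- function(site_lists) {
  if (length(site_lists) < 2) {
    stop("shared_targets(): at least two site lists are required")
  }
  pairs <- unique(do.call(rbind, lapply(names(site_lists), function(id) {
    s <- site_lists[[id]]
    if (nrow(s) == 0) return(NULL)
    data.frame(mirna = id, transcript_id = unique(s$transcript_id),
               stringsAsFactors = FALSE)
  })))
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(transcript_id = character(), mirnas = character(),
                      stringsAsFactors = FALSE))
  }
  counts <- table(pairs$transcript_id)
  multi <- names(counts)[counts >= 2]
  out <- lapply(multi, function(tx) {
    data.frame(transcript_id = tx,
               mirnas = paste(sort(unique(
                 pairs$mirna[pairs$transcript_id == tx])), collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(), mirnas = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
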