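# Novel miRNA discovery: exact transcript mapping, hairpin window excision,
# folding, duplex analysis, five-criteria annotation, feature detection.

#' Discovery parameter set
#'
#' Defaults are the standard plant hairpin-prediction parameter set:
#' miRNA length 18-26 nt, reference (star) length 20-24 nt, at most 280
#' mapping loci per tag, free energy below -30 kcal/mol, mature-star spacer
#' 5-450 nt, at least 16 paired mature bases, bulges of at most 3 nt, total
#' duplex asymmetry at most 4 nt, 20 nt flanks, plus the manual annotation
#' criteria: at least 2 reads, at most 4 unpaired mature bases, at most 2
#' asymmetric bulges in the duplex, and MFEI of at least 0.85.
#'
#' @param min_mirna_len,max_mirna_len mature length bounds (nt).
#' @param min_ref_len,max_ref_len star length bounds (nt).
#' @param uniqueness maximum mapping loci per tag; tags above are dropped.
#' @param max_dg free energy threshold, kcal/mol (criterion: dG < max_dg).
#' @param min_space,max_space spacer bounds between mature and star (nt).
#' @param min_mature_pair minimum paired mature bases in the duplex.
#' @param max_mature_bulge maximum single bulge length (nt).
#' @param max_duplex_asymmetry maximum total duplex asymmetry (nt).
#' @param flank flanking sequence length for excision (nt).
#' @param min_reads minimum read support for a mature.
#' @param min_mfei minimum MFEI (criterion: mfei >= min_mfei).
#' @param max_mature_mismatch maximum unpaired mature bases in the duplex.
#' @param max_asym_bulges maximum asymmetric bulges in the duplex.
#' @param space_grid spacer extents tried during window excision.
#' @return `discovery_params` list.
#' @export
discovery_params <- function(min_mirna_len = 18, max_mirna_len = 26,
                             min_ref_len = 20, max_ref_len = 24,
                             uniqueness = 280, max_dg = -30,
                             min_space = 5, max_space = 450,
                             min_mature_pair = 16, max_mature_bulge = 3,
                             max_duplex_asymmetry = 4, flank = 20,
                             min_reads = 2, min_mfei = 0.85,
                             max_mature_mismatch = 4, max_asym_bulges = 2,
                             space_grid = c(15, 30, 60, 100, 150, 250,
                                            350, 450)) {
  p <- list(min_mirna_len = min_mirna_len, max_mirna_len = max_mirna_len,
            min_ref_len = min_ref_len, max_ref_len = max_ref_len,
            uniqueness = uniqueness, max_dg = max_dg, min_space = min_space,
            max_space = max_space, min_mature_pair = min_mature_pair,
            max_mature_bulge = max_mature_bulge,
            max_duplex_asymmetry = max_duplex_asymmetry, flank = flank,
            min_reads = min_reads, min_mfei = min_mfei,
            max_mature_mismatch = max_mature_mismatch,
            max_asym_bulges = max_asym_bulges,
            space_grid = pmin(space_grid, max_space))
  stopifnot(p$min_mirna_len <= p$max_mirna_len,
            p$min_ref_len <= p$max_ref_len, p$min_space <= p$max_space)
  class(p) <- "discovery_params"
  p
}

#' Map tags exactly to transcripts on both strands
#'
#' Exact substring matches; minus-strand hits are reverse-complement
#' matches reported in forward-transcript coordinates with `strand = "-"`.
#' Tags mapping to more than `uniqueness` loci are dropped (repeat filter).
#'
#' @param tags data.frame with `sequence` (RNA alphabet) and `count`.
#' @param transcripts named character vector of transcript sequences.
#' @param uniqueness maximum loci per tag.
#' @return data.frame with `sequence`, `count`, `transcript_id`, `strand`,
#'   `start`, `end` (0-based half-open on the forward transcript).
#' @export
map_exact <- function(tags, transcripts, uniqueness = 280) {
  out <- list()
  txn <- names(transcripts)
  for (i in seq_len(nrow(tags))) {
    tag <- tags$sequence[i]
    rc <- revcomp_rna(tag)
    hits <- list()
    for (t in seq_along(transcripts)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") tag else rc
        starts <- find_fixed_matches(pat, transcripts[[t]])
        if (length(starts)) {
          hits[[length(hits) + 1L]] <- data.frame(
            sequence = tag, count = tags$count[i], transcript_id = txn[t],
            strand = strand, start = starts, end = starts + nchar(tag),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      if (nrow(h) <= uniqueness) out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(), count = integer(),
                      transcript_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Excise candidate hairpin windows around a mapped tag
#'
#' For each spacer extent in `params$space_grid` and each direction (star
#' downstream or upstream of the tag), a window extending `flank` beyond
#' the putative duplex is cut from the transcript, capped at its ends.
#' Minus-strand loci are reverse-complemented so the returned window
#' sequence is always in hairpin orientation; `mat_off` gives the 0-based
#' mature offset within the oriented window. Windows shorter than 50 nt
#' are skipped.
#'
#' @param locus one row of [map_exact()] output.
#' @param transcript the transcript sequence.
#' @param params [discovery_params()].
#' @return data.frame with `win_start`, `win_end` (forward coords),
#'   `direction`, `window` (oriented sequence), `mat_off`.
#' @export
excise_candidates <- function(locus, transcript, params) {
  L <- nchar(transcript)
  mlen <- locus$end - locus$start
  rows <- list()
  for (space in unique(params$space_grid)) {
    ext <- space + params$max_ref_len + params$flank
    for (direction in c("downstream", "upstream")) {
      if (direction == "downstream") {
        ws <- max(0L, locus$start - params$flank)
        we <- min(L, locus$end + ext)
      } else {
        ws <- max(0L, locus$start - ext)
        we <- min(L, locus$end + params$flank)
      }
      if (we - ws < 50) next
      win <- substr(transcript, ws + 1, we)
      if (locus$strand == "+") {
        mat_off <- locus$start - ws
        dir_o <- direction
      } else {
        win <- revcomp_rna(win)
        mat_off <- we - locus$end
        # orientation flips which side the star is searched on
        dir_o <- if (direction == "downstream") "upstream" else "downstream"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        win_start = ws, win_end = we, direction = dir_o, window = win,
        mat_off = mat_off, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(win_start = integer(), win_end = integer(),
                      direction = character(), window = character(),
                      mat_off = integer(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

#' Apply the annotation criteria to a folded candidate
#'
#' Criterion flags: (1) read support, (2) free energy, (3) unpaired mature
#' bases, (4) asymmetric bulges, (5) MFEI, plus the structural bounds
#' (minimum mature pairing, maximum bulge, total asymmetry, spacer bounds,
#' mature length). `accepted` is true iff every flag is.
#'
#' @param candidate list/row with `reads`, `dG`, `mfei`, `mature_len`.
#' @param stats [duplex_stats()] output.
#' @param params [discovery_params()].
#' @return list of logical flags plus `accepted`.
#' @export
annotate_candidate <- function(candidate, stats, params) {
  max_bulge <- if (nrow(stats$bulges) == 0) 0L else max(stats$bulges$length)
  flags <- list(
    crit1_reads = candidate$reads >= params$min_reads,
    crit2_dg = candidate$dG < params$max_dg,
    crit3_mature_mismatch =
      stats$mature_unpaired <= params$max_mature_mismatch,
    crit4_asym_bulges = stats$asym_bulge_count <= params$max_asym_bulges,
    crit5_mfei = candidate$mfei >= params$min_mfei,
    pair_min = stats$paired >= params$min_mature_pair,
    bulge_max = max_bulge <= params$max_mature_bulge,
    asymmetry_max = stats$total_asymmetry <= params$max_duplex_asymmetry,
    space_bounds = stats$space >= params$min_space &&
      stats$space <= params$max_space,
    mature_len_bounds = candidate$mature_len >= params$min_mirna_len &&
      candidate$mature_len <= params$max_mirna_len
  )
  flags$accepted <- all(unlist(flags))
  flags
}

# evaluate one oriented window: fold, locate the star, trim to the
# precursor, refold, compute stats and the verdict
evaluate_window <- function(win, reads, params, engine = "bundled",
                            pad = 5L) {
  f1 <- fold_rna(win$window, engine = engine)
  mlen <- attr(win, "mature_len")
  mature <- c(win$mat_off, win$mat_off + mlen)
  star_w <- predict_star(f1$structure, mature, overhang = 0)
  if (is.null(star_w)) return(NULL)
  # trim to the precursor and refold so dG/MFEI describe the hairpin itself
  lo <- max(0L, min(mature[1], star_w[1]) - pad)
  hi <- min(nchar(win$window), max(mature[2], star_w[2]) + pad)
  pre <- substr(win$window, lo + 1, hi)
  f2 <- fold_rna(pre, engine = engine)
  mat2 <- mature - lo
  gc <- gc_fraction(pre)
  mfei <- if (gc > 0) compute_mfei(f2$dG, nchar(pre), gc) else 0
  cand <- list(reads = reads, dG = f2$dG, mfei = mfei, mature_len = mlen)
  # the trimmed refold can restructure; assess the duplex both in the
  # original window fold and in the refold, and keep the better verdict.
  # Pairing statistics use the raw duplex partner span; the reported star
  # interval carries the conventional 2-nt 3' overhang.
  variants <- list()
  star0 <- predict_star(f2$structure, mat2, overhang = 0)
  if (!is.null(star0)) {
    stats <- duplex_stats(f2$structure, mat2, star0)
    variants[[1]] <- list(stats = stats,
                          verdict = annotate_candidate(cand, stats, params),
                          structure = f2$structure,
                          star = predict_star(f2$structure, mat2,
                                              overhang = 2))
  }
  stats_w <- duplex_stats(f1$structure, mature, star_w)
  variants[[length(variants) + 1L]] <- list(
    stats = stats_w, verdict = annotate_candidate(cand, stats_w, params),
    structure = f2$structure,
    star = predict_star(f1$structure, mature, overhang = 2) - lo)
  pick <- variants[[1]]
  for (v in variants[-1]) {
    if ((v$verdict$accepted && !pick$verdict$accepted) ||
        (v$verdict$accepted == pick$verdict$accepted &&
         sum(!unlist(v$verdict)) < sum(!unlist(pick$verdict)))) {
      pick <- v
    }
  }
  star_rep <- pick$star
  list(sequence = pre, dot_bracket = f2$structure, dG = f2$dG,
       gc_fraction = gc, mfei = mfei, pre_off = lo, mat_off = mat2[1],
       star_off = star_rep[1], star_len = star_rep[2] - star_rep[1],
       stats = pick$stats, verdict = pick$verdict)
}

#' Discover miRNA hairpin candidates in transcripts
#'
#' The full discovery pipeline: tags are length- and support-filtered,
#' mapped exactly to both strands, candidate windows are excised and
#' folded, the miRNA* is predicted from the structure, the window is
#' trimmed to the precursor and refolded, duplex statistics are computed
#' and the annotation criteria applied. For each locus the best window is
#' kept (an accepted verdict wins, then lower dG). Overlapping accepted
#' precursors on one strand are merged, so a precursor producing several
#' matures appears once with `multi_mature` detectable downstream.
#'
#' @param tags data.frame with `sequence`, `count` (e.g. from
#'   [collapse_tags()]); in homology mode, known mature sequences with
#'   `count` set to their observed read support.
#' @param transcripts named character vector of transcripts (RNA alphabet).
#' @param params [discovery_params()].
#' @param engine folding engine passed to [fold_rna()].
#' @return list with `candidates` (one row per evaluated locus: locus,
#'   precursor coordinates, structure, dG, MFEI, duplex stats, star
#'   prediction, accepted flag) and `verdicts` (one column per criterion).
#' @export
discover_mirnas <- function(tags, transcripts, params = discovery_params(),
                            engine = "bundled") {
  tags <- tags[nchar(tags$sequence) >= params$min_mirna_len &
                 nchar(tags$sequence) <= params$max_mirna_len &
                 tags$count >= params$min_reads, , drop = FALSE]
  loci <- map_exact(tags, transcripts, uniqueness = params$uniqueness)
  cand_rows <- list()
  verd_rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    tx <- transcripts[[locus$transcript_id]]
    wins <- excise_candidates(locus, tx, params)
    best <- NULL
    for (w in seq_len(nrow(wins))) {
      win <- wins[w, ]
      attr(win, "mature_len") <- locus$end - locus$start
      ev <- evaluate_window(win, reads = locus$count, params = params,
                            engine = engine)
      if (is.null(ev)) next
      ev$win <- win
      # prefer accepted, then fewest failed criteria, then lower dG
      n_fail <- function(e) sum(!unlist(e$verdict))
      if (is.null(best) ||
          (ev$verdict$accepted && !best$verdict$accepted) ||
          (ev$verdict$accepted == best$verdict$accepted &&
           (n_fail(ev) < n_fail(best) ||
            (n_fail(ev) == n_fail(best) && ev$dG < best$dG)))) {
        best <- ev
      }
      if (ev$verdict$accepted) break # early stop per locus
    }
    if (is.null(best)) next
    # map precursor back to forward-transcript coordinates
    ws <- best$win$win_start
    we <- best$win$win_end
    if (locus$strand == "+") {
      pre_start <- ws + best$pre_off
      pre_end <- pre_start + nchar(best$sequence)
    } else {
      pre_end <- we - best$pre_off
      pre_start <- pre_end - nchar(best$sequence)
    }
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      sequence = locus$sequence, count = locus$count,
      transcript_id = locus$transcript_id, strand = locus$strand,
      mat_start = locus$start, mat_end = locus$end,
      pre_start = pre_start, pre_end = pre_end,
      precursor_seq = best$sequence, dot_bracket = best$dot_bracket,
      dG = best$dG, gc_fraction = best$gc_fraction, mfei = best$mfei,
      star_off = best$star_off, star_len = best$star_len,
      paired = best$stats$paired,
      mature_unpaired = best$stats$mature_unpaired,
      asym_bulge_count = best$stats$asym_bulge_count,
      total_asymmetry = best$stats$total_asymmetry,
      space = best$stats$space, accepted = best$verdict$accepted,
      stringsAsFactors = FALSE)
    verd_rows[[length(verd_rows) + 1L]] <-
      as.data.frame(best$verdict, stringsAsFactors = FALSE)
  }
  if (length(cand_rows) == 0) {
    return(list(candidates = data.frame(), verdicts = data.frame()))
  }
  candidates <- do.call(rbind, cand_rows)
  verdicts <- do.call(rbind, verd_rows)
  rownames(candidates) <- rownames(verdicts) <- NULL
  list(candidates = candidates, verdicts = verdicts)
}

#' Detect precursor-level features among accepted candidates
#'
#' Merges accepted candidates whose precursor intervals overlap on the same
#' transcript strand into precursors, then flags: clusters (two or more
#' non-overlapping precursors in one transcript, any strand), multi-mature
#' precursors (two or more distinct mature loci in one precursor), and
#' antisense pairs (precursors on opposite strands with overlapping
#' forward intervals).
#'
#' @param accepted data.frame of accepted rows from
#'   [discover_mirnas()]`$candidates`.
#' @return data.frame, one row per precursor: `precursor_id`,
#'   `transcript_id`, `strand`, `start`, `end`, `n_matures`,
#'   `multi_mature`, `cluster_id`, `antisense_partner`.
#' @export
detect_features <- function(accepted) {
  if (nrow(accepted) == 0) {
    stop("detect_features(): accepted candidate set is empty")
  }
  acc <- accepted[order(accepted$transcript_id, accepted$strand,
                        accepted$pre_start), , drop = FALSE]
  # merge overlapping same-strand precursor intervals
  acc$grp <- NA_integer_
  g <- 0L
  for (i in seq_len(nrow(acc))) {
    if (i > 1 &&
        acc$transcript_id[i] == acc$transcript_id[i - 1] &&
        acc$strand[i] == acc$strand[i - 1] &&
        acc$pre_start[i] < max(acc$pre_end[seq_len(i - 1)][
          acc$grp[seq_len(i - 1)] == g])) {
      acc$grp[i] <- g
    } else {
      g <- g + 1L
      acc$grp[i] <- g
    }
  }
  pre <- do.call(rbind, lapply(split(acc, acc$grp), function(d) {
    data.frame(transcript_id = d$transcript_id[1], strand = d$strand[1],
               start = min(d$pre_start), end = max(d$pre_end),
               n_matures = length(unique(paste(d$mat_start, d$mat_end))),
               stringsAsFactors = FALSE)
  }))
  pre$precursor_id <- sprintf("HFP%03d", seq_len(nrow(pre)))
  pre$multi_mature <- pre$n_matures >= 2
  # clusters: >= 2 precursors with disjoint intervals in one transcript
  pre$cluster_id <- NA_character_
  for (tx in unique(pre$transcript_id)) {
    sel <- which(pre$transcript_id == tx)
    if (length(sel) >= 2) {
      ov <- outer(seq_along(sel), seq_along(sel), function(a, b) {
        pre$start[sel[a]] < pre$end[sel[b]] &
          pre$start[sel[b]] < pre$end[sel[a]]
      })
      # members of a cluster must not overlap (overlap = antisense pair)
      disjoint <- sel[colSums(ov) == 1]
      if (length(disjoint) >= 2) {
        pre$cluster_id[disjoint] <- paste0("cluster_", tx)
      }
    }
  }
  # antisense pairs: overlapping intervals on opposite strands
  pre$antisense_partner <- NA_character_
  for (i in seq_len(nrow(pre))) {
    for (j in seq_len(nrow(pre))) {
      if (i != j && pre$transcript_id[i] == pre$transcript_id[j] &&
          pre$strand[i] != pre$strand[j] &&
          pre$start[i] < pre$end[j] && pre$start[j] < pre$end[i]) {
        pre$antisense_partner[i] <- pre$precursor_id[j]
      }
    }
  }
  rownames(pre) <- NULL
  pre[, c("precursor_id", "transcript_id", "strand", "start", "end",
          "n_matures", "multi_mature", "cluster_id", "antisense_partner")]
}

#' Group accepted precursors into families by sequence identity
#'
#' Single-linkage clustering of precursor sequences at a global identity
#' threshold (default 80%), using ungapped pairwise identity over the
#' shorter sequence length as a pragmatic proxy for global alignment at
#' this scale.
#'
#' @param precursor_seqs character vector of precursor sequences.
#' @param min_identity identity threshold in \[0, 1\].
#' @return integer vector of family ids, one per input sequence.
#' @export
group_precursor_families <- function(precursor_seqs, min_identity = 0.8) {
  n <- length(precursor_seqs)
  if (n == 0) return(integer(0))
  fam <- seq_len(n)
  ident <- function(a, b) {
    la <- nchar(a); lb <- nchar(b)
    if (la > lb) { tmp <- a; a <- b; b <- tmp; l <- la; la <- lb; lb <- l }
    best <- 0
    va <- seq_chars(a)
    for (off in 0:(lb - la)) {
      vb <- seq_chars(substr(b, off + 1, off + la))
      best <- max(best, sum(va == vb) / la)
    }
    best
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (ident(precursor_seqs[i], precursor_seqs[j]) >= min_identity) {
        old <- fam[j]
        fam[fam == old] <- fam[i]
      }
    }
  }
  match(fam, unique(fam))
}
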