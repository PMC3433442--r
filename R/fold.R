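# Secondary structure: bundled folding engine, pairing-table utilities,
# MFEI, and miRNA/miRNA* duplex statistics.

#' Fold an RNA sequence
#'
#' Delegates to a pluggable thermodynamic engine. The bundled deterministic
#' engine is a weighted maximum base-pairing dynamic program (pair energies
#' GC -3, AU -2, GU -1 kcal/mol, minimum hairpin loop 3 nt) with a helix
#' initiation penalty (+8 kcal/mol per helix, charged at the outermost
#' pair). The penalty is the calibration that keeps shuffled sequence from
#' amassing spurious short helices, so that non-hairpin windows score above
#' the -30 kcal/mol threshold and below the 0.85 MFEI threshold while
#' near-perfect planted stems clear both. Energies are engine-relative, not
#' comparable to nearest-neighbour models. Same input always gives the same
#' structure.
#'
#' @param sequence RNA (or DNA; T is read as U) sequence.
#' @param engine either `"bundled"` or a function `f(sequence)` returning
#'   `list(structure=, dG=)` (e.g. a ViennaRNA wrapper).
#' @param min_loop minimum hairpin loop size (bundled engine).
#' @param helix_init helix initiation penalty, kcal/mol (bundled engine).
#' @param pair_energies named vector with `GC`, `AU`, `GU` energies.
#' @return list with `structure` (dot-bracket), `dG` (kcal/mol, <= 0) and
#'   `engine` (identity string recorded in output metadata).
#' @export
fold_rna <- function(sequence, engine = "bundled", min_loop = 3,
                     helix_init = 8,
                     pair_energies = c(GC = -3, AU = -2, GU = -1)) {
  if (is.function(engine)) {
    res <- engine(sequence)
    return(list(structure = res$structure, dG = res$dG, engine = "custom"))
  }
  s <- rna_norm(sequence)
  if (grepl("[^ACGUN]", s)) stop("fold_rna(): sequence must be RNA alphabet")
  res <- .fold_engine_cpp(s, as.integer(min_loop), helix_init,
                          pair_energies[["GC"]], pair_energies[["AU"]],
                          pair_energies[["GU"]])
  list(structure = res$structure, dG = res$dG, engine = "bundled-maxpair-v1")
}

#' Minimal folding free energy index
#'
#' `MFEI = (|dG| / length x 100) / (GC% )`, i.e. the adjusted MFE per 100 nt
#' divided by the GC percentage, reported as a positive number. Hairpin
#' precursors have characteristically high MFEI compared with other RNAs.
#'
#' @param dG folding free energy, kcal/mol (<= 0).
#' @param length sequence length, nt (> 0).
#' @param gc_fraction GC fraction in (0, 1].
#' @return MFEI (unitless, >= 0).
#' @export
compute_mfei <- function(dG, length, gc_fraction) {
  if (any(length <= 0)) stop("compute_mfei(): length must be positive")
  if (any(gc_fraction <= 0)) {
    stop("compute_mfei(): undefined MFEI for zero GC content")
  }
  (abs(dG) / length * 100) / (gc_fraction * 100)
}

#' Pairing table of a dot-bracket structure
#'
#' @param dot_bracket Vienna dot-bracket string (only `(`, `)`, `.`).
#' @return integer vector; element i holds the 1-based partner of position
#'   i, or `NA` if unpaired.
#' @export
pairing_table <- function(dot_bracket) {
  v <- seq_chars(dot_bracket)
  partner <- rep(NA_integer_, length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") {
      stack <- c(stack, i)
    } else if (v[i] == ")") {
      if (length(stack) == 0) {
        stop("structure parse error: unbalanced brackets at position ", i)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    } else if (v[i] != ".") {
      stop("structure parse error: unexpected character '", v[i],
           "' at position ", i)
    }
  }
  if (length(stack) > 0) {
    stop("structure parse error: unbalanced brackets (",
         length(stack), " unclosed)")
  }
  partner
}

#' Predict the miRNA* interval from a folded structure
#'
#' The star is taken as the duplex partner region of the mature with the
#' standard 2-nt 3' overhang (the partner span shifted 2 nt toward the
#' star's 3' direction), clamped to the sequence.
#'
#' @param dot_bracket structure string.
#' @param mature 0-based half-open mature interval `c(start, end)`.
#' @param overhang 3' overhang in nt (default 2; use 0 to obtain the raw
#'   duplex partner span, e.g. for pairing statistics).
#' @return 0-based half-open star interval, or `NULL` if fewer than 4
#'   mature bases are paired.
#' @export
predict_star <- function(dot_bracket, mature, overhang = 2) {
  pt <- pairing_table(dot_bracket)
  idx <- seq(mature[1] + 1, mature[2]) # 1-based mature positions
  partners <- pt[idx]
  partners <- partners[!is.na(partners)]
  # only partners outside the mature itself form a duplex
  partners <- partners[partners < mature[1] + 1 | partners > mature[2]]
  if (length(partners) < 4) return(NULL)
  smin <- min(partners) - 1 # back to 0-based
  smax <- max(partners)     # 0-based half-open end
  if (smin >= mature[2]) {
    iv <- c(smin + overhang, smax + overhang) # star downstream: 3' end high
  } else {
    iv <- c(smin - overhang, smax - overhang) # star upstream: 3' end low
  }
  c(max(0L, iv[1]), min(nchar(dot_bracket), iv[2]))
}

#' miRNA/miRNA* duplex statistics
#'
#' Builds the pairing table and summarizes the duplex between the mature
#' and star intervals: paired mature bases, unpaired ("mismatched") mature
#' bases, the internal loops/bulges between consecutive paired positions,
#' how many of those are asymmetric (opposing arms contribute unpaired runs
#' of different lengths), the total asymmetry, and the spacer between the
#' two intervals.
#'
#' @param dot_bracket structure string.
#' @param mature 0-based half-open mature interval.
#' @param star 0-based half-open star interval.
#' @return list with `paired`, `mature_unpaired`, `bulges` (data.frame
#'   `arm`, `length`), `asym_bulge_count`, `total_asymmetry`, `space`.
#' @export
duplex_stats <- function(dot_bracket, mature, star) {
  n <- nchar(dot_bracket)
  if (mature[1] < 0 || mature[2] > n || star[1] < 0 || star[2] > n) {
    stop("duplex_stats(): loci outside structure")
  }
  pt <- pairing_table(dot_bracket)
  mpos <- seq(mature[1] + 1, mature[2])
  in_star <- function(p) !is.na(p) & p >= star[1] + 1 & p <= star[2]
  paired_mask <- in_star(pt[mpos])
  paired <- sum(paired_mask)
  mature_unpaired <- length(mpos) - paired
  bulges <- data.frame(arm = character(0), length = integer(0),
                       stringsAsFactors = FALSE)
  asym <- 0L
  tot_m <- 0L
  tot_s <- 0L
  pp <- mpos[paired_mask]
  if (length(pp) >= 2) {
    for (k in seq_len(length(pp) - 1)) {
      gap_m <- pp[k + 1] - pp[k] - 1L
      gap_s <- abs(pt[pp[k]] - pt[pp[k + 1]]) - 1L
      if (gap_m > 0 || gap_s > 0) {
        if (gap_m > 0) {
          bulges <- rbind(bulges, data.frame(arm = "mature", length = gap_m))
        }
        if (gap_s > 0) {
          bulges <- rbind(bulges, data.frame(arm = "star", length = gap_s))
        }
        if (gap_m != gap_s) asym <- asym + 1L
        tot_m <- tot_m + gap_m
        tot_s <- tot_s + gap_s
      }
    }
  }
  space <- if (star[1] >= mature[2]) star[1] - mature[2]
           else mature[1] - star[2]
  list(paired = paired, mature_unpaired = mature_unpaired, bulges = bulges,
       asym_bulge_count = asym, total_asymmetry = abs(tot_m - tot_s),
       space = as.integer(space))
}
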