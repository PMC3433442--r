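# Independent oracles and shared fixtures. Oracles deliberately use naive
# algorithms distinct from the package implementation paths.

# --- brute-force pairing-table oracle -----------------------------------
# repeatedly erase innermost "(.*)" pairs instead of using a stack
oracle_pairing_table <- function(db) {
  v <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(v))
  work <- v
  repeat {
    open <- NA
    found <- FALSE
    for (i in seq_along(work)) {
      if (work[i] == "(") open <- i
      if (work[i] == ")") {
        if (is.na(open)) stop("unbalanced")
        partner[open] <- i
        partner[i] <- open
        work[open] <- "."
        work[i] <- "."
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  if (any(work == "(")) stop("unbalanced")
  partner
}

# --- brute-force duplex-stats oracle ------------------------------------
# position-by-position scan; independent of the implementation's run logic
oracle_duplex_stats <- function(db, mature, star) {
  pt <- oracle_pairing_table(db)
  mpos <- seq(mature[1] + 1, mature[2])
  instar <- function(p) !is.na(p) && p >= star[1] + 1 && p <= star[2]
  flags <- vapply(pt[mpos], instar, logical(1))
  paired_pos <- mpos[flags]
  paired <- length(paired_pos)
  res <- list(paired = paired, mature_unpaired = length(mpos) - paired)
  bul <- list()
  asym <- 0
  tm <- 0
  ts <- 0
  if (paired >= 2) {
    for (k in seq_len(paired - 1)) {
      gm <- paired_pos[k + 1] - paired_pos[k] - 1
      gs <- abs(pt[paired_pos[k]] - pt[paired_pos[k + 1]]) - 1
      if (gm > 0) bul[[length(bul) + 1]] <- c("mature", gm)
      if (gs > 0) bul[[length(bul) + 1]] <- c("star", gs)
      if ((gm > 0 || gs > 0) && gm != gs) asym <- asym + 1
      tm <- tm + gm
      ts <- ts + gs
    }
  }
  res$n_bulges <- length(bul)
  res$max_bulge <- if (length(bul)) max(vapply(bul, function(b)
    as.integer(b[2]), integer(1))) else 0L
  res$asym_bulge_count <- asym
  res$total_asymmetry <- abs(tm - ts)
  res
}

# --- exhaustive Hamming-scan oracle -------------------------------------
oracle_hamming_hits <- function(tag, ref, max_mm) {
  tl <- nchar(tag)
  out <- list()
  tv <- strsplit(tag, "")[[1]]
  rv <- strsplit(ref, "")[[1]]
  for (off in 0:(nchar(ref) - tl)) {
    mm <- sum(tv != rv[(off + 1):(off + tl)])
    if (mm <= max_mm) out[[length(out) + 1]] <- c(off, mm)
  }
  out
}

# --- penalty expected from the scheme for a single edit -----------------
oracle_single_edit_penalty <- function(kind, pos, scheme) {
  w <- if (pos >= scheme$seed_start && pos <= scheme$seed_end)
    scheme$seed_multiplier else 1
  base <- switch(kind, mismatch = scheme$mismatch_penalty,
                 gu = scheme$gu_penalty, gap = scheme$gap_penalty)
  base * w
}

# --- naive alignment-enumeration oracle for duplex scoring --------------
# builds every admissible alignment column-by-column and sums penalties
# directly from the scheme; no prefix/suffix tricks
oracle_align_penalty <- function(mir, window, scheme) {
  mv <- strsplit(rna_norm(mir), "")[[1]]
  tv <- strsplit(revcomp_rna(window), "")[[1]]
  m <- length(mv)
  n <- length(tv)
  colpen <- function(x, t, mirpos) {
    w <- if (mirpos >= scheme$seed_start && mirpos <= scheme$seed_end)
      scheme$seed_multiplier else 1
    if (x == t) return(0)
    if ((x == "G" && t == "A") || (x == "U" && t == "C"))
      return(scheme$gu_penalty * w)
    scheme$mismatch_penalty * w
  }
  gappen <- function(mirpos) {
    w <- if (mirpos >= scheme$seed_start && mirpos <= scheme$seed_end)
      scheme$seed_multiplier else 1
    scheme$gap_penalty * w
  }
  cands <- c()
  if (n == m) {
    cands <- c(cands, sum(vapply(seq_len(m), function(i)
      colpen(mv[i], tv[i], i), numeric(1))))
  }
  if (scheme$max_gaps >= 1 && n == m - 1) {
    for (g in seq_len(m)) {
      p <- gappen(g)
      ti <- 1
      for (i in seq_len(m)) {
        if (i == g) next
        p <- p + colpen(mv[i], tv[ti], i)
        ti <- ti + 1
      }
      cands <- c(cands, p)
    }
  }
  if (scheme$max_gaps >= 1 && n == m + 1) {
    for (g in seq_len(n)) {
      p <- gappen(min(g, m))
      mi <- 1
      for (j in seq_len(n)) {
        if (j == g) next
        p <- p + colpen(mv[mi], tv[j], mi)
        mi <- mi + 1
      }
      cands <- c(cands, p)
    }
  }
  min(cands)
}

# random dot-bracket structures via random sequences + the bundled engine
random_structures <- function(n, len_range = c(40, 90), seed = 101) {
  set.seed(seed)
  replicate(n, {
    s <- paste(sample(c("A", "C", "G", "U"), sample(len_range[1]:len_range[2], 1),
                      replace = TRUE), collapse = "")
    fold_rna(s)$structure
  })
}

# --- shared small simulation, built once per test run -------------------
.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 11, n_transcripts = 30, n_planted_mirnas = 10,
                      n_decoys = 8, n_clusters = 1, n_multi_mature = 1,
                      n_antisense_pairs = 1, background_tag_rate = 40)
    sim <- generate_transcriptome(cfg)
    reads <- simulate_reads(sim$truth, cfg)
    .sim_cache$sim <- list(cfg = cfg, sim = sim, reads = reads)
  }
  .sim_cache$sim
}

# truth-vs-accepted matcher used by recovery tests
planted_recovered <- function(truth_rows, accepted, tol = 3) {
  any(vapply(seq_len(nrow(truth_rows)), function(k) {
    r <- truth_rows[k, ]
    any(accepted$transcript_id == r$transcript_id &
          accepted$strand == r$strand &
          abs(accepted$mat_start - r$mat_start) <= tol)
  }, logical(1)))
}
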