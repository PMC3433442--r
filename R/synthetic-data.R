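# Ground-truth simulator: transcriptomes with planted hairpin precursors and
# decoy loci, small RNA reads, and Cq tables with planted effects.
#
# All randomness flows from the single integer seed in the config; the
# sub-generators draw from it in a fixed, documented order
# (generate_transcriptome: seed; simulate_reads: seed + 1), so identical
# configs give byte-identical outputs.

#' Simulation configuration
#'
#' Defaults describe a small but structurally complete world: 50 planted
#' precursors (including 2 two-precursor clusters, 2 multi-mature
#' precursors and 2 antisense pairs), 50 decoy loci, log-normally skewed
#' read depths with a floor of 5 reads, error-free reads and a constant
#' high base quality. Stems are near-perfect inverted repeats (about 91%
#' paired for the default 32 bp stem) with arm GC fraction constrained to
#' 0.45-0.65 so every planted hairpin clears the dG and MFEI annotation
#' thresholds under the bundled folding engine.
#'
#' @param seed integer RNG seed.
#' @param n_transcripts number of transcripts to generate.
#' @param n_planted_mirnas number of planted precursors (multi-mature
#'   precursors count once, antisense pairs count two).
#' @param n_decoys number of decoy (non-hairpin) loci, one per transcript.
#' @param mature_len_range mature length bounds, within 18-26 nt.
#' @param stem_len stem length in bp (each arm), >= max mature length + 4.
#' @param loop_len hairpin loop length in nt.
#' @param read_error_rate per-base substitution probability in reads.
#' @param adapter_seq 3' adapter appended to every read (DNA alphabet).
#' @param depth_meanlog,depth_sdlog log-normal read-depth model.
#' @param depth_min floor on per-miRNA read depth.
#' @param star_depth reads simulated from each star sequence (default 1,
#'   below the 2-read annotation threshold, as sequenced stars are rare).
#' @param background_tag_rate number of random background 18-30 nt tags.
#' @param n_clusters transcripts carrying two precursors each.
#' @param n_multi_mature precursors producing a 5p and a 3p mature.
#' @param n_antisense_pairs hairpin regions planted with a mature on each
#'   strand (the reverse complement of a hairpin is itself a hairpin).
#' @param transcript_len_range transcript length bounds in nt.
#' @param low_quality_fraction fraction of simulated reads given a low
#'   (failing) quality string, to exercise the quality filter.
#' @param jitter_max maximum end-trimming jitter applied to reads (0-2 nt).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 120L,
                       n_planted_mirnas = 50L,
                       n_decoys = 50L,
                       mature_len_range = c(20L, 24L),
                       stem_len = 32L,
                       loop_len = 12L,
                       read_error_rate = 0,
                       adapter_seq = "TCGTATGCCGTCTTCTGCTTG",
                       depth_meanlog = log(20),
                       depth_sdlog = 1.2,
                       depth_min = 5L,
                       star_depth = 1L,
                       background_tag_rate = 200L,
                       n_clusters = 2L,
                       n_multi_mature = 2L,
                       n_antisense_pairs = 2L,
                       transcript_len_range = c(300L, 800L),
                       low_quality_fraction = 0,
                       jitter_max = 0L) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              n_planted_mirnas = as.integer(n_planted_mirnas),
              n_decoys = as.integer(n_decoys),
              mature_len_range = as.integer(mature_len_range),
              stem_len = as.integer(stem_len), loop_len = as.integer(loop_len),
              read_error_rate = read_error_rate, adapter_seq = adapter_seq,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              depth_min = as.integer(depth_min),
              star_depth = as.integer(star_depth),
              background_tag_rate = as.integer(background_tag_rate),
              n_clusters = as.integer(n_clusters),
              n_multi_mature = as.integer(n_multi_mature),
              n_antisense_pairs = as.integer(n_antisense_pairs),
              transcript_len_range = as.integer(transcript_len_range),
              low_quality_fraction = low_quality_fraction,
              jitter_max = as.integer(jitter_max))
  if (cfg$read_error_rate < 0 || cfg$read_error_rate >= 1) {
    stop("invalid config: read_error_rate must be in [0, 1)")
  }
  if (cfg$mature_len_range[1] < 18 || cfg$mature_len_range[2] > 26 ||
      cfg$mature_len_range[1] > cfg$mature_len_range[2]) {
    stop("invalid config: mature_len_range must lie within [18, 26]")
  }
  if (cfg$n_transcripts == 0 && cfg$n_planted_mirnas > 0) {
    stop("invalid config: cannot plant miRNAs into zero transcripts")
  }
  if (cfg$stem_len < cfg$mature_len_range[2] + 4) {
    stop("invalid config: stem_len must be at least max mature length + 4")
  }
  special <- 2L * cfg$n_clusters + cfg$n_multi_mature +
    cfg$n_antisense_pairs * 2L
  if (cfg$n_planted_mirnas > 0 && special > cfg$n_planted_mirnas) {
    stop("invalid config: requested special structures exceed n_planted_mirnas")
  }
  class(cfg) <- "sim_config"
  cfg
}

rand_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random stem arm with GC fraction constrained so the hairpin comfortably
# clears the energy threshold even for unlucky draws
rand_arm <- function(stem_len) {
  repeat {
    arm <- rand_rna(stem_len)
    gc <- gc_fraction(arm)
    if (gc >= 0.45 && gc <= 0.65) return(arm)
  }
}

# substitute bases in the 3' arm so they no longer pair (WC or wobble) with
# the opposing 5' arm base; positions are spread and kept off the arm ends
mutate_arm3 <- function(arm3, arm5, n_mut) {
  L <- nchar(arm3)
  v <- seq_chars(arm3)
  v5 <- seq_chars(arm5)
  pairs_with <- list(A = c("U"), C = c("G"), G = c("C", "U"),
                     U = c("A", "G"))
  if (n_mut > 0) {
    # keep mutations in the middle half of the stem so every helix segment
    # stays long enough to form under the bundled engine's initiation cost
    pos <- round(seq(L / 4, 3 * L / 4, length.out = n_mut))
    for (p in pos) {
      opp <- v5[L - p + 1] # base this position pairs with in a perfect stem
      banned <- c(pairs_with[[opp]], v[p])
      repl <- setdiff(c("A", "C", "G", "U"), banned)
      v[p] <- repl[1] # deterministic choice
    }
  }
  paste(v, collapse = "")
}

# build one hairpin precursor; returns sequence plus 0-based mature/star
# intervals for the requested arms
build_hairpin <- function(cfg, arms = "5p") {
  stem <- cfg$stem_len
  loop_seq <- rand_rna(cfg$loop_len, alphabet = c("A", "C"))
  arm5 <- rand_arm(stem)
  arm3 <- mutate_arm3(revcomp_rna(arm5), arm5, max(0L, round(0.09 * stem)))
  pre <- paste0(arm5, loop_seq, arm3)
  L <- nchar(pre)
  matures <- lapply(arms, function(arm) {
    mlen <- sample(seq(cfg$mature_len_range[1], cfg$mature_len_range[2]), 1)
    if (arm == "5p") {
      a <- 2L # 0-based start inside the 5' arm
      b <- a + mlen
      star <- c(L - b + 2L, L - a + 2L)
    } else {
      b <- L - 2L
      a <- b - mlen
      star <- c(L - b - 2L, L - a - 2L)
    }
    list(arm = arm, mat = c(a, b), star = star,
         mature_seq = substr(pre, a + 1, b),
         star_seq = substr(pre, star[1] + 1, star[2]))
  })
  list(sequence = pre, matures = matures)
}

# a decoy window: shuffled hairpin-like composition, re-sampled until the
# bundled engine scores it as a non-hairpin (fails dG or MFEI)
build_decoy <- function(cfg, max_dg = -30, min_mfei = 0.85, max_tries = 50) {
  L <- 2L * cfg$stem_len + cfg$loop_len
  template <- seq_chars(paste0(rand_arm(cfg$stem_len),
                               rand_rna(cfg$loop_len),
                               rand_arm(cfg$stem_len)))
  for (i in seq_len(max_tries)) {
    s <- paste(sample(template), collapse = "")
    f <- fold_rna(s)
    mfei <- compute_mfei(f$dG, nchar(s), gc_fraction(s))
    if (!(f$dG < max_dg) || !(mfei >= min_mfei)) return(s)
  }
  stop("failed to construct a non-hairpin decoy window") # practically unreachable
}

empty_truth <- function() {
  data.frame(record_id = character(), precursor_id = character(),
             transcript_id = character(), strand = character(),
             pre_start = integer(), pre_end = integer(),
             mat_start = integer(), mat_end = integer(),
             mature_seq = character(), star_start = integer(),
             star_end = integer(), star_seq = character(),
             arm = character(), planted_depth = integer(),
             is_decoy = logical(), cluster_id = character(),
             antisense_partner = character(), stringsAsFactors = FALSE)
}

#' Generate a synthetic transcriptome with planted hairpins and decoys
#'
#' Transcripts are random background sequence into which near-perfect
#' inverted-repeat precursors (planted miRNAs) and shuffled non-hairpin
#' windows (decoys) are embedded. Requested cluster (two precursors per
#' transcript), multi-mature (5p + 3p matures from one precursor) and
#' antisense-pair (a mature on each strand of one hairpin region)
#' structures are planted first, then plain precursors, then decoys in
#' their own transcripts. Remaining transcripts carry background only.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (named character vector, RNA alphabet)
#'   and `truth` (data.frame, one row per planted mature or decoy window;
#'   intervals 0-based half-open on the forward transcript).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  if (cfg$n_transcripts == 0) {
    return(list(transcripts = character(0), truth = empty_truth()))
  }
  tlen <- sample(seq(cfg$transcript_len_range[1], cfg$transcript_len_range[2]),
                 cfg$n_transcripts, replace = TRUE)
  transcripts <- vapply(tlen, rand_rna, character(1))
  names(transcripts) <- sprintf("tx%03d", seq_len(cfg$n_transcripts))

  rows <- list()
  depth_draw <- function() {
    max(cfg$depth_min, as.integer(round(rlnorm(1, cfg$depth_meanlog,
                                               cfg$depth_sdlog))))
  }
  tx_cursor <- 0L
  next_tx <- function() {
    tx_cursor <<- tx_cursor + 1L
    if (tx_cursor > cfg$n_transcripts) {
      stop("invalid config: not enough transcripts for requested loci")
    }
    tx_cursor
  }
  mir_i <- 0L
  # embed `hp` into transcript ti at a position leaving >= 25 nt margins;
  # returns the 0-based precursor interval
  embed <- function(ti, hp_seq, at = NULL) {
    s <- transcripts[[ti]]
    L <- nchar(hp_seq)
    if (is.null(at)) {
      lo <- 25L
      hi <- nchar(s) - L - 25L
      if (hi < lo) stop("transcript too short to embed a precursor")
      at <- sample(seq(lo, hi), 1)
    }
    transcripts[[ti]] <<- paste0(substr(s, 1, at), hp_seq,
                                 substr(s, at + L + 1, nchar(s)))
    c(at, at + L)
  }
  add_rows <- function(ti, pre_iv, hp, strand, precursor_id, depth = NULL,
                       cluster_id = NA_character_,
                       antisense_partner = NA_character_) {
    for (m in hp$matures) {
      mir_i <<- mir_i + 1L
      d <- if (is.null(depth)) depth_draw() else depth
      if (strand == "+") {
        mat <- pre_iv[1] + m$mat
        star <- pre_iv[1] + m$star
      } else {
        # hp coordinates are on the reverse strand; map to forward
        mat <- c(pre_iv[2] - m$mat[2], pre_iv[2] - m$mat[1])
        star <- c(pre_iv[2] - m$star[2], pre_iv[2] - m$star[1])
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        record_id = sprintf("mir%03d", mir_i), precursor_id = precursor_id,
        transcript_id = names(transcripts)[ti], strand = strand,
        pre_start = pre_iv[1], pre_end = pre_iv[2],
        mat_start = mat[1], mat_end = mat[2], mature_seq = m$mature_seq,
        star_start = star[1], star_end = star[2], star_seq = m$star_seq,
        arm = m$arm, planted_depth = d, is_decoy = FALSE,
        cluster_id = cluster_id, antisense_partner = antisense_partner,
        stringsAsFactors = FALSE)
    }
  }

  pre_i <- 0L
  new_pre_id <- function() {
    pre_i <<- pre_i + 1L
    sprintf("pre%03d", pre_i)
  }
  n_special <- 2L * cfg$n_clusters + cfg$n_multi_mature +
    2L * cfg$n_antisense_pairs
  n_plain <- cfg$n_planted_mirnas - n_special

  if (cfg$n_planted_mirnas > 0) {
    # clusters: two precursors in one transcript
    for (ci in seq_len(cfg$n_clusters)) {
      ti <- next_tx()
      cl <- sprintf("cluster%02d", ci)
      hp1 <- build_hairpin(cfg, "5p")
      hp2 <- build_hairpin(cfg, "3p")
      L1 <- nchar(hp1$sequence)
      s <- transcripts[[ti]]
      at1 <- 25L
      at2 <- at1 + L1 + 60L # >= 60 nt of background between the two
      if (at2 + nchar(hp2$sequence) + 25L > nchar(s)) {
        stop("transcript too short for a precursor cluster")
      }
      iv2 <- embed(ti, hp2$sequence, at = at2)
      iv1 <- embed(ti, hp1$sequence, at = at1)
      add_rows(ti, iv1, hp1, "+", new_pre_id(), cluster_id = cl)
      add_rows(ti, iv2, hp2, "+", new_pre_id(), cluster_id = cl)
    }
    # multi-mature: one precursor, 5p and 3p matures
    for (mi in seq_len(cfg$n_multi_mature)) {
      ti <- next_tx()
      hp <- build_hairpin(cfg, c("5p", "3p"))
      iv <- embed(ti, hp$sequence)
      add_rows(ti, iv, hp, "+", new_pre_id())
    }
    # antisense pairs: one hairpin region, a mature on each strand
    for (ai in seq_len(cfg$n_antisense_pairs)) {
      ti <- next_tx()
      hp_fwd <- build_hairpin(cfg, "5p")
      iv <- embed(ti, hp_fwd$sequence)
      id_f <- new_pre_id()
      id_r <- new_pre_id()
      add_rows(ti, iv, hp_fwd, "+", id_f, antisense_partner = id_r)
      # the reverse complement of the region is itself a hairpin; plant its
      # own 5p mature in reverse-strand coordinates
      rc <- revcomp_rna(hp_fwd$sequence)
      mlen <- sample(seq(cfg$mature_len_range[1], cfg$mature_len_range[2]), 1)
      L <- nchar(rc)
      a <- 2L
      b <- a + mlen
      hp_rev <- list(sequence = rc, matures = list(list(
        arm = "5p", mat = c(a, b), star = c(L - b + 2L, L - a + 2L),
        mature_seq = substr(rc, a + 1, b),
        star_seq = substr(rc, L - b + 3L, L - a + 2L))))
      add_rows(ti, iv, hp_rev, "-", id_r, antisense_partner = id_f)
    }
    # plain precursors
    for (pi in seq_len(n_plain)) {
      ti <- next_tx()
      hp <- build_hairpin(cfg, sample(c("5p", "3p"), 1))
      iv <- embed(ti, hp$sequence)
      add_rows(ti, iv, hp, "+", new_pre_id())
    }
  }
  # decoys: one shuffled non-hairpin window per transcript, with a
  # read-source window recorded so decoy reads exercise discovery
  mlen_mid <- as.integer(round(mean(cfg$mature_len_range)))
  for (di in seq_len(cfg$n_decoys)) {
    ti <- next_tx()
    dec <- build_decoy(cfg)
    iv <- embed(ti, dec)
    a <- iv[1] + 6L
    b <- a + mlen_mid
    mir_i <- mir_i # decoys get their own id space
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = sprintf("decoy%03d", di),
      precursor_id = sprintf("decoypre%03d", di),
      transcript_id = names(transcripts)[ti], strand = "+",
      pre_start = iv[1], pre_end = iv[2], mat_start = a, mat_end = b,
      mature_seq = substr(transcripts[[ti]], a + 1, b),
      star_start = NA_integer_, star_end = NA_integer_,
      star_seq = NA_character_, arm = NA_character_,
      planted_depth = depth_draw(), is_decoy = TRUE,
      cluster_id = NA_character_, antisense_partner = NA_character_,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else empty_truth()
  rownames(truth) <- NULL
  list(transcripts = transcripts, truth = truth)
}

phred_string <- function(len, q = 40L) {
  strrep(rawToChar(as.raw(q + 33L)), len)
}

#' Simulate raw small RNA reads from a truth table
#'
#' Each truth row contributes `planted_depth` reads of its mature sequence
#' (and `star_depth` reads of the star, when present), with optional end
#' jitter (trimming up to `jitter_max` nt) and per-base substitution errors,
#' the 3' adapter appended, and constant high-quality Phred strings. A
#' configurable fraction of reads is instead given a failing quality string,
#' and `background_tag_rate` random 18-30 nt tags are added. Read ids encode
#' their origin class (`mir|`, `star|`, `decoy|`, `bg|`).
#'
#' @param truth truth data.frame from [generate_transcriptome()].
#' @param config the same [sim_config()].
#' @return data.frame of FASTQ records (`id`, `sequence`, `quality`), DNA
#'   alphabet, writable with [write_fastq_records()].
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (nchar(cfg$adapter_seq) < 6) {
    stop("invalid config: adapter_seq must be at least 6 nt")
  }
  set.seed(cfg$seed + 1L)
  adapter <- dna_norm(cfg$adapter_seq)
  ids <- character(0); seqs <- character(0)
  emit <- function(class, rid, s, n) {
    if (n <= 0 || is.na(s) || nchar(s) == 0) return(invisible())
    for (k in seq_len(n)) {
      insert <- s
      if (cfg$jitter_max > 0) {
        trim5 <- sample(0:cfg$jitter_max, 1)
        trim3 <- sample(0:cfg$jitter_max, 1)
        if (nchar(insert) - trim5 - trim3 >= 18) {
          insert <- substr(insert, 1 + trim5, nchar(insert) - trim3)
        }
      }
      if (cfg$read_error_rate > 0) {
        v <- seq_chars(insert)
        hit <- runif(length(v)) < cfg$read_error_rate
        if (any(hit)) {
          for (p in which(hit)) {
            v[p] <- sample(setdiff(c("A", "C", "G", "U"), v[p]), 1)
          }
          insert <- paste(v, collapse = "")
        }
      }
      ids <<- c(ids, sprintf("%s|%s|%d", class, rid, k))
      seqs <<- c(seqs, paste0(dna_norm(insert), adapter))
    }
  }
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    cls <- if (r$is_decoy) "decoy" else "mir"
    emit(cls, r$record_id, r$mature_seq, r$planted_depth)
    if (!r$is_decoy) emit("star", r$record_id, r$star_seq, cfg$star_depth)
  }
  if (cfg$background_tag_rate > 0) {
    for (b in seq_len(cfg$background_tag_rate)) {
      tag <- rand_rna(sample(18:30, 1))
      emit("bg", sprintf("bg%04d", b), tag, sample(1:2, 1))
    }
  }
  n <- length(seqs)
  qual <- vapply(nchar(seqs), phred_string, character(1))
  if (cfg$low_quality_fraction > 0 && n > 0) {
    nlq <- round(cfg$low_quality_fraction * n)
    if (nlq > 0) {
      sel <- sample(n, nlq)
      qual[sel] <- vapply(nchar(seqs[sel]), phred_string, character(1), q = 2L)
      ids[sel] <- sub("^[a-z]+\\|", "lowq|", ids[sel])
    }
  }
  data.frame(id = ids, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Generate a Cq table with planted log2 fold-change effects
#'
#' Cq values follow `baseline(assay) - effect(assay, condition) + noise`;
#' the reference assay always has zero planted effect, so downstream ddCq
#' analysis recovers `2^(effect - effect_at_calibrator)` exactly when
#' `noise_sd = 0`.
#'
#' @param conditions character vector of condition labels (tissues or time
#'   points); the first is conventionally the calibrator.
#' @param assays character vector of assay names; must include
#'   `reference_assay`.
#' @param effects numeric matrix of planted log2 effects, rownames = assays
#'   (reference row ignored/zeroed), colnames = conditions. Missing rows or
#'   columns default to 0.
#' @param noise_sd Gaussian noise SD in Cq units (default 0).
#' @param n_replicates replicates per condition x assay (default 3,
#'   matching standard qPCR triplicates).
#' @param reference_assay endogenous reference assay name (default "5.8S").
#' @param seed integer seed for baselines and noise.
#' @return data.frame with `condition`, `assay`, `replicate`, `cq`.
#' @export
generate_cq_table <- function(conditions, assays, effects = NULL,
                              noise_sd = 0, n_replicates = 3,
                              reference_assay = "5.8S", seed = 1L) {
  if (!(reference_assay %in% assays)) {
    stop("invalid design: reference assay '", reference_assay,
         "' missing from assays")
  }
  if (length(conditions) < 1) stop("invalid design: no conditions")
  set.seed(as.integer(seed))
  baseline <- setNames(runif(length(assays), 22, 30), assays)
  baseline[reference_assay] <- 15
  eff <- matrix(0, nrow = length(assays), ncol = length(conditions),
                dimnames = list(assays, conditions))
  if (!is.null(effects)) {
    ra <- intersect(rownames(effects), assays)
    ca <- intersect(colnames(effects), conditions)
    eff[ra, ca] <- effects[ra, ca]
  }
  eff[reference_assay, ] <- 0
  grid <- expand.grid(replicate = seq_len(n_replicates), assay = assays,
                      condition = conditions, stringsAsFactors = FALSE)
  cq <- baseline[grid$assay] - eff[cbind(grid$assay, grid$condition)] +
    if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
  data.frame(condition = grid$condition, assay = grid$assay,
             replicate = grid$replicate, cq = as.numeric(cq),
             stringsAsFactors = FALSE)
}

#' Write a truth table as TSV
#' @param truth truth data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
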