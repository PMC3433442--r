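# Hairpin discovery: mapping, excision, annotation criteria, features,
# recovery of planted structures on a small simulation.

test_that("exact mapping is strand-aware and applies the repeat filter", {
  tx <- c(t1 = paste0(strrep("A", 30), "GGCAUGCCUAGGCAUCGAUGCA",
                      strrep("C", 30)))
  tag <- "GGCAUGCCUAGGCAUCGAUGCA"
  hits <- map_exact(data.frame(sequence = tag, count = 3L), tx)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 30L)
  expect_equal(hits$end, 52L)
  rc <- revcomp_rna(tag)
  h2 <- map_exact(data.frame(sequence = rc, count = 3L), tx)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 30L) # forward coordinates of the rc match
  # repeat filter: tag present at many loci is dropped
  rep_tx <- c(r1 = paste(rep("GGCAUGCCUAGGCAUCGAUGCA", 12), collapse = ""))
  h3 <- map_exact(data.frame(sequence = tag, count = 3L), rep_tx,
                  uniqueness = 10)
  expect_equal(nrow(h3), 0)
  h4 <- map_exact(data.frame(sequence = tag, count = 3L), rep_tx,
                  uniqueness = 12)
  expect_equal(nrow(h4), 12)
})

test_that("excision respects transcript bounds and orientation", {
  params <- discovery_params()
  tx <- paste(rep("ACGU", 100), collapse = "")
  # tag at the very start: no full upstream extension possible
  locus <- data.frame(sequence = substr(tx, 1, 22), count = 3L,
                      transcript_id = "t", strand = "+", start = 0L,
                      end = 22L, stringsAsFactors = FALSE)
  wins <- excise_candidates(locus, tx, params)
  expect_true(all(wins$win_start >= 0 & wins$win_end <= nchar(tx)))
  expect_true(all(wins$win_end - wins$win_start >= 50))
  expect_true(all(nchar(wins$window) == wins$win_end - wins$win_start))
  # minus-strand windows are reverse-complemented with a consistent offset
  locus2 <- locus
  locus2$strand <- "-"
  locus2$start <- 100L
  locus2$end <- 122L
  w2 <- excise_candidates(locus2, tx, params)
  for (k in seq_len(nrow(w2))) {
    m <- substr(w2$window[k], w2$mat_off[k] + 1, w2$mat_off[k] + 22)
    expect_equal(m, revcomp_rna(substr(tx, 101, 122)))
  }
})

test_that("annotation criteria flag failures and boundary passes", {
  params <- discovery_params()
  stats <- list(paired = 20, mature_unpaired = 1,
                bulges = data.frame(arm = character(), length = integer()),
                asym_bulge_count = 0, total_asymmetry = 0, space = 30L)
  good <- list(reads = 5, dG = -45, mfei = 1.2, mature_len = 21)
  expect_true(annotate_candidate(good, stats, params)$accepted)
  # single-criterion failures
  v <- annotate_candidate(modifyList(good, list(dG = -25)), stats, params)
  expect_false(v$crit2_dg)
  expect_false(v$accepted)
  expect_true(all(unlist(v[c("crit1_reads", "crit3_mature_mismatch",
                             "crit4_asym_bulges", "crit5_mfei")])))
  # MFEI exactly at the threshold passes ("at least 0.85")
  expect_true(annotate_candidate(modifyList(good, list(mfei = 0.85)),
                                 stats, params)$crit5_mfei)
  expect_false(annotate_candidate(modifyList(good, list(mfei = 0.8499)),
                                  stats, params)$crit5_mfei)
  expect_false(annotate_candidate(modifyList(good, list(reads = 1)),
                                  stats, params)$crit1_reads)
  bad_stats <- modifyList(stats, list(mature_unpaired = 5))
  expect_false(annotate_candidate(good, bad_stats,
                                  params)$crit3_mature_mismatch)
})

test_that("acceptance is monotone under threshold tightening", {
  s <- small_sim()
  tags <- collapse_tags(clean_reads(s$reads, adapter = s$cfg$adapter_seq))
  loose <- discovery_params()
  disc <- discover_mirnas(tags, s$sim$transcripts, loose)
  tighter <- list(
    discovery_params(min_reads = 10),
    discovery_params(max_dg = -40),
    discovery_params(min_mfei = 1.0),
    discovery_params(max_mature_mismatch = 1),
    discovery_params(min_mature_pair = 20),
    discovery_params(max_space = 40)
  )
  cand <- disc$candidates
  for (tp in tighter) {
    for (i in seq_len(nrow(cand))) {
      stats <- list(paired = cand$paired[i],
                    mature_unpaired = cand$mature_unpaired[i],
                    bulges = data.frame(arm = character(),
                                        length = integer()),
                    asym_bulge_count = cand$asym_bulge_count[i],
                    total_asymmetry = cand$total_asymmetry[i],
                    space = cand$space[i])
      cnd <- list(reads = cand$count[i], dG = cand$dG[i],
                  mfei = cand$mfei[i],
                  mature_len = cand$mat_end[i] - cand$mat_start[i])
      v_loose <- annotate_candidate(cnd, stats, loose)
      v_tight <- annotate_candidate(cnd, stats, tp)
      if (!v_loose$accepted) expect_false(v_tight$accepted)
    }
  }
})

test_that("planted miRNAs are recovered and decoys rejected (small world)", {
  s <- small_sim()
  tags <- collapse_tags(clean_reads(s$reads, adapter = s$cfg$adapter_seq))
  disc <- discover_mirnas(tags, s$sim$transcripts, discovery_params())
  acc <- disc$candidates[disc$candidates$accepted, , drop = FALSE]
  truth <- s$sim$truth
  pl <- truth[!truth$is_decoy, ]
  rec <- vapply(unique(pl$precursor_id), function(p) {
    planted_recovered(pl[pl$precursor_id == p, ], acc)
  }, logical(1))
  expect_gte(mean(rec), 0.9)
  dec <- truth[truth$is_decoy, ]
  expect_false(any(vapply(seq_len(nrow(dec)), function(k) {
    planted_recovered(dec[k, , drop = FALSE], acc)
  }, logical(1))))
  # features: cluster, multi-mature, antisense pair all present
  feats <- detect_features(acc)
  expect_gte(length(unique(stats::na.omit(feats$cluster_id))), 1)
  expect_true(any(feats$multi_mature))
  expect_gte(sum(!is.na(feats$antisense_partner)), 2)
})

test_that("a max_space below the planted loop misses the precursor", {
  s <- small_sim()
  truth <- s$sim$truth
  r <- truth[!truth$is_decoy & truth$arm == "5p" & truth$strand == "+", ][1, ]
  tag <- data.frame(sequence = r$mature_seq, count = 10L)
  tiny <- discovery_params(min_space = 1, max_space = 4,
                           space_grid = c(2, 4))
  disc <- discover_mirnas(tag, s$sim$transcripts, tiny)
  if (nrow(disc$candidates) > 0) {
    expect_false(any(disc$candidates$accepted))
  } else {
    succeed()
  }
})

test_that("homology mode recovers a planted hairpin from a known mature", {
  s <- small_sim()
  truth <- s$sim$truth
  r <- truth[!truth$is_decoy & truth$strand == "+", ][1, ]
  # seed discovery with the known mature sequence (as if from miRBase)
  seeds <- data.frame(sequence = r$mature_seq, count = r$planted_depth)
  disc <- discover_mirnas(seeds, s$sim$transcripts, discovery_params())
  acc <- disc$candidates[disc$candidates$accepted, , drop = FALSE]
  expect_true(planted_recovered(truth[truth$record_id == r$record_id, ],
                                acc))
  # the recovered precursor contains the planted mature interval
  row <- acc[acc$transcript_id == r$transcript_id &
               abs(acc$mat_start - r$mat_start) <= 3, ][1, ]
  expect_lte(row$pre_start, r$mat_start)
  expect_gte(row$pre_end, r$mat_end)
})

test_that("feature detection handles isolated precursors and empties", {
  one <- data.frame(sequence = "x", count = 5L, transcript_id = "t1",
                    strand = "+", mat_start = 10L, mat_end = 31L,
                    pre_start = 5L, pre_end = 80L, stringsAsFactors = FALSE)
  f <- detect_features(one)
  expect_equal(nrow(f), 1)
  expect_false(f$multi_mature)
  expect_true(is.na(f$cluster_id))
  expect_true(is.na(f$antisense_partner))
  expect_error(detect_features(one[0, ]), "empty")
})

test_that("precursor family grouping clusters by identity", {
  a <- paste(rep("ACGU", 20), collapse = "")
  b <- paste0(substr(a, 1, 70), "AAAAAAAAAA") # ~87% identical to a
  c_ <- paste(rep("GAUC", 20), collapse = "")
  fam <- group_precursor_families(c(a, b, c_), min_identity = 0.8)
  expect_equal(fam[1], fam[2])
  expect_false(fam[1] == fam[3])
  expect_equal(group_precursor_families(character(0)), integer(0))
})
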