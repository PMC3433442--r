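# Conserved miRNA identification against known precursors.

# tiny known-precursor fixture built in code: one hairpin-ish sequence with
# annotated mature (5-24) and star (40-59) intervals, 0-based half-open
mk_precursors <- function() {
  set.seed(9)
  mat <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
               collapse = "")
  star <- revcomp_rna(mat)
  pre <- paste0("ACGUA", mat, "AAACCCGGGUUUAC", substr(star, 2, 21), "GCAUA")
  list(seqs = c(pre1 = pre, pre2 = pre), mature = mat,
       ann = data.frame(
         id = c("pre1", "pre1", "pre2", "pre2"),
         family = c("MIR166", "MIR166", "MIR159", "MIR159"),
         region = c("mature", "star", "mature", "star"),
         start = c(5L, 40L, 5L, 40L), end = c(26L, 60L, 26L, 60L),
         arm = c("5p", "3p", "5p", "3p"), stringsAsFactors = FALSE))
}

test_that("mapping finds exact and mismatched placements, oracle-checked", {
  px <- mk_precursors()
  tags <- data.frame(sequence = px$mature, count = 10L)
  hits <- map_to_precursors(tags, px$seqs, max_mismatch = 2)
  # identical duplicate precursors: one hit in each
  expect_equal(sort(unique(hits$precursor_id)), c("pre1", "pre2"))
  expect_true(all(hits$mismatches[hits$offset == 5] == 0))
  # three substitutions exceed the tolerance everywhere
  v <- strsplit(px$mature, "")[[1]]
  for (p in c(3, 10, 17)) v[p] <- setdiff(c("A", "C", "G", "U"), v[p])[1]
  far <- paste(v, collapse = "")
  h3 <- map_to_precursors(data.frame(sequence = far, count = 1L), px$seqs)
  expect_true(all(h3$mismatches <= 2))
  expect_false(any(h3$offset == 5)) # the planted locus needs 3 mismatches
  expect_warning(
    map_to_precursors(data.frame(sequence = "ACGN", count = 1L), px$seqs),
    "non-ACGU")
  expect_error(map_to_precursors(tags, character(0)), "no precursors")
})

test_that("implementation matches the brute-force Hamming oracle", {
  set.seed(23)
  ref <- paste(sample(c("A", "C", "G", "U"), 150, replace = TRUE),
               collapse = "")
  refs <- c(p1 = ref)
  tags <- data.frame(
    sequence = vapply(1:40, function(i) {
      if (i <= 20) { # embedded substrings with 0-2 substitutions
        off <- sample(0:(150 - 21), 1)
        v <- strsplit(substr(ref, off + 1, off + 21), "")[[1]]
        nmm <- sample(0:2, 1)
        if (nmm > 0) for (p in sample(21, nmm))
          v[p] <- setdiff(c("A", "C", "G", "U"), v[p])[1]
        paste(v, collapse = "")
      } else {
        paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
              collapse = "")
      }
    }, character(1)), count = 1L)
  tags <- tags[!duplicated(tags$sequence), , drop = FALSE]
  for (mm in 0:2) {
    got <- map_to_precursors(tags, refs, max_mismatch = mm)
    want <- do.call(rbind, lapply(tags$sequence, function(tg) {
      hits <- oracle_hamming_hits(tg, ref, mm)
      if (length(hits) == 0) return(NULL)
      data.frame(sequence = tg,
                 offset = vapply(hits, `[`, numeric(1), 1),
                 mismatches = vapply(hits, `[`, numeric(1), 2))
    }))
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got_key <- sort(paste(got$sequence, got$offset, got$mismatches))
      want_key <- sort(paste(want$sequence, want$offset, want$mismatches))
      expect_equal(got_key, want_key)
    }
  }
  # subset property: stricter tolerance is a subset
  h0 <- map_to_precursors(tags, refs, max_mismatch = 0)
  h2 <- map_to_precursors(tags, refs, max_mismatch = 2)
  expect_true(all(paste(h0$sequence, h0$offset) %in%
                    paste(h2$sequence, h2$offset)))
})

test_that("region classification applies tolerance and precedence", {
  px <- mk_precursors()
  mk_hit <- function(seq, off) data.frame(sequence = seq, count = 1L,
                                          precursor_id = "pre1",
                                          offset = off,
                                          mismatches = 0L,
                                          stringsAsFactors = FALSE)
  expect_equal(classify_hit(mk_hit(px$mature, 5L), px$ann), "mature")
  expect_equal(classify_hit(mk_hit(px$mature, 8L), px$ann), "mature") # +3 ok
  expect_equal(classify_hit(mk_hit(px$mature, 10L), px$ann), "other") # +5
  # tag spanning only the loop
  expect_equal(classify_hit(mk_hit(strrep("A", 10), 27L), px$ann), "other")
  # star region
  expect_equal(classify_hit(mk_hit(strrep("A", 20), 40L), px$ann), "star")
})

test_that("candidate grouping merges length variants and splits families", {
  px <- mk_precursors()
  tags <- data.frame(
    sequence = c(px$mature, substr(px$mature, 2, 21)), # a trimmed variant
    count = c(10L, 4L))
  hits <- classify_hits(map_to_precursors(tags, px$seqs), px$ann)
  cand <- group_candidates(hits, px$ann)
  # one candidate per family, both member tags merged
  expect_equal(sort(cand$family), c("MIR159", "MIR166"))
  expect_equal(cand$total_reads, c(14L, 14L))
  expect_equal(cand$n_members, c(2L, 2L))
  expect_equal(unique(cand$representative), px$mature)
  empty <- group_candidates(
    classify_hits(map_to_precursors(
      data.frame(sequence = strrep("A", 20), count = 1L), px$seqs)[0, ],
      px$ann), px$ann)
  expect_equal(nrow(empty), 0)
})

test_that("family abundance reproduces printed-percentage arithmetic", {
  cand <- data.frame(family = c("MIR166", "MIR159", "MIR393"),
                     total_reads = c(228538L, 61264L, 15942L))
  # denominator fixed to the published total by adding the remainder family
  cand2 <- rbind(cand, data.frame(family = "other",
                                  total_reads = 305744L - sum(cand$total_reads)))
  fa <- family_abundance(cand2)
  expect_equal(fa$percent[fa$family == "MIR159"], 20.0)
  one <- family_abundance(data.frame(family = "MIR156", total_reads = 7L))
  expect_equal(one$percent, 100.0)
  zero <- family_abundance(data.frame(family = c("a", "b"),
                                      total_reads = c(0L, 10L)))
  expect_equal(zero$percent[zero$family == "a"], 0.0)
})

test_that("simulated planted matures classify as mature; decoys do not", {
  s <- small_sim()
  truth <- s$sim$truth
  pl <- truth[!truth$is_decoy, ]
  # build a known-precursor set from the planted truth itself
  seqs <- character(0)
  ann <- NULL
  for (i in seq_len(nrow(pl))) {
    r <- pl[i, ]
    pre <- substr(s$sim$transcripts[[r$transcript_id]], r$pre_start + 1,
                  r$pre_end)
    mat <- c(r$mat_start, r$mat_end) - r$pre_start
    if (r$strand == "-") {
      pre <- revcomp_rna(pre)
      mat <- c(r$pre_end - r$mat_end, r$pre_end - r$mat_start) - r$pre_start
    }
    id <- paste0(r$record_id, "_pre")
    seqs[id] <- pre
    ann <- rbind(ann, data.frame(id = id, family = r$precursor_id,
                                 region = "mature", start = mat[1],
                                 end = mat[2], arm = r$arm,
                                 stringsAsFactors = FALSE))
  }
  tags <- collapse_tags(clean_reads(s$reads, adapter = s$cfg$adapter_seq))
  hits <- classify_hits(map_to_precursors(tags, seqs), ann)
  mature_tags <- unique(hits$sequence[hits$region == "mature"])
  expect_true(all(pl$mature_seq %in% mature_tags))
  decoy_tags <- truth$mature_seq[truth$is_decoy]
  expect_false(any(decoy_tags %in% mature_tags))
})
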