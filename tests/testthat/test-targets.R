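# Penalty-score target prediction.

test_that("perfect complements score zero; single edits match the scheme", {
  sch <- scoring_scheme()
  set.seed(5)
  mir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
               collapse = "")
  site <- revcomp_rna(mir)
  expect_equal(score_duplex(mir, site, sch), 0)
  # exhaustive single-edit enumeration: every mismatch/G:U/gap at every
  # miRNA position must score exactly the scheme's weighted penalty
  mv <- strsplit(mir, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (pos in seq_len(21)) {
    x <- mv[pos]
    site_pos <- 21 - pos + 1 # duplex is antiparallel
    sv <- strsplit(site, "")[[1]]
    # G:U wobble: miRNA G opposite U, or miRNA U opposite G
    if (x %in% c("G", "U")) {
      sv2 <- sv
      sv2[site_pos] <- if (x == "G") "U" else "G"
      expect_equal(score_duplex(mir, paste(sv2, collapse = ""), sch),
                   oracle_single_edit_penalty("gu", pos, sch),
                   info = paste("gu at", pos))
    }
    # mismatch: replace the paired base with something pairing-neutral
    sv3 <- sv
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(comp[[x]], if (x == "G") "U" else if (x == "U") "G"))
    sv3[site_pos] <- bad[1]
    expect_equal(score_duplex(mir, paste(sv3, collapse = ""), sch),
                 oracle_single_edit_penalty("mismatch", pos, sch),
                 info = paste("mismatch at", pos))
    # gap: delete the site base opposite this position; repeats can allow
    # cheaper placements, so compare against the enumeration oracle
    sv4 <- sv[-site_pos]
    w4 <- paste(sv4, collapse = "")
    expect_equal(score_duplex(mir, w4, sch),
                 oracle_align_penalty(mir, w4, sch),
                 info = paste("gap at", pos))
  }
})

test_that("scoring equals the alignment-enumeration oracle on random pairs", {
  sch <- scoring_scheme()
  set.seed(31)
  for (rep in 1:40) {
    m <- sample(18:24, 1)
    mir <- paste(sample(c("A", "C", "G", "U"), m, replace = TRUE),
                 collapse = "")
    wl <- m + sample(-1:1, 1)
    # half the cases are mutated complements, half pure random
    window <- if (rep %% 2 == 0) {
      paste(sample(c("A", "C", "G", "U"), wl, replace = TRUE),
            collapse = "")
    } else {
      v <- strsplit(revcomp_rna(mir), "")[[1]]
      for (p in sample(m, sample(0:3, 1))) {
        v[p] <- sample(c("A", "C", "G", "U"), 1)
      }
      v <- if (wl < m) v[-sample(m, 1)] else if (wl > m)
        append(v, sample(c("A", "C", "G", "U"), 1), after = sample(m, 1))
      else v
      paste(v, collapse = "")
    }
    expect_equal(score_duplex(mir, window, sch),
                 oracle_align_penalty(mir, window, sch))
  }
})

test_that("specific worked examples: wobble outside seed, mismatch inside", {
  sch <- scoring_scheme()
  mir <- "UGGAGCUCCCUUCAUUCCAAU" # 21 nt
  site <- revcomp_rna(mir)
  # G:U at miRNA position 16 (outside seed 2-13): 0.5
  mirv <- strsplit(mir, "")[[1]]
  stopifnot(mirv[16] %in% c("G", "U"))
  sv <- strsplit(site, "")[[1]]
  sv[21 - 16 + 1] <- if (mirv[16] == "G") "U" else "G"
  expect_equal(score_duplex(mir, paste(sv, collapse = "")), 0.5)
  # mismatch at position 5 (in seed): doubled to 2.0
  sv <- strsplit(site, "")[[1]]
  sv[21 - 5 + 1] <- "C" # position 5 is G; C:G -> G..C? choose non-pairing
  mirv <- strsplit(mir, "")[[1]]
  x <- mirv[5]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  bad <- setdiff(c("A", "C", "G", "U"),
                 c(comp[[x]], if (x == "G") "U" else if (x == "U") "G"))
  sv[21 - 5 + 1] <- bad[1]
  expect_equal(score_duplex(mir, paste(sv, collapse = "")), 2.0)
})

test_that("penalties are monotone under added edits", {
  sch <- scoring_scheme()
  set.seed(8)
  for (rep in 1:20) {
    mir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                 collapse = "")
    mirv <- strsplit(mir, "")[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    sv <- strsplit(revcomp_rna(mir), "")[[1]]
    p_prev <- score_duplex(mir, paste(sv, collapse = ""), sch)
    # each edit breaks a fresh, previously matching position
    for (pos in sample(21, 3)) {
      mpos <- 21 - pos + 1
      sv[pos] <- sample(setdiff(c("A", "C", "G", "U"),
                                c(sv[pos], comp[[mirv[mpos]]])), 1)
      p_now <- score_duplex(mir, paste(sv, collapse = ""), sch)
      expect_gte(p_now, p_prev - 1e-9)
      p_prev <- p_now
    }
  }
})

test_that("input validation", {
  expect_error(score_duplex("ACGX", "ACGU"), "A/C/G/U")
  expect_error(score_duplex("ACGUACGU", "ACGUAC"), "within max_gaps")
})

test_that("scanning finds planted sites at the planted coordinates", {
  sch <- scoring_scheme()
  set.seed(12)
  mir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
               collapse = "")
  bg <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                          collapse = "")
  perfect <- revcomp_rna(mir)
  # plant a 1.5 site: one seed G:U (1.0) plus one non-seed G:U (0.5)
  mirv <- strsplit(mir, "")[[1]]
  gu_seed <- which(mirv %in% c("G", "U"))
  pos_a <- gu_seed[gu_seed >= 2 & gu_seed <= 13][1]
  pos_b <- rev(gu_seed[gu_seed > 13])[1]
  sv <- strsplit(perfect, "")[[1]]
  for (p in c(pos_a, pos_b)) {
    sv[21 - p + 1] <- if (mirv[p] == "G") "U" else "G"
  }
  site15 <- paste(sv, collapse = "")
  expect_equal(score_duplex(mir, site15, sch), 1.5)
  tx <- c(tx1 = paste0(bg(57), site15, bg(40)))
  sites <- scan_targets(mir, tx, sch, mirna_id = "m1")
  hit <- sites[sites$penalty == 1.5, ]
  expect_equal(hit$start, 57L)
  # cleavage opposite miRNA position 10, 1-based
  expect_equal(hit$cleavage_pos, 57L + 21L - 10L + 1L)
  expect_match(hit$pairing, "o")
  # a site scoring exactly 3.0 is retained (inclusive cutoff)
  mm <- strsplit(perfect, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  # three non-seed mismatches at positions 15, 17, 19 -> 3.0
  for (p in c(15, 17, 19)) {
    x <- mirv[p]
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(comp[[x]], if (x == "G") "U" else if (x == "U") "G"))
    mm[21 - p + 1] <- bad[1]
  }
  site30 <- paste(mm, collapse = "")
  expect_equal(score_duplex(mir, site30, sch), 3.0)
  tx2 <- c(tx2 = paste0(bg(20), site30, bg(20)))
  s2 <- scan_targets(mir, tx2, sch, mirna_id = "m1")
  expect_true(any(s2$start == 20 & s2$penalty == 3.0))
  # no qualifying window -> empty
  empty <- scan_targets(strrep("A", 21), c(t = strrep("A", 100)), sch)
  expect_equal(nrow(empty), 0)
  # reverse-complement self-test
  self <- scan_targets(mir, c(m = revcomp_rna(mir)), sch)
  expect_true(any(self$start == 0 & self$penalty == 0))
})

test_that("shared targets intersect by transcript", {
  a <- data.frame(mirna = "m1", transcript_id = c("t1", "t2"),
                  stringsAsFactors = FALSE)
  b <- data.frame(mirna = "m2", transcript_id = c("t2", "t3"),
                  stringsAsFactors = FALSE)
  sh <- shared_targets(list(m1 = a, m2 = b))
  expect_equal(sh$transcript_id, "t2")
  expect_equal(sh$mirnas, "m1,m2")
  none <- shared_targets(list(m1 = a,
                              m3 = data.frame(mirna = "m3",
                                              transcript_id = "t9")))
  expect_equal(nrow(none), 0)
  # the same miRNA listed twice does not self-intersect
  dup <- shared_targets(list(m1 = a, m1 = a))
  expect_equal(nrow(dup), 0)
  expect_error(shared_targets(list(m1 = a)), "at least two")
})
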