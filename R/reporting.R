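# Shared summary arithmetic, packaged reference-table fixtures, run report.

#' Percentage with decimal half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places.
#' A zero denominator yields 0.0 (a convention chosen so empty categories
#' print as 0.0% rather than erroring).
#'
#' @param numerator,denominator non-negative counts.
#' @param decimals decimal places (default 1, matching printed summaries).
#' @return numeric percentage.
#' @examples
#' percent(61264, 305744)    # 20.0
#' percent(152436, 1502664)  # 10.1
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(numerator < 0) || any(denominator < 0)) {
    stop("percent(): negative inputs are not allowed")
  }
  if (length(numerator) == 0) return(numeric(0))
  n <- max(length(numerator), length(denominator))
  num <- rep_len(numerator, n)
  den <- rep_len(denominator, n)
  out <- numeric(n)
  nz <- den != 0
  out[nz] <- round_half_up(100 * num[nz] / den[nz], decimals)
  out
}

# expected md5 checksums of the packaged fixture transcriptions; guards
# against silent drift of the reference tables
.FIXTURE_MD5 <- c(
  table1_nonconserved_mirnas.tsv = "1ed9358e6e60f8245701acdbc83fd704",
  table2_nonconserved_targets.tsv = "5c88d8bcfa107815e9151aebe577f981"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "hairpinforge")
  if (p == "") stop("fixture not found: ", file)
  p
}

check_fixture_md5 <- function(file, path) {
  want <- .FIXTURE_MD5[[file]]
  if (!is.null(want) && nzchar(want)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, want)) {
      warning("fixture checksum mismatch for ", file,
              " (expected ", want, ", got ", got, ")")
    }
  }
  invisible(TRUE)
}

#' Load the packaged non-conserved miRNA reference table
#'
#' A transcription of the published table of non-conserved miRNAs and the
#' one sequenced star: name, mature sequence, size, read count, MFEI of the
#' hairpin, source unigene and its length, a star flag, and the transcript
#' strand (three unigenes are bidirectionally transcribed). Validation
#' enforces that the printed size equals the sequence length in every row
#' and that read counts are at least 1.
#'
#' @param validate check row invariants and the file checksum.
#' @param path alternative TSV to load (default: the packaged fixture).
#' @return data.frame with derived columns `family` (e.g. "MIR6135") and
#'   `precursor_key` (unigene, strand and member letter; rows such as
#'   miR6135e.1/e.2 or miR6143b-5p/-3p share one key).
#' @export
load_table1_fixture <- function(validate = TRUE, path = NULL) {
  if (is.null(path)) path <- fixture_path("table1_nonconserved_mirnas.tsv")
  t1 <- read.delim(path, stringsAsFactors = FALSE)
  if (validate) {
    if (basename(path) %in% names(.FIXTURE_MD5)) {
      check_fixture_md5(basename(path), path)
    }
    bad <- which(nchar(t1$sequence) != t1$size_nt)
    if (length(bad) > 0) {
      stop("table1 fixture validation: size != sequence length in row ",
           bad[1], " (", t1$name[bad[1]], ")")
    }
    if (any(t1$reads < 1)) {
      stop("table1 fixture validation: reads < 1 in row ",
           which(t1$reads < 1)[1])
    }
  }
  t1$family <- sub("^miR(\\d+).*$", "MIR\\1", t1$name)
  # member label: strip the star flag and the .1/.2 / -5p/-3p suffixes that
  # mark multiple matures of one precursor
  member <- sub("\\*$", "", t1$name)
  member <- sub("\\.\\d+$", "", member)
  member <- sub("-[35]p$", "", member)
  t1$precursor_key <- paste(t1$unigene_id, t1$strand, member, sep = "|")
  t1
}

#' Load the packaged non-conserved target table
#'
#' Transcription of the published non-conserved target predictions:
#' miRNA family, annotated target function, unigene id and penalty score.
#'
#' @param validate check the penalty range invariant and file checksum.
#' @param path alternative TSV to load (default: the packaged fixture).
#' @return data.frame with columns `family`, `target_function`,
#'   `unigene_id`, `penalty`.
#' @export
load_table2_fixture <- function(validate = TRUE, path = NULL) {
  if (is.null(path)) path <- fixture_path("table2_nonconserved_targets.tsv")
  t2 <- read.delim(path, stringsAsFactors = FALSE)
  if (validate) {
    if (basename(path) %in% names(.FIXTURE_MD5)) {
      check_fixture_md5(basename(path), path)
    }
    bad <- which(t2$penalty < 0 | t2$penalty > 3)
    if (length(bad) > 0) {
      stop("table2 fixture validation: penalty outside [0, 3] in row ",
           bad[1])
    }
  }
  t2
}

#' Summary counts from the packaged reference tables
#'
#' Counts mature miRNAs (star rows excluded), distinct precursors (rows
#' sharing a precursor key count once), per-family precursor membership,
#' and target entries.
#'
#' @param table1 data.frame from [load_table1_fixture()] (default: load it).
#' @param table2 data.frame from [load_table2_fixture()] (default: load it).
#' @return list with `n_mature`, `n_precursors`, `family_members` (named
#'   integer vector of distinct precursors per family), `n_targets`.
#' @export
fixture_counts <- function(table1 = load_table1_fixture(),
                           table2 = load_table2_fixture()) {
  mature <- table1[table1$is_star == 0, , drop = FALSE]
  keys <- unique(table1$precursor_key)
  fam_of_key <- vapply(keys, function(k) {
    table1$family[match(k, table1$precursor_key)]
  }, character(1))
  fam_tab <- table(fam_of_key)
  list(
    n_mature = nrow(mature),
    n_precursors = length(keys),
    family_members = setNames(as.integer(fam_tab), names(fam_tab)),
    n_targets = nrow(table2)
  )
}

#' Assemble a run report from stage outputs
#'
#' Stitches whatever stage outputs are supplied into a single markdown
#' report plus a flat key/value table. Sections are emitted only for the
#' stages present; reruns on identical inputs produce identical text.
#'
#' @param preprocess optional list with `size_distribution` (data.frame)
#'   and `n_clean_reads`.
#' @param conserved optional data.frame of family abundances.
#' @param discovery optional list with `verdicts` (data.frame of criterion
#'   flags) and optionally `truth_eval` (list with sensitivity/precision).
#' @param targets optional data.frame of target sites.
#' @param expression optional list of stress-call data.frames by stressor.
#' @param config optional named list echoed into the header.
#' @return list with `markdown` (character vector of lines) and `table`
#'   (data.frame of key/value summary rows).
#' @export
run_report <- function(preprocess = NULL, conserved = NULL, discovery = NULL,
                       targets = NULL, expression = NULL, config = NULL) {
  if (is.null(preprocess) && is.null(conserved) && is.null(discovery) &&
      is.null(targets) && is.null(expression)) {
    stop("run_report(): at least one stage output must be supplied")
  }
  md <- c("# hairpinforge run report", "",
          paste0("package version: ",
                 as.character(utils::packageVersion("hairpinforge"))))
  kv <- list()
  add <- function(key, value) kv[[length(kv) + 1]] <<- data.frame(
    key = key, value = as.character(value), stringsAsFactors = FALSE)
  if (!is.null(config)) {
    md <- c(md, "", "## Configuration", "",
            paste0("- ", names(config), ": ",
                   vapply(config, function(x) paste(format(x), collapse = ","),
                          character(1))))
  }
  if (!is.null(preprocess)) {
    md <- c(md, "", "## Read population", "",
            paste0("clean reads: ", preprocess$n_clean_reads))
    add("clean_reads", preprocess$n_clean_reads)
    sd <- preprocess$size_distribution
    if (!is.null(sd) && nrow(sd) > 0) {
      md <- c(md, "", paste0("| length | reads | read% | unique | unique% |"),
              "|---|---|---|---|---|",
              sprintf("| %d | %d | %.1f | %d | %.1f |", sd$length,
                      sd$read_count, sd$read_percent, sd$unique_count,
                      sd$unique_percent))
    }
  }
  if (!is.null(conserved) && nrow(conserved) > 0) {
    md <- c(md, "", "## Conserved miRNA families", "",
            sprintf("- %s: %d reads (%.1f%%)", conserved$family,
                    conserved$reads, conserved$percent))
    add("conserved_families", nrow(conserved))
  }
  if (!is.null(discovery)) {
    v <- discovery$verdicts
    n_acc <- if (is.null(v)) 0L else sum(v$accepted)
    md <- c(md, "", "## Hairpin discovery", "",
            paste0("candidates evaluated: ", if (is.null(v)) 0 else nrow(v)),
            paste0("accepted: ", n_acc))
    add("accepted_candidates", n_acc)
    te <- discovery$truth_eval
    if (!is.null(te)) {
      md <- c(md, sprintf("sensitivity vs truth: %.3f", te$sensitivity),
              sprintf("precision vs truth: %.3f", te$precision))
      add("sensitivity", te$sensitivity)
      add("precision", te$precision)
    }
  }
  if (!is.null(targets)) {
    md <- c(md, "", "## Target prediction", "",
            paste0("sites at or below cutoff: ", nrow(targets)))
    add("target_sites", nrow(targets))
  }
  if (!is.null(expression)) {
    md <- c(md, "", "## Stress response calls", "")
    for (st in names(expression)) {
      calls <- expression[[st]]
      resp <- calls$assay[calls$responsive]
      md <- c(md, paste0("- ", st, ": ",
                         if (length(resp)) paste(resp, collapse = ", ")
                         else "(none)"))
      add(paste0("responsive_", st), length(resp))
    }
  }
  list(markdown = md,
       table = if (length(kv)) do.call(rbind, kv) else
         data.frame(key = character(), value = character()))
}
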