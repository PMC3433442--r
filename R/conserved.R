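# Conserved miRNA identification: mismatch-tolerant mapping of unique tags
# to known precursors, region classification, candidate grouping, family
# abundance profiling.

#' Read a known-precursor annotation table
#'
#' TSV with one row per annotated mature/star interval: `id`, `family`,
#' `region` ("mature" or "star"), `start`, `end` (0-based half-open on the
#' precursor), `arm` ("5p"/"3p", optional). Precursor sequences come from a
#' companion FASTA keyed by `id`.
#'
#' @param path annotation TSV.
#' @return data.frame of interval annotations.
#' @export
read_precursor_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "family", "region", "start", "end")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  ann
}

#' Map tags to known precursors with mismatch tolerance
#'
#' Ungapped Hamming-distance scan of every tag against the sense strand of
#' every precursor (hairpins are oriented, so only sense placements are
#' meaningful); all placements with at most `max_mismatch` substitutions
#' are reported, and a tag may hit several precursors. Tags containing
#' non-ACGU characters are rejected with a warning.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @param precursors named character vector of precursor sequences
#'   (RNA alphabet).
#' @param max_mismatch maximum substitutions (default 2).
#' @return data.frame with `sequence`, `count`, `precursor_id`, `offset`
#'   (0-based), `mismatches`.
#' @export
map_to_precursors <- function(tags, precursors, max_mismatch = 2) {
  if (length(precursors) == 0) stop("map_to_precursors(): no precursors")
  bad <- grepl("[^ACGU]", tags$sequence)
  if (any(bad)) {
    warning("rejecting ", sum(bad), " tag(s) with non-ACGU characters")
    tags <- tags[!bad, , drop = FALSE]
  }
  out <- list()
  for (p in seq_along(precursors)) {
    hits <- .hamming_scan_cpp(tags$sequence, precursors[[p]],
                              as.integer(max_mismatch))
    if (nrow(hits) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        sequence = tags$sequence[hits$tag], count = tags$count[hits$tag],
        precursor_id = names(precursors)[p], offset = hits$offset,
        mismatches = hits$mismatches, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(), count = integer(),
                      precursor_id = character(), offset = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a precursor hit by region
#'
#' A hit is `mature` if its start lies within `tol` nt of an annotated
#' mature start and it overlaps the annotated interval by at least
#' `min_overlap` nt; analogously `star`; otherwise `other`. Precedence is
#' mature > star > other.
#'
#' @param hit one row of [map_to_precursors()] output (needs
#'   `precursor_id`, `offset`, `sequence`).
#' @param annotation data.frame from [read_precursor_annotation()].
#' @param tol start-position tolerance in nt (default 3).
#' @param min_overlap minimum overlap with the annotated interval.
#' @return region label: "mature", "star" or "other".
#' @export
classify_hit <- function(hit, annotation, tol = 3, min_overlap = 16) {
  s <- hit$offset
  e <- s + nchar(hit$sequence)
  ann <- annotation[annotation$id == hit$precursor_id, , drop = FALSE]
  match_region <- function(region) {
    rows <- ann[ann$region == region, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      ov <- min(e, rows$end[k]) - max(s, rows$start[k])
      if (abs(s - rows$start[k]) <= tol && ov >= min_overlap) return(TRUE)
    }
    FALSE
  }
  if (match_region("mature")) return("mature")
  if (match_region("star")) return("star")
  "other"
}

#' Classify all hits
#'
#' @param hits [map_to_precursors()] output.
#' @param annotation precursor annotation.
#' @param tol,min_overlap see [classify_hit()].
#' @return `hits` with an added `region` column.
#' @export
classify_hits <- function(hits, annotation, tol = 3, min_overlap = 16) {
  hits$region <- vapply(seq_len(nrow(hits)), function(i) {
    classify_hit(hits[i, ], annotation, tol = tol, min_overlap = min_overlap)
  }, character(1))
  hits
}

#' Group mature-region hits into miRNA candidates
#'
#' Mature-region tags hitting the same family at the same mature locus
#' (starts within `tol` nt on one precursor's annotated mature) merge into
#' one candidate; the representative is the most abundant member tag and
#' reads are summed over distinct member tags. A tag hitting two families
#' contributes to a candidate in each, but is counted once per candidate.
#'
#' @param hits classified hits (`region == "mature"` rows are used).
#' @param annotation precursor annotation (for family and locus lookup).
#' @param tol start tolerance used for locus identity (default 3).
#' @return data.frame with `family`, `precursor_id`, `locus_start`,
#'   `representative`, `n_members`, `total_reads`.
#' @export
group_candidates <- function(hits, annotation, tol = 3) {
  mh <- hits[hits$region == "mature", , drop = FALSE]
  if (nrow(mh) == 0) {
    return(data.frame(family = character(), precursor_id = character(),
                      locus_start = integer(), representative = character(),
                      n_members = integer(), total_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  fam <- annotation$family[match(mh$precursor_id, annotation$id)]
  mat_ann <- annotation[annotation$region == "mature", , drop = FALSE]
  # locus key: the annotated mature start nearest the hit start
  locus <- vapply(seq_len(nrow(mh)), function(i) {
    rows <- mat_ann[mat_ann$id == mh$precursor_id[i], , drop = FALSE]
    rows$start[which.min(abs(rows$start - mh$offset[i]))]
  }, numeric(1))
  key <- paste(fam, locus, sep = "|")
  grp <- split(seq_len(nrow(mh)), key)
  out <- lapply(grp, function(idx) {
    d <- mh[idx, , drop = FALSE]
    d <- d[!duplicated(d$sequence), , drop = FALSE]
    rep_i <- which.max(d$count)
    data.frame(family = fam[idx[1]], precursor_id = d$precursor_id[rep_i],
               locus_start = locus[idx[1]],
               representative = d$sequence[rep_i], n_members = nrow(d),
               total_reads = sum(d$count), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(-res$total_reads, res$family), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Family abundance profile
#'
#' Reads summed per family with one-decimal percentages of the total
#' conserved mature reads.
#'
#' @param candidates [group_candidates()] output.
#' @return data.frame with `family`, `reads`, `percent`, ordered by reads.
#' @export
family_abundance <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(data.frame(family = character(), reads = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(total_reads ~ family, data = candidates, FUN = sum)
  names(agg) <- c("family", "reads")
  agg$percent <- percent(agg$reads, sum(agg$reads))
  agg <- agg[order(-agg$reads, agg$family), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
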