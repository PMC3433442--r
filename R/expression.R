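# Relative quantification (2^-ddCq) and stress-response calling.

#' Fold changes by the 2^-ddCq method
#'
#' Per condition, `dCq = mean Cq(assay) - mean Cq(reference)`; then
#' `ddCq = dCq(condition) - dCq(calibrator)` and `fold = 2^-ddCq`, so the
#' calibrator fold change is exactly 1. Replicates are aggregated by
#' arithmetic mean of Cq before subtraction; the SD over per-replicate dCq
#' values (replicate i of the assay paired with replicate i of the
#' reference) is reported, together with the SD of the per-replicate fold
#' changes.
#'
#' @param records data.frame with `condition`, `assay`, `replicate`, `cq`
#'   (e.g. from [generate_cq_table()] or a Cq TSV).
#' @param assay assay to profile.
#' @param reference_assay endogenous reference (default "5.8S").
#' @param calibrator calibrator condition (fold set to 1 there).
#' @return data.frame with `assay`, `condition`, `dcq`, `fold`, `sd_dcq`,
#'   `sd_fold`; conditions lacking the reference are reported with `NA`
#'   fold (missing, not zero).
#' @export
fold_changes <- function(records, assay, reference_assay = "5.8S",
                         calibrator) {
  conds <- unique(records$condition)
  if (!(calibrator %in% conds)) {
    stop("fold_changes(): calibrator condition '", calibrator,
         "' not present")
  }
  dcq_of <- function(cond) {
    a <- records[records$condition == cond & records$assay == assay, ]
    r <- records[records$condition == cond &
                   records$assay == reference_assay, ]
    if (nrow(r) == 0 || nrow(a) == 0) {
      return(list(dcq = NA_real_, reps = NA_real_))
    }
    reps <- NULL
    if (nrow(a) == nrow(r)) {
      aa <- a$cq[order(a$replicate)]
      rr <- r$cq[order(r$replicate)]
      reps <- aa - rr
    }
    list(dcq = mean(a$cq) - mean(r$cq), reps = reps)
  }
  cal <- dcq_of(calibrator)
  if (is.na(cal$dcq)) {
    stop("fold_changes(): reference assay missing in calibrator condition")
  }
  rows <- lapply(conds, function(cond) {
    d <- dcq_of(cond)
    if (is.na(d$dcq)) {
      return(data.frame(assay = assay, condition = cond, dcq = NA_real_,
                        fold = NA_real_, sd_dcq = NA_real_,
                        sd_fold = NA_real_, stringsAsFactors = FALSE))
    }
    ddcq <- d$dcq - cal$dcq
    fold <- if (cond == calibrator) 1.0 else 2^(-ddcq)
    sd_dcq <- if (!is.null(d$reps) && length(d$reps) > 1) sd(d$reps)
              else NA_real_
    sd_fold <- if (!is.null(d$reps) && length(d$reps) > 1) {
      sd(2^(-(d$reps - cal$dcq)))
    } else NA_real_
    data.frame(assay = assay, condition = cond, dcq = d$dcq, fold = fold,
               sd_dcq = sd_dcq, sd_fold = sd_fold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold-change profiles for every assay in a Cq table
#'
#' @param records Cq data.frame.
#' @param reference_assay endogenous reference assay.
#' @param calibrator calibrator condition.
#' @return data.frame of stacked [fold_changes()] profiles (reference
#'   assay excluded).
#' @export
fold_change_profiles <- function(records, reference_assay = "5.8S",
                                 calibrator) {
  assays <- setdiff(unique(records$assay), reference_assay)
  do.call(rbind, lapply(assays, function(a) {
    fold_changes(records, a, reference_assay = reference_assay,
                 calibrator = calibrator)
  }))
}

#' Call a stress-responsive assay from a fold-change time course
#'
#' Responsive iff the maximum pairwise ratio of fold changes across time
#' points exceeds `threshold` (default 2; "more than two-fold change
#' between at least two time points"). `mode = "baseline"` restricts the
#' comparison to ratios against the first time point.
#'
#' @param profile data.frame with `condition` (time point) and `fold` for
#'   one assay, in time order; needs >= 2 time points.
#' @param assay assay label carried into the output.
#' @param threshold fold-ratio threshold (exclusive).
#' @param mode "pairwise" (default) or "baseline".
#' @return one-row data.frame: `assay`, `responsive`, `max_ratio`.
#' @export
call_stress_responsive <- function(profile, assay = profile$assay[1],
                                   threshold = 2,
                                   mode = c("pairwise", "baseline")) {
  mode <- match.arg(mode)
  f <- profile$fold
  if (length(f) < 2) {
    stop("call_stress_responsive(): need at least two time points")
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("invalid profile: fold changes must be positive")
  }
  ratios <- if (mode == "pairwise") {
    outer(f, f, "/")
  } else {
    f / f[1]
  }
  mr <- max(ratios)
  data.frame(assay = assay, responsive = mr > threshold, max_ratio = mr,
             stringsAsFactors = FALSE)
}

#' Assays responsive to two or more stressors
#'
#' @param calls_by_stressor named list (stressor -> data.frame of
#'   [call_stress_responsive()] rows), at least two stressors.
#' @return character vector of assays responsive under >= 2 stressors.
#' @export
crosstalk <- function(calls_by_stressor) {
  if (length(calls_by_stressor) < 2) {
    stop("crosstalk(): at least two stressors are required")
  }
  resp <- lapply(calls_by_stressor, function(d) d$assay[d$responsive])
  all_assays <- unique(unlist(resp))
  hits <- vapply(all_assays, function(a) {
    sum(vapply(resp, function(r) a %in% r, logical(1)))
  }, integer(1))
  sort(names(hits)[hits >= 2])
}
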