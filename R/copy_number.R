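# Founder/progressor copy-number calls from segmented log R ratios (LRR)
# over predefined recurrent arm-level and focal regions.

#' Average segmented LRR over predefined chromosomal regions
#'
#' Per sample, segment LRRs are first centered by subtracting the sample
#' median (over segments); per region, the mean LRR is the overlap-length
#' weighted mean of the centered segment values.  Regions with no
#' overlapping segment in a sample get `NA` with a warning and are
#' excluded from downstream calls.
#'
#' @param segments data frame with columns `sample`, `chrom`, `start`,
#'   `end` (1-based inclusive), `lrr`.
#' @param regions data frame with columns `region_id`, `chrom`, `start`,
#'   `end`, `scale` (`"arm"` or `"focal"`), and optionally `arm_id`
#'   (containing arm region of a focal region).
#' @return An object of class `region_lrr`: list with `lrr` (regions x
#'   samples matrix) and `regions`.
#' @export
region_mean_lrr <- function(segments, regions) {
  need_s <- c("sample", "chrom", "start", "end", "lrr")
  need_r <- c("region_id", "chrom", "start", "end", "scale")
  if (length(miss <- setdiff(need_s, names(segments)))) {
    stop("segments: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(miss <- setdiff(need_r, names(regions)))) {
    stop("regions: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(segments$lrr)) stop("segments contain missing LRR", call. = FALSE)
  stopifnot(all(regions$scale %in% c("arm", "focal")))
  samples <- unique(segments$sample)
  m <- matrix(NA_real_, nrow(regions), length(samples),
              dimnames = list(regions$region_id, samples))
  for (sm in samples) {
    seg <- segments[segments$sample == sm, , drop = FALSE]
    seg$lrr <- seg$lrr - stats::median(seg$lrr)
    for (i in seq_len(nrow(regions))) {
      hit <- seg$chrom == regions$chrom[i] &
        seg$end >= regions$start[i] & seg$start <= regions$end[i]
      if (!any(hit)) next
      ov <- pmin(seg$end[hit], regions$end[i]) -
        pmax(seg$start[hit], regions$start[i]) + 1
      m[i, sm] <- sum(seg$lrr[hit] * ov) / sum(ov)
    }
  }
  if (anyNA(m)) {
    warning("some regions have no overlapping segment in some sample; ",
            "they are excluded from calls")
  }
  structure(list(lrr = m, regions = regions), class = "region_lrr")
}

#' Founder copy-number calls
#'
#' A region carries a founder alteration when all samples deviate in the
#' same direction with `|LRR| > t_low` and at least one sample has
#' `|LRR| > t_high`.  Requiring a shared sign makes the gain/loss
#' direction well defined.
#'
#' @param mat a `region_lrr` object.
#' @param t_high threshold at least one sample must exceed.
#' @param t_low threshold every sample must exceed.
#' @return Data frame of calls: `region_id`, `scale`, `category`
#'   (`"founder"`), `direction` (`"gain"`/`"loss"`), `statistic` (max
#'   `|LRR|`, signed).
#' @export
call_founder_cn <- function(mat, t_high = 0.12, t_low = 0.06) {
  stopifnot(inherits(mat, "region_lrr"))
  out <- list()
  for (i in seq_len(nrow(mat$lrr))) {
    v <- mat$lrr[i, ]
    if (anyNA(v)) next
    same_sign <- all(v > 0) || all(v < 0)
    if (!same_sign) next
    if (!(all(abs(v) > t_low) && any(abs(v) > t_high))) next
    stat <- v[which.max(abs(v))]
    out[[length(out) + 1L]] <- data.frame(
      region_id = rownames(mat$lrr)[i],
      scale = mat$regions$scale[i],
      category = "founder",
      direction = if (stat > 0) "gain" else "loss",
      statistic = unname(stat),
      bipartition = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty_cn_calls())
  do.call(rbind, out)
}

empty_cn_calls <- function() {
  data.frame(region_id = character(0), scale = character(0),
             category = character(0), direction = character(0),
             statistic = numeric(0), bipartition = character(0),
             stringsAsFactors = FALSE)
}

#' Progressor copy-number calls over tree bipartitions
#'
#' For every region not already called founder, the statistic dLRR is the
#' group-mean difference with the largest absolute value over the
#' tree-derived sample bipartitions; a region with `|dLRR| > t_delta` is
#' called a progressor alteration.  The altered side is taken to be the
#' group whose mean deviates more from the (median-centered) baseline, and
#' the direction is the sign of that group's mean.
#'
#' @param mat a `region_lrr` object.
#' @param bipartitions list of bipartitions from [branch_bipartitions()].
#' @param t_delta threshold on `|dLRR|`.
#' @param exclude region ids to skip (typically founder-called regions).
#' @return Data frame of calls as in [call_founder_cn()], with
#'   `bipartition` recording the supporting split (altered side first).
#' @export
call_progressor_cn <- function(mat, bipartitions, t_delta = 0.06,
                               exclude = character(0)) {
  stopifnot(inherits(mat, "region_lrr"), length(bipartitions) >= 1)
  samples <- colnames(mat$lrr)
  out <- list()
  for (i in seq_len(nrow(mat$lrr))) {
    rid <- rownames(mat$lrr)[i]
    if (rid %in% exclude) next
    v <- mat$lrr[i, ]
    if (anyNA(v)) next
    best <- NULL
    for (bp in bipartitions) {
      m1 <- mean(v[match(bp$side1, samples)])
      m2 <- mean(v[match(bp$side2, samples)])
      d <- abs(m1 - m2)
      if (is.null(best) || d > best$d) {
        alt <- if (abs(m1) >= abs(m2)) 1L else 2L
        best <- list(d = d, m_alt = if (alt == 1L) m1 else m2,
                     side_alt = if (alt == 1L) bp$side1 else bp$side2,
                     side_other = if (alt == 1L) bp$side2 else bp$side1)
      }
    }
    if (best$d <= t_delta) next
    out[[length(out) + 1L]] <- data.frame(
      region_id = rid,
      scale = mat$regions$scale[i],
      category = "progressor",
      direction = if (best$m_alt > 0) "gain" else "loss",
      statistic = best$m_alt - mean(v[match(best$side_other, samples)]),
      bipartition = paste(paste(best$side_alt, collapse = ","), "|",
                          paste(best$side_other, collapse = ",")),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty_cn_calls())
  do.call(rbind, out)
}

#' Discard focal calls shadowed by an arm-level call of the same category
#'
#' A focal call is removed when its containing arm-level region (via
#' `arm_id` in the region table) carries a call of the same category
#' (founder or progressor); focal calls whose containing arm carries a
#' call of the other category, or no call, are kept.
#'
#' @param calls data frame of calls (founder and/or progressor).
#' @param regions region table with `region_id`, `scale`, `arm_id`.
#' @return The filtered calls.
#' @export
resolve_focal_vs_arm <- function(calls, regions) {
  if (!nrow(calls)) return(calls)
  arm_of <- stats::setNames(
    if ("arm_id" %in% names(regions)) regions$arm_id else
      rep(NA_character_, nrow(regions)),
    regions$region_id)
  drop <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (calls$scale[i] != "focal") next
    arm <- arm_of[[calls$region_id[i]]]
    if (is.na(arm)) next
    drop[i] <- any(calls$region_id == arm &
                     calls$category == calls$category[i])
  }
  calls[!drop, , drop = FALSE]
}
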