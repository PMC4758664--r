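# Multiregional mutation profiles: rescue-and-filter construction,
# founder/shared/unique classification, clone color codes, and
# mutation-spectrum tabulation.

#' Build a multiregional mutation profile for one case
#'
#' Variants called in at least one sample are kept only if their position
#' has read depth at least `min_depth` in every sample of the case; a
#' variant is then considered present in a sample if its VAF is strictly
#' greater than `vaf_threshold` there.  This rescues variants missed by the
#' caller in individual samples while filtering positions that could hide
#' false negatives through low coverage.  Variants present nowhere after
#' filtering are dropped.
#'
#' @param vaf,depth aligned numeric matrices, variants x samples (shared
#'   row and column names).
#' @param min_depth minimum read depth required in every sample.
#' @param vaf_threshold presence threshold on the VAF (strict).
#' @param case_id optional case label.
#' @param variants optional data frame of per-variant annotation (e.g.
#'   `chrom`, `pos`, `ref`, `alt`, `context`), aligned with the rows of
#'   `vaf`; subset along with them.
#' @return An object of class `mr_profile`: list with `vaf`, `depth`,
#'   `presence` (logical matrix), `category` (factor
#'   founder/shared/unique), `variants`, `samples`, `case_id`.
#' @export
build_profile <- function(vaf, depth, min_depth = 10, vaf_threshold = 0.05,
                          case_id = NA_character_, variants = NULL) {
  stopifnot(is.matrix(vaf), is.matrix(depth))
  if (!identical(dim(vaf), dim(depth))) {
    stop("vaf and depth matrices must have identical dimensions",
         call. = FALSE)
  }
  if (anyNA(vaf) || anyNA(depth)) {
    stop("vaf/depth matrices contain missing entries", call. = FALSE)
  }
  if (!is.null(rownames(depth)) && !is.null(rownames(vaf)) &&
      !identical(rownames(vaf), rownames(depth))) {
    stop("vaf and depth matrices are not aligned on variant ids",
         call. = FALSE)
  }
  keep <- rowSums(depth >= min_depth) == ncol(depth)
  vaf <- vaf[keep, , drop = FALSE]
  depth <- depth[keep, , drop = FALSE]
  if (!is.null(variants)) variants <- variants[keep, , drop = FALSE]
  presence <- vaf > vaf_threshold
  keep2 <- rowSums(presence) > 0
  vaf <- vaf[keep2, , drop = FALSE]
  depth <- depth[keep2, , drop = FALSE]
  presence <- presence[keep2, , drop = FALSE]
  if (!is.null(variants)) variants <- variants[keep2, , drop = FALSE]
  prof <- list(vaf = vaf, depth = depth, presence = presence,
               variants = variants, samples = colnames(vaf),
               case_id = case_id)
  class(prof) <- "mr_profile"
  prof$category <- classify_mutations(prof)$category
  prof
}

#' @export
print.mr_profile <- function(x, ...) {
  counts <- table(x$category)
  cat(sprintf(
    "Multiregional mutation profile%s: %d variants x %d samples\n",
    if (is.na(x$case_id)) "" else paste0(" (", x$case_id, ")"),
    nrow(x$vaf), ncol(x$vaf)))
  cat(sprintf("  founder %d, shared %d, unique %d\n",
              counts[["founder"]], counts[["shared"]], counts[["unique"]]))
  invisible(x)
}

#' Classify variants as founder, shared, or unique
#'
#' A variant present in all samples of the case is a founder mutation;
#' progressor mutations are shared (present in more than one but not all
#' samples) or unique (present in exactly one sample).
#'
#' @param profile an `mr_profile`, or a logical/numeric presence matrix
#'   (nonzero = present).
#' @return List with `category` (factor, levels founder/shared/unique,
#'   one per variant; rows present nowhere, as can occur in raw simulated
#'   profiles, are `NA`) and `counts`.
#' @export
classify_mutations <- function(profile) {
  pres <- if (inherits(profile, "mr_profile")) profile$presence else
    profile > 0
  stopifnot(is.matrix(pres))
  n <- rowSums(pres)
  category <- factor(
    ifelse(n == 0, NA,
           ifelse(n == ncol(pres), "founder",
                  ifelse(n == 1, "unique", "shared"))),
    levels = c("founder", "shared", "unique")
  )
  names(category) <- rownames(pres)
  list(category = category, counts = table(category))
}

#' PCA color codes for samples (or cells)
#'
#' Projects each column's variant profile onto the first three principal
#' axes and min-max scales each component across columns to 0..255,
#' yielding an RGB triple per column; color similarity then reflects
#' profile similarity.  With fewer than three informative components the
#' missing channels are neutral (128), and a zero-variance profile maps
#' every column to the same neutral gray.
#'
#' @param x an `mr_profile`, or a numeric matrix (variants/genes x
#'   samples/cells).
#' @return Data frame with columns `sample`, `r`, `g`, `b`, `hex`.
#' @export
color_code_samples <- function(x) {
  m <- if (inherits(x, "mr_profile")) x$vaf else x
  stopifnot(is.matrix(m))
  sm <- t(m)  # observations = samples
  ids <- rownames(sm)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(sm)))
  keep <- apply(sm, 2, function(v) stats::var(v) > 0)
  rgb01 <- matrix(128, nrow(sm), 3)
  if (any(keep)) {
    pc <- stats::prcomp(sm[, keep, drop = FALSE], center = TRUE,
                        scale. = FALSE)
    ncomp <- min(3L, ncol(pc$x))
    for (i in seq_len(ncomp)) {
      v <- pc$x[, i]
      rng <- range(v)
      rgb01[, i] <- if (diff(rng) == 0) 128 else
        round(255 * (v - rng[1]) / diff(rng))
    }
  }
  data.frame(
    sample = ids,
    r = rgb01[, 1], g = rgb01[, 2], b = rgb01[, 3],
    hex = grDevices::rgb(rgb01[, 1], rgb01[, 2], rgb01[, 3],
                         maxColorValue = 255),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Mutation spectrum over substitution classes and trinucleotide channels
#'
#' Substitutions are collapsed to the pyrimidine strand (C>A, C>G, C>T,
#' T>A, T>C, T>G).  In the class tabulation the C>* classes are split by
#' whether the mutated cytosine sits in a CpG dinucleotide (3' neighbor
#' G), the signature of spontaneous 5-methyl-cytosine deamination.  With
#' trinucleotide context available, proportions over the standard 96
#' channels (6 classes x 16 flanking-base combinations) are also returned.
#'
#' @param variants data frame with columns `ref`, `alt` (single bases) and
#'   optionally `context` (trinucleotide centered on the mutated base).
#' @return List with `classes` (named proportion vector; C>* classes split
#'   into CpG / non-CpG) and `channels96` (named proportion vector, `NULL`
#'   when no context is available); each sums to 1.  Variants with
#'   ambiguous bases are skipped with a warning.
#' @export
mutation_spectrum <- function(variants) {
  stopifnot(all(c("ref", "alt") %in% names(variants)))
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  ctx <- if ("context" %in% names(variants)) toupper(variants$context) else
    rep(NA_character_, length(ref))
  ok <- ref %in% names(.COMPLEMENT) & alt %in% names(.COMPLEMENT) & ref != alt
  has_ctx <- !is.na(ctx) & nchar(ctx) == 3L &
    !is.na(ok) & vapply(strsplit(ifelse(is.na(ctx), "NNN", ctx), ""),
                        function(b) all(b %in% names(.COMPLEMENT)),
                        logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " variant(s) with ambiguous or invalid bases skipped")
    ref <- ref[ok]; alt <- alt[ok]; ctx <- ctx[ok]; has_ctx <- has_ctx[ok]
  }
  if (!length(ref)) stop("no valid substitutions to tabulate", call. = FALSE)
  # collapse purine-reference substitutions to the pyrimidine strand
  flip <- ref %in% c("A", "G")
  ref[flip] <- .COMPLEMENT[ref[flip]]
  alt[flip] <- .COMPLEMENT[alt[flip]]
  revcomp <- function(s) {
    vapply(strsplit(s, ""), function(b)
      paste(rev(.COMPLEMENT[b]), collapse = ""), character(1))
  }
  ctx[flip & has_ctx] <- revcomp(ctx[flip & has_ctx])
  cls <- paste0(ref, ">", alt)
  three_prime <- ifelse(has_ctx, substr(ctx, 3, 3), NA_character_)
  cpg <- ref == "C" & !is.na(three_prime) & three_prime == "G"
  cls_split <- ifelse(cpg, paste0(cls, " at CpG"), cls)
  class_levels <- c("C>A", "C>A at CpG", "C>G", "C>G at CpG",
                    "C>T", "C>T at CpG", "T>A", "T>C", "T>G")
  classes <- table(factor(cls_split, levels = class_levels))
  classes <- classes / sum(classes)
  channels96 <- NULL
  if (all(has_ctx)) {
    bases <- c("A", "C", "G", "T")
    lv <- as.vector(t(outer(
      c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
      as.vector(outer(bases, bases, function(a, b) paste0(a, ".", b))),
      function(cl, fl) {
        paste0(substr(fl, 1, 1), "[", cl, "]", substr(fl, 3, 3))
      })))
    ch <- paste0(substr(ctx, 1, 1), "[", cls, "]", substr(ctx, 3, 3))
    channels96 <- table(factor(ch, levels = sort(lv)))
    channels96 <- channels96 / sum(channels96)
  }
  list(classes = c(unclass(classes)),
       channels96 = if (is.null(channels96)) NULL else c(unclass(channels96)))
}
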