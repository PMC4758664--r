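# Synthetic multiregional fixtures with planted tree structure.
#
# The generators produce mutation, copy-number and methylation data whose
# founder/shared/unique (or founder/progressor) structure is consistent
# with a planted sample tree, together with the planted truth, so every
# analysis operator can be exercised and validated without external data.

#' Specification of a synthetic multiregional fixture
#'
#' @param n_samples samples per case.
#' @param clades planted internal clades (list of integer vectors over
#'   `1:n_samples`, laminar); `NULL` plants a caterpillar topology.
#' @param n_founder,n_shared,n_unique variant counts per category; shared
#'   variants are spread over the planted clades, unique ones over leaves.
#' @param vaf_mean mean VAF of a present variant.
#' @param vaf_noise standard deviation of the truncated-Gaussian VAF noise
#'   (0 = noise-free).
#' @param mean_depth mean sequencing depth (Poisson, floored at 10).
#' @param cn_noise Gaussian noise of segment LRR values.
#' @param cn_events planted copy-number events: data frame with
#'   `region_id`, `where` (`"founder"`, `"clade:<i>"`, or
#'   `"sample:<j>"`), `lrr` (signed magnitude); `NULL` plants a default
#'   trio (founder arm gain, clade arm loss, leaf focal amplification).
#' @param n_cases,samples_per_case methylation fixture layout.
#' @param n_probes methylation probes.
#' @param n_meth_founder_hyper,n_meth_founder_hypo,n_meth_progressor
#'   planted methylation event counts (all planted in case 1; progressor
#'   events sit on the first planted clade).
#' @param meth_effect planted delta-beta magnitude.
#' @param beta_noise per-sample Gaussian noise on beta values.
#' @param seed integer seed; every generator is deterministic given the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 5L, clades = NULL,
                         n_founder = 30L, n_shared = 20L, n_unique = 10L,
                         vaf_mean = 0.3, vaf_noise = 0.05,
                         mean_depth = 100, cn_noise = 0.01,
                         cn_events = NULL,
                         n_cases = 4L, samples_per_case = 8L,
                         n_probes = 500L,
                         n_meth_founder_hyper = 20L,
                         n_meth_founder_hypo = 10L,
                         n_meth_progressor = 20L,
                         meth_effect = 0.4, beta_noise = 0.02,
                         seed = 1L) {
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 2L, n_founder >= 0, n_shared >= 0, n_unique >= 0,
            vaf_noise >= 0, vaf_mean > 0, vaf_mean <= 1, meth_effect >= 0,
            meth_effect <= 1, beta_noise >= 0, cn_noise >= 0)
  if (is.null(clades)) {
    # caterpillar: {n-1, n}, {n-2, n-1, n}, ... (only clades of size >= 2)
    clades <- lapply(rev(seq_len(n_samples - 2L) + 1L), function(k)
      seq.int(n_samples - k + 1L, n_samples))
    if (n_samples == 2L) clades <- list()
  }
  structure(list(
    n_samples = n_samples, clades = clades,
    n_founder = as.integer(n_founder), n_shared = as.integer(n_shared),
    n_unique = as.integer(n_unique),
    vaf_mean = vaf_mean, vaf_noise = vaf_noise, mean_depth = mean_depth,
    cn_noise = cn_noise, cn_events = cn_events,
    n_cases = as.integer(n_cases),
    samples_per_case = as.integer(samples_per_case),
    n_probes = as.integer(n_probes),
    n_meth_founder_hyper = as.integer(n_meth_founder_hyper),
    n_meth_founder_hypo = as.integer(n_meth_founder_hypo),
    n_meth_progressor = as.integer(n_meth_progressor),
    meth_effect = meth_effect, beta_noise = beta_noise,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

# truncated-Gaussian noise keeping VAFs inside [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(mean, n))
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

fixture_samples <- function(spec) sprintf("s%d", seq_len(spec$n_samples))

#' Generate a multiregional mutation profile with planted truth
#'
#' Founder variants are present in every sample, shared variants in the
#' samples of a planted clade, unique variants in a single sample; present
#' entries get VAF `vaf_mean` plus truncated-Gaussian noise, absent
#' entries 0.  Depths are Poisson around `mean_depth`, floored at 10 so no
#' variant is lost to the depth filter.
#'
#' @param spec a [fixture_spec()].
#' @return List with `vaf`, `depth` (matrices), `variants` (annotation
#'   with random ref/alt/trinucleotide context), `profile` (the
#'   [build_profile()] result), and `truth` (data frame `variant`,
#'   `category`, `clade`).
#' @export
gen_mutation_profile <- function(spec) {
  set.seed(spec$seed)
  ns <- spec$n_samples
  samples <- fixture_samples(spec)
  n_var <- spec$n_founder + spec$n_shared + spec$n_unique
  if (n_var == 0) stop("fixture with no variants", call. = FALSE)
  ids <- sprintf("v%04d", seq_len(n_var))
  vaf <- matrix(0, n_var, ns, dimnames = list(ids, samples))
  category <- character(n_var)
  clade <- character(n_var)
  row <- 0L
  for (i in seq_len(spec$n_founder)) {
    row <- row + 1L
    vaf[row, ] <- rnorm_trunc(ns, spec$vaf_mean, spec$vaf_noise,
                              lo = 0.06, hi = 1)
    category[row] <- "founder"; clade[row] <- "all"
  }
  if (spec$n_shared > 0 && !length(spec$clades)) {
    stop("shared variants require at least one planted clade",
         call. = FALSE)
  }
  for (i in seq_len(spec$n_shared)) {
    row <- row + 1L
    ci <- 1L + (i - 1L) %% length(spec$clades)
    members <- spec$clades[[ci]]
    vaf[row, members] <- rnorm_trunc(length(members), spec$vaf_mean,
                                     spec$vaf_noise, lo = 0.06, hi = 1)
    category[row] <- "shared"
    clade[row] <- paste(members, collapse = ",")
  }
  for (i in seq_len(spec$n_unique)) {
    row <- row + 1L
    s <- 1L + (i - 1L) %% ns
    vaf[row, s] <- rnorm_trunc(1, spec$vaf_mean, spec$vaf_noise,
                               lo = 0.06, hi = 1)
    category[row] <- "unique"; clade[row] <- as.character(s)
  }
  depth <- matrix(pmax(10, stats::rpois(n_var * ns, spec$mean_depth)),
                  n_var, ns, dimnames = list(ids, samples))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  variants <- data.frame(
    variant = ids,
    chrom = sample(paste0("chr", 1:5), n_var, replace = TRUE),
    pos = sample.int(1e6, n_var),
    ref = ref, alt = unname(alt),
    context = paste0(sample(bases, n_var, TRUE), ref,
                     sample(bases, n_var, TRUE)),
    stringsAsFactors = FALSE
  )
  rownames(variants) <- ids
  profile <- build_profile(vaf, depth, case_id = "fixture",
                           variants = variants)
  list(vaf = vaf, depth = depth, variants = variants, profile = profile,
       truth = data.frame(variant = ids, category = category,
                          clade = clade, stringsAsFactors = FALSE))
}

default_cn_regions <- function() {
  data.frame(
    region_id = c("1p", "1q", "7p", "8q", "20q", "FOC7p", "FOC8q"),
    chrom = c("chr1", "chr1", "chr7", "chr8", "chr20", "chr7", "chr8"),
    start = c(1, 1.3e6, 1, 1, 1, 4e5, 2e5),
    end = c(1.2e6, 2.4e6, 1e6, 1e6, 6e5, 5e5, 3e5),
    scale = c(rep("arm", 5), "focal", "focal"),
    arm_id = c(NA, NA, NA, NA, NA, "7p", "8q"),
    stringsAsFactors = FALSE
  )
}

#' Generate a segmented copy-number fixture with planted truth
#'
#' Each sample gets one segment per region plus neutral filler segments
#' (so the per-sample median is near 0); planted events add their signed
#' LRR to the samples of their branch.  Default events: a founder gain on
#' arm `1q`, a progressor loss on arm `7p` carried by the first planted
#' clade, and a focal progressor amplification of `FOC8q` on sample 1.
#'
#' @param spec a [fixture_spec()].
#' @return List with `segments`, `regions`, `events` (the planted
#'   events), and `truth` (expected calls: `region_id`, `category`,
#'   `direction`).
#' @export
gen_cn_profile <- function(spec) {
  set.seed(spec$seed + 1L)
  samples <- fixture_samples(spec)
  regions <- default_cn_regions()
  events <- spec$cn_events
  if (is.null(events)) {
    events <- data.frame(
      region_id = c("1q", "7p", "FOC8q"),
      where = c("founder", "clade:1", "sample:1"),
      lrr = c(0.3, -0.3, 0.4),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(events$region_id %in% regions$region_id))
  event_samples <- function(where) {
    if (where == "founder") return(seq_along(samples))
    if (grepl("^clade:", where)) {
      return(spec$clades[[as.integer(sub("clade:", "", where))]])
    }
    as.integer(sub("sample:", "", where))
  }
  segs <- list()
  for (si in seq_along(samples)) {
    # region-covering segments
    lrr <- stats::rnorm(nrow(regions), 0, spec$cn_noise)
    for (e in seq_len(nrow(events))) {
      if (si %in% event_samples(events$where[e])) {
        i <- match(events$region_id[e], regions$region_id)
        lrr[i] <- lrr[i] + events$lrr[e]
        # a focal event also shifts the overlapped part of its arm;
        # the toy focal regions are small against their arm, so the
        # arm mean stays essentially unchanged and is not adjusted
      }
    }
    segs[[length(segs) + 1L]] <- data.frame(
      sample = samples[si], chrom = regions$chrom,
      start = regions$start, end = regions$end, lrr = lrr,
      stringsAsFactors = FALSE
    )
    # neutral filler segments keep the per-sample median at baseline
    segs[[length(segs) + 1L]] <- data.frame(
      sample = samples[si],
      chrom = rep(paste0("chr", 10:15), each = 2),
      start = rep(c(1, 1.1e6), 6),
      end = rep(c(1e6, 2e6), 6),
      lrr = stats::rnorm(12, 0, spec$cn_noise),
      stringsAsFactors = FALSE
    )
  }
  truth <- data.frame(
    region_id = events$region_id,
    category = ifelse(events$where == "founder", "founder", "progressor"),
    direction = ifelse(events$lrr > 0, "gain", "loss"),
    where = events$where,
    stringsAsFactors = FALSE
  )
  list(segments = do.call(rbind, segs), regions = regions,
       events = events, truth = truth)
}

#' Generate a methylation beta-value fixture with planted truth
#'
#' Cases get probe-wise baseline shifts (larger for `island` probes, so
#' intertumor variance concentrates there); case 1 carries the planted
#' founder hyper/hypomethylation (all samples) and progressor events (the
#' samples of the first planted clade).  Beta values are clipped to
#' `[0, 1]`.
#'
#' @param spec a [fixture_spec()].
#' @return List with `beta` (probes x all samples), `normal_beta`,
#'   `delta_case1`, `cases` (per-sample case labels), `probe_categories`,
#'   and `truth` (lists of planted probe ids).
#' @export
gen_beta_profile <- function(spec) {
  set.seed(spec$seed + 2L)
  np <- spec$n_probes
  n_planted <- spec$n_meth_founder_hyper + spec$n_meth_founder_hypo +
    spec$n_meth_progressor
  stopifnot(n_planted <= np)
  probes <- sprintf("cg%05d", seq_len(np))
  categories <- sample(c("island", "shore", "open_sea"), np, replace = TRUE,
                       prob = c(0.3, 0.3, 0.4))
  hyper_idx <- seq_len(spec$n_meth_founder_hyper)
  hypo_idx <- seq_len(spec$n_meth_founder_hypo) + spec$n_meth_founder_hyper
  prog_idx <- seq_len(spec$n_meth_progressor) +
    spec$n_meth_founder_hyper + spec$n_meth_founder_hypo
  normal_beta <- stats::runif(np, 0.2, 0.8)
  normal_beta[hyper_idx] <- stats::runif(length(hyper_idx), 0.15, 0.4)
  normal_beta[hypo_idx] <- stats::runif(length(hypo_idx), 0.6, 0.85)
  normal_beta[prog_idx] <- stats::runif(length(prog_idx), 0.2, 0.4)

  cases <- rep(sprintf("case%d", seq_len(spec$n_cases)),
               each = spec$samples_per_case)
  sample_ids <- paste0(cases, "_s", rep(seq_len(spec$samples_per_case),
                                        spec$n_cases))
  beta <- matrix(0, np, length(sample_ids),
                 dimnames = list(probes, sample_ids))
  clade1 <- if (length(spec$clades)) spec$clades[[1]] else 1L
  clade1 <- clade1[clade1 <= spec$samples_per_case]
  for (ci in seq_len(spec$n_cases)) {
    # case-level baselines plant intertumor variance (largest for island
    # probes) but stay below the founder threshold, so the planted truth
    # is the only founder signal
    case_shift <- ifelse(categories == "island",
                         pmin(0.25, pmax(-0.25, stats::rnorm(np, 0, 0.15))),
                         stats::rnorm(np, 0, 0.02))
    cols <- which(cases == sprintf("case%d", ci))
    for (j in seq_along(cols)) {
      b <- normal_beta + case_shift + stats::rnorm(np, 0, spec$beta_noise)
      if (ci == 1L) {
        b[hyper_idx] <- normal_beta[hyper_idx] + spec$meth_effect +
          stats::rnorm(length(hyper_idx), 0, spec$beta_noise)
        b[hypo_idx] <- normal_beta[hypo_idx] - spec$meth_effect +
          stats::rnorm(length(hypo_idx), 0, spec$beta_noise)
        # progressor probes sit on a flat baseline; only clade samples
        # carry the planted branch effect
        b[prog_idx] <- normal_beta[prog_idx] +
          (if (j %in% clade1) spec$meth_effect else 0) +
          stats::rnorm(length(prog_idx), 0, spec$beta_noise)
      }
      beta[, cols[j]] <- pmin(1, pmax(0, b))
    }
  }
  delta_case1 <- beta[, cases == "case1", drop = FALSE] - normal_beta
  colnames(delta_case1) <- sub("case1_", "", colnames(delta_case1))
  list(
    beta = beta, normal_beta = stats::setNames(normal_beta, probes),
    delta_case1 = delta_case1, cases = cases,
    probe_categories = stats::setNames(categories, probes),
    truth = list(
      founder_hyper = probes[hyper_idx],
      founder_hypo = probes[hypo_idx],
      progressor = probes[prog_idx],
      progressor_clade = clade1
    )
  )
}
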