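# Founder/progressor methylation calls from delta-beta values, variance
# decomposition of beta values into inter- and intratumor components, and
# probe-category enrichment among top-variance probes.

#' Founder methylation calls for one case
#'
#' A probe is subject to founder hypermethylation when its delta-beta
#' (tumor beta minus matched-normal beta) exceeds `t` in every sample of
#' the case, and to founder hypomethylation when delta-beta is below `-t`
#' in every sample.
#'
#' @param delta numeric matrix, probes x samples of one case, values in
#'   `[-1, 1]`.
#' @param t threshold on delta-beta (strict).
#' @return Data frame: `probe`, `direction` (`"hyper"`/`"hypo"`),
#'   `statistic` (the delta-beta of smallest magnitude across samples).
#' @export
call_founder_methylation <- function(delta, t = 0.3) {
  stopifnot(is.matrix(delta), ncol(delta) >= 1)
  hyper <- rowSums(delta > t) == ncol(delta)
  hypo <- rowSums(delta < -t) == ncol(delta)
  probes <- rownames(delta)
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(delta)))
  stat <- numeric(0); dir <- character(0); ids <- character(0)
  if (any(hyper)) {
    ids <- c(ids, probes[hyper]); dir <- c(dir, rep("hyper", sum(hyper)))
    stat <- c(stat, apply(delta[hyper, , drop = FALSE], 1, min))
  }
  if (any(hypo)) {
    ids <- c(ids, probes[hypo]); dir <- c(dir, rep("hypo", sum(hypo)))
    stat <- c(stat, apply(delta[hypo, , drop = FALSE], 1, max))
  }
  data.frame(probe = ids, direction = dir, statistic = unname(stat),
             stringsAsFactors = FALSE)
}

# max-|difference| of group-mean delta-beta over bipartitions, per probe
dprime_beta <- function(delta, groups1, groups2) {
  best <- rep(0, nrow(delta))
  for (i in seq_along(groups1)) {
    d <- rowMeans(delta[, groups1[[i]], drop = FALSE]) -
      rowMeans(delta[, groups2[[i]], drop = FALSE])
    take <- abs(d) > abs(best)
    best[take] <- d[take]
  }
  best
}

#' Progressor methylation calls with permutation-based FDR control
#'
#' Per probe, the statistic delta-prime-beta is the group-mean delta-beta
#' difference of largest magnitude over the tree-derived sample
#' bipartitions.  The threshold `theta` is chosen as the smallest value on
#' `theta_grid` at which the permutation FDR - the mean number of probes
#' exceeding `theta` after permuting sample labels, divided by the
#' observed number - is at most `fdr_target`.  Called probes are split
#' into hyper- and hypomethylation by the sign of their mean delta-beta
#' across samples.
#'
#' @param delta numeric matrix, probes x samples of one case.
#' @param bipartitions list of bipartitions (see [branch_bipartitions()])
#'   over the column names of `delta`.
#' @param fdr_target target false discovery rate.
#' @param n_perm number of sample-label permutations.
#' @param theta_grid candidate thresholds.
#' @return List with `calls` (data frame `probe`, `direction`,
#'   `statistic`), `theta` (chosen threshold, `NA` when no threshold meets
#'   the target), and `fdr` (data frame of the FDR estimate per grid
#'   value).
#' @export
call_progressor_methylation <- function(delta, bipartitions,
                                        fdr_target = 0.1, n_perm = 100L,
                                        theta_grid = seq(0.05, 0.6,
                                                         by = 0.01)) {
  stopifnot(is.matrix(delta), length(bipartitions) >= 1)
  samples <- colnames(delta)
  if (is.null(samples)) {
    samples <- sprintf("s%d", seq_len(ncol(delta)))
    colnames(delta) <- samples
  }
  g1 <- lapply(bipartitions, function(b) match(b$side1, samples))
  g2 <- lapply(bipartitions, function(b) match(b$side2, samples))
  if (anyNA(unlist(c(g1, g2)))) {
    stop("bipartition samples not found among the columns of delta",
         call. = FALSE)
  }
  obs <- dprime_beta(delta, g1, g2)
  obs_counts <- vapply(theta_grid, function(th) sum(abs(obs) > th),
                       numeric(1))
  perm_counts <- matrix(0, n_perm, length(theta_grid))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(ncol(delta))
    dp <- dprime_beta(delta[, perm, drop = FALSE], g1, g2)
    perm_counts[b, ] <- vapply(theta_grid, function(th)
      sum(abs(dp) > th), numeric(1))
  }
  fdr <- colMeans(perm_counts) / obs_counts
  fdr[obs_counts == 0] <- NA_real_
  ok <- which(!is.na(fdr) & fdr <= fdr_target)
  probes <- rownames(delta)
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(delta)))
  fdr_tab <- data.frame(theta = theta_grid, observed = obs_counts,
                        expected_null = colMeans(perm_counts), fdr = fdr)
  if (!length(ok)) {
    message("no threshold reaches the FDR target; no progressor ",
            "methylation called")
    return(list(calls = data.frame(probe = character(0),
                                   direction = character(0),
                                   statistic = numeric(0),
                                   stringsAsFactors = FALSE),
                theta = NA_real_, fdr = fdr_tab))
  }
  theta <- theta_grid[ok[1]]
  called <- which(abs(obs) > theta)
  mean_delta <- rowMeans(delta)[called]
  list(
    calls = data.frame(
      probe = probes[called],
      direction = ifelse(mean_delta > 0, "hyper", "hypo"),
      statistic = obs[called],
      stringsAsFactors = FALSE
    ),
    theta = theta,
    fdr = fdr_tab
  )
}

#' Decompose per-probe beta variance into inter- and intratumor components
#'
#' For each probe, the total sum of squares over all samples is
#' partitioned as in one-way ANOVA into the within-case component
#' (`ss_within`, intratumor heterogeneity) and the between-case component
#' (`ss_between`, intertumor heterogeneity), with
#' `ss_total = ss_within + ss_between`.
#'
#' @param beta numeric matrix, probes x samples.
#' @param cases factor/character vector of case labels, one per column.
#' @return Data frame: `probe`, `ss_total`, `ss_within`, `ss_between`.
#' @export
variance_decomposition <- function(beta, cases) {
  stopifnot(is.matrix(beta), length(cases) == ncol(beta))
  cases <- as.factor(cases)
  if (nlevels(cases) < 2) {
    stop("at least 2 cases are needed for a variance decomposition",
         call. = FALSE)
  }
  grand <- rowMeans(beta)
  ss_total <- rowSums((beta - grand)^2)
  ss_within <- rep(0, nrow(beta))
  ss_between <- rep(0, nrow(beta))
  for (lv in levels(cases)) {
    cols <- which(cases == lv)
    gm <- rowMeans(beta[, cols, drop = FALSE])
    ss_within <- ss_within +
      rowSums((beta[, cols, drop = FALSE] - gm)^2)
    ss_between <- ss_between + length(cols) * (gm - grand)^2
  }
  probes <- rownames(beta)
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(beta)))
  data.frame(probe = probes, ss_total = unname(ss_total),
             ss_within = unname(ss_within),
             ss_between = unname(ss_between), stringsAsFactors = FALSE)
}

#' Probe-category enrichment among top-variance probes
#'
#' Probes are ranked by decreasing variance component; for each requested
#' cutoff, the enrichment of a category is its fraction among the top
#' `top_n` probes divided by its overall fraction.
#'
#' @param variances numeric vector, one variance per probe.
#' @param categories character/factor vector of probe categories, aligned
#'   with `variances`.
#' @param top_ns integer vector of top-list sizes.
#' @return Data frame: `top_n`, `category`, `enrichment`.
#' @export
variance_enrichment <- function(variances, categories, top_ns) {
  stopifnot(length(variances) == length(categories))
  if (any(top_ns > length(variances)) || any(top_ns < 1)) {
    stop("top_ns must lie between 1 and the number of probes",
         call. = FALSE)
  }
  categories <- as.character(categories)
  overall <- table(categories) / length(categories)
  ord <- order(-variances)
  out <- list()
  for (n in top_ns) {
    top <- categories[ord[seq_len(n)]]
    for (cat in names(overall)) {
      out[[length(out) + 1L]] <- data.frame(
        top_n = n, category = cat,
        enrichment = (sum(top == cat) / n) / as.numeric(overall[[cat]]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
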