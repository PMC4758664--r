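# Cancer-cell-fraction (CCF) posterior from read counts, tumor purity, and
# allele-specific copy number.

#' Prior over mutation multiplicity from allele-specific copy numbers
#'
#' A mutation at a locus with allele-specific copy numbers `q_a` and `q_b`
#' can be present in 1..`q_a` copies of allele a or 1..`q_b` copies of
#' allele b; every such configuration is assumed equally probable, and the
#' probabilities are aggregated over distinct multiplicities `p`.
#'
#' @param cn_a,cn_b non-negative integer allele-specific copy numbers;
#'   `cn_a + cn_b` must be at least 1.
#' @return Named numeric vector: `P(p)` over the distinct multiplicities,
#'   names are the values of `p`.
#' @examples
#' multiplicity_prior(1, 1)  # P(p = 1) = 1
#' multiplicity_prior(1, 2)  # P(p = 1) = 2/3, P(p = 2) = 1/3
#' @export
multiplicity_prior <- function(cn_a, cn_b) {
  cn_a <- as.integer(cn_a); cn_b <- as.integer(cn_b)
  stopifnot(cn_a >= 0L, cn_b >= 0L)
  if (cn_a + cn_b < 1L) {
    stop("at least one allele must have positive copy number", call. = FALSE)
  }
  configs <- c(seq_len(cn_a), seq_len(cn_b))
  tab <- table(configs) / length(configs)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Expected variant allele fraction of a mutation
#'
#' For a mutation present in `p` copies in a fraction `c` of cancer cells,
#' in a sample of purity `alpha` and locus copy numbers `q_a`, `q_b`, the
#' expected allele fraction is
#' `alpha * c * p / (2 * (1 - alpha) + alpha * (q_a + q_b))` (normal cells
#' contribute two reference copies), clipped to `[0, 1]`.
#'
#' @param c cancer-cell fraction in `[0, 1]`.
#' @param p mutation multiplicity (positive integer).
#' @param purity tumor purity `alpha` in `(0, 1]`.
#' @param cn_a,cn_b allele-specific copy numbers.
#' @return Expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(c, p, purity, cn_a, cn_b) {
  f <- purity * c * p / (2 * (1 - purity) + purity * (cn_a + cn_b))
  pmin(1, pmax(0, f))
}

#' Posterior over the cancer-cell fraction of a mutation
#'
#' Over a regular grid of 100 `c` values in `[0.01, 1]`, computes
#' `P(c | n, m, alpha, q_a, q_b)` proportional to
#' `sum_p Binom(m | n, f(c, p, ...)) P(p | q_a, q_b)` with a uniform prior
#' on `c`, normalized over the grid.  The CCF is the posterior median,
#' defined as the smallest grid value whose cumulative mass reaches 0.5;
#' a mutation is flagged clonal when its CCF exceeds 0.8.
#'
#' @param alt_reads number of variant-supporting reads (`m`).
#' @param total_depth total read depth (`n`, positive).
#' @param purity tumor purity `alpha` in `(0, 1]`.
#' @param cn_a,cn_b allele-specific copy numbers.
#' @return Object of class `ccf_posterior`: list with `grid`, `probs`
#'   (normalized), `ccf`, `clonal`, and `multiplicity_prior`.
#' @examples
#' post <- ccf_posterior(50, 100, purity = 1, cn_a = 1, cn_b = 1)
#' post$ccf
#' @export
ccf_posterior <- function(alt_reads, total_depth, purity, cn_a, cn_b) {
  stopifnot(total_depth > 0, alt_reads >= 0, alt_reads <= total_depth,
            purity > 0, purity <= 1)
  prior <- multiplicity_prior(cn_a, cn_b)
  grid <- seq(0.01, 1, length.out = 100)
  lik <- rep(0, length(grid))
  for (i in seq_along(prior)) {
    p <- as.integer(names(prior)[i])
    f <- expected_vaf(grid, p, purity, cn_a, cn_b)
    lik <- lik + prior[i] * stats::dbinom(alt_reads, total_depth, f)
  }
  if (sum(lik) == 0) {
    stop("zero posterior mass over the whole grid (numerically degenerate ",
         "input)", call. = FALSE)
  }
  probs <- lik / sum(lik)
  ccf <- grid[which(cumsum(probs) >= 0.5)[1]]
  structure(list(grid = grid, probs = unname(probs), ccf = ccf,
                 clonal = ccf > 0.8, multiplicity_prior = prior),
            class = "ccf_posterior")
}

#' @export
print.ccf_posterior <- function(x, ...) {
  cat(sprintf("CCF posterior: median %.2f (%s)\n", x$ccf,
              if (x$clonal) "clonal" else "subclonal"))
  invisible(x)
}

#' Clonality call from a CCF posterior
#'
#' Mutations are only evaluated in samples with purity strictly above 0.6;
#' an evaluated mutation is clonal when its CCF strictly exceeds 0.8 and
#' subclonal otherwise.
#'
#' @param posterior a `ccf_posterior`.
#' @param purity tumor purity of the sample.
#' @param purity_min purity threshold below or at which no call is made.
#' @param ccf_min CCF threshold for a clonal call (strict).
#' @return One of `"clonal"`, `"subclonal"`, `"not_evaluated"`.
#' @export
classify_clonality <- function(posterior, purity, purity_min = 0.6,
                               ccf_min = 0.8) {
  if (purity <= purity_min) return("not_evaluated")
  if (posterior$ccf > ccf_min) "clonal" else "subclonal"
}

#' CCF and clonality for a table of mutations
#'
#' @param table data frame with columns `alt_reads`, `depth`, `purity`,
#'   `cn_a`, `cn_b`.
#' @return The table with `ccf` and `clonality` columns appended (`ccf` is
#'   `NA` where not evaluated).
#' @export
ccf_table <- function(table) {
  need <- c("alt_reads", "depth", "purity", "cn_a", "cn_b")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ccf <- rep(NA_real_, nrow(table))
  clonality <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    if (table$purity[i] <= 0.6) {
      clonality[i] <- "not_evaluated"
      next
    }
    post <- ccf_posterior(table$alt_reads[i], table$depth[i],
                          table$purity[i], table$cn_a[i], table$cn_b[i])
    ccf[i] <- post$ccf
    clonality[i] <- classify_clonality(post, table$purity[i])
  }
  table$ccf <- ccf
  table$clonality <- clonality
  table
}
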