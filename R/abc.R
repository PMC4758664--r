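# Summary statistics and grid-based approximate Bayesian computation for
# fitting the BEP model to observed multiregional mutation profiles.

#' Founder and unique mutation summary statistics
#'
#' For a multiregional mutation profile matrix (genes/variants x samples),
#' `phi` is the proportion of mutated rows (rows with at least one nonzero
#' element) that are nonzero in all columns, and `theta` is the mean over
#' columns of the proportion of mutated rows nonzero uniquely in that
#' column.  Founder and unique rows are disjoint, so `phi + theta <= 1`.
#'
#' @param vafs numeric matrix in `[0, 1]`, rows = genes/variants,
#'   columns = samples.
#' @return A list with `phi`, `theta`, and `n_mutated_rows` (the shared
#'   denominator).
#' @examples
#' m <- rbind(founder = c(.4, .5), unique1 = c(.4, 0))
#' summary_statistics(m)
#' @export
summary_statistics <- function(vafs) {
  stopifnot(is.matrix(vafs), ncol(vafs) >= 1)
  nz <- vafs > 0
  per_row <- rowSums(nz)
  denom <- sum(per_row > 0)
  if (denom == 0) {
    stop("summary statistics are undefined for an all-zero profile matrix",
         call. = FALSE)
  }
  phi <- sum(per_row == ncol(vafs)) / denom
  theta <- sum(per_row == 1) / ncol(vafs) / denom
  list(phi = phi, theta = theta, n_mutated_rows = denom)
}

#' Observed summary statistics with per-case downsampling
#'
#' phi and theta depend on the number of samples, so every case is reduced
#' to `s` samples: a case with exactly `s` samples is computed directly;
#' a case with more is averaged over `n_downsample` uniformly drawn
#' `s`-subsets of its samples.  The mean and standard deviation over cases
#' define the acceptance window of the ABC fit.
#'
#' @param case_profiles named list of VAF matrices (one per case).
#' @param s number of samples to reduce each case to.
#' @param n_downsample number of random subsets per case.
#' @return A list with `phi_mean`, `phi_sd`, `theta_mean`, `theta_sd`, and
#'   `per_case` (data frame of per-case means).
#' @export
observed_statistics <- function(case_profiles, s = 5L, n_downsample = 10L) {
  stopifnot(length(case_profiles) >= 1)
  one_case <- function(v) {
    if (ncol(v) < s) {
      stop(sprintf("a case has %d samples but s = %d are required",
                   ncol(v), s), call. = FALSE)
    }
    if (ncol(v) == s) {
      st <- summary_statistics(v)
      return(c(st$phi, st$theta))
    }
    st <- vapply(seq_len(n_downsample), function(i) {
      sub <- v[, sample.int(ncol(v), s), drop = FALSE]
      st <- summary_statistics(sub)
      c(st$phi, st$theta)
    }, numeric(2))
    rowMeans(st)
  }
  per <- t(vapply(case_profiles, one_case, numeric(2)))
  colnames(per) <- c("phi", "theta")
  nms <- names(case_profiles)
  if (is.null(nms)) nms <- sprintf("case%d", seq_along(case_profiles))
  list(
    phi_mean = mean(per[, "phi"]),
    phi_sd = stats::sd(per[, "phi"]),
    theta_mean = mean(per[, "theta"]),
    theta_sd = stats::sd(per[, "theta"]),
    per_case = data.frame(case = nms, per, row.names = NULL)
  )
}

#' The ABC parameter grid
#'
#' The Cartesian grid over the three fitted BEP parameters: driver count
#' `d` in 1..10, driver strength `f` in 0.1..1.0 by 0.1, and mutation rate
#' `r` in {0.0001, 0.0003, 0.001, 0.003, 0.01} - 500 settings in total.
#'
#' @param d,f,r grid values for each parameter.
#' @return Data frame with columns `n_drivers`, `driver_strength`,
#'   `mutation_rate`.
#' @export
abc_settings <- function(d = 1:10,
                         f = seq(0.1, 1.0, by = 0.1),
                         r = c(0.0001, 0.0003, 0.001, 0.003, 0.01)) {
  g <- expand.grid(n_drivers = d, driver_strength = f, mutation_rate = r,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("n_drivers", "driver_strength", "mutation_rate")]
}

#' Grid ABC fit of the BEP model
#'
#' For each grid setting, `reps` simulations are run, profiled by in-silico
#' multiregional sequencing with `s` samples, and summarized by `phi` and
#' `theta`; the acceptance fraction is the proportion of repetitions whose
#' statistics both fall within one standard deviation of the observed means
#' (closed interval).  Repetitions whose profile carries no mutated rows
#' (statistics undefined) are counted as rejected.
#'
#' @param observed list with `phi_mean`, `phi_sd`, `theta_mean`, `theta_sd`
#'   (see [observed_statistics()]).
#' @param base_params a [bep_params()] object supplying all non-fitted
#'   parameters; `n_drivers`, `driver_strength` and `mutation_rate` are
#'   overridden per grid setting.
#' @param grid data frame as returned by [abc_settings()].
#' @param reps simulations per setting.
#' @param s samples per in-silico multiregional profile.
#' @param window sampling-window side length.
#' @param seed integer seed; per-repetition seeds are derived from it so
#'   the whole fit is reproducible.
#' @return `abc_result`: the grid with columns `accepted`, `reps` and
#'   `acceptance_fraction` appended, plus the acceptance window.
#' @export
abc_grid_fit <- function(observed, base_params, grid = abc_settings(),
                         reps = 50L, s = 5L, window = 31L, seed = 1L) {
  stopifnot(reps >= 1L)
  acc <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- base_params
    params$n_drivers <- as.integer(grid$n_drivers[i])
    params$driver_strength <- grid$driver_strength[i]
    params$mutation_rate <- grid$mutation_rate[i]
    for (j in seq_len(reps)) {
      run <- run_bep(params, seed = (seed + 7919L * i + j) %% .Machine$integer.max)
      st <- tryCatch({
        prof <- multiregional_profile(run$state, s = s, window = window)
        summary_statistics(prof)
      }, error = function(e) NULL)
      if (!is.null(st) &&
          abs(st$phi - observed$phi_mean) <= observed$phi_sd &&
          abs(st$theta - observed$theta_mean) <= observed$theta_sd) {
        acc[i] <- acc[i] + 1L
      }
    }
  }
  out <- grid
  out$accepted <- acc
  out$reps <- reps
  out$acceptance_fraction <- acc / reps
  structure(list(table = out, window = observed), class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("ABC grid fit: %d settings, %d repetitions each\n",
              nrow(x$table), x$table$reps[1]))
  best <- x$table[order(-x$table$acceptance_fraction), ][1, ]
  cat(sprintf("  best setting: d = %d, f = %.1f, r = %g (acceptance %.2f)\n",
              best$n_drivers, best$driver_strength, best$mutation_rate,
              best$acceptance_fraction))
  invisible(x)
}

#' Reshape an ABC result into one acceptance heat map per mutation rate
#'
#' @param result an `abc_result`.
#' @return Named list (one element per mutation rate) of d x f matrices of
#'   acceptance fractions.
#' @export
abc_heatmaps <- function(result) {
  tab <- result$table
  lapply(split(tab, tab$mutation_rate), function(g) {
    m <- stats::xtabs(acceptance_fraction ~ n_drivers + driver_strength,
                      data = g)
    unclass(as.matrix(m))
  })
}
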