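# In-silico multiregional sequencing, summary statistics, and the ABC fit.

test_that("sampling windows are 25 disjoint squares on a symmetric grid", {
  reg <- place_sampling_regions(205, window = 31)
  expect_equal(nrow(reg), 25)
  expect_true(all(reg$x1 - reg$x0 + 1 == 31))
  expect_true(all(reg$y1 - reg$y0 + 1 == 31))
  expect_true(all(reg$x0 >= 1 & reg$x1 <= 205))
  # pairwise disjoint
  overlap <- outer(seq_len(25), seq_len(25), Vectorize(function(i, j) {
    i != j &&
      reg$x0[i] <= reg$x1[j] && reg$x1[i] >= reg$x0[j] &&
      reg$y0[i] <= reg$y1[j] && reg$y1[i] >= reg$y0[j]
  }))
  expect_false(any(overlap))
  # symmetric under 90-degree rotation of the lattice (center set maps to
  # itself under i -> L + 1 - i)
  centers <- sort(unique(reg$cx))
  expect_identical(as.integer(sort(205 + 1 - centers)), centers)
  expect_identical(sort(unique(reg$cy)), centers)

  expect_error(place_sampling_regions(150, window = 31), "25 disjoint")
})

test_that("window VAFs are mutated-cell fractions with an inclusive 0.3 floor", {
  # one fully eligible 5x5 window holding 20 cells; gene 2 sits exactly at
  # the detection floor (6/20 = 0.3), gene 3 just above it (7/20 = 0.35)
  p <- bep_params(n_genes = 3, n_drivers = 0, init_cells = 1, max_cells = 625,
                  lattice_side = 25)
  reg <- place_sampling_regions(25, window = 5)
  ctr <- reg[reg$cx == 13 & reg$cy == 13, ]
  occ <- matrix(0L, 25, 25)
  pts <- expand.grid(x = ctr$x0:ctr$x1, y = ctr$y0:ctr$y1)[1:20, ]
  occ[cbind(pts$x, pts$y)] <- 1:20
  gen <- matrix(0L, 3, 20)
  gen[1, ] <- 1L
  gen[2, 1:6] <- 1L
  gen[3, 1:7] <- 1L
  st <- make_state(occ, p, gen)
  set.seed(1)
  prof <- multiregional_profile(st, s = 1, window = 5)
  expect_equal(unname(prof[, 1]), c(1, 0, 0.35))
  expect_true(attr(prof, "filtered"))
  # only one eligible window: asking for more is an error
  expect_error(multiregional_profile(st, s = 2, window = 5),
               "half occupied")
})

test_that("single-cell sampling is a census at m = population", {
  p <- bep_params(n_genes = 4, n_drivers = 0, init_cells = 6, max_cells = 100,
                  lattice_side = 15)
  s <- bep_init(p)
  set.seed(2)
  m <- single_cell_profile(s, m = 6)
  expect_identical(dim(m), c(4L, 6L))
  expect_true(all(m == 0L))  # all-normal tumor
  expect_setequal(as.integer(colnames(m)), s$alive_ids)
  expect_error(single_cell_profile(s, m = 7), "smaller")
  # columns are the cells' genome vectors
  gen <- cell_genomes(s)
  expect_identical(m[, colnames(m)[1]], gen[, colnames(m)[1]])
})

test_that("phi and theta match the worked example and a brute-force classifier", {
  m <- toy_phi_theta_matrix()
  st <- summary_statistics(m)
  expect_equal(st$phi, 0.7)
  expect_equal(st$theta, 0.04)
  expect_equal(st$n_mutated_rows, 10)

  # saturation: every mutated row founder
  all_f <- matrix(0.5, 4, 5)
  expect_equal(summary_statistics(all_f)$phi, 1)
  expect_equal(summary_statistics(all_f)$theta, 0)

  # column permutation invariance
  perm <- m[, c(3, 1, 5, 2, 4)]
  expect_equal(summary_statistics(perm)[c("phi", "theta")],
               st[c("phi", "theta")])

  expect_error(summary_statistics(matrix(0, 3, 4)), "undefined")

  # equality with the brute-force row classifier on random matrices
  set.seed(99)
  agree <- vapply(1:40, function(i) {
    r <- matrix(rbinom(60, 1, 0.4) * runif(60), 12, 5)
    if (all(r == 0)) return(TRUE)
    a <- summary_statistics(r)
    b <- oracle_stats(r)
    isTRUE(all.equal(a$phi, b$phi)) && isTRUE(all.equal(a$theta, b$theta))
  }, logical(1))
  expect_true(all(agree))
})

test_that("observed statistics: direct computation and downsampling", {
  m <- toy_phi_theta_matrix()
  # identical cases give zero spread
  obs <- observed_statistics(list(a = m, b = m, c = m), s = 5)
  expect_equal(obs$phi_mean, 0.7)
  expect_equal(obs$phi_sd, 0)
  expect_equal(obs$theta_mean, 0.04)
  expect_equal(obs$theta_sd, 0)

  # a case with exactly s samples bypasses downsampling: rng-independent
  set.seed(1); o1 <- observed_statistics(list(m), s = 5)
  set.seed(999); o2 <- observed_statistics(list(m), s = 5)
  expect_identical(o1, o2)

  expect_error(observed_statistics(list(m), s = 6), "required")

  # Monte-Carlo downsampling converges to the exhaustive-subset average
  set.seed(5)
  m6 <- cbind(m, extra = c(rep(0.5, 7), 0, 0.4, 0))
  subs <- utils::combn(6, 5)
  exact <- rowMeans(apply(subs, 2, function(cols) {
    st <- summary_statistics(m6[, cols])
    c(st$phi, st$theta)
  }))
  sds <- apply(apply(subs, 2, function(cols) {
    st <- summary_statistics(m6[, cols])
    c(st$phi, st$theta)
  }), 1, stats::sd)
  got <- observed_statistics(list(m6), s = 5, n_downsample = 60)
  expect_lt(abs(got$phi_mean - exact[1]), 4 * sds[1] / sqrt(60) + 1e-12)
  expect_lt(abs(got$theta_mean - exact[2]), 4 * sds[2] / sqrt(60) + 1e-12)
})

test_that("the ABC grid enumerates the full parameter lattice", {
  g <- abc_settings()
  expect_equal(nrow(g), 500)
  expect_equal(nrow(unique(g)), 500)
  expect_setequal(unique(g$n_drivers), 1:10)
  expect_equal(sort(unique(g$driver_strength)), seq(0.1, 1, by = 0.1))
  expect_equal(sort(unique(g$mutation_rate)),
               c(0.0001, 0.0003, 0.001, 0.003, 0.01))
})

test_that("an infinitely wide acceptance window accepts every repetition", {
  base <- bep_params(n_genes = 40, init_cells = 10, max_cells = 400,
                     lattice_side = 30, max_steps = 1e5)
  observed <- list(phi_mean = 0.5, phi_sd = Inf,
                   theta_mean = 0.1, theta_sd = Inf)
  grid <- data.frame(n_drivers = c(1L, 2L), driver_strength = 0.1,
                     mutation_rate = 0.05)
  fit <- abc_grid_fit(observed, base, grid = grid, reps = 1, s = 3,
                      window = 5, seed = 4)
  expect_equal(fit$table$acceptance_fraction, c(1, 1))
  hm <- abc_heatmaps(fit)
  expect_named(hm, "0.05")
  expect_equal(sum(hm[["0.05"]]), 2)
})

test_that("a degenerate window (zero spread) requires exact equality", {
  base <- bep_params(n_genes = 40, init_cells = 10, max_cells = 400,
                     lattice_side = 30, max_steps = 1e5)
  observed <- list(phi_mean = 0.5, phi_sd = 0, theta_mean = 0.1,
                   theta_sd = 0)
  grid <- data.frame(n_drivers = 1L, driver_strength = 0.1,
                     mutation_rate = 0.05)
  fit <- abc_grid_fit(observed, base, grid = grid, reps = 2, s = 3,
                      window = 5, seed = 4)
  expect_true(fit$table$acceptance_fraction %in% c(0, 0.5, 1))
})

test_that("summary statistics sit closer to the observed window at the fitted mutation rate", {
  # a scaled-down trace of the acceptance gradient: distance of (phi,
  # theta) to the observed means, standardized by the observed SDs
  base <- bep_params(max_cells = 3000, lattice_side = 120,
                     n_drivers = 6, driver_strength = 0.8, max_steps = 5e6)
  dist_for <- function(r, seeds) {
    params <- base
    params$mutation_rate <- r
    mean(vapply(seeds, function(s) {
      run <- run_bep(params, seed = s)
      st <- tryCatch({
        prof <- multiregional_profile(run$state, s = 5, window = 15)
        summary_statistics(prof)
      }, error = function(e) NULL)
      if (is.null(st)) return(50)  # no informative profile at all
      max(abs(st$phi - 0.718) / 0.115, abs(st$theta - 0.138) / 0.040)
    }, numeric(1)))
  }
  expect_lt(dist_for(0.01, 1:3), dist_for(1e-4, 1:3))
})
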