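# Lattice cellular-automaton core: division probability, mutation,
# placement, unit step, and full runs.

test_that("division probability follows p0 * 10^(f*k) with a cap at 1", {
  p <- bep_params(init_cells = 1, max_cells = 100, lattice_side = 20)
  expect_equal(division_probability(rep(0L, p$n_genes), p), 0.001)
  expect_equal(division_probability(1L, p), 0.001 * 10^0.8,
               tolerance = 1e-12)
  expect_equal(division_probability(1L, p), 0.0063096, tolerance = 1e-5)
  # k = 6, f = 0.8: raw value 63.1, capped because it is a probability
  expect_identical(division_probability(6L, p), 1)
  pk <- vapply(0:12, function(k) division_probability(k, p), numeric(1))
  expect_true(all(diff(pk) >= 0))
})

test_that("genome mutation is irreversible and monotone", {
  g <- c(1L, 0L, 0L, 1L, 0L)
  expect_identical(mutate_genome(g, 0), g)
  expect_identical(mutate_genome(g, 1), rep(1L, 5))
  set.seed(1)
  monotone <- vapply(1:50, function(i) {
    g <- as.integer(runif(40) < 0.3)
    all(mutate_genome(g, runif(1)) >= g)
  }, logical(1))
  expect_true(all(monotone))
})

test_that("initialization packs cells around the lattice center", {
  p1 <- bep_params(init_cells = 1, max_cells = 100, lattice_side = 21)
  s1 <- bep_init(p1)
  expect_equal(s1$population, 1)
  pos <- which(s1$occ != 0L, arr.ind = TRUE)
  expect_equal(unname(pos[1, ]), c(11, 11))

  p10 <- bep_params(init_cells = 10, max_cells = 400, lattice_side = 21)
  s10 <- bep_init(p10)
  expect_equal(s10$population, 10)
  expect_true(all(s10$gen[, s10$alive_ids] == 0L))
  expect_true(all(s10$k[s10$alive_ids] == 0L))
  # minimal-radius packing: the center plus its full Moore ring, then one
  # edge-adjacent point of the next ring
  pos <- which(s10$occ != 0L, arr.ind = TRUE)
  cheb <- pmax(abs(pos[, 1] - 11), abs(pos[, 2] - 11))
  expect_equal(sum(cheb <= 1), 9)
  expect_true(all(cheb <= 2))
  # deterministic
  expect_identical(s10$occ, bep_init(p10)$occ)

  expect_error(bep_params(init_cells = 10, max_cells = 9, lattice_side = 3),
               "lattice")
})

test_that("an isolated cell places its daughter uniformly on the 8 neighbors", {
  p <- bep_params(init_cells = 1, max_cells = 100, lattice_side = 11)
  s <- bep_init(p)
  set.seed(10)
  draws <- replicate(8000, {
    site <- find_division_site(s, 6L, 6L)
    stopifnot(!site$shifted)
    paste(site$x, site$y)
  })
  freq <- table(draws) / 8000
  expect_equal(length(freq), 8L)
  # 4 sigma band around 1/8
  expect_lt(max(abs(freq - 1 / 8)), 4 * sqrt(1 / 8 * 7 / 8 / 8000))
})

enclosed_state <- function() {
  # center cell fully enclosed; east run length 1, all other runs length 2
  dx <- bepith:::.DX8
  dy <- bepith:::.DY8
  occ <- matrix(0L, 9, 9)
  id <- 0L
  occ[5, 5] <- id <- id + 1L
  for (d in 1:8) occ[5 + dx[d], 5 + dy[d]] <- id <- id + 1L
  for (d in 2:8) occ[5 + 2L * dx[d], 5 + 2L * dy[d]] <- id <- id + 1L
  p <- bep_params(init_cells = 1, max_cells = 81, lattice_side = 9)
  make_state(occ, p)
}

test_that("run-shift direction is drawn proportional to 1/run-length", {
  s <- enclosed_state()
  set.seed(3)
  n <- 6000
  east <- 0L
  for (i in seq_len(n)) {
    occ0 <- s$occ; px <- s$posx; py <- s$posy
    site <- find_division_site(s, 5L, 5L)
    stopifnot(site$shifted)
    if (site$direction == 1L) east <- east + 1L
    s$occ <- occ0; s$posx <- px; s$posy <- py
  }
  # run lengths (1, 2 x 7): P(east) = (1/1) / (1/1 + 7/2) = 2/9
  expect_lt(abs(east / n - 2 / 9), 4 * sqrt(2 / 9 * 7 / 9 / n))
})

test_that("run shifting conserves all cells and frees exactly the neighbor", {
  s <- enclosed_state()
  before <- sort(s$occ[s$occ != 0L])
  set.seed(4)
  site <- find_division_site(s, 5L, 5L)
  after <- sort(s$occ[s$occ != 0L])
  expect_identical(after, before)
  expect_identical(s$occ[site$x, site$y], 0L)
  # position bookkeeping matches the lattice
  ids <- s$alive_ids
  expect_identical(s$occ[cbind(s$posx[ids], s$posy[ids])], ids)
})

test_that("a fully boxed-in boundary cell skips its division", {
  # 3x3 lattice fully occupied: no run reaches an empty point
  occ <- matrix(1:9, 3, 3)
  p <- bep_params(init_cells = 1, max_cells = 9, lattice_side = 3)
  s <- make_state(occ, p)
  expect_null(find_division_site(s, 2L, 2L))
})

test_that("unit-step boundary behavior: total death and frozen dynamics", {
  p <- bep_params(init_cells = 5, death_prob = 1, max_cells = 100,
                  lattice_side = 11)
  s <- bep_init(p)
  set.seed(1)
  bep_step(s)
  expect_equal(s$population, 0)
  expect_equal(sum(s$occ != 0L), 0)
  expect_equal(s$time_step, 1L)

  p2 <- bep_params(init_cells = 5, base_division_prob = 0,
                   death_prob = 0, max_cells = 100, lattice_side = 11)
  s2 <- bep_init(p2)
  occ0 <- s2$occ
  set.seed(1)
  bep_step(s2)
  expect_identical(s2$occ, occ0)
  expect_equal(s2$population, 5)
  expect_equal(s2$time_step, 1L)
})

test_that("mean one-step growth matches the binomial expectation", {
  p <- bep_params(init_cells = 100, n_drivers = 0, mutation_rate = 0,
                  base_division_prob = 0.05, death_prob = 0,
                  max_cells = 1000, lattice_side = 40)
  set.seed(42)
  pops <- replicate(600, {
    s <- bep_init(p)
    bep_step(s)
    s$population
  })
  expect_lt(abs(mean(pops) - 100 * 1.05),
            3 * stats::sd(pops) / sqrt(length(pops)))
})

test_that("runs stop at the boundaries and are reproducible", {
  p0 <- bep_params(init_cells = 10, max_steps = 0, max_cells = 100,
                   lattice_side = 15)
  r0 <- run_bep(p0, seed = 1)
  expect_equal(r0$state$population, 10)
  expect_equal(r0$state$time_step, 0L)

  p <- bep_params(n_genes = 50, n_drivers = 3, driver_strength = 1,
                  mutation_rate = 0.05, init_cells = 10, max_cells = 500,
                  max_steps = 1e5, lattice_side = 50)
  r1 <- run_bep(p, seed = 7)
  r2 <- run_bep(p, seed = 7)
  expect_identical(cell_genomes(r1$state), cell_genomes(r2$state))
  expect_identical(r1$state$occ, r2$state$occ)
  expect_gt(r1$state$population, p$max_cells)
  # growth curve ends at the final state
  expect_equal(utils::tail(r1$growth$population, 1), r1$state$population)
  expect_equal(utils::tail(r1$growth$time_step, 1),
               as.numeric(r1$state$time_step))

  snaps <- run_bep(p, seed = 7, snapshot_times = c(0, 5))$snapshots
  expect_named(snaps, c("t0", "t5"))
  expect_equal(sum(snaps$t0 != 0L), 10)
})

test_that("driver selection makes scaled runs supercritical", {
  p <- bep_params(mutation_rate = 0.01, n_drivers = 6,
                  driver_strength = 0.8, max_cells = 2000,
                  lattice_side = 100, max_steps = 5e6)
  crossed <- vapply(1:6, function(s) {
    run_bep(p, seed = s)$state$population > p$max_cells
  }, logical(1))
  expect_true(all(crossed))
})

test_that("occupancy is conserved and genomes grow monotonically along lineages", {
  p <- bep_params(n_genes = 50, n_drivers = 0, mutation_rate = 0.1,
                  base_division_prob = 0.2, death_prob = 0.02,
                  init_cells = 1, max_cells = 40, lattice_side = 30,
                  max_steps = 500)
  run <- run_bep(p, seed = 11, record_lineage = TRUE)
  st <- run$state
  ids <- st$alive_ids
  expect_gt(length(ids), 5)
  # conservation: population equals occupied points, one cell per point
  expect_equal(sum(st$occ != 0L), st$population)
  expect_identical(sort(st$occ[st$occ != 0L]), sort(ids))
  expect_identical(st$occ[cbind(st$posx[ids], st$posy[ids])], ids)
  # genome monotonicity along parent -> daughter chains
  monotone <- vapply(ids, function(id) {
    pid <- st$parent[id]
    all(st$birth_mut[[id]] %in% which(st$gen[, id] == 1L)) &&
      (pid == 0L || all(st$birth_mut[[pid]] %in% st$birth_mut[[id]]))
  }, logical(1))
  expect_true(all(monotone))
})

test_that("mutations carried by the common ancestor are fixed in the tumor", {
  p <- bep_params(n_genes = 60, n_drivers = 0, mutation_rate = 0.15,
                  base_division_prob = 0.3, death_prob = 0.1,
                  init_cells = 1, max_cells = 60, lattice_side = 40,
                  max_steps = 2000)
  run <- run_bep(p, seed = 5, record_lineage = TRUE)
  st <- run$state
  ids <- st$alive_ids
  expect_gt(length(ids), 10)
  # brute-force genealogy: alive descendants of every internal ancestor
  desc <- new.env(parent = emptyenv())
  for (id in ids) {
    a <- id
    repeat {
      a <- st$parent[a]
      if (a == 0L) break
      key <- as.character(a)
      assign(key, c(if (exists(key, desc)) get(key, desc), id), desc)
    }
  }
  # mutations carried by an ancestor at birth are fixed in its whole clade
  checked <- 0L
  ok <- TRUE
  for (key in ls(desc)) {
    a <- as.integer(key)
    bm <- st$birth_mut[[a]]
    D <- get(key, desc)
    if (length(D) < 3L || length(bm) == 0L) next
    shared <- Reduce(intersect,
                     lapply(D, function(i) which(st$gen[, i] == 1L)))
    checked <- checked + 1L
    ok <- ok && all(bm %in% shared)
  }
  expect_gt(checked, 5L)
  expect_true(ok)
  # and the tumor-wide founder set contains the common ancestor's mutations
  paths <- lapply(ids, function(id) {
    path <- id
    while (st$parent[id] > 0L) {
      id <- st$parent[id]
      path <- c(path, id)
    }
    path
  })
  common <- Reduce(intersect, paths)
  # the deepest common ancestor comes first on any leaf-to-root path
  lca <- paths[[1]][paths[[1]] %in% common][1]
  shared_all <- Reduce(intersect,
                       lapply(ids, function(i) which(st$gen[, i] == 1L)))
  expect_true(all(st$birth_mut[[lca]] %in% shared_all))
})

test_that("without driver strength the division probability stays neutral", {
  p <- bep_params(n_genes = 40, n_drivers = 6, driver_strength = 0,
                  mutation_rate = 0.2, base_division_prob = 0.2,
                  death_prob = 0, init_cells = 5, max_cells = 100,
                  lattice_side = 20, max_steps = 100)
  run <- run_bep(p, seed = 2)
  st <- run$state
  expect_true(any(st$k[st$alive_ids] > 0))  # drivers were mutated...
  expect_true(all(st$pdiv[st$alive_ids] == 0.2))  # ...but do not select
})
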