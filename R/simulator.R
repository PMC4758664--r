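# Lattice cellular-automaton core of the BEP tumor model.
#
# The tumor state is held in an environment so the step function can update
# occupancy, genomes and bookkeeping in place; a full run touches the state
# tens of thousands of times and value semantics would copy the genome
# matrix at every step.  Cell identifiers are never reused within a run and
# index columns of the genome matrix directly.

# Moore neighborhood offsets, fixed order (E, NE, N, NW, W, SW, S, SE in
# matrix row/col coordinates; the order only needs to be deterministic).
.DX8 <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.DY8 <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Per-step division probability of a cell
#'
#' A cell with `k` mutated driver genes divides with probability
#' `min(1, p0 * 10^(f*k))`: each driver mutation multiplies the baseline
#' division probability by `10^f`.  The raw value can exceed 1 for large
#' `f*k`; it is capped because it is used as a Bernoulli probability.
#'
#' @param genome integer (0/1) genome vector, or an integer driver count.
#' @param params a [bep_params()] object.
#' @return A probability in `[0, 1]`, non-decreasing in the driver count.
#' @examples
#' p <- bep_params(max_cells = 100, lattice_side = 32)
#' division_probability(rep(0L, p$n_genes), p)   # p0 = 0.001
#' @export
division_probability <- function(genome, params) {
  k <- if (length(genome) == 1L) as.integer(genome) else
    driver_count(genome, params$n_drivers)
  min(1, params$base_division_prob * 10^(params$driver_strength * k))
}

driver_count <- function(genome, n_drivers) {
  if (n_drivers == 0L) 0L else sum(genome[seq_len(n_drivers)] > 0L)
}

#' Mutate a genome vector
#'
#' Each wild-type (0) gene flips to the mutated state (1) independently
#' with probability `r`; mutated genes never revert.
#'
#' @param genome integer 0/1 vector.
#' @param r per-gene mutation probability in `[0, 1]`.
#' @return The mutated genome vector.
#' @export
mutate_genome <- function(genome, r) {
  stopifnot(r >= 0, r <= 1)
  if (r == 0) return(genome)
  zeros <- which(genome == 0L)
  if (length(zeros)) {
    flip <- zeros[stats::runif(length(zeros)) < r]
    genome[flip] <- 1L
  }
  genome
}

# -- state construction ------------------------------------------------------

#' Initialize a tumor state
#'
#' Places `init_cells` all-wild-type cells in a minimal-radius packing
#' around the central lattice point (points sorted by Euclidean distance to
#' the center, ties broken by a fixed spiral order).  Initialization is
#' deterministic: it consumes no random numbers.
#'
#' @param params a [bep_params()] object.
#' @param record_lineage if `TRUE`, record each cell's parent and its genome
#'   at birth (as a set of mutated gene indices) for genealogy analyses;
#'   intended for small runs.
#' @return A `bep_state` environment with fields `occ` (integer lattice,
#'   0 = empty), `gen` (genes x cells genome matrix), `posx`/`posy`,
#'   `alive_ids`, `population`, `time_step`.
#' @export
bep_init <- function(params, record_lineage = FALSE) {
  L <- params$lattice_side
  c0 <- params$init_cells
  ctr <- (L + 1L) %/% 2L

  # candidate points: square block around the center large enough for c0
  R <- 0L
  while ((2L * R + 1L)^2 < c0) R <- R + 1L
  R <- min(R + 1L, ctr - 1L, L - ctr)
  xs <- (ctr - R):(ctr + R)
  cand <- expand.grid(x = xs, y = xs)
  dx <- cand$x - ctr; dy <- cand$y - ctr
  ring <- pmax(abs(dx), abs(dy))
  idx <- ring_position(dx, dy, ring)
  ord <- order(dx^2 + dy^2, ring, idx)
  cand <- cand[ord[seq_len(c0)], , drop = FALSE]

  state <- new.env(parent = emptyenv())
  state$params <- params
  cap <- max(1024L, 2L * c0)
  state$occ <- matrix(0L, L, L)
  state$gen <- matrix(0L, params$n_genes, cap)
  state$posx <- integer(cap)
  state$posy <- integer(cap)
  state$k <- integer(cap)
  state$pdiv <- numeric(cap)
  state$alive <- logical(cap)
  state$parent <- integer(cap)
  state$cap <- cap
  state$record_lineage <- record_lineage
  state$birth_mut <- if (record_lineage) vector("list", cap) else NULL

  ids <- seq_len(c0)
  state$occ[cbind(cand$x, cand$y)] <- ids
  state$posx[ids] <- cand$x
  state$posy[ids] <- cand$y
  state$pdiv[ids] <- division_probability(0L, params)
  state$alive[ids] <- TRUE
  state$alive_ids <- ids
  state$next_id <- c0
  state$population <- c0
  state$time_step <- 0L
  if (record_lineage) for (i in ids) state$birth_mut[[i]] <- integer(0)

  # growth-curve record, grown by doubling
  state$gc_t <- numeric(1024L)
  state$gc_c <- numeric(1024L)
  state$gc_n <- 1L
  state$gc_t[1L] <- 0
  state$gc_c[1L] <- c0
  class(state) <- "bep_state"
  state
}

#' @export
print.bep_state <- function(x, ...) {
  cat(sprintf("BEP tumor state: %d cells at time step %g on a %d x %d lattice\n",
              x$population, as.numeric(x$time_step),
              x$params$lattice_side, x$params$lattice_side))
  invisible(x)
}

# grow per-cell storage to hold at least `n` ids
grow_state <- function(state, n) {
  while (state$cap < n) {
    new_cap <- state$cap * 2L
    gen <- matrix(0L, nrow(state$gen), new_cap)
    gen[, seq_len(state$cap)] <- state$gen
    state$gen <- gen
    for (f in c("posx", "posy", "k", "parent")) {
      v <- state[[f]]; length(v) <- new_cap; v[is.na(v)] <- 0L; state[[f]] <- v
    }
    v <- state$pdiv; length(v) <- new_cap; v[is.na(v)] <- 0; state$pdiv <- v
    v <- state$alive; length(v) <- new_cap; v[is.na(v)] <- FALSE; state$alive <- v
    if (state$record_lineage) length(state$birth_mut) <- new_cap
    state$cap <- new_cap
  }
  invisible(state)
}

# deep copy of a state (environments have reference semantics)
clone_state <- function(state) {
  s2 <- new.env(parent = emptyenv())
  for (nm in ls(state, all.names = TRUE)) assign(nm, get(nm, state), s2)
  class(s2) <- "bep_state"
  s2
}

# -- spiral ordering ---------------------------------------------------------

# Canonical position of (dx, dy) along its square ring m = max(|dx|, |dy|):
# 0 .. 8m-1, traversing right side upward, then top leftward, left downward,
# bottom rightward.  Vectorized; ring 0 maps to 0.
ring_position <- function(dx, dy, m) {
  idx <- integer(length(dx))
  right <- dx == m & dy > -m
  top <- dy == m & dx < m
  left <- dx == -m & dy < m
  bottom <- dy == -m & dx > -m
  idx[right] <- dy[right] + m[right] - 1L
  idx[top] <- 2L * m[top] + (m[top] - 1L - dx[top])
  idx[left] <- 4L * m[left] + (m[left] - 1L - dy[left])
  idx[bottom] <- 6L * m[bottom] + (dx[bottom] + m[bottom] - 1L)
  idx[m == 0L] <- 0L
  idx
}

# Order cell ids along an outward square spiral from the lattice center.
# Per ring ("round" of the spiral) the traversal direction is flipped with
# probability 1/2 to keep spatial symmetry; rings are always processed
# inside-out.
spiral_order <- function(state, ids) {
  ctr <- (state$params$lattice_side + 1L) %/% 2L
  dx <- state$posx[ids] - ctr
  dy <- state$posy[ids] - ctr
  m <- pmax(abs(dx), abs(dy))
  idx <- ring_position(dx, dy, m)
  rings <- sort(unique(m))
  flip <- stats::runif(length(rings)) < 0.5
  fl <- flip[match(m, rings)]
  per <- pmax(8L * m, 1L)
  idx <- ifelse(fl, (per - idx) %% per, idx)
  ids[order(m, idx)]
}

# -- division placement ------------------------------------------------------

#' Find (and if necessary create) an empty lattice point for a daughter cell
#'
#' If the parent has empty Moore neighbors (8 surrounding points), one is
#' chosen uniformly.  Otherwise, for each of the 8 directions the run length
#' `l_i` of consecutive occupied points (from the neighbor up to immediately
#' before the nearest empty point) is computed; a direction is drawn with
#' probability proportional to `1/l_i` among directions whose run reaches an
#' empty point before the lattice boundary, and that run is shifted outward
#' by one point, freeing the neighbor.  Cell positions are updated in place.
#'
#' @param state a `bep_state`.
#' @param x,y lattice coordinates of the (occupied) parent.
#' @return `list(x, y, shifted, direction, run_length)` for the freed
#'   daughter position, or `NULL` if no direction reaches an empty point
#'   before the boundary (the division is skipped by the caller).
#' @export
find_division_site <- function(state, x, y) {
  L <- state$params$lattice_side
  occ <- state$occ  # local alias for reads only (released before writes)
  nx <- x + .DX8; ny <- y + .DY8
  inb <- nx >= 1L & nx <= L & ny >= 1L & ny <= L
  emp <- logical(8L)
  emp[inb] <- occ[cbind(nx[inb], ny[inb])] == 0L
  if (any(emp)) {
    w <- which(emp)
    d <- w[sample.int(length(w), 1L)]
    return(list(x = nx[d], y = ny[d], shifted = FALSE,
                direction = d, run_length = 0L))
  }
  len <- integer(8L)
  for (d in 1:8) {
    # whole ray from the neighbor to the lattice boundary, scanned at once
    mx <- if (.DX8[d] > 0L) L - x else if (.DX8[d] < 0L) x - 1L else L
    my <- if (.DY8[d] > 0L) L - y else if (.DY8[d] < 0L) y - 1L else L
    mlen <- min(mx, my)
    if (mlen < 1L) next
    j <- seq_len(mlen)
    e <- match(0L, occ[cbind(x + j * .DX8[d], y + j * .DY8[d])])
    if (!is.na(e)) len[d] <- e - 1L  # run reaches an empty point
  }
  rm(occ)
  w <- which(len > 0L)
  if (!length(w)) return(NULL)
  d <- w[sample.int(length(w), 1L, prob = 1 / len[w])]
  e <- len[d] + 1L  # distance of the empty point
  j <- e:2L
  fx <- x + (j - 1L) * .DX8[d]; fy <- y + (j - 1L) * .DY8[d]
  cids <- state$occ[cbind(fx, fy)]
  state$occ[cbind(x + j * .DX8[d], y + j * .DY8[d])] <- cids
  state$posx[cids] <- x + j * .DX8[d]
  state$posy[cids] <- y + j * .DY8[d]
  state$occ[x + .DX8[d], y + .DY8[d]] <- 0L
  list(x = x + .DX8[d], y = y + .DY8[d], shifted = TRUE,
       direction = d, run_length = len[d])
}

# -- unit time step ----------------------------------------------------------

#' Advance the tumor state by one unit time step
#'
#' Phase 1 marks each cell dead with probability `q0` and, for survivors,
#' marks division with the cell's division probability; both marks are
#' decided from the pre-step state.  Phase 2 removes dead cells.  Phase 3
#' processes marked cells along an outward square spiral from the lattice
#' center (per-ring random direction flip): the parent genome is mutated,
#' then a daughter carrying a copy of the mutated genome is placed via
#' [find_division_site()]; placement failures skip that division.
#'
#' @param state a `bep_state`, modified in place.
#' @return The state, invisibly.
#' @export
bep_step <- function(state) {
  p <- state$params
  ids <- state$alive_ids
  nc <- length(ids)
  if (nc) {
    die <- stats::runif(nc) < p$death_prob
    div <- logical(nc)
    ns <- nc - sum(die)
    if (ns) div[!die] <- stats::runif(ns) < state$pdiv[ids[!die]]
    if (any(die)) {
      dead <- ids[die]
      state$occ[cbind(state$posx[dead], state$posy[dead])] <- 0L
      state$alive[dead] <- FALSE
      ids <- ids[!die]
      div <- div[!die]
      state$alive_ids <- ids
      state$population <- length(ids)
    }
    dividers <- ids[div]
    nd <- length(dividers)
    if (nd) {
      if (nd > 1L) dividers <- spiral_order(state, dividers)
      grow_state(state, state$next_id + nd)
      ndrv <- p$n_drivers
      r <- p$mutation_rate
      if (r > 0) {
        # mutate every dividing parent before its division (the daughter
        # copies the mutated genome, so both carry the new mutations);
        # batched over the step's dividers for speed
        G <- state$gen[, dividers, drop = FALSE]
        newmut <- matrix(stats::runif(length(G)), nrow(G)) < r & G == 0L
        if (any(newmut)) {
          G[newmut] <- 1L
          state$gen[, dividers] <- G
          kd <- if (ndrv > 0L)
            colSums(G[seq_len(ndrv), , drop = FALSE] > 0L) else
              integer(nd)
          state$k[dividers] <- kd
          state$pdiv[dividers] <-
            pmin(1, p$base_division_prob * 10^(p$driver_strength * kd))
        }
      }
      parents <- integer(nd)
      children <- integer(nd)
      np <- 0L
      for (id in dividers) {
        site <- find_division_site(state, state$posx[id], state$posy[id])
        if (is.null(site)) next
        nid <- state$next_id + 1L
        state$next_id <- nid
        np <- np + 1L
        parents[np] <- id
        children[np] <- nid
        state$posx[nid] <- site$x
        state$posy[nid] <- site$y
        state$occ[site$x, site$y] <- nid
      }
      if (np) {
        pp <- parents[seq_len(np)]
        ch <- children[seq_len(np)]
        state$gen[, ch] <- state$gen[, pp]
        state$k[ch] <- state$k[pp]
        state$pdiv[ch] <- state$pdiv[pp]
        state$parent[ch] <- pp
        state$alive[ch] <- TRUE
        state$alive_ids <- c(state$alive_ids, ch)
        if (state$record_lineage) {
          for (i in seq_len(np)) {
            state$birth_mut[[ch[i]]] <- which(state$gen[, pp[i]] == 1L)
          }
        }
        state$population <- length(state$alive_ids)
      }
    }
  }
  state$time_step <- state$time_step + 1L
  n <- state$gc_n + 1L
  if (n > length(state$gc_t)) {
    length(state$gc_t) <- 2L * length(state$gc_t)
    length(state$gc_c) <- 2L * length(state$gc_c)
  }
  state$gc_t[n] <- as.numeric(state$time_step)
  state$gc_c[n] <- state$population
  state$gc_n <- n
  invisible(state)
}

# -- full run ----------------------------------------------------------------

#' Run a full BEP tumor simulation
#'
#' Repeats the unit time step while the population is positive, at most
#' `max_cells`, and fewer than `max_steps` steps were simulated; i.e. the
#' run terminates as soon as the population exceeds `max_cells`, the step
#' budget is exhausted, or the tumor dies out.  A single global random
#' stream is used, seeded explicitly, so runs are fully reproducible.
#'
#' @param params a [bep_params()] object.
#' @param seed integer seed for the run.
#' @param snapshot_times integer vector of time steps at which to capture an
#'   occupancy snapshot (0 captures the initial state).
#' @param record_lineage see [bep_init()].
#' @return An object of class `bep_run`: a list with `state` (final
#'   `bep_state`), `growth` (data frame `time_step`, `population`),
#'   `snapshots` (named list of occupancy matrices), and the `params`.
#' @examples
#' run <- run_bep(bep_params(max_cells = 200, max_steps = 2000,
#'                           lattice_side = 40), seed = 1)
#' tail(run$growth, 3)
#' @export
run_bep <- function(params, seed, snapshot_times = integer(0),
                    record_lineage = FALSE) {
  set.seed(seed)
  state <- bep_init(params, record_lineage = record_lineage)
  snapshots <- list()
  snap <- function() {
    if (as.numeric(state$time_step) %in% snapshot_times) {
      snapshots[[paste0("t", state$time_step)]] <<- state$occ
    }
  }
  snap()
  while (state$population > 0 &&
         state$population <= params$max_cells &&
         as.numeric(state$time_step) < params$max_steps) {
    bep_step(state)
    if (length(snapshot_times)) snap()
  }
  structure(list(
    state = state,
    growth = data.frame(time_step = state$gc_t[seq_len(state$gc_n)],
                        population = state$gc_c[seq_len(state$gc_n)]),
    snapshots = snapshots,
    params = params,
    seed = seed
  ), class = "bep_run")
}

#' @export
print.bep_run <- function(x, ...) {
  cat(sprintf("BEP run (seed %s): %d cells after %g time steps\n",
              format(x$seed), x$state$population,
              as.numeric(x$state$time_step)))
  invisible(x)
}

#' Genomes of all living cells
#'
#' @param state a `bep_state`.
#' @return Integer 0/1 matrix, genes x living cells; column names are cell
#'   identifiers.
#' @export
cell_genomes <- function(state) {
  ids <- state$alive_ids
  g <- state$gen[, ids, drop = FALSE]
  colnames(g) <- as.character(ids)
  rownames(g) <- gene_ids(state$params)
  g
}

gene_ids <- function(params) {
  sprintf("g%03d", seq_len(params$n_genes))
}
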