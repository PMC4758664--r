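# Shared test helpers: hand-built tumor states and brute-force oracles.

# Build a bep_state with prescribed occupancy (integer matrix, 0 = empty,
# positive entries are cell ids) and optional genome matrix (genes x ids).
make_state <- function(occ, params, genomes = NULL) {
  ids <- sort(occ[occ != 0L])
  stopifnot(!anyDuplicated(ids))
  cap <- max(ids)
  state <- new.env(parent = emptyenv())
  state$params <- params
  state$occ <- occ
  state$gen <- if (is.null(genomes)) matrix(0L, params$n_genes, cap) else {
    stopifnot(nrow(genomes) == params$n_genes, ncol(genomes) >= cap)
    genomes
  }
  state$posx <- integer(cap)
  state$posy <- integer(cap)
  for (id in ids) {
    w <- which(occ == id, arr.ind = TRUE)
    state$posx[id] <- w[1, 1]
    state$posy[id] <- w[1, 2]
  }
  state$k <- integer(cap)
  state$pdiv <- numeric(cap)
  for (id in ids) {
    state$k[id] <- sum(state$gen[seq_len(params$n_drivers), id] > 0L)
    state$pdiv[id] <- division_probability(state$k[id], params)
  }
  state$alive <- logical(cap)
  state$alive[ids] <- TRUE
  state$alive_ids <- ids
  state$parent <- integer(cap)
  state$cap <- cap
  state$record_lineage <- FALSE
  state$birth_mut <- NULL
  state$next_id <- cap
  state$population <- length(ids)
  state$time_step <- 0L
  state$gc_t <- 0
  state$gc_c <- length(ids)
  state$gc_n <- 1L
  class(state) <- "bep_state"
  state
}

# brute-force row classifier for phi/theta
oracle_stats <- function(m) {
  nz <- m > 0
  founder <- 0L
  unique_per_col <- numeric(ncol(m))
  mutated <- 0L
  for (i in seq_len(nrow(m))) {
    cols <- which(nz[i, ])
    if (!length(cols)) next
    mutated <- mutated + 1L
    if (length(cols) == ncol(m)) founder <- founder + 1L
    if (length(cols) == 1L) {
      unique_per_col[cols] <- unique_per_col[cols] + 1
    }
  }
  list(phi = founder / mutated,
       theta = mean(unique_per_col / mutated))
}

# toy 10 x 5 profile from the summary-statistic worked example:
# 7 founder rows, one row in samples 1-2, one row only sample 1, one row
# only sample 2 -> phi = 0.7, theta = 0.04
toy_phi_theta_matrix <- function() {
  m <- matrix(0, 10, 5)
  m[1:7, ] <- 0.5
  m[8, 1:2] <- 0.4
  m[9, 1] <- 0.4
  m[10, 2] <- 0.4
  m
}

default_bipartitions <- function(samples, clades) {
  c(
    lapply(clades, function(cl)
      list(side1 = samples[cl], side2 = samples[-cl])),
    lapply(seq_along(samples), function(i)
      list(side1 = samples[i], side2 = samples[-i]))
  )
}
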