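#' Parameters of the branching-evolutionary-process (BEP) tumor model
#'
#' Bundles the parameters of the lattice cellular-automaton tumor model.
#' Each cell carries a binary genome of `n_genes` genes; the first
#' `n_drivers` of them are driver genes.  Per unit time step a cell dies
#' with probability `death_prob` and, if it survives, divides with
#' probability `min(1, base_division_prob * 10^(driver_strength * k))`
#' where `k` is the number of mutated driver genes.  At each division,
#' every wild-type gene of the parent genome mutates independently with
#' probability `mutation_rate` (mutations are irreversible).
#'
#' @param n_genes number of genes in the binary genome.
#' @param n_drivers number of driver genes (the first `n_drivers` positions).
#' @param driver_strength dimensionless exponent factor: one driver mutation
#'   multiplies the division probability by `10^driver_strength`.
#' @param mutation_rate per-gene, per-division mutation probability.
#' @param base_division_prob per-step division probability of a cell with
#'   no driver mutations.
#' @param death_prob per-step death probability (constant for all cells).
#' @param init_cells number of cells the simulation starts from.
#' @param max_cells the run stops once the population exceeds this size.
#' @param max_steps the run stops once this many time steps were simulated.
#' @param lattice_side side length of the square lattice (lattice points per
#'   side); `lattice_side^2` must be at least `max_cells`.
#'
#' @return An object of class `bep_params` (a validated named list).
#' @examples
#' p <- bep_params(max_cells = 1e4, lattice_side = 200)
#' p$n_genes
#' @export
bep_params <- function(n_genes = 300L,
                       n_drivers = 6L,
                       driver_strength = 0.8,
                       mutation_rate = 0.01,
                       base_division_prob = 0.001,
                       death_prob = 1e-7,
                       init_cells = 10L,
                       max_cells = 1e6,
                       max_steps = 5e6,
                       lattice_side = 2048L) {
  p <- list(
    n_genes = as.integer(n_genes),
    n_drivers = as.integer(n_drivers),
    driver_strength = as.numeric(driver_strength),
    mutation_rate = as.numeric(mutation_rate),
    base_division_prob = as.numeric(base_division_prob),
    death_prob = as.numeric(death_prob),
    init_cells = as.integer(init_cells),
    max_cells = as.numeric(max_cells),
    max_steps = as.numeric(max_steps),
    lattice_side = as.integer(lattice_side)
  )
  stopifnot(
    p$n_genes >= 1L,
    p$n_drivers >= 0L, p$n_drivers <= p$n_genes,
    p$mutation_rate >= 0, p$mutation_rate <= 1,
    p$base_division_prob >= 0, p$base_division_prob <= 1,
    p$death_prob >= 0, p$death_prob <= 1,
    p$init_cells >= 1L,
    p$max_cells >= 1,
    p$max_steps >= 0,
    p$lattice_side >= 1L
  )
  if (as.numeric(p$lattice_side)^2 < p$max_cells) {
    stop("lattice_side^2 must be >= max_cells: the lattice cannot hold ",
         "the target population", call. = FALSE)
  }
  if (as.numeric(p$lattice_side)^2 < p$init_cells) {
    stop("lattice too small for init_cells", call. = FALSE)
  }
  class(p) <- "bep_params"
  p
}

#' @export
print.bep_params <- function(x, ...) {
  cat("BEP model parameters\n")
  cat(sprintf("  genome: %d genes, %d drivers (f = %g)\n",
              x$n_genes, x$n_drivers, x$driver_strength))
  cat(sprintf("  rates : r = %g per gene per division, p0 = %g, q0 = %g\n",
              x$mutation_rate, x$base_division_prob, x$death_prob))
  cat(sprintf("  run   : c0 = %d, cmax = %g, tmax = %g, lattice %d x %d\n",
              x$init_cells, x$max_cells, x$max_steps,
              x$lattice_side, x$lattice_side))
  invisible(x)
}
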