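# In-silico multiregional sequencing of simulated tumors.

#' Place the multiregional sampling windows on the lattice
#'
#' 25 square windows of `window` x `window` lattice points whose centers lie
#' on a 5 x 5 grid spaced evenly and as symmetrically as the integer lattice
#' allows about the lattice center (exact symmetry requires compatible
#' parities of `lattice_side` and the spacing).  Windows are pairwise
#' disjoint.
#'
#' @param lattice_side lattice side length; must be at least `5 * window`.
#' @param window window side length (odd); 31 emulates multiregional
#'   sampling of a full-scale tumor.
#' @return A data frame with one row per window: `id`, `cx`, `cy`,
#'   `x0`, `x1`, `y0`, `y1` (inclusive lattice ranges).
#' @export
place_sampling_regions <- function(lattice_side, window = 31L) {
  lattice_side <- as.integer(lattice_side)
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (lattice_side < 5L * window) {
    stop("lattice_side must be at least 5 * window to place 25 disjoint ",
         "sampling windows", call. = FALSE)
  }
  s <- lattice_side %/% 5L
  c1 <- (lattice_side + 1L - 4L * s) %/% 2L
  centers <- c1 + (0:4) * s
  half <- window %/% 2L
  g <- expand.grid(cx = centers, cy = centers)
  data.frame(
    id = sprintf("w%02d", seq_len(nrow(g))),
    cx = g$cx, cy = g$cy,
    x0 = g$cx - half, x1 = g$cx + half,
    y0 = g$cy - half, y1 = g$cy + half,
    stringsAsFactors = FALSE
  )
}

#' In-silico multiregional sequencing of a simulated tumor
#'
#' From the 25 sampling windows, those in which at least half of the
#' lattice points are occupied are eligible; `s` eligible windows are
#' chosen uniformly at random.  Per window and gene, the VAF is the
#' fraction of its cells carrying the mutation (the simulated tumor is
#' haploid and free of normal-cell contamination, so VAF equals the
#' mutated-cell fraction).  VAFs that do not exceed `vaf_floor` are set to
#' 0, emulating the failure of multiregional sequencing to detect
#' low-frequency variants.
#'
#' @param state a `bep_state`.
#' @param s number of regions to sample.
#' @param window sampling-window side length (see
#'   [place_sampling_regions()]).
#' @param vaf_floor VAF detection floor (inclusive: a raw VAF equal to the
#'   floor is zeroed).
#' @return A genes x samples VAF matrix with attribute `filtered = TRUE`
#'   and attribute `windows` (ids of the sampled windows).
#' @export
multiregional_profile <- function(state, s = 5L, window = 31L,
                                  vaf_floor = 0.3) {
  regions <- place_sampling_regions(state$params$lattice_side, window)
  npts <- window^2
  occ_count <- vapply(seq_len(nrow(regions)), function(i) {
    sum(state$occ[regions$x0[i]:regions$x1[i],
                  regions$y0[i]:regions$y1[i]] != 0L)
  }, numeric(1))
  eligible <- which(occ_count >= ceiling(npts / 2))
  if (length(eligible) < s) {
    stop(sprintf(
      "only %d of 25 sampling windows are at least half occupied; %d needed",
      length(eligible), s), call. = FALSE)
  }
  take <- eligible[sample.int(length(eligible), s)]
  vaf <- vapply(take, function(i) {
    ids <- state$occ[regions$x0[i]:regions$x1[i],
                     regions$y0[i]:regions$y1[i]]
    ids <- ids[ids != 0L]
    rowMeans(state$gen[, ids, drop = FALSE])
  }, numeric(state$params$n_genes))
  vaf[vaf <= vaf_floor] <- 0
  rownames(vaf) <- gene_ids(state$params)
  colnames(vaf) <- sprintf("s%d", seq_len(s))
  attr(vaf, "windows") <- regions$id[take]
  attr(vaf, "filtered") <- TRUE
  vaf
}

#' Sample a single-cell mutation profile matrix
#'
#' Draws `m` distinct cells uniformly without replacement; columns are
#' their binary genome vectors.
#'
#' @param state a `bep_state`.
#' @param m number of cells to sample.
#' @return Integer 0/1 matrix, genes x `m` cells.
#' @export
single_cell_profile <- function(state, m = 500L) {
  ids <- state$alive_ids
  if (length(ids) < m) {
    stop(sprintf("population (%d) is smaller than the requested sample (%d)",
                 length(ids), m), call. = FALSE)
  }
  take <- ids[sample.int(length(ids), m)]
  g <- state$gen[, take, drop = FALSE]
  colnames(g) <- as.character(take)
  rownames(g) <- gene_ids(state$params)
  g
}
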