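# Readers and writers for the TSV/SEG/BED-like/Newick/config artifacts.
# All tables are tab-separated with a header; genomic coordinates are
# 1-based inclusive throughout.

read_tsv_checked <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop(sprintf("%s %s: missing required column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a multiregional variant table
#'
#' Expects a TSV with columns `case`, `sample`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, `alt_reads`, `depth` (one row per variant per sample; a
#' `vaf` column is accepted and otherwise computed as
#' `alt_reads / depth`).  Rows are assembled into per-case aligned VAF and
#' depth matrices.
#'
#' @param path path to the TSV file.
#' @return Named list (per case) of lists with `vaf`, `depth` (variants x
#'   samples matrices) and `variants` (annotation data frame).
#' @export
read_variant_table <- function(path) {
  tab <- read_tsv_checked(path, c("case", "sample", "chrom", "pos", "ref",
                                  "alt", "alt_reads", "depth"),
                          "variant table")
  bad <- which(is.na(tab$depth) | is.na(tab$alt_reads) |
                 tab$depth < 0 | tab$alt_reads < 0 |
                 tab$alt_reads > tab$depth)
  if (length(bad)) {
    stop("variant table: invalid read counts on data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!"vaf" %in% names(tab)) {
    if (any(tab$depth == 0)) {
      stop("variant table: depth 0 makes the VAF undefined (line(s) ",
           paste(utils::head(which(tab$depth == 0), 5), collapse = ", "),
           ")", call. = FALSE)
    }
    tab$vaf <- tab$alt_reads / tab$depth
  }
  out <- list()
  for (cs in unique(tab$case)) {
    sub <- tab[tab$case == cs, , drop = FALSE]
    vid <- paste(sub$chrom, sub$pos, sub$ref, sub$alt, sep = ":")
    variants <- unique(data.frame(
      variant = vid, chrom = sub$chrom, pos = sub$pos,
      ref = sub$ref, alt = sub$alt,
      context = if ("context" %in% names(sub)) sub$context else
        NA_character_,
      stringsAsFactors = FALSE))
    samples <- unique(sub$sample)
    vaf <- matrix(0, nrow(variants), length(samples),
                  dimnames = list(variants$variant, samples))
    depth <- matrix(0, nrow(variants), length(samples),
                    dimnames = list(variants$variant, samples))
    vaf[cbind(match(vid, variants$variant), match(sub$sample, samples))] <-
      sub$vaf
    depth[cbind(match(vid, variants$variant), match(sub$sample, samples))] <-
      sub$depth
    rownames(variants) <- variants$variant
    out[[as.character(cs)]] <- list(vaf = vaf, depth = depth,
                                    variants = variants)
  }
  out
}

#' Write a multiregional variant table
#'
#' Inverse of [read_variant_table()]: emits one row per variant per
#' sample.
#'
#' @param cases named list as returned by [read_variant_table()].
#' @param path output path.
#' @export
write_variant_table <- function(cases, path) {
  rows <- list()
  for (cs in names(cases)) {
    x <- cases[[cs]]
    for (sm in colnames(x$vaf)) {
      rows[[length(rows) + 1L]] <- data.frame(
        case = cs, sample = sm,
        chrom = x$variants$chrom, pos = x$variants$pos,
        ref = x$variants$ref, alt = x$variants$alt,
        alt_reads = round(x$vaf[, sm] * x$depth[, sm]),
        depth = x$depth[, sm], vaf = x$vaf[, sm],
        stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, rows), path)
}

#' Read a SEG-style segment table
#'
#' Columns `sample`, `chrom`, `start`, `end` (1-based inclusive), `lrr`.
#'
#' @param path path to the TSV file.
#' @return Data frame of segments.
#' @export
read_seg <- function(path) {
  seg <- read_tsv_checked(path, c("sample", "chrom", "start", "end", "lrr"),
                          "segment table")
  if (anyNA(seg$lrr) || any(!is.finite(seg$lrr))) {
    stop("segment table: non-finite LRR values", call. = FALSE)
  }
  if (any(seg$end < seg$start)) {
    stop("segment table: end < start on data line(s) ",
         paste(utils::head(which(seg$end < seg$start), 5), collapse = ", "),
         call. = FALSE)
  }
  seg
}

#' Read a BED-like region table with scale and containment columns
#'
#' Columns `region_id`, `chrom`, `start`, `end`, `scale`
#' (`arm`/`focal`), optional `arm_id`.
#'
#' @param path path to the TSV file.
#' @return Data frame of regions.
#' @export
read_regions <- function(path) {
  reg <- read_tsv_checked(path, c("region_id", "chrom", "start", "end",
                                  "scale"), "region table")
  if (!all(reg$scale %in% c("arm", "focal"))) {
    stop("region table: scale must be 'arm' or 'focal'", call. = FALSE)
  }
  reg
}

#' Read a beta-value (or delta-beta) matrix
#'
#' Probes x samples TSV whose first column holds probe ids.
#'
#' @param path path to the TSV file.
#' @param range admissible value range (use `c(-1, 1)` for delta-beta).
#' @return Numeric matrix with probe rownames.
#' @export
read_beta_matrix <- function(path, range = c(0, 1)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("beta matrix contains missing values", call. = FALSE)
  if (any(m < range[1] | m > range[2])) {
    stop(sprintf("beta matrix values outside [%g, %g]", range[1], range[2]),
         call. = FALSE)
  }
  m
}

#' Write a matrix as TSV with an id column
#'
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_name name of the id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_tsv(df, path)
}

#' Write / read a sample tree in Newick format
#'
#' @param tree a `sample_tree` (or an `ape::phylo`).
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "sample_tree")) {
    writeLines(tree$newick, path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' @rdname write_newick
#' @return `read_newick` returns an `ape::phylo`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read a run configuration file
#'
#' A YAML document whose keys mirror the [bep_params()] arguments; unknown
#' keys are rejected.
#'
#' @param path path to the YAML file.
#' @return A `bep_params` object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(bep_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(bep_params, cfg)
}

#' Write run metadata (resolved parameters, seed, package version)
#'
#' @param params parameter list to echo.
#' @param seed seed used.
#' @param path output path (JSON).
#' @export
write_run_metadata <- function(params, seed, path) {
  meta <- list(
    package = "bepith",
    version = as.character(utils::packageVersion("bepith")),
    seed = seed,
    parameters = unclass(params),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Render an occupancy snapshot (or final state) as a PNG image
#'
#' Cells are colored by PCA-based clone color codes computed from the
#' genomes of the living cells; empty lattice points are white.
#'
#' @param state a `bep_state`, or an occupancy matrix (then cells are a
#'   single color).
#' @param path output PNG path.
#' @export
snapshot_png <- function(state, path) {
  if (inherits(state, "bep_state")) {
    occ <- state$occ
    ids <- state$alive_ids
    cols <- color_code_samples(cell_genomes(state))
    pal <- stats::setNames(cols$hex, cols$sample)
    img <- matrix("#FFFFFF", nrow(occ), ncol(occ))
    img[occ != 0L] <- pal[as.character(occ[occ != 0L])]
  } else {
    occ <- state
    img <- matrix("#FFFFFF", nrow(occ), ncol(occ))
    img[occ != 0L] <- "#B2182B"
  }
  grDevices::png(path, width = ncol(occ), height = nrow(occ))
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1,
                        interpolate = FALSE)
  grDevices::dev.off()
  invisible(path)
}
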