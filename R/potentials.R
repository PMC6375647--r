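#' Construct a distance-binned pairwise potential
#'
#' The potential maps (probe SYBYL type, protein SYBYL type, distance bin)
#' to an energy value (arbitrary units).  Beyond the last bin edge (the
#' cutoff) the energy is zero; pairs absent from the table are zero.
#'
#' @param probe_types Ordered probe (channel) SYBYL codes.
#' @param protein_types Protein SYBYL codes covered by the table.
#' @param bin_edges Strictly increasing distance bin edges (Angstrom),
#'   length `nbin + 1`, starting at the lower bound of the first bin.
#' @param energies Numeric array `(probe, protein_type, bin)`.
#' @return A `pair_potential` object.
#' @export
pair_potential <- function(probe_types, protein_types, bin_edges, energies) {
  stopifnot(all(diff(bin_edges) > 0), length(bin_edges) >= 2)
  energies <- array(energies, dim = c(length(probe_types),
                                      length(protein_types),
                                      length(bin_edges) - 1))
  stopifnot(all(is.finite(energies)))
  structure(list(probe_types = probe_types, protein_types = protein_types,
                 bin_edges = as.numeric(bin_edges), energies = energies,
                 cutoff = bin_edges[length(bin_edges)]),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf("pair_potential: %d probes x %d protein types x %d bins (cutoff %g A)\n",
              length(x$probe_types), length(x$protein_types),
              dim(x$energies)[3], x$cutoff))
  invisible(x)
}

#' Load a pairwise potential table
#'
#' Tab-separated text with a header and columns `probe_type`,
#' `protein_type`, `bin_low`, `bin_high`, `energy`.  The distinct
#' (bin_low, bin_high) pairs must form a contiguous, non-overlapping,
#' increasing set of bins.  Missing (probe, protein type) pairs default to
#' zero with a warning giving their count; an empty table yields an
#' all-zero single-bin potential with a warning.
#'
#' @param path Path to the table.
#' @return A `pair_potential`.
#' @export
load_potential_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("probe_type", "protein_type", "bin_low", "bin_high", "energy")
  if (!all(need %in% names(tab)))
    stopf("potential table must have columns %s", paste(need, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("empty potential table: all energies zero", call. = FALSE)
    return(pair_potential(sybyl_probe_types(), sybyl_probe_types(),
                          c(0, 14.5), 0))
  }
  bins <- unique(tab[, c("bin_low", "bin_high")])
  bins <- bins[order(bins$bin_low), , drop = FALSE]
  if (any(bins$bin_high <= bins$bin_low))
    stopf("potential table: bin_high must exceed bin_low")
  if (nrow(bins) > 1 &&
      any(abs(bins$bin_low[-1] - bins$bin_high[-nrow(bins)]) > 1e-9))
    stopf("potential table: bins must be contiguous and non-overlapping")
  edges <- c(bins$bin_low[1], bins$bin_high)

  probes <- sybyl_probe_types()
  extra <- setdiff(unique(tab$probe_type), probes)
  probes <- c(probes, extra)
  ptypes <- sort(unique(c(tab$protein_type, sybyl_probe_types())))

  e <- array(0, dim = c(length(probes), length(ptypes), nrow(bins)))
  bi <- match(paste(tab$bin_low, tab$bin_high),
              paste(bins$bin_low, bins$bin_high))
  e[cbind(match(tab$probe_type, probes), match(tab$protein_type, ptypes), bi)] <-
    tab$energy

  n_missing <- sum(apply(e == 0, c(1, 2), all))
  if (n_missing > 0)
    warning(sprintf("%d (probe, protein type) pair(s) absent from table; defaulting to 0",
                    n_missing), call. = FALSE)
  pair_potential(probes, ptypes, edges, e)
}

#' Write a pairwise potential as tab-separated text
#'
#' Inverse of [load_potential_table()]; zero entries are kept so the
#' round trip is exact.
#'
#' @param pot A `pair_potential`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_potential_table <- function(pot, path) {
  nb <- dim(pot$energies)[3]
  g <- expand.grid(probe = seq_along(pot$probe_types),
                   ptype = seq_along(pot$protein_types),
                   bin = seq_len(nb))
  out <- data.frame(probe_type = pot$probe_types[g$probe],
                    protein_type = pot$protein_types[g$ptype],
                    bin_low = pot$bin_edges[g$bin],
                    bin_high = pot$bin_edges[g$bin + 1],
                    energy = pot$energies[as.matrix(g)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate the potential for one probe/protein-type pair at a distance
#'
#' @param pot A `pair_potential`.
#' @param probe,ptype SYBYL codes.
#' @param d Distance(s), Angstrom.
#' @return Energy value(s); zero beyond the cutoff or for unknown types.
#' @export
potential_energy <- function(pot, probe, ptype, d) {
  pi_ <- match(probe, pot$probe_types)
  ti <- match(ptype, pot$protein_types)
  if (is.na(pi_)) stopf("unknown probe type '%s'", probe)
  out <- numeric(length(d))
  if (is.na(ti)) return(out)
  inb <- d >= pot$bin_edges[1] & d <= pot$cutoff
  b <- findInterval(d[inb], pot$bin_edges, rightmost.closed = TRUE)
  out[inb] <- pot$energies[cbind(pi_, ti, b)]
  out
}

#' Interaction-energy channels for every grid point
#'
#' Channel `c` at point `p` is the sum over protein atoms `a` within the
#' potential cutoff of `pot(probe_c, sybyl(a), bin(d(p, a)))`.  Points with
#' no atom inside the cutoff get zero in every channel.
#'
#' @param grid A `pocket_grid`.
#' @param protein A SYBYL-typed `typed_structure`.
#' @param pot A `pair_potential`.
#' @return An `energy_grid`: list with the `grid`, the per-point `channels`
#'   matrix (points x probes) and `channel_labels`.
#' @export
energy_channels <- function(grid, protein, pot) {
  atoms <- protein$atoms
  if (anyNA(atoms$sybyl))
    stopf("protein atoms are not SYBYL-typed; run assign_sybyl_types() first")
  pts <- grid$points
  n <- nrow(pts)
  np <- length(pot$probe_types)
  nt <- length(pot$protein_types)
  nb <- dim(pot$energies)[3]

  ti <- match(atoms$sybyl, pot$protein_types)  # NA types contribute zero
  amat <- coords_matrix(atoms)

  ii <- list(); kk <- list()
  chunk <- 4000L
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    d <- cross_dist(pts[s:e, , drop = FALSE], amat)
    hit <- which(d >= pot$bin_edges[1] & d <= pot$cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    tj <- ti[hit[, 2]]
    ok <- !is.na(tj)
    hit <- hit[ok, , drop = FALSE]; tj <- tj[ok]
    if (nrow(hit) == 0) next
    b <- findInterval(d[hit], pot$bin_edges, rightmost.closed = TRUE)
    ii[[length(ii) + 1]] <- hit[, 1] + (s - 1L)
    kk[[length(kk) + 1]] <- tj + (b - 1L) * nt
  }

  channels <- matrix(0, n, np, dimnames = list(NULL, pot$probe_types))
  if (length(ii) > 0) {
    counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(kk), x = 1,
                                   dims = c(n, nt * nb))
    emat <- matrix(pot$energies, nrow = np)  # np x (nt*nb), col = ptype + (bin-1)*nt
    channels[] <- as.matrix(counts %*% t(emat))
  }
  structure(list(grid = grid, channels = channels,
                 channel_labels = pot$probe_types),
            class = "energy_grid")
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("energy_grid: %d points x %d channels\n",
              nrow(x$channels), ncol(x$channels)))
  invisible(x)
}
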