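#' Radial distribution function
#'
#' Standard pair-count g(r) between two species under the minimum-image
#' convention, normalised by the ideal-gas shell density; for identical
#' species each unordered pair is counted once and self-pairs are excluded.
#'
#' @param traj a [trajectory()].
#' @param species_a,species_b species labels.
#' @param r_max histogram range, Å (must not exceed half the smallest box
#'   edge).
#' @param dr bin width, Å.
#' @return tibble of class `rdf` with columns `r` (bin centers) and `g`;
#'   attributes `pair`, `n_frames`, `dr`.
#' @export
rdf <- function(traj, species_a, species_b, r_max = NULL, dr = 0.1) {
  box <- traj_box(traj)
  L <- box$edge_lengths
  lim <- min(L) / 2
  if (is.null(r_max)) r_max <- lim
  if (r_max > lim + 1e-9) {
    abort(sprintf("r_max = %g Å exceeds half the smallest box edge (%g Å)",
                  r_max, lim))
  }
  same <- identical(species_a, species_b)
  frames <- unique(traj$frame)
  nbins <- ceiling(r_max / dr - 1e-9)
  counts <- numeric(nbins)
  na <- nb <- 0
  for (f in frames) {
    fp <- frame_positions(traj, f)
    pos <- wrap_positions(fp$pos, box)
    ia <- which(fp$species == species_a)
    ib <- which(fp$species == species_b)
    na <- length(ia)
    nb <- length(ib)
    if (!na || !nb) abort("species not present in trajectory")
    counts <- counts + cpp_pair_hist(pos, ia, if (same) ia else ib, same, L,
                                     r_max, dr)
  }
  V <- prod(L)
  edges <- seq(0, nbins) * dr
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  npairs <- if (same) na * (na - 1) / 2 else na * nb
  ideal <- npairs * shell / V * length(frames)
  out <- tibble(r = (edges[-1] + edges[-(nbins + 1)]) / 2, g = counts / ideal)
  structure(out, pair = c(species_a, species_b), n_frames = length(frames),
            dr = dr, class = c("rdf", class(tibble())))
}

#' Difference of two radial distribution functions
#'
#' g1 - g2 on the overlap of the two grids; when bin centers are offset the
#' second curve is linearly interpolated onto the first grid.  Non-overlap
#' is trimmed with a warning; bin widths must match.
#'
#' @param g1,g2 `rdf` objects (or tibbles with `r`, `g`).
#' @return tibble with `r` and `delta_g` on the common grid.
#' @export
delta_rdf <- function(g1, g2) {
  d1 <- attr(g1, "dr")
  d2 <- attr(g2, "dr")
  if (!is.null(d1) && !is.null(d2) && abs(d1 - d2) > 1e-9) {
    abort("bin widths differ between the two g(r)")
  }
  lo <- max(min(g1$r), min(g2$r))
  hi <- min(max(g1$r), max(g2$r))
  if (lo > hi) {
    warn("g(r) ranges do not overlap; empty difference")
    return(tibble(r = numeric(0), delta_g = numeric(0)))
  }
  keep <- g1$r >= lo - 1e-9 & g1$r <= hi + 1e-9
  if (!all(keep) || any(g2$r < lo - 1e-9 | g2$r > hi + 1e-9)) {
    warn("non-overlapping range trimmed in delta_rdf")
  }
  r <- g1$r[keep]
  g2i <- approx(g2$r, g2$g, xout = r, rule = 2)$y
  tibble(r = r, delta_g = g1$g[keep] - g2i)
}

#' Sharp-cutoff coordination number
#'
#' Mean number of neighbour-species atoms within `cutoff` of each
#' center-species atom (minimum image, closed boundary: a neighbour exactly
#' at the cutoff counts), averaged over frames, with a block-average
#' standard error.
#'
#' @param traj a [trajectory()].
#' @param center_species,neighbor_species labels.
#' @param cutoff Å.
#' @param blocks number of blocks for the standard error.
#' @return one-row tibble: `mean`, `se`, `n_frames`.
#' @export
coordination_sharp <- function(traj, center_species, neighbor_species, cutoff,
                               blocks = 5) {
  box <- traj_box(traj)
  frames <- unique(traj$frame)
  per_frame <- vapply(frames, function(f) {
    fp <- frame_positions(traj, f)
    ia <- which(fp$species == center_species)
    ib <- which(fp$species == neighbor_species)
    if (!length(ia) || !length(ib)) abort("species not present in trajectory")
    cnt <- 0
    for (i in ia) {
      d <- minimum_image_displacement(
        matrix(fp$pos[i, ], length(ib), 3, byrow = TRUE),
        fp$pos[ib, , drop = FALSE], box)
      d <- matrix(d, ncol = 3)
      rij <- sqrt(rowSums(d^2))
      cnt <- cnt + sum(rij <= cutoff & ib != i)
    }
    cnt / length(ia)
  }, 1.0)
  m <- mean(per_frame)
  se <- if (length(frames) >= blocks && blocks >= 2) {
    bl <- split(per_frame, cut(seq_along(per_frame), blocks, labels = FALSE))
    bm <- vapply(bl, mean, 1.0)
    sd(bm) / sqrt(length(bm))
  } else NA_real_
  tibble(mean = m, se = se, n_frames = length(frames))
}

#' Cubic switching function
#'
#' Smooth, C^1 replacement for a sharp cutoff: weight 1 for `d <= D0`, 0 for
#' `d >= Dmax`, and `(y - 1)^2 (1 + 2 y)` with `y = (d - D0)/(Dmax - D0)`
#' in between (0.5 at the midpoint); the derivative vanishes at both ends,
#' so coordination numbers built from it are continuous and differentiable
#' along any continuous particle path.
#'
#' @param d distance(s), Å.
#' @param spec a [switch_spec()] (or `D0` and `Dmax` directly).
#' @param D0,Dmax switching bounds, Å, used when `spec` is missing.
#' @return weights in `[0, 1]`.
#' @examples
#' switch_cubic(c(2.5, 3.125, 3.75), switch_spec(2.5, 3.75)) # 1, 0.5, 0
#' @export
switch_cubic <- function(d, spec = NULL, D0 = NULL, Dmax = NULL) {
  if (!is.null(spec)) {
    D0 <- spec$D0
    Dmax <- spec$Dmax
  }
  y <- (d - D0) / (Dmax - D0)
  w <- (y - 1)^2 * (1 + 2 * y)
  w[d <= D0] <- 1
  w[d >= Dmax] <- 0
  w
}

#' @rdname switch_cubic
#' @export
switch_spec <- function(D0, Dmax) {
  if (!(0 <= D0 && D0 < Dmax)) abort("need 0 <= D0 < Dmax")
  structure(list(D0 = D0, Dmax = Dmax), class = "switch_spec")
}

#' Smooth coordination number of a frame
#'
#' Sum of cubic-switch weights over neighbour atoms for each center atom --
#' the collective-variable form of the coordination number.
#'
#' @inheritParams coordination_sharp
#' @param spec a [switch_spec()].
#' @return numeric vector, one smooth count per center atom per frame
#'   (concatenated over frames).
#' @export
coordination_smooth <- function(traj, center_species, neighbor_species, spec) {
  box <- traj_box(traj)
  unlist(lapply(unique(traj$frame), function(f) {
    fp <- frame_positions(traj, f)
    ia <- which(fp$species == center_species)
    ib <- which(fp$species == neighbor_species)
    vapply(ia, function(i) {
      jb <- ib[ib != i]
      d <- matrix(minimum_image_displacement(
        matrix(fp$pos[i, ], length(jb), 3, byrow = TRUE),
        fp$pos[jb, , drop = FALSE], box), ncol = 3)
      sum(switch_cubic(sqrt(rowSums(d^2)), spec))
    }, 1.0)
  }))
}

#' Interfacial electron-density profile
#'
#' Weighted sum of per-species histograms of the nuclear density along z:
#' each nucleus contributes its electron count (O 8, H 1, C 6, Ca 20) to its
#' z bin.  The origin is the mean height of the topmost Ca layer (Ca z
#' values clustered with a `linkage` Å gap threshold), so heights are
#' reported relative to the outermost cation plane.  The profile conserves
#' electrons exactly: `sum(electrons) = n_frames^-1 * sum_i weight_i` per
#' frame, and `integral(value dz) * lateral area = total electrons`.
#'
#' @param traj a [trajectory()].
#' @param electrons named electron counts per species.
#' @param bin_width z bin width, Å.
#' @param origin `"ca_top"` (default) or `"zero"`.
#' @param linkage gap threshold (Å) for the Ca layer clustering.
#' @param smooth_sigma optional Gaussian smoothing of the profile (Å);
#'   total electrons are preserved.
#' @return tibble of class `density_profile` with `z` (bin centers, Å),
#'   `electrons` (e per bin per frame) and `value` (e/Å^3); attributes
#'   `origin_z`, `lateral_area`, `bin_width`, `weights`.
#' @export
electron_density_profile <- function(traj,
                                     electrons = c(O = 8, H = 1, C = 6, Ca = 20),
                                     bin_width = 0.1,
                                     origin = c("ca_top", "zero"),
                                     linkage = 1.0, smooth_sigma = 0) {
  origin <- match.arg(origin)
  box <- traj_box(traj)
  area <- box$edge_lengths[1] * box$edge_lengths[2]
  nf <- n_frames(traj)
  unknown <- setdiff(unique(traj$species), names(electrons))
  if (length(unknown)) {
    abort(sprintf("no electron count for species: %s",
                  paste(unknown, collapse = ", ")))
  }
  z0 <- 0
  if (origin == "ca_top") {
    caz <- traj$z[traj$species == "Ca"]
    if (!length(caz)) abort("no Ca present but Ca-layer origin requested")
    zs <- sort(caz, decreasing = TRUE)
    gap <- which(-diff(zs) > linkage)
    top <- if (length(gap)) zs[seq_len(gap[1])] else zs
    z0 <- mean(top)
  }
  zrel <- traj$z - z0
  w <- unname(electrons[traj$species])
  lo <- floor(min(zrel) / bin_width) * bin_width
  hi <- ceiling(max(zrel) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  idx <- findInterval(zrel, edges, rightmost.closed = TRUE)
  ebin <- vapply(split(w, factor(idx, levels = seq_len(length(edges) - 1))),
                 sum, 1.0) / nf
  total <- sum(ebin)
  if (smooth_sigma > 0) {
    half <- ceiling(4 * smooth_sigma / bin_width)
    kern <- exp(-0.5 * ((-half:half) * bin_width / smooth_sigma)^2)
    kern <- kern / sum(kern)
    sm <- stats::filter(c(rep(0, half), ebin, rep(0, half)), kern, sides = 2)
    ebin <- as.numeric(sm[(half + 1):(half + length(ebin))])
    ebin[is.na(ebin)] <- 0
    ebin <- ebin * total / sum(ebin) # conserve electrons exactly
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- tibble(z = centers, electrons = unname(ebin),
                value = unname(ebin) / (bin_width * area))
  structure(out, origin_z = z0, lateral_area = area, bin_width = bin_width,
            weights = electrons,
            class = c("density_profile", class(tibble())))
}
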