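#' Locate free-energy basins on a grid
#'
#' Finds local minima of the visited region: bins whose free energy is no
#' higher than every visited neighbour within a Chebyshev radius of
#' `radius` bins.  Plateau ties are resolved to the lowest linear (row)
#' index and flagged.  A constant surface yields no basins and a warning.
#'
#' @param fes a [fes_grid()] (1D or 2D).
#' @param radius neighbourhood radius in bins.
#' @return tibble with the axis coordinates of each basin, its `free_energy`
#'   (depth), row index `bin` and a `tie` flag, sorted by depth.
#' @export
locate_basins <- function(fes, radius = 1) {
  axn <- fes_axis_names(fes)
  nb <- fes_nbins(fes)
  vals <- fes$free_energy
  vis <- fes$visited
  nd <- length(nb)
  # row index -> multi-index (last axis fastest)
  lin_of <- function(ix) {
    if (nd == 1) ix[[1]] else (ix[[1]] - 1L) * nb[2] + ix[[2]]
  }
  n <- nrow(fes)
  is_min <- rep(FALSE, n)
  tie <- rep(FALSE, n)
  offs <- as.matrix(do.call(expand.grid,
                            rep(list(seq(-radius, radius)), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (i in seq_len(n)) {
    if (!vis[i]) next
    if (nd == 1) mi <- c(i) else mi <- c((i - 1L) %/% nb[2] + 1L,
                                         (i - 1L) %% nb[2] + 1L)
    ok <- TRUE
    tied <- FALSE
    for (o in seq_len(nrow(offs))) {
      nbix <- mi + offs[o, ]
      if (any(nbix < 1) || any(nbix > nb)) next
      j <- lin_of(as.list(nbix))
      if (!vis[j]) next
      if (vals[j] < vals[i]) {
        ok <- FALSE
        break
      }
      if (vals[j] == vals[i]) {
        tied <- TRUE
        if (j < i) { # plateau: keep only the lowest-index bin
          ok <- FALSE
          break
        }
      }
    }
    is_min[i] <- ok
    tie[i] <- ok && tied
  }
  if (all(vis) && length(unique(vals[vis])) == 1) {
    warn("constant surface: no basins")
    is_min[] <- FALSE
  }
  out <- fes[is_min, c(axn, "free_energy")]
  out <- as_tibble(out)
  out$bin <- which(is_min)
  out$tie <- tie[is_min]
  out[order(out$free_energy), ]
}

# neighbours of row i under 4-connectivity (2-connectivity in 1D)
grid_neighbours <- function(i, nb) {
  nd <- length(nb)
  if (nd == 1) {
    res <- c(i - 1L, i + 1L)
    return(res[res >= 1L & res <= nb])
  }
  r <- (i - 1L) %/% nb[2] + 1L
  c2 <- (i - 1L) %% nb[2] + 1L
  out <- integer(0)
  if (r > 1L) out <- c(out, i - nb[2])
  if (r < nb[1]) out <- c(out, i + nb[2])
  if (c2 > 1L) out <- c(out, i - 1L)
  if (c2 < nb[2]) out <- c(out, i + 1L)
  out
}

#' Minimax barrier between two regions of a free-energy grid
#'
#' The pass value is the minimum over 4-connected grid paths from region A
#' to region B of the maximum free energy along the path, computed exactly
#' by flooding bins in order of increasing free energy (union-find); the
#' barrier is the pass value minus the minimum free energy over A.  If the
#' regions are not connected within the visited region the barrier is
#' infinite and flagged.
#'
#' @param fes a [fes_grid()] (1D or 2D).
#' @param from,to logical vectors over rows of `fes` (or row indices)
#'   defining the two states; both must intersect the visited region.
#' @return list with `barrier` (kJ/mol), `pass_value`, `pass_bin`, `path`
#'   (row indices of one minimax path, `NULL` when disconnected) and
#'   `connected`.
#' @export
minimax_barrier <- function(fes, from, to) {
  n <- nrow(fes)
  as_set <- function(x) {
    if (is.logical(x)) which(x) else as.integer(x)
  }
  A <- intersect(as_set(from), which(fes$visited))
  B <- intersect(as_set(to), which(fes$visited))
  if (!length(A) || !length(B)) abort("both regions must intersect the visited region")
  fa_min <- min(fes$free_energy[A])
  if (length(intersect(A, B))) {
    return(list(barrier = 0, pass_value = fa_min, pass_bin = A[which.min(fes$free_energy[A])],
                path = intersect(A, B)[1], connected = TRUE))
  }
  nb <- fes_nbins(fes)
  vals <- fes$free_energy
  ord <- order(vals)
  ord <- ord[fes$visited[ord]]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  hasA <- rep(FALSE, n)
  hasB <- rep(FALSE, n)
  inA <- rep(FALSE, n)
  inB <- rep(FALSE, n)
  inA[A] <- TRUE
  inB[B] <- TRUE
  added <- rep(FALSE, n)
  pass_bin <- NA_integer_
  for (i in ord) {
    added[i] <- TRUE
    ri <- find(i)
    hasA[ri] <- hasA[ri] || inA[i]
    hasB[ri] <- hasB[ri] || inB[i]
    for (j in grid_neighbours(i, nb)) {
      if (!added[j]) next
      rj <- find(j)
      ri <- find(i)
      if (ri != rj) {
        parent[rj] <- ri
        hasA[ri] <- hasA[ri] || hasA[rj]
        hasB[ri] <- hasB[ri] || hasB[rj]
      }
    }
    ri <- find(i)
    if (hasA[ri] && hasB[ri]) {
      pass_bin <- i
      break
    }
  }
  if (is.na(pass_bin)) {
    warn("regions are disconnected within the visited region: infinite barrier")
    return(list(barrier = Inf, pass_value = Inf, pass_bin = NA_integer_,
                path = NULL, connected = FALSE))
  }
  pass_value <- vals[pass_bin]
  # reconstruct one path through bins <= pass_value (BFS from A to B)
  allow <- fes$visited & vals <= pass_value + 1e-12
  prev <- rep(NA_integer_, n)
  queue <- A[allow[A]]
  seen <- rep(FALSE, n)
  seen[queue] <- TRUE
  path <- NULL
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    if (inB[i]) {
      path <- i
      while (!is.na(prev[i])) {
        i <- prev[i]
        path <- c(i, path)
      }
      break
    }
    for (j in grid_neighbours(i, nb)) {
      if (allow[j] && !seen[j]) {
        seen[j] <- TRUE
        prev[j] <- i
        queue <- c(queue, j)
      }
    }
  }
  list(barrier = pass_value - fa_min, pass_value = pass_value,
       pass_bin = pass_bin, path = path, connected = TRUE)
}

#' Free-energy difference between two regions
#'
#' `DeltaF = -kB T log( sum_B exp(-beta F) / sum_A exp(-beta F) )` over
#' visited bins (bin volumes are uniform on a regular grid and cancel).
#'
#' @inheritParams minimax_barrier
#' @param thermo a [thermo_state()] or temperature (K).
#' @return `DeltaF` in kJ/mol (B relative to A; negative means B is more
#'   stable).
#' @export
state_free_energy_difference <- function(fes, from, to, thermo = thermo_state()) {
  thermo <- as_thermo(thermo)
  as_set <- function(x) if (is.logical(x)) which(x) else as.integer(x)
  A <- intersect(as_set(from), which(fes$visited))
  B <- intersect(as_set(to), which(fes$visited))
  if (!length(A) || !length(B)) abort("both regions must intersect the visited region")
  lw <- function(ix) {
    f <- fes$free_energy[ix]
    m <- min(f)
    -thermo$beta * m + log(sum(exp(-thermo$beta * (f - m))))
  }
  -thermo$kt * (lw(B) - lw(A))
}
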