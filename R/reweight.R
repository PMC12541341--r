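#' Reweight biased samples onto a free-energy grid
#'
#' Umbrella-sampling-type reweighting of a quasi-statically biased run: each
#' sample enters the histogram with weight `exp(beta V)` where `V` is the
#' total bias acting on it (adaptive bias plus, by default, wall energy), and
#' the free energy of bin s is `F(s) = -kB T log` of the weighted mass.  The
#' reweighting axes need not coincide with the biased CVs -- any recorded
#' column can be gridded.  Adding a constant to the bias changes no value
#' (gauge invariance); the result is minimum-subtracted and unvisited bins
#' are flagged `NA`, never zero-filled.
#'
#' @param table a CV tibble (see [cv_table()]) with `bias` (kJ/mol; may be
#'   zero) and `wall` columns.
#' @param cv character vector of column names to grid (1 or 2 axes).
#' @param grid named list: for each axis `c(min, max, nbins)`.
#' @param thermo a [thermo_state()] (or temperature in K).
#' @param include_wall include the wall energy in the reweighting bias
#'   (default TRUE; walls are part of the applied bias).
#' @param burnin fraction of initial rows to drop before reweighting, for
#'   runs whose bias was still filling in (default 0).
#' @return a [fes_grid()]; attribute `n_dropped` counts samples outside the
#'   grid.
#' @export
reweight_fes <- function(table, cv, grid, thermo = thermo_state(),
                         include_wall = TRUE, burnin = 0) {
  thermo <- as_thermo(thermo)
  stopifnot(length(cv) %in% 1:2, all(cv %in% names(table)))
  if (!"bias" %in% names(table)) abort("`table` must have a `bias` column")
  if (burnin > 0) {
    table <- table[-seq_len(floor(burnin * nrow(table))), , drop = FALSE]
  }
  axes <- lapply(cv, function(nm) {
    g <- grid[[nm]]
    if (is.null(g) || length(g) != 3) {
      abort(sprintf("`grid` must supply c(min, max, nbins) for axis '%s'", nm))
    }
    list(name = nm, edges = seq(g[1], g[2], length.out = g[3] + 1L))
  })
  v <- table$bias
  if (include_wall && "wall" %in% names(table)) v <- v + table$wall
  w <- exp(thermo$beta * (v - max(v)))
  idx <- lapply(axes, function(a) {
    i <- findInterval(table[[a$name]], a$edges, rightmost.closed = TRUE)
    i[i < 1 | i > length(a$edges) - 1L] <- NA_integer_
    i
  })
  nb <- vapply(axes, function(a) length(a$edges) - 1L, 1L)
  lin <- if (length(axes) == 1) idx[[1]] else (idx[[1]] - 1L) * nb[2] + idx[[2]]
  keep <- !is.na(lin)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("reweight_fes: %d of %d samples outside the grid",
                   n_dropped, length(lin)))
  }
  nbin_tot <- prod(nb)
  wsum <- unname(vapply(
    split(w[keep], factor(lin[keep], levels = seq_len(nbin_tot))), sum, 1.0))
  cnt <- tabulate(lin[keep], nbins = nbin_tot)
  if (sum(cnt > 0) <= 1) {
    warn("degenerate grid: all samples fall in a single bin")
  }
  fe <- ifelse(wsum > 0, -thermo$kt * log(wsum), NA_real_)
  out <- fes_grid(axes, fe, count = cnt, min_subtracted = TRUE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "thermo") <- thermo
  out
}

#' Average free-energy surfaces over independent runs
#'
#' Reweights each run, fixes the common additive gauge by subtracting each
#' run's Boltzmann-weighted mean free energy over the globally deepest
#' basin's bins (bins of the pooled surface within `basin_window` of its
#' minimum), and returns the bin-wise mean with its standard error.
#'
#' @inheritParams reweight_fes
#' @param tables list of CV tibbles (independent runs).
#' @param basin_window kJ/mol above the pooled minimum defining the anchor
#'   basin (default 2).
#' @return a [fes_grid()] with extra columns `se` (standard error, `NA`
#'   where fewer than 2 runs visited) and `n_runs`.
#' @export
multi_run_fes <- function(tables, cv, grid, thermo = thermo_state(),
                          include_wall = TRUE, burnin = 0, basin_window = 2) {
  thermo <- as_thermo(thermo)
  if (length(tables) < 2) {
    warn("fewer than 2 runs: per-bin spread is undefined")
  }
  fl <- lapply(tables, reweight_fes, cv = cv, grid = grid, thermo = thermo,
               include_wall = include_wall, burnin = burnin)
  fmat <- vapply(fl, function(f) f$free_energy, numeric(nrow(fl[[1]])))
  fmat <- matrix(fmat, nrow = nrow(fl[[1]]))
  cmat <- vapply(fl, function(f) f$count, numeric(nrow(fl[[1]])))
  cmat <- matrix(cmat, nrow = nrow(fl[[1]]))
  pooled <- rowMeans(fmat)
  vis_all <- apply(is.finite(fmat), 1, all)
  if (!any(vis_all)) abort("no bin visited by every run; cannot align gauges")
  anchor <- vis_all & pooled <= min(pooled[vis_all]) + basin_window
  wb <- exp(-thermo$beta * pooled[anchor])
  wb <- wb / sum(wb)
  for (k in seq_len(ncol(fmat))) {
    fmat[, k] <- fmat[, k] - sum(wb * fmat[anchor, k])
  }
  n_runs <- rowSums(is.finite(fmat))
  fmean <- ifelse(n_runs > 0, rowMeans(fmat, na.rm = TRUE), NA_real_)
  fsd <- apply(fmat, 1, sd, na.rm = TRUE)
  se <- ifelse(n_runs >= 2, fsd / sqrt(n_runs), NA_real_)
  out <- fes_grid(fes_axes(fl[[1]]), fmean, count = rowSums(cmat),
                  min_subtracted = TRUE)
  out$se <- se
  out$n_runs <- n_runs
  attr(out, "thermo") <- thermo
  out
}

#' Format a value with uncertainty in the last digit
#'
#' Standard compact notation: the standard error is rounded to one
#' significant digit, the mean to the matching decimal place, and the
#' uncertainty digit is appended in parentheses, e.g. `-8.53(5)`.
#' A zero (or missing) uncertainty is rendered as `(0)` at 3 decimals.
#'
#' @param mean value.
#' @param se standard error (same units).
#' @return character.
#' @examples
#' format_uncertainty(-8.53, 0.05) # "-8.53(5)"
#' @export
format_uncertainty <- function(mean, se) {
  mapply(function(m, s) {
    if (is.na(s) || s <= 0) return(sprintf("%.3f(0)", m))
    expo <- floor(log10(s))
    digit <- round(s / 10^expo)
    if (digit == 10) {
      digit <- 1
      expo <- expo + 1
    }
    dec <- max(0, -expo)
    sprintf("%.*f(%d)", dec, round(m, dec), digit)
  }, mean, se)
}
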