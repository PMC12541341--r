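#' Diffusion coefficient from the Einstein relation
#'
#' Mean squared displacement averaged over particles and multiple time
#' origins (origin spacing at least the fit-window length, limiting origin
#' correlation), with `D = slope/6` fitted over `fit_window` (fractions of
#' the trajectory length, default 10--50%).  The result is reported in
#' 1e-5 cm^2/s (0.1 Å^2/ps).  A log-log slope of the MSD far from 1
#' indicates non-diffusive (e.g. ballistic) motion and is flagged.
#'
#' @param traj an unwrapped [trajectory()].
#' @param species restrict to one species (default: all particles).
#' @param fit_window numeric(2), fractions of the total time.
#' @param n_lags number of lag times evaluated.
#' @return object of class `diffusion_fit`; see [glance.diffusion_fit()],
#'   [tidy.diffusion_fit()], [autoplot.diffusion_fit()].
#' @export
einstein_diffusion <- function(traj, species = NULL,
                               fit_window = c(0.1, 0.5), n_lags = 60) {
  if (traj_wrapped(traj)) {
    warn("trajectory is wrapped; MSD requires unwrapped coordinates")
  }
  arr <- positions_array(traj, species)
  nf <- dim(arr)[3]
  dt <- diff(unique(traj$time)[1:2])
  maxlag <- floor(fit_window[2] * (nf - 1))
  lags <- sort(unique(round(seq(1, maxlag, length.out = n_lags))))
  spacing <- max(1, maxlag)
  msd <- vapply(lags, function(lag) {
    origins <- seq(1, nf - lag, by = spacing)
    tot <- 0
    for (t0 in origins) {
      d <- arr[, , t0 + lag] - arr[, , t0]
      tot <- tot + mean(rowSums(matrix(d, ncol = 3)^2))
    }
    tot / length(origins)
  }, 1.0)
  tb <- tibble(lag_time = lags * dt, msd = msd)
  fit_sel <- tb$lag_time >= fit_window[1] * (nf - 1) * dt
  fit <- lm(msd ~ lag_time, data = tb[fit_sel, ])
  slope <- coef(fit)[["lag_time"]]
  r2 <- summary(fit)$r.squared
  pos <- tb$msd > 0
  expo <- if (sum(pos) >= 3) {
    coef(lm(log(msd) ~ log(lag_time), data = tb[pos, ]))[[2]]
  } else NA_real_
  if (is.finite(expo) && (expo > 1.3 || expo < 0.7)) {
    warn(sprintf(
      "MSD grows as t^%.2f; motion is not diffusive, D estimate unreliable",
      expo))
  }
  D_ang <- max(slope, 0) / 6 # Å^2/ps
  structure(list(D = D_ang / 0.1, # 1e-5 cm^2/s
                 slope = slope, r_squared = r2, msd_exponent = expo,
                 msd = tb, fit_window = fit_window,
                 n_particles = dim(arr)[1]),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g x 1e-5 cm^2/s (r^2 = %.4f, MSD ~ t^%.2f)\n",
              x$D, x$r_squared, x$msd_exponent))
  invisible(x)
}

#' Extrapolate diffusion coefficients to infinite system size
#'
#' Finite-size effects on D scale as 1/L for a periodic cubic box; ordinary
#' least squares of D against 1/L gives the infinite-size intercept.
#'
#' @param D diffusion coefficients (1e-5 cm^2/s), one per box size (or a
#'   data frame with columns `D` and `L`).
#' @param L box edges, Å.
#' @return object of class `fse_fit` with `D_inf`, `slope`, and the input
#'   table; see [glance.fse_fit()].
#' @export
finite_size_extrapolate <- function(D, L = NULL) {
  if (is.data.frame(D)) {
    L <- D$L
    D <- D$D
  }
  if (length(D) < 2) abort("need at least two system sizes")
  fit <- lm(D ~ I(1 / L))
  structure(list(D_inf = coef(fit)[[1]], slope = coef(fit)[[2]],
                 data = tibble(L = L, D = D)),
            class = "fse_fit")
}

#' @export
print.fse_fit <- function(x, ...) {
  cat(sprintf("<fse_fit> D_inf = %.4g (slope %.4g vs 1/L, %d sizes)\n",
              x$D_inf, x$slope, nrow(x$data)))
  invisible(x)
}

# fill FALSE runs shorter than t_star (flanked by TRUE) in a logical vector
fill_short_excursions <- function(b, dt, t_star) {
  if (t_star <= 0 || !any(b)) return(b)
  r <- rle(b)
  k <- which(!r$values & r$lengths * dt < t_star)
  k <- k[k > 1 & k < length(r$values)]
  r$values[k] <- TRUE
  inverse.rle(r)
}

#' Residence time from a bound/unbound indicator
#'
#' Survival-function estimator: S(t) is the probability that a particle
#' bound at a time origin remains continuously bound at t, ignoring
#' excursions shorter than the transient tolerance `t_star`; the residence
#' time tau comes from an exponential fit to S.  This estimator is a
#' convention of this package (survival with transient tolerance), not a
#' reproduction of any specific literature estimator.
#'
#' @param x either a tibble with columns `time` and `bound` (one particle,
#'   as from [two_state_residence_series()]), a logical matrix
#'   (particles x frames), or a [trajectory()] (then `center_species`,
#'   `neighbor_species` and `cutoff` define binding).
#' @param dt time resolution, ps (taken from `x$time` when available).
#' @param t_star transient tolerance, ps (default 2).
#' @param s_floor smallest survival fraction used in the fit.
#' @param center_species,neighbor_species,cutoff binding definition for the
#'   trajectory interface: a neighbour is bound when within `cutoff` of the
#'   (single) center atom.
#' @return object of class `residence_fit` with `tau` (ps; `NA` and a flag
#'   when never bound), the survival curve, and the interval count.
#' @export
residence_time <- function(x, dt = NULL, t_star = 2, s_floor = 0.05,
                           center_species = NULL, neighbor_species = NULL,
                           cutoff = NULL) {
  if (inherits(x, "trajectory")) {
    stopifnot(!is.null(center_species), !is.null(neighbor_species),
              !is.null(cutoff))
    box <- traj_box(x)
    frames <- unique(x$frame)
    dt <- diff(unique(x$time)[1:2])
    ind <- vapply(frames, function(f) {
      fp <- frame_positions(x, f)
      ic <- which(fp$species == center_species)[1]
      ib <- which(fp$species == neighbor_species)
      d <- matrix(minimum_image_displacement(
        matrix(fp$pos[ic, ], length(ib), 3, byrow = TRUE),
        fp$pos[ib, , drop = FALSE], box), ncol = 3)
      sqrt(rowSums(d^2)) <= cutoff
    }, logical(sum(x$species[x$frame == frames[1]] == neighbor_species)))
    mat <- matrix(ind, ncol = length(frames))
  } else if (is.data.frame(x)) {
    if (is.null(dt)) dt <- diff(x$time[1:2])
    mat <- matrix(x$bound, nrow = 1)
  } else {
    mat <- as.matrix(x)
    if (is.null(dt)) abort("`dt` required for a bare indicator matrix")
  }
  # bound-interval lengths (frames), pooled over particles
  lens <- integer(0)
  for (p in seq_len(nrow(mat))) {
    b <- fill_short_excursions(as.logical(mat[p, ]), dt, t_star)
    r <- rle(b)
    lens <- c(lens, r$lengths[r$values])
  }
  if (!length(lens)) {
    warn("never bound: residence time undefined")
    return(structure(list(tau = NA_real_, survival = tibble(),
                          n_intervals = 0L, flag = "never_bound"),
                     class = "residence_fit"))
  }
  kmax <- max(lens) - 1L
  k <- 0:kmax
  surv <- vapply(k, function(kk) sum(pmax(0L, lens - kk)), 1.0)
  S <- surv / surv[1]
  tb <- tibble(t = k * dt, S = S)
  sel <- tb$S >= s_floor & tb$t > 0
  tau <- if (sum(sel) >= 2) {
    -1 / coef(lm(log(S) ~ t, data = tb[sel, ]))[[2]]
  } else {
    mean(lens) * dt # too few points for a fit: mean dwell
  }
  structure(list(tau = tau, survival = tb, n_intervals = length(lens),
                 t_star = t_star, flag = NULL),
            class = "residence_fit")
}

#' @export
print.residence_fit <- function(x, ...) {
  if (is.na(x$tau)) cat("<residence_fit> tau undefined (never bound)\n")
  else cat(sprintf("<residence_fit> tau = %.4g ps (%d intervals)\n",
                   x$tau, x$n_intervals))
  invisible(x)
}

#' Lattice constants from an NPT box-edge series
#'
#' Time-mean of each supercell edge divided by its replication count, with a
#' block-averaged standard error and the compact uncertainty-in-last-digit
#' label (e.g. `4.984(4)`).
#'
#' @param edges data frame with a `time` column and one column per axis, or
#'   a numeric matrix (frames x axes), Å.
#' @param replication integer replication counts per axis (recycled).
#' @param blocks number of blocks for the standard error.
#' @return tibble with `axis`, `constant` (Å), `se`, `label`.
#' @export
lattice_constants <- function(edges, replication = 1, blocks = 10) {
  if (is.data.frame(edges)) {
    edges <- as.matrix(edges[, setdiff(names(edges), "time"), drop = FALSE])
  }
  edges <- as.matrix(edges)
  replication <- rep_len(replication, ncol(edges))
  out <- lapply(seq_len(ncol(edges)), function(k) {
    series <- edges[, k] / replication[k]
    m <- mean(series)
    se <- if (length(series) >= blocks && blocks >= 2) {
      bm <- vapply(split(series, cut(seq_along(series), blocks, labels = FALSE)),
                   mean, 1.0)
      sd(bm) / sqrt(length(bm))
    } else 0
    if (is.na(se)) se <- 0
    tibble(axis = colnames(edges)[k] %||% letters[k], constant = m, se = se,
           label = format_uncertainty(m, se))
  })
  bind_rows(out)
}
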