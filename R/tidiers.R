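#' Tidy and glance methods
#'
#' Broom-style accessors for the package's fitted/result objects.
#'
#' @param x the object.
#' @param ... unused.
#' @name pairfes-tidiers
NULL

#' @rdname pairfes-tidiers
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, slope = x$slope, r_squared = x$r_squared,
         msd_exponent = x$msd_exponent, n_particles = x$n_particles)
}

#' @rdname pairfes-tidiers
#' @export
tidy.diffusion_fit <- function(x, ...) x$msd

#' @rdname pairfes-tidiers
#' @export
glance.fse_fit <- function(x, ...) {
  tibble(D_inf = x$D_inf, slope = x$slope, n_sizes = nrow(x$data))
}

#' @rdname pairfes-tidiers
#' @export
tidy.fse_fit <- function(x, ...) x$data

#' @rdname pairfes-tidiers
#' @export
glance.residence_fit <- function(x, ...) {
  tibble(tau = x$tau, n_intervals = x$n_intervals,
         flagged = !is.null(x$flag))
}

#' @rdname pairfes-tidiers
#' @export
tidy.residence_fit <- function(x, ...) x$survival

#' @rdname pairfes-tidiers
#' @export
glance.assoc_fe <- function(x, ...) {
  tibble(delta_g = as.numeric(x), integral = attr(x, "integral"),
         r_star = attr(x, "r_star"), volume = attr(x, "volume"),
         alignment = attr(x, "alignment"))
}

#' @rdname pairfes-tidiers
#' @export
tidy.fes_grid <- function(x, ...) as_tibble(x)

#' @rdname pairfes-tidiers
#' @export
tidy.radial_pmf <- function(x, ...) as_tibble(x)

#' @rdname pairfes-tidiers
#' @export
glance.opes_bias <- function(x, ...) {
  tibble(n_kernels = nrow(x$kernels), gamma = x$gamma, barrier = x$barrier,
         max_bias = max(x$grid$bias), max_bias_bound = x$max_bias_bound,
         converged = x$converged)
}

#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: free-energy curves and
#' maps, PMFs, radial distribution functions, density profiles and MSD fits.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @name pairfes-autoplot
NULL

#' @rdname pairfes-autoplot
#' @export
autoplot.fes_grid <- function(object, ...) {
  axn <- fes_axis_names(object)
  if (length(axn) == 1) {
    ggplot2::ggplot(object[object$visited, ],
                    ggplot2::aes(x = .data[[axn]], y = .data$free_energy)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = axn, y = "free energy (kJ/mol)")
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data[[axn[1]]], y = .data[[axn[2]]],
                                 fill = .data$free_energy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white") +
      ggplot2::labs(x = axn[1], y = axn[2], fill = "F (kJ/mol)")
  }
}

#' @rdname pairfes-autoplot
#' @export
autoplot.radial_pmf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$W)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "W(r) (kJ/mol)",
                  subtitle = sprintf("alignment: %s", pmf_alignment(object)))
}

#' @rdname pairfes-autoplot
#' @export
autoplot.rdf <- function(object, ...) {
  pair <- attr(object, "pair")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey") +
    ggplot2::labs(x = "r (Å)", y = sprintf("g(r) %s-%s", pair[1], pair[2]))
}

#' @rdname pairfes-autoplot
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "height above top Ca layer (Å)",
                  y = expression(rho[e] ~ (e / ring(A)^3)))
}

#' @rdname pairfes-autoplot
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  ggplot2::ggplot(object$msd, ggplot2::aes(x = .data$lag_time, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         linetype = 2, colour = "red") +
    ggplot2::labs(x = "lag time (ps)", y = expression(MSD ~ (ring(A)^2)))
}

#' @importFrom ggplot2 .data
NULL
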