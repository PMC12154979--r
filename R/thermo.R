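#' Helmholtz free energy per base pair
#'
#' \eqn{f(T) = -\frac{k_B T}{2}\ln(2\pi m k_B T) - \frac{k_B T}{N}\ln Z_c}.
#' The first term is the analytically integrated momentum sector (its only
#' contribution to the specific heat is the constant \eqn{k_B/2} per base
#' pair); the second carries all sequence and crowding dependence through
#' the configurational partition function. Evaluated in the package's
#' internal unit system (eV, Angstrom, K, amu), whose unit constants shift
#' f by terms linear in T and T ln T only — invisible to the specific-heat
#' peak.
#'
#' @inheritParams compute_partition
#' @param temperature temperature(s) in K; vectorised.
#' @return Numeric vector of free energies (eV per base pair).
#' @export
free_energy <- function(duplex, depths = NULL, params = pbd_params(),
                        temperature, ctx = NULL) {
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  if (is.null(depths)) depths <- base_depths(duplex, params)
  if (is.null(ctx)) ctx <- ti_context(params)
  widths <- site_morse_widths(duplex, params)
  logZ <- ti_logZ_batch(ctx, matrix(depths, ncol = 1), widths, temperature)[, 1]
  kB <- params$k_B
  -0.5 * kB * temperature * log(2 * pi * params$m * kB * temperature) -
    kB * temperature * logZ / duplex$n
}

#' Specific heat from the free energy
#'
#' \eqn{C_v = -T\, \partial^2 f / \partial T^2}, evaluated by a central
#' second difference with stencil half-width \code{dT} around each
#' requested temperature. By default reported in units of \eqn{k_B} per
#' base pair; \code{units = "eV"} gives raw eV/K.
#'
#' @inheritParams free_energy
#' @param t_grid temperatures (K) at which to evaluate Cv.
#' @param dT finite-difference step (K); a step above 1 K is allowed but
#'   draws a warning because the peak region is only a few K wide.
#' @param units \code{"kB"} (default) or \code{"eV"}.
#' @return Numeric vector of Cv values on \code{t_grid}.
#' @export
specific_heat <- function(duplex, depths = NULL, params = pbd_params(),
                          t_grid, dT = 0.1, units = c("kB", "eV"),
                          ctx = NULL) {
  units <- match.arg(units)
  if (dT <= 0) stop("dT must be > 0", call. = FALSE)
  if (dT > 1) warning("dT = ", dT, " K is coarse for a melting peak; ",
                      "consider dT <= 1")
  if (is.null(ctx)) ctx <- ti_context(params)
  tt <- c(t_grid - dT, t_grid, t_grid + dT)
  f <- free_energy(duplex, depths, params, tt, ctx = ctx)
  m <- length(t_grid)
  cv <- -t_grid * (f[1:m] - 2 * f[(m + 1):(2 * m)] + f[(2 * m + 1):(3 * m)]) /
    dT^2
  if (units == "kB") cv / params$k_B else cv
}

# Cv (kB units) on a uniformly spaced fine grid directly from a free-energy
# matrix (temps x C); interior points only.
cv_from_f <- function(temps, fmat, k_B) {
  m <- length(temps)
  dT <- temps[2] - temps[1]
  i <- 2:(m - 1)
  cv <- -(temps[i] * (fmat[i - 1, , drop = FALSE] -
                        2 * fmat[i, , drop = FALSE] +
                        fmat[i + 1, , drop = FALSE])) / dT^2 / k_B
  list(temps = temps[i], cv = cv)
}

#' Melting temperature from a specific-heat curve
#'
#' Tm is the temperature of the global maximum of \eqn{C_v(T)}, refined by
#' a three-point parabolic fit through the discrete peak and its
#' neighbours. Ties between equal discrete maxima break toward lower T. A
#' maximum sitting on the first or last grid point is an error: widen the
#' scan range.
#'
#' @param temperatures increasing temperature grid (K).
#' @param cv specific-heat values on that grid.
#' @return Refined Tm (K).
#' @examples
#' tt <- seq(300, 320, 0.5)
#' melting_temperature(tt, exp(-(tt - 310)^2))  # 310
#' @export
melting_temperature <- function(temperatures, cv) {
  stopifnot(length(temperatures) == length(cv), length(cv) >= 3)
  i <- which(cv == max(cv))[1]
  if (i == 1L || i == length(cv)) {
    stop("specific-heat maximum lies on the scan boundary (T = ",
         temperatures[i], " K); widen the temperature range", call. = FALSE)
  }
  parabolic_peak(temperatures[(i - 1):(i + 1)], cv[(i - 1):(i + 1)])
}

# Vertex of the parabola through three equally spaced (T, Cv) points;
# falls back to the middle point when the stencil is not concave.
parabolic_peak <- function(t3, c3) {
  h <- (t3[3] - t3[1]) / 2
  d2 <- c3[1] - 2 * c3[2] + c3[3]
  if (d2 >= 0) return(t3[2])
  t3[2] + h * (c3[1] - c3[3]) / (2 * d2)
}

#' Full melting scan of one duplex
#'
#' Computes the temperature dependence of the free energy, specific heat
#' and fraction of open base pairs, and extracts the melting temperature.
#' The scan is two-stage: a coarse pass over \code{t_range} brackets the
#' specific-heat peak, then a fine pass (step \code{fine_step}) in a
#' \code{± window} K window refines Tm with parabolic interpolation.
#'
#' @param duplex a \code{pbd_duplex}.
#' @param crowders optional \code{crowder_config}.
#' @param params a [pbd_params()] object.
#' @param t_range length-2 scan range (K), default 200-400 K.
#' @param coarse_step coarse grid step (K).
#' @param fine_step fine grid step (K) used both as the Cv stencil and the
#'   refinement grid.
#' @param window half-width (K) of the fine window around the coarse peak.
#' @param phi compute the open fraction along the coarse grid? (adds one
#'   forward/backward contraction per temperature).
#' @return Object of class \code{melting_profile}: data frame
#'   \code{profile} with columns \code{temperature, free_energy, cv, phi},
#'   scalar \code{tm}, plus the inputs echoed (\code{duplex},
#'   \code{crowders}, \code{params}).
#' @examples
#' \donttest{
#' d <- parse_duplex("GGGAGAAG")
#' mp <- melting_scan(d, crowder_config(c(2, 7, 8), 1.5))
#' mp$tm
#' }
#' @export
melting_scan <- function(duplex, crowders = NULL, params = pbd_params(),
                         t_range = c(200, 400), coarse_step = 1,
                         fine_step = 0.1, window = 10, phi = TRUE) {
  stopifnot(length(t_range) == 2, t_range[1] < t_range[2])
  ctx <- ti_context(params)
  depths <- effective_depths(duplex, crowders, params)
  widths <- site_morse_widths(duplex, params)
  dmat <- matrix(depths, ncol = 1)

  coarse <- seq(t_range[1], t_range[2], by = coarse_step)
  tt <- c(coarse - fine_step, coarse, coarse + fine_step)
  fall <- ti_f_per_bp(ctx, dmat, widths, tt, duplex$n)
  m <- length(coarse)
  f_c <- fall[(m + 1):(2 * m), 1]
  cv_c <- -coarse * (fall[1:m, 1] - 2 * f_c + fall[(2 * m + 1):(3 * m), 1]) /
    fine_step^2 / params$k_B

  ipk <- which.max(cv_c)
  if (ipk == 1L || ipk == m) {
    stop("specific-heat maximum at the edge of t_range; widen the range",
         call. = FALSE)
  }
  fine <- seq(max(t_range[1], coarse[ipk] - window),
              min(t_range[2], coarse[ipk] + window), by = fine_step)
  ffine <- ti_f_per_bp(ctx, dmat, widths, fine, duplex$n)
  cvf <- cv_from_f(fine, ffine, params$k_B)
  tm <- melting_temperature(cvf$temps, cvf$cv[, 1])

  phi_c <- if (phi) {
    vapply(coarse, function(T) {
      fraction_open(duplex, depths, params, T, ctx = ctx)
    }, numeric(1))
  } else {
    rep(NA_real_, m)
  }

  structure(list(
    profile = data.frame(temperature = coarse, free_energy = f_c,
                         cv = cv_c, phi = phi_c),
    fine = data.frame(temperature = cvf$temps, cv = cvf$cv[, 1]),
    tm = tm,
    duplex = duplex, crowders = crowders, params = params,
    settings = list(t_range = t_range, coarse_step = coarse_step,
                    fine_step = fine_step, window = window)
  ), class = "melting_profile")
}

# free energy per bp for a depth matrix over a temperature vector
ti_f_per_bp <- function(ctx, dmat, widths, temps, N) {
  logZ <- ti_logZ_batch(ctx, dmat, widths, temps)
  kB <- ctx$params$k_B
  mom <- -0.5 * kB * temps * log(2 * pi * ctx$params$m * kB * temps)
  sweep(-kB * temps * logZ / N, 1, mom, "+")
}

#' @export
print.melting_profile <- function(x, ...) {
  cr <- if (is.null(x$crowders) || length(x$crowders$sites) == 0) {
    "uncrowded"
  } else {
    paste(sprintf("%d:%g", x$crowders$sites, x$crowders$alpha), collapse = ",")
  }
  cat(sprintf("Melting profile of '%s' (%d bp, %s)\n", x$duplex$label,
              x$duplex$n, cr))
  cat(sprintf("  scan %g-%g K; Tm = %.2f K (Cv peak)\n",
              x$settings$t_range[1], x$settings$t_range[2], x$tm))
  if (!all(is.na(x$profile$phi))) {
    i <- which.min(abs(x$profile$phi - 0.5))
    cat(sprintf("  phi = 0.5 near %g K\n", x$profile$temperature[i]))
  }
  invisible(x)
}

#' Melting temperatures for a batch of crowder configurations
#'
#' Computes Tm for every configuration in \code{configs} on a shared
#' temperature grid, reusing the stacking kernel across configurations
#' (it depends only on temperature, not on crowder placement). This is the
#' engine behind the exhaustive placement scan: all
#' \code{choose(8, 3) = 56} placements of three alpha = 1.5 crowders on an
#' 8-bp duplex run in one call.
#'
#' @param duplex a \code{pbd_duplex}.
#' @param configs list of \code{crowder_config} objects, e.g. from
#'   [enumerate_crowder_configs()].
#' @param params a [pbd_params()] object.
#' @param t_range scan range (K) containing every peak.
#' @param coarse_step,fine_step,window as in [melting_scan()].
#' @return A data frame with one row per configuration: \code{config}
#'   (compact site list), \code{sites}, \code{alpha}, \code{tm}. The mean
#'   Tm is attached as attribute \code{"mean_tm"}.
#' @export
scan_crowder_configs <- function(duplex, configs, params = pbd_params(),
                                 t_range = c(250, 350), coarse_step = 1,
                                 fine_step = 0.1, window = 3) {
  stopifnot(is.list(configs), length(configs) >= 1)
  ctx <- ti_context(params)
  widths <- site_morse_widths(duplex, params)
  dmat <- vapply(configs, function(cc) effective_depths(duplex, cc, params),
                 numeric(duplex$n))

  coarse <- seq(t_range[1], t_range[2], by = coarse_step)
  fcoarse <- ti_f_per_bp(ctx, dmat, widths, coarse, duplex$n)
  cvc <- cv_from_f(coarse, fcoarse, params$k_B)
  ipk <- apply(cvc$cv, 2, which.max)
  if (any(ipk == 1L) || any(ipk == length(cvc$temps))) {
    stop("a specific-heat peak lies at the edge of t_range; widen it",
         call. = FALSE)
  }
  tpk <- cvc$temps[ipk]

  fine <- seq(max(t_range[1], min(tpk) - window),
              min(t_range[2], max(tpk) + window), by = fine_step)
  ffine <- ti_f_per_bp(ctx, dmat, widths, fine, duplex$n)
  cvf <- cv_from_f(fine, ffine, params$k_B)
  tms <- vapply(seq_along(configs), function(j) {
    melting_temperature(cvf$temps, cvf$cv[, j])
  }, numeric(1))

  out <- data.frame(
    config = vapply(configs, function(cc) {
      paste(cc$sites, collapse = ",")
    }, character(1)),
    alpha = vapply(configs, function(cc) {
      paste(unique(cc$alpha), collapse = ",")
    }, character(1)),
    tm = tms,
    stringsAsFactors = FALSE
  )
  attr(out, "mean_tm") <- mean(tms)
  out
}
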