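#' Morse on-site potential
#'
#' Hydrogen-bond potential of a base pair as a function of the stretching
#' coordinate: \eqn{V_M(y) = D (e^{-a y} - 1)^2}. The minimum (0) sits at
#' the closed equilibrium y = 0; the potential approaches the dissociation
#' plateau D as y grows and rises steeply (repulsive wall) for y < 0.
#'
#' @param y displacement from equilibrium (Angstrom); vectorised.
#' @param D well depth (eV).
#' @param a inverse well width (1/Angstrom).
#' @return Energy in eV, same length as \code{y}.
#' @examples
#' morse(0, 0.0395, 4.2)    # 0 at equilibrium
#' morse(1.0, 0.0395, 4.2)  # ~ 0.038324 eV, nearly dissociated
#' @export
morse <- function(y, D, a) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  D * (exp(-a * y) - 1)^2
}

#' Anharmonic stacking potential
#'
#' Nearest-neighbour stacking interaction of the PBD model:
#' \eqn{V_s(y_n, y_{n-1}) = (\kappa/2)(y_n - y_{n-1})^2
#' [1 + \rho e^{-b (y_n + y_{n-1})}]}. The exponential factor stiffens the
#' coupling while both pairs are closed and relaxes it once either opens,
#' which is what sharpens the melting transition. Symmetric in its two
#' displacement arguments.
#'
#' @param y_n,y_prev displacements of adjacent base pairs (Angstrom);
#'   vectorised (recycled to common length).
#' @param params a [pbd_params()] object supplying kappa, rho, b.
#' @return Energy in eV.
#' @examples
#' p <- pbd_params()
#' stacking(1.0, 0.0, p)  # ~ 0.036141 eV
#' stacking(3, 3, p)      # 0: no relative displacement
#' @export
stacking <- function(y_n, y_prev, params) {
  stopifnot(is.numeric(y_n), is.numeric(y_prev),
            all(is.finite(y_n)), all(is.finite(y_prev)))
  0.5 * params$kappa * (y_n - y_prev)^2 *
    (1 + params$rho * exp(-params$b * (y_n + y_prev)))
}

# Per-site Morse parameters for a duplex: depth comes from `depths` (already
# crowder-scaled), width from the pair class.
site_morse_widths <- function(duplex, params) {
  ifelse(duplex$pairs == "GC", params$a_GC, params$a_AT)
}

base_depths <- function(duplex, params) {
  ifelse(duplex$pairs == "GC", params$D_GC, params$D_AT)
}

# Total configurational energy of one chain microstate (used by the MC
# sampler and brute-force oracles).
chain_energy <- function(y, depths, widths, params) {
  e <- sum(morse(y, depths, widths))
  if (length(y) > 1) {
    e <- e + sum(stacking(y[-1], y[-length(y)], params))
  }
  e
}
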