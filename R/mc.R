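#' Metropolis Monte Carlo sampler of the configurational ensemble
#'
#' Independent validation route for the transfer-integral results: samples
#' the Boltzmann distribution \eqn{\propto e^{-\beta E(y)}} of the same
#' chain energy (Morse + anharmonic stacking) on the same truncated domain
#' \code{[y_min, y_max]}, using single-site symmetric uniform proposals.
#' Proposals leaving the domain are rejected, which preserves detailed
#' balance with respect to the truncated measure the quadrature integrates
#' over. Step sizes adapt per site during the burn-in (first 20% of
#' sweeps, discarded) and are frozen afterwards. Standard errors come from
#' block averaging over at least 20 blocks.
#'
#' Single-site random-walk moves alone mix very slowly across the
#' closed/open free-energy barrier (the chain must unzip collectively), so
#' two additional symmetric proposal types are mixed in: with probability
#' \code{jump_prob} a site proposes a uniform draw over the whole domain,
#' and once per sweep a rigid translation of the entire chain is proposed
#' (it leaves all stacking energies unchanged, letting a fully open chain
#' diffuse freely). Both satisfy detailed balance.
#'
#' @inheritParams compute_partition
#' @param n_sweeps total number of sweeps (one proposed move per site per
#'   sweep, plus one global translation).
#' @param step_size initial proposal half-width (Angstrom).
#' @param jump_prob probability that a single-site proposal is a uniform
#'   redraw over \code{[y_min, y_max]} instead of a local step.
#' @param global_step half-width (Angstrom) of the rigid-translation
#'   proposal; defaults to the full domain width so a dissociated chain can
#'   propose to re-enter the Morse well (and vice versa) in one move,
#'   keeping closed/open exchange frequent.
#' @param seed integer seed; the same seed reproduces the run exactly.
#' @param n_blocks number of blocks for the standard-error estimate.
#' @return Object of class \code{mc_result}: \code{mean_y} and
#'   \code{se_y} (per site), \code{open_freq} and \code{se_open} (per
#'   site, frequency of \code{y >= y0}), \code{acceptance_rate},
#'   \code{samples}, \code{seed}.
#' @examples
#' \donttest{
#' d <- parse_duplex("AAAA")
#' mc <- metropolis_sample(d, params = pbd_params(), temperature = 300,
#'                         n_sweeps = 5000, seed = 1)
#' mc$mean_y
#' }
#' @export
metropolis_sample <- function(duplex, depths = NULL, params = pbd_params(),
                              temperature, n_sweeps = 20000,
                              step_size = 0.5, jump_prob = 0.1,
                              global_step = NULL, seed = 1, n_blocks = 25) {
  stopifnot(n_sweeps >= 1, n_blocks >= 20)
  if (is.null(depths)) depths <- base_depths(duplex, params)
  N <- duplex$n
  widths <- site_morse_widths(duplex, params)
  beta <- 1 / (params$k_B * temperature)
  kap <- params$kappa; rho <- params$rho; b <- params$b
  ylo <- params$y_min; yhi <- params$y_max; y0 <- params$y0
  if (is.null(global_step)) global_step <- yhi - ylo

  # energy terms touching site i only
  local_energy <- function(y, i, yi) {
    e <- depths[i] * (exp(-widths[i] * yi) - 1)^2
    if (i > 1) {
      e <- e + 0.5 * kap * (yi - y[i - 1])^2 *
        (1 + rho * exp(-b * (yi + y[i - 1])))
    }
    if (i < N) {
      e <- e + 0.5 * kap * (y[i + 1] - yi)^2 *
        (1 + rho * exp(-b * (y[i + 1] + yi)))
    }
    e
  }

  withr::with_seed(seed, {
    y <- rep(0, N)
    step <- rep(step_size, N)
    burn <- max(1L, floor(0.2 * n_sweeps))
    n_keep <- n_sweeps - burn
    keep_y <- matrix(0, n_keep, N)
    acc <- 0L
    acc_site <- rep(0L, N)

    for (sw in seq_len(n_sweeps)) {
      for (i in seq_len(N)) {
        yi <- if (stats::runif(1) < jump_prob) {
          stats::runif(1, ylo, yhi)
        } else {
          y[i] + stats::runif(1, -step[i], step[i])
        }
        if (yi < ylo || yi > yhi) next  # rejected: outside truncated domain
        dE <- local_energy(y, i, yi) - local_energy(y, i, y[i])
        if (dE <= 0 || stats::runif(1) < exp(-beta * dE)) {
          y[i] <- yi
          if (sw > burn) acc <- acc + 1L
          acc_site[i] <- acc_site[i] + 1L
        }
      }
      # rigid translation: the quadratic stacking prefactor is invariant
      # but the Morse terms and the anharmonic stacking factor both change,
      # so the full chain energy enters the acceptance test
      dy <- stats::runif(1, -global_step, global_step)
      if (min(y) + dy >= ylo && max(y) + dy <= yhi) {
        dEg <- chain_energy(y + dy, depths, widths, params) -
          chain_energy(y, depths, widths, params)
        if (dEg <= 0 || stats::runif(1) < exp(-beta * dEg)) y <- y + dy
      }
      if (sw <= burn) {
        # gentle per-site step adaptation toward ~50% acceptance
        if (sw %% 50L == 0L) {
          rate <- acc_site / (50L * 1)
          step <- pmin(pmax(step * ifelse(rate > 0.5, 1.3, 0.77), 1e-3),
                       (yhi - ylo) / 2)
          acc_site[] <- 0L
        }
      } else {
        keep_y[sw - burn, ] <- y
      }
    }

    blocks <- cut(seq_len(n_keep), n_blocks, labels = FALSE)
    block_stat <- function(M) {
      bm <- apply(M, 2, function(col) tapply(col, blocks, mean))
      list(mean = colMeans(bm),
           se = apply(bm, 2, stats::sd) / sqrt(n_blocks))
    }
    ym <- block_stat(keep_y)
    om <- block_stat((keep_y >= y0) * 1)

    structure(list(mean_y = ym$mean, se_y = ym$se,
                   open_freq = om$mean, se_open = om$se,
                   acceptance_rate = acc / (n_keep * N),
                   samples = n_keep, seed = seed,
                   temperature = temperature, step = step),
              class = "mc_result")
  }) -> res
  if (res$acceptance_rate < 0.1 || res$acceptance_rate > 0.9) {
    warning(sprintf(
      "MC acceptance rate %.2f outside [0.1, 0.9]; consider retuning step_size",
      res$acceptance_rate))
  }
  res
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "Metropolis MC: %d retained sweeps at T = %g K (acceptance %.2f)\n",
    x$samples, x$temperature, x$acceptance_rate))
  cat("  <y> per site:",
      paste(sprintf("%.3g (±%.2g)", x$mean_y, x$se_y), collapse = ", "), "\n")
  cat("  open freq   :",
      paste(sprintf("%.3g", x$open_freq), collapse = ", "), "\n")
  invisible(x)
}
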