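#' Build the Gauss-Legendre quadrature grid
#'
#' Nodes and weights of single-interval Gauss-Legendre quadrature mapped to
#' the truncated displacement domain \code{[y_min, y_max]}. The weights sum
#' to the interval length and polynomials up to degree 2n-1 integrate
#' exactly.
#'
#' @param params a [pbd_params()] object (supplies bounds and node count).
#' @return Object of class \code{pbd_grid}: list with \code{nodes}
#'   (increasing), \code{weights} (> 0) and \code{n}.
#' @export
build_grid <- function(params = pbd_params()) {
  if (params$y_min >= params$y_max) stop("invalid bounds", call. = FALSE)
  if (params$n_grid < 2L) stop("need at least 2 nodes", call. = FALSE)
  gl <- pracma::gaussLegendre(params$n_grid, params$y_min, params$y_max)
  structure(list(nodes = gl$x, weights = gl$w, n = params$n_grid),
            class = "pbd_grid")
}

# Transfer-integral context: everything T-independent that the contraction
# reuses across temperatures and crowder configurations. The stacking
# kernel energy Vs(y_i, y_j) is an n x n matrix built once per grid; per
# temperature only exp(-beta * Vs) has to be refreshed.
ti_context <- function(params = pbd_params(), grid = build_grid(params)) {
  y <- grid$nodes
  Vs <- outer(y, y, function(a_, b_) stacking(a_, b_, params))
  list(params = params, grid = grid, Vs = Vs)
}

# exp(-beta * Vs) for one temperature
ti_kernel <- function(ctx, temperature) {
  beta <- 1 / (ctx$params$k_B * temperature)
  exp(-beta * ctx$Vs)
}

# Per-site statistical weights d_n(i) = w_i * exp(-beta * V_Morse,n(y_i)).
# The quadrature weight is absorbed here so the kernel stays weight-free;
# the sum over node paths is then the exact tensor-quadrature of
# exp(-beta * [sum V_M + sum V_s]).
ti_site_factors <- function(ctx, depths, widths, temperature) {
  beta <- 1 / (ctx$params$k_B * temperature)
  y <- ctx$grid$nodes
  w <- ctx$grid$weights
  vapply(seq_along(depths),
         function(s) w * exp(-beta * morse(y, depths[s], widths[s])),
         numeric(ctx$grid$n))
}

# Forward/backward contraction with per-step max-rescaling. Returns the
# log partition function and, if marginals = TRUE, the unnormalised site
# masses M (n x N, each column the weighted marginal of one site, all on a
# common but arbitrary log scale per column).
ti_contract <- function(ctx, D, temperature, marginals = FALSE,
                        mask_site = NULL, mask_keep = NULL) {
  n <- ctx$grid$n
  N <- ncol(D)
  if (!is.null(mask_site)) {
    D <- D  # local copy
    D[!mask_keep, mask_site] <- 0
  }
  if (N == 1L) {
    z <- sum(D[, 1])
    if (z <= 0) stop("partition underflow at T = ", temperature, call. = FALSE)
    out <- list(log_Z = log(z))
    if (marginals) out$masses <- D
    if (marginals) out$log_scale <- 0
    return(out)
  }
  G <- ti_kernel(ctx, temperature)

  fwd <- if (marginals) vector("list", N) else NULL
  f <- D[, 1]
  log_f <- 0
  fscale <- numeric(N)  # accumulated log factor after absorbing site k
  fscale[1] <- 0
  if (marginals) fwd[[1]] <- f
  for (k in 2:N) {
    f <- as.vector(G %*% f) * D[, k]
    s <- max(f)
    if (!is.finite(s) || s <= 0) {
      stop("partition over/underflow at T = ", temperature,
           " (step ", k, ")", call. = FALSE)
    }
    f <- f / s
    log_f <- log_f + log(s)
    fscale[k] <- log_f
    if (marginals) fwd[[k]] <- f
  }
  log_Z <- log(sum(f)) + log_f
  out <- list(log_Z = log_Z)

  if (marginals) {
    # backward pass; site mass M_k = (G b_{k+1}) * f_k with b carrying the
    # site factors of k+1..N, so each column sums (up to scale) to Z.
    masses <- matrix(0, n, N)
    log_bscale <- numeric(N)
    b <- rep(1, n)
    log_b <- 0
    masses[, N] <- fwd[[N]]
    log_bscale[N] <- 0
    for (k in (N - 1):1) {
      b <- as.vector(G %*% (b * D[, k + 1]))
      s <- max(b)
      b <- b / s
      log_b <- log_b + log(s)
      masses[, k] <- b * fwd[[k]]
      log_bscale[k] <- log_b
    }
    out$masses <- masses
    # column k of masses sums to Z on scale exp(fscale[k] + log_bscale[k])
    out$log_scale <- fscale + log_bscale
  }
  out
}

# Batched log Zc over many crowder configurations sharing one duplex
# length, width vector and temperature grid. depth_mat is N x C (one
# column of per-site depths per configuration). The stacking kernel is
# built once per temperature and shared across configurations; Morse
# Boltzmann vectors are computed once per unique (depth, width) pair.
# Returns a length(temps) x C matrix of log Zc.
ti_logZ_batch <- function(ctx, depth_mat, widths, temps) {
  n <- ctx$grid$n
  N <- nrow(depth_mat)
  C <- ncol(depth_mat)
  w <- ctx$grid$weights
  y <- ctx$grid$nodes

  key <- paste(rep(widths, C), as.vector(depth_mat))
  u <- !duplicated(key)
  uD <- as.vector(depth_mat)[u]
  uA <- rep(widths, C)[u]
  idx <- matrix(match(key, key[u]), N, C)
  Vm <- vapply(seq_along(uD), function(j) morse(y, uD[j], uA[j]),
               numeric(n))  # n x U, T-independent

  out <- matrix(NA_real_, length(temps), C)
  for (t in seq_along(temps)) {
    beta <- 1 / (ctx$params$k_B * temps[t])
    G <- exp(-beta * ctx$Vs)
    E <- exp(-beta * Vm) * w
    f <- E[, idx[1, ], drop = FALSE]
    logacc <- numeric(C)
    if (N > 1) {
      for (k in 2:N) {
        f <- (G %*% f) * E[, idx[k, ], drop = FALSE]
        s <- apply(f, 2, max)
        if (any(!is.finite(s)) || any(s <= 0)) {
          stop("partition over/underflow at T = ", temps[t], call. = FALSE)
        }
        f <- sweep(f, 2, s, "/")
        logacc <- logacc + log(s)
      }
    }
    out[t, ] <- log(colSums(f)) + logacc
  }
  out
}

#' Configurational partition function by transfer-integral contraction
#'
#' Evaluates \eqn{Z_c}, the Boltzmann integral of the chain's
#' configurational energy over the truncated domain, by left-to-right
#' kernel contraction on the quadrature grid, with per-step rescaling so
#' neither overflow nor underflow occurs across the full temperature scan.
#' Also returns the per-site marginal densities of the stretching
#' coordinate.
#'
#' @param duplex a \code{pbd_duplex}.
#' @param depths per-site Morse depths (eV), e.g. from
#'   [effective_depths()]; defaults to the uncrowded depths.
#' @param params a [pbd_params()] object.
#' @param temperature temperature in K (> 0).
#' @param ctx optional precomputed internal context (kernel cache); built
#'   from \code{params} when omitted.
#' @return Object of class \code{pbd_partition}: \code{log_Zc},
#'   \code{marginals} (n x N matrix of per-site densities over the nodes;
#'   each column integrates to 1 with the grid weights), \code{grid},
#'   \code{temperature}.
#' @examples
#' d <- parse_duplex("GGGAGAAG")
#' p <- pbd_params(n_grid = 120)  # coarse grid for a quick look
#' z <- compute_partition(d, params = p, temperature = 300)
#' z$log_Zc
#' @export
compute_partition <- function(duplex, depths = NULL, params = pbd_params(),
                              temperature, ctx = NULL) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (is.null(depths)) depths <- base_depths(duplex, params)
  if (length(depths) != duplex$n) {
    stop("depths must have one entry per site", call. = FALSE)
  }
  if (is.null(ctx)) ctx <- ti_context(params)
  widths <- site_morse_widths(duplex, params)
  D <- ti_site_factors(ctx, depths, widths, temperature)
  res <- ti_contract(ctx, D, temperature, marginals = TRUE)
  dens <- sweep(res$masses, 2, colSums(res$masses), "/") / ctx$grid$weights
  structure(list(log_Zc = res$log_Z, marginals = dens,
                 masses = res$masses, grid = ctx$grid,
                 temperature = temperature),
            class = "pbd_partition")
}

#' Partition function with one site restricted to its open or closed region
#'
#' Same contraction as [compute_partition()], but the chosen site's
#' integral runs only over \code{y >= y0} (\code{region = "open"}) or
#' \code{y < y0} (\code{region = "closed"}); excluded nodes get zero
#' weight. The two restricted partition functions sum exactly to the
#' unrestricted one on the shared grid, which is what makes
#' \eqn{P_i(open) + P_i(closed) = 1} exact.
#'
#' @inheritParams compute_partition
#' @param site 1-based site index to restrict.
#' @param region \code{"open"} or \code{"closed"}.
#' @return \code{log_Zc} of the restricted chain (scalar).
#' @export
compute_restricted_partition <- function(duplex, depths = NULL,
                                         params = pbd_params(), temperature,
                                         site, region = c("open", "closed"),
                                         ctx = NULL) {
  region <- match.arg(region)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (site < 1 || site > duplex$n) {
    stop("site must be in 1..", duplex$n, call. = FALSE)
  }
  if (is.null(depths)) depths <- base_depths(duplex, params)
  if (is.null(ctx)) ctx <- ti_context(params)
  widths <- site_morse_widths(duplex, params)
  D <- ti_site_factors(ctx, depths, widths, temperature)
  keep <- if (region == "open") {
    ctx$grid$nodes >= ctx$params$y0
  } else {
    ctx$grid$nodes < ctx$params$y0
  }
  res <- ti_contract(ctx, D, temperature, mask_site = site, mask_keep = keep)
  res$log_Z
}
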