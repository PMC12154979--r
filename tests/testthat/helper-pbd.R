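# Shared fixtures and independent oracles for the test suite.

chain_a <- function() parse_duplex("GGGAGAAG", label = "chain-A")
chain_b <- function() parse_duplex("GGAAGAGG", label = "chain-B")

# Reduced-size parameter set for property loops: a compact displacement
# domain so a few hundred Gauss-Legendre nodes still resolve the ~0.3 A
# Morse wells. Same Hamiltonian; transition temperatures shift upward
# relative to the production domain because the open state holds less
# entropy, which no qualitative test here depends on.
quick_params <- function(n_grid = 300, y_max = 25, ...) {
  pbd_params(n_grid = n_grid, y_max = y_max, ...)
}

# Independent oracle: configurational partition function by explicit
# tensor-product quadrature (no kernel contraction; nested sums written
# out). Usable for N <= 3 on reduced grids.
bf_log_partition <- function(duplex, depths, params, temperature,
                             restrict_site = NULL, region = "open") {
  g <- pracma::gaussLegendre(params$n_grid, params$y_min, params$y_max)
  beta <- 1 / (params$k_B * temperature)
  widths <- ifelse(duplex$pairs == "GC", params$a_GC, params$a_AT)
  site <- lapply(seq_len(duplex$n), function(s) {
    d <- g$w * exp(-beta * morse(g$x, depths[s], widths[s]))
    if (!is.null(restrict_site) && s == restrict_site) {
      keep <- if (region == "open") g$x >= params$y0 else g$x < params$y0
      d[!keep] <- 0
    }
    d
  })
  S <- exp(-beta * outer(g$x, g$x, function(a, b) stacking(a, b, params)))
  n <- params$n_grid
  tot <- 0
  if (duplex$n == 1L) {
    tot <- sum(site[[1]])
  } else if (duplex$n == 2L) {
    for (i in seq_len(n)) {
      tot <- tot + site[[1]][i] * sum(S[i, ] * site[[2]])
    }
  } else if (duplex$n == 3L) {
    inner <- as.vector(S %*% site[[3]])
    for (i in seq_len(n)) {
      tot <- tot + site[[1]][i] * sum(S[i, ] * site[[2]] * inner)
    }
  } else {
    stop("brute-force oracle only for N <= 3")
  }
  log(tot)
}

# Memoised chain-A 56-configuration scan shared by the acceptance tests
# (criteria about the mean and about per-configuration stabilization use
# the same expensive computation).
.pbd_cache <- new.env(parent = emptyenv())

cached_scan56 <- function() {
  if (is.null(.pbd_cache$scan56)) {
    cfgs <- enumerate_crowder_configs(8, 3, alpha = 1.5)
    .pbd_cache$scan56 <- scan_crowder_configs(chain_a(), cfgs, pbd_params(),
                                              t_range = c(250, 350))
  }
  .pbd_cache$scan56
}

cached_chain_a_tm <- function(n_grid = 900) {
  key <- paste0("tmA", n_grid)
  if (is.null(.pbd_cache[[key]])) {
    .pbd_cache[[key]] <- melting_scan(chain_a(),
                                      params = pbd_params(n_grid = n_grid),
                                      t_range = c(200, 340),
                                      phi = FALSE)$tm
  }
  .pbd_cache[[key]]
}
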