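test_that("Gauss-Legendre grid has textbook nodes and polynomial exactness", {
  p2 <- pbd_params(y_min = -1, y_max = 1, n_grid = 2, y0 = 0.5)
  g2 <- build_grid(p2)
  expect_equal(g2$nodes, c(-1, 1) / sqrt(3))
  expect_equal(g2$weights, c(1, 1))

  g <- build_grid(pbd_params(n_grid = 40))
  expect_equal(sum(g$weights * g$nodes^2), (200^3 + 5^3) / 3)
  expect_equal(sum(g$weights), 205)
  expect_false(is.unsorted(g$nodes))

  expect_equal(build_grid(pbd_params())$n, 900L)
})

test_that("contraction equals direct 1-D quadrature for a single pair", {
  p <- pbd_params()
  d1 <- parse_duplex("A")
  g <- build_grid(p)
  for (T in c(150, 300)) {
    z <- compute_partition(d1, params = p, temperature = T)
    beta <- 1 / (p$k_B * T)
    ref <- log(sum(g$weights * exp(-beta * morse(g$nodes, p$D_AT, p$a_AT))))
    expect_equal(z$log_Zc, ref, tolerance = 1e-12)
  }
  # and the quadrature itself is converged against adaptive integration
  beta <- 1 / (p$k_B * 300)
  adaptive <- log(stats::integrate(function(y) {
    exp(-beta * morse(y, p$D_AT, p$a_AT))
  }, p$y_min, p$y_max, rel.tol = 1e-12)$value)
  expect_equal(compute_partition(d1, params = p, temperature = 300)$log_Zc,
               adaptive, tolerance = 1e-4)
})

test_that("contraction matches brute-force tensor quadrature for N <= 3", {
  p <- quick_params(n_grid = 60)
  for (s in c("AA", "GA", "AGA", "GGG")) {
    d <- parse_duplex(s)
    dep <- effective_depths(d, crowder_config(1, alpha = 1.5), p)
    for (T in c(200, 300)) {
      ti <- compute_partition(d, dep, p, temperature = T)$log_Zc
      bf <- bf_log_partition(d, dep, p, T)
      expect_equal(ti, bf, tolerance = 1e-10)
    }
  }
})

test_that("restricted contraction matches its brute-force counterpart", {
  p <- quick_params(n_grid = 60)
  d <- parse_duplex("AGA")
  dep <- effective_depths(d, NULL, p)
  for (site in 1:3) {
    ti <- compute_restricted_partition(d, dep, p, 300, site, "open")
    bf <- bf_log_partition(d, dep, p, 300, restrict_site = site)
    expect_equal(ti, bf, tolerance = 1e-10)
  }
})

test_that("site marginals are normalised densities that sharpen at low T", {
  p <- quick_params(n_grid = 300)
  d <- chain_a()
  z <- compute_partition(d, params = p, temperature = 300)
  norms <- colSums(z$marginals * z$grid$weights)
  expect_true(all(abs(norms - 1) < 1e-8))
  expect_true(all(z$marginals >= 0))

  # deep cold: every marginal concentrates at the Morse minimum y = 0
  zc <- compute_partition(d, params = p, temperature = 20)
  ybar <- colSums(zc$masses * zc$grid$nodes) / colSums(zc$masses)
  expect_true(all(abs(ybar) < 0.05))
})

test_that("partition function is reversal-symmetric and monotone in T", {
  p <- quick_params()
  d <- parse_duplex("GGAAGAGG")
  cr <- crowder_config(c(2, 5), alpha = c(1.5, 3))
  dep <- effective_depths(d, cr, p)
  drev <- parse_duplex(paste(rev(strsplit("GGAAGAGG", "")[[1]]), collapse = ""))
  dep_rev <- rev(dep)
  for (T in c(220, 320)) {
    expect_equal(compute_partition(d, dep, p, T)$log_Zc,
                 compute_partition(drev, dep_rev, p, T)$log_Zc,
                 tolerance = 1e-12)
  }

  temps <- seq(150, 500, 25)
  lz <- vapply(temps, function(T) {
    compute_partition(d, dep, p, T)$log_Zc
  }, numeric(1))
  expect_true(all(diff(lz) > 0))
  expect_true(all(is.finite(lz)))
})

test_that("open and closed restricted partitions sum to the whole", {
  p <- quick_params()
  d <- chain_a()
  dep <- effective_depths(d, NULL, p)
  z <- compute_partition(d, dep, p, 250)$log_Zc
  for (site in c(1, 4, 8)) {
    lo <- compute_restricted_partition(d, dep, p, 250, site, "open")
    lc <- compute_restricted_partition(d, dep, p, 250, site, "closed")
    expect_equal(exp(lo - z) + exp(lc - z), 1, tolerance = 1e-12)
    expect_lte(lo, z)
  }
})

test_that("temperature validation and error reporting", {
  d <- parse_duplex("AG")
  expect_error(compute_partition(d, params = quick_params(), temperature = -5),
               "temperature")
  expect_error(compute_restricted_partition(d, params = quick_params(),
                                            temperature = 300, site = 7),
               "site")
})
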