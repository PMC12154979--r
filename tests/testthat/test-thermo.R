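test_that("finite-difference Cv recovers a closed-form test function", {
  # f = -c T ln T has Cv = -T f'' = c exactly
  c0 <- 3.2e-4
  temps <- seq(299, 301, 0.1)
  fmat <- matrix(-c0 * temps * log(temps), ncol = 1)
  out <- pbdmelt:::cv_from_f(temps, fmat, k_B = 1)
  expect_true(all(abs(out$cv - c0) < 1e-6 * c0))

  # momentum sector alone contributes k_B/2 per base pair
  p <- pbd_params()
  mom <- function(T) -0.5 * p$k_B * T * log(2 * pi * p$m * p$k_B * T)
  dT <- 0.1
  cv_mom <- -300 * (mom(300 - dT) - 2 * mom(300) + mom(300 + dT)) / dT^2
  expect_equal(cv_mom, p$k_B / 2, tolerance = 1e-6)
})

test_that("free energy decreases with temperature (positive entropy)", {
  p <- quick_params()
  d <- chain_a()
  temps <- seq(200, 400, 10)
  f <- free_energy(d, params = p, temperature = temps)
  expect_true(all(diff(f) < 0))
  # determinism: identical inputs, identical output
  expect_identical(f, free_energy(d, params = p, temperature = temps))
})

test_that("melting_temperature refines the Cv peak and flags bad input", {
  tt <- seq(300, 320, 0.5)
  expect_equal(melting_temperature(tt, exp(-(tt - 310)^2)), 310)
  # off-grid true peak recovered by parabolic interpolation
  expect_equal(melting_temperature(tt, exp(-(tt - 311.3)^2 / 4)), 311.3,
               tolerance = 0.05)
  expect_error(melting_temperature(tt, seq_along(tt)), "boundary")
  # discrete ties break toward lower temperature before refinement
  expect_equal(melting_temperature(1:5, c(1, 2, 2, 1, 1)), 2.5)
})

test_that("melting scans are deterministic and order chains physically", {
  p <- quick_params(n_grid = 250)
  m1 <- melting_scan(chain_a(), params = p, t_range = c(180, 350),
                     phi = FALSE)
  m2 <- melting_scan(chain_a(), params = p, t_range = c(180, 350),
                     phi = FALSE)
  expect_identical(m1$profile, m2$profile)
  expect_identical(m1$tm, m2$tm)
  expect_true(m1$tm > 180 && m1$tm < 350)
  expect_true(all(m1$profile$cv > 0))

  # terminal GC content stabilises chain-A relative to chain-B
  mB <- melting_scan(chain_b(), params = p, t_range = c(180, 350),
                     phi = FALSE)
  expect_gte(m1$tm, mB$tm)

  # class depths order homopolymer melting
  gc8 <- melting_scan(parse_duplex("GGGGGGGG"), params = p,
                      t_range = c(180, 360), phi = FALSE)$tm
  at8 <- melting_scan(parse_duplex("AAAAAAAA"), params = p,
                      t_range = c(140, 320), phi = FALSE)$tm
  expect_gt(gc8, at8)
})

test_that("a crowded chain never melts below its uncrowded self", {
  p <- quick_params(n_grid = 250)
  free_tm <- melting_scan(chain_a(), params = p, t_range = c(180, 350),
                          phi = FALSE)$tm
  crowded <- melting_scan(chain_a(), crowder_config(c(2, 7, 8), 1.5),
                          params = p, t_range = c(180, 350), phi = FALSE)
  expect_gte(crowded$tm, free_tm)

  # doubly-occupied sites (product rule) stabilise beyond single occupancy
  twice <- melting_scan(chain_a(), crowder_config(c(8, 8, 2), 1.5),
                        params = p, t_range = c(180, 360), phi = FALSE)
  single <- melting_scan(chain_a(), crowder_config(c(8, 2), 1.5),
                         params = p, t_range = c(180, 360), phi = FALSE)
  expect_gte(twice$tm, single$tm)
})

test_that("batch configuration scan agrees with individual scans", {
  p <- quick_params(n_grid = 250)
  cfgs <- list(crowder_config(c(2, 7, 8), 1.5),
               crowder_config(c(4, 5, 8), 1.5),
               crowder_config(c(1, 2, 3), 1.5))
  res <- scan_crowder_configs(chain_a(), cfgs, p, t_range = c(180, 350))
  expect_equal(nrow(res), 3L)
  expect_equal(attr(res, "mean_tm"), mean(res$tm))
  solo <- melting_scan(chain_a(), cfgs[[1]], p, t_range = c(180, 350),
                       phi = FALSE)$tm
  expect_equal(res$tm[1], solo, tolerance = 0.05)
})
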