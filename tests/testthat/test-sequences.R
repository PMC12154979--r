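test_that("shorthand parsing maps G to GC and A to AT in order", {
  a <- chain_a()
  expect_equal(a$pairs, c("GC", "GC", "GC", "AT", "GC", "AT", "AT", "GC"))
  expect_equal(a$n, 8L)
  expect_equal(parse_duplex("A")$pairs, "AT")

  b <- chain_b()
  expect_equal(b$pairs, c("GC", "GC", "AT", "AT", "GC", "AT", "GC", "GC"))
  # literal composition: the string GGAAGAGG holds five G letters
  expect_equal(sum(b$pairs == "GC"), 5L)
  expect_equal(sum(b$pairs == "AT"), 3L)
})

test_that("literal alphabet folds complements onto pair classes", {
  d <- parse_duplex("GCcAtT", alphabet = "literal")
  expect_equal(d$pairs, c("GC", "GC", "GC", "AT", "AT", "AT"))
  # shorthand alphabet rejects letters outside {G, A}
  expect_error(parse_duplex("GGT"), "position 3")
  expect_error(parse_duplex("GCXA", alphabet = "literal"), "position 3")
  expect_error(parse_duplex(""), "non-empty")
})

test_that("format_duplex inverts parse_duplex on random sequences", {
  for (seed in 1:5) {
    s <- paste(sample(c("G", "A"), 20, replace = TRUE), collapse = "")
    expect_equal(format_duplex(parse_duplex(s)), s)
  }
  d <- generate_random_duplex(37, 0.4, seed = 9)
  expect_equal(parse_duplex(format_duplex(d))$pairs, d$pairs)
})

test_that("FASTA round trip preserves the sequence and label", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chain-A demo", "GGGAGAAG"), tmp)
  d <- read_duplex_fasta(tmp)
  expect_equal(format_duplex(d), "GGGAGAAG")
  expect_match(d$label, "chain-A")
})

test_that("random duplexes are reproducible with exact GC counts", {
  d1 <- generate_random_duplex(50, 0.5, seed = 7)
  d2 <- generate_random_duplex(50, 0.5, seed = 7)
  expect_identical(d1$pairs, d2$pairs)
  expect_equal(sum(d1$pairs == "GC"), 25L)
  expect_true(all(generate_random_duplex(10, 1.0, seed = 1)$pairs == "GC"))
  expect_equal(sum(generate_random_duplex(300, 0.5, seed = 1)$pairs == "GC"),
               150L)
  expect_error(generate_random_duplex(10, 1.2, seed = 1), "gc_fraction")
})

test_that("crowder enumeration matches subset counts and ordering", {
  expect_length(enumerate_crowder_configs(8, 3), 56)
  expect_length(enumerate_crowder_configs(3, 3), 1)
  expect_equal(enumerate_crowder_configs(3, 3)[[1]]$sites, 1:3)
  expect_length(enumerate_crowder_configs(5, 2), 10)
  # identical crowders allowed to share a site: multiset count C(n+k-1, k)
  expect_length(enumerate_crowder_configs(8, 3, allow_repeats = TRUE), 120)
  expect_error(enumerate_crowder_configs(3, 4), "impossible")

  for (n in 4:8) {
    for (k in 1:n) {
      cfgs <- enumerate_crowder_configs(n, k)
      expect_length(cfgs, choose(n, k))
      keys <- vapply(cfgs, function(cc) paste(cc$sites, collapse = ","),
                     character(1))
      expect_false(anyDuplicated(keys) > 0)
      # deterministic lexicographic order by site tuple (single-digit
      # sites here, so string order coincides with tuple order)
      expect_false(is.unsorted(keys))
      expect_identical(cfgs[[1]]$sites, seq_len(k))
    }
  }
})

test_that("effective depths scale the class depth by the local alpha", {
  p <- pbd_params()
  d <- chain_a()
  base <- effective_depths(d, NULL, p)
  expect_equal(base, ifelse(d$pairs == "GC", 0.059, 0.0395))

  one <- effective_depths(d, crowder_config(4, alpha = 1.5), p)
  expect_equal(one[4], 1.5 * 0.0395)  # crowded AT site
  expect_equal(one[-4], base[-4])

  nine <- effective_depths(d, crowder_config(1, alpha = 9), p)
  expect_equal(nine[1], 9 * 0.059)  # crowded GC site

  expect_equal(effective_depths(d, crowder_config(1:8, alpha = 1), p), base)

  # increasing alpha strictly deepens the crowded site
  a_grid <- c(1, 1.25, 1.5, 5, 9)
  dep4 <- vapply(a_grid, function(a) {
    effective_depths(d, crowder_config(4, alpha = a), p)[4]
  }, numeric(1))
  expect_true(all(diff(dep4) > 0))
})

test_that("multiple crowders on one site combine by the multiplicity rule", {
  p <- pbd_params()
  d <- chain_a()
  prod_cfg <- crowder_config(c(4, 4), alpha = 1.5)
  expect_equal(effective_depths(d, prod_cfg, p)[4], 1.5^2 * 0.0395)
  single_cfg <- crowder_config(c(4, 4), alpha = c(1.5, 1.2),
                               multiplicity_rule = "single")
  expect_equal(effective_depths(d, single_cfg, p)[4], 1.5 * 0.0395)
  expect_error(effective_depths(d, crowder_config(9, 1.5), p), "exceeds")
  expect_error(crowder_config(2, alpha = -1), "alpha")
})
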