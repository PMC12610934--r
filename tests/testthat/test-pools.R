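test_that("parameter validation enforces model invariants", {
  expect_error(model_params(R1 = 0.6), "outside")
  expect_error(model_params(k = 1), "outside")
  expect_error(model_params(h = 1.5), "outside")
  expect_error(model_params(p0 = 1), "outside")
  expect_error(model_params(location = "autosome", R2 = 0.1), "R2")
  # R2 silently resolves to 0.5 for an autosomal meiosis locus.
  expect_identical(model_params(location = "autosome")$R2, 0.5)
  expect_identical(model_params(location = "autosome", R2 = 0.5)$R2, 0.5)
})

test_that("relative effective sizes follow breeding-sex accounting", {
  expect_identical(relative_ne("autosome"), 1)
  expect_identical(relative_ne("X"), 0.75)
  expect_identical(relative_ne("Y"), 0.25)
  # Skewed sex ratios move the ratio: with excess breeding males the X
  # loses less Ne relative to autosomes.
  expect_gt(relative_ne("X", n_females = 1, n_males = 3), 0.75)
  expect_lt(relative_ne("X", n_females = 3, n_males = 1), 0.75)
})

test_that("pool construction checks the frequency invariants", {
  expect_error(
    gamete_pools(c(X_mc = 0.9), c(Y_mc = 0.5, X_mc = 0.5)),
    "sum to 1"
  )
  expect_error(
    gamete_pools(
      c(X_mc = 1),
      c(X_mc = 0.7, Y_mc = 0.3) # Y-sperm must total 0.5
    ),
    "0.5"
  )
  expect_error(
    gamete_pools(c(X_mc = 2, X_fc = -1), c(X_mc = 0.5, Y_mc = 0.5)),
    "non-negative"
  )
  expect_error(
    gamete_pools(c(bogus = 1), c(X_mc = 0.5, Y_mc = 0.5)),
    "valid egg haplotypes"
  )
})

test_that("initial pools place the achiasmy allele on the right class", {
  # Y-located, Ne-adjusted: within-Y frequency p0 / 0.25.
  p <- initialize_pools(model_params(location = "Y", p0 = 1e-4))
  expect_equal(allele_frequency(p, "ml", "a", restrict_to = "Y"), 4e-4)
  expect_identical(sum(p$egg[c("X_ma", "X_fa")]), 0)
  expect_identical(sum(p$sperm[c("X_ma", "X_fa")]), 0)

  # X-located, unadjusted: conditional frequency p0 in every X class.
  px <- initialize_pools(
    model_params(location = "X", p0 = 1e-4, ne_adjust = FALSE)
  )
  expect_equal(allele_frequency(px, "ml", "a", restrict_to = "X"), 1e-4)
  expect_equal(sum(px$egg[c("X_ma", "X_fa")]), 1e-4)
  expect_identical(sum(px$sperm[c("Y_ma", "Y_fa")]), 0)

  # X-located, adjusted: p0 / 0.75.
  px2 <- initialize_pools(model_params(location = "X", p0 = 1e-4))
  expect_equal(
    allele_frequency(px2, "ml", "a", restrict_to = "X"), 1e-4 / 0.75
  )

  # Autosomal: equal conditional frequency everywhere.
  pa <- initialize_pools(model_params(location = "autosome", p0 = 1e-4))
  expect_equal(allele_frequency(pa, "ml", "a"), 1e-4)
  expect_equal(allele_frequency(pa, "ml", "a", restrict_to = "Y"), 1e-4)

  # All variants satisfy the pool invariants (validated on construction)
  # and start the antagonistic alleles at 0.5.
  for (pp in list(p, px, px2, pa)) {
    expect_silent(validate_pools(pp))
    expect_equal(allele_frequency(pp, "sal", "m"), 0.5)
  }
})

test_that("allele frequencies are consistent and complementary", {
  set.seed(42)
  for (i in 1:10) {
    pools <- random_pools()
    for (locus in c("sal", "ml", "sdl")) {
      alleles <- switch(locus,
        sal = c("m", "f"), ml = c("c", "a"), sdl = c("X", "Y")
      )
      expect_equal(
        allele_frequency(pools, locus, alleles[1]) +
          allele_frequency(pools, locus, alleles[2]),
        1,
        tolerance = 1e-12
      )
    }
    # Restricted queries are conditional frequencies in [0, 1].
    fy <- allele_frequency(pools, "ml", "a", restrict_to = "Y")
    fx <- allele_frequency(pools, "ml", "a", restrict_to = "X")
    expect_true(fy >= 0 && fy <= 1 && fx >= 0 && fx <= 1)
  }
  expect_error(
    allele_frequency(random_pools(), "ml", "z"),
    "Unknown allele"
  )
})

test_that("random union produces normalized per-sex genotype tables", {
  pools <- gamete_pools(
    c(X_fc = 1),
    c(X_fc = 0.5, Y_fc = 0.5)
  )
  u <- union_gametes(pools)
  females <- u[u$sex == "female" & u$frequency > 0, ]
  males <- u[u$sex == "male" & u$frequency > 0, ]
  expect_identical(nrow(females), 1L)
  expect_identical(females$egg_haplotype, "X_fc")
  expect_identical(females$sperm_haplotype, "X_fc")
  expect_equal(females$frequency, 1)
  expect_identical(nrow(males), 1L)
  expect_identical(males$sperm_haplotype, "Y_fc")
  expect_equal(males$frequency, 1)

  set.seed(7)
  for (i in 1:5) {
    u <- union_gametes(random_pools())
    sums <- tapply(u$frequency, u$sex, sum)
    expect_equal(unname(sums["female"]), 1, tolerance = 1e-12)
    expect_equal(unname(sums["male"]), 1, tolerance = 1e-12)
  }
})

test_that("as_tibble on pools returns the long frequency table", {
  tb <- as_tibble(initialize_pools(model_params(location = "Y")))
  expect_identical(nrow(tb), 12L)
  expect_named(tb, c("pool", "haplotype", "frequency"))
  expect_equal(sum(tb$frequency), 2)
})
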