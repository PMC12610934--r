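test_that("degenerate initial frequencies give the trivial outcomes", {
  sim0 <- iterate_model(model_params(location = "Y", k = 0.05, p0 = 0))
  expect_identical(sim0$outcome, "not_fixed")
  expect_identical(sim0$final_frequency, 0)

  # An all-achiasmatic start is fixed at generation 0.
  p1 <- model_params(location = "Y", k = 0.05, p0 = 0.999, ne_adjust = FALSE)
  p1$fixation_threshold <- 0.99
  sim1 <- iterate_model(p1)
  expect_identical(sim1$outcome, "fixed")
  expect_identical(sim1$generations_to_fixation, 0L)
  expect_identical(sim1$generations_run, 0L)
})

test_that("time to fixation matches the scalar oracle's count", {
  params <- model_params(location = "Y", s = 0, k = 0.05, L = 0, p0 = 1e-4)
  sim <- iterate_model(params)
  oracle <- scalar_y_recursion(4e-4, k = 0.05, fixation_threshold = 0.99)
  expect_identical(sim$outcome, "fixed")
  expect_identical(sim$generations_to_fixation, oracle$fixed_at)
})

test_that("outcome labels follow the fixation threshold exactly", {
  set.seed(5)
  for (i in 1:8) {
    params <- random_params()
    sim <- iterate_model(params, record_trajectory = FALSE)
    expect_identical(
      sim$outcome,
      if (sim$final_frequency >= params$fixation_threshold) {
        "fixed"
      } else {
        "not_fixed"
      }
    )
  }
})

test_that("trajectories are bounded and equilibrium detection fires", {
  params <- model_params(location = "Y", s = 0, k = 0.02, L = 0)
  sim <- iterate_model(params)
  tr <- tidy(sim)
  expect_true(all(tr$a_frequency >= 0 & tr$a_frequency <= 1))
  expect_true(all(
    tr$a_frequency_within_class >= 0 & tr$a_frequency_within_class <= 1
  ))
  # The neutral run flatlines immediately, so equilibrium is detected.
  neutral <- iterate_model(model_params(location = "Y", s = 0, k = 0, L = 0))
  expect_identical(neutral$generations_to_equilibrium, 1L)
  expect_true(is.na(neutral$generations_to_fixation))
})

test_that("a numerically lost allele stops the run early", {
  params <- model_params(location = "Y", s = 0, k = 0, L = 5e6, p0 = 1e-4)
  sim <- iterate_model(params)
  expect_identical(sim$outcome, "not_fixed")
  expect_lt(sim$final_frequency, 1e-15)
  expect_lt(sim$generations_run, 1000L)
})

test_that("burn-in settles the antagonistic locus before introduction", {
  params <- model_params(
    location = "Y", s = 0.3, h = 0.5, k = 0, L = 0, burn_in = 500
  )
  sim <- iterate_model(params)
  # The introduced class frequency still honours the Ne adjustment.
  expect_equal(sim$trajectory$a_frequency_within_class[1], 4e-4,
    tolerance = 1e-12
  )
  # After burn-in the male-beneficial allele has accumulated on the Y
  # (and the population frequency has moved off its 0.5 start); without
  # burn-in the run starts exactly at 0.5.
  pools <- initialize_pools(modifyList_params(params, p0 = 0, burn_in = 0L))
  p_burn <- modifyList_params(params, p0 = 0, burn_in = 0L)
  for (t in 0:499) pools <- step_generation(pools, p_burn, t)
  expect_equal(
    sim$trajectory$sal_m_frequency[1],
    allele_frequency(pools, "sal", "m"),
    tolerance = 1e-9
  )
  expect_gt(
    abs(sim$trajectory$sal_m_frequency[1] - 0.5), 0.01
  )
  no_burn <- iterate_model(modifyList_params(params, burn_in = 0L))
  expect_identical(no_burn$trajectory$sal_m_frequency[1], 0.5)
})

test_that("tidy, glance and autoplot expose the run", {
  sim <- iterate_model(model_params(location = "Y", k = 0.05))
  g <- glance(sim)
  expect_identical(nrow(g), 1L)
  expect_identical(g$outcome, "fixed")
  expect_named(
    tidy(sim),
    c(
      "generation", "a_frequency", "a_frequency_within_class",
      "sal_m_frequency"
    )
  )
  expect_s3_class(autoplot(sim), "ggplot")
  slim <- iterate_model(
    model_params(location = "Y", k = 0.05),
    record_trajectory = FALSE
  )
  expect_error(tidy(slim), "not recorded")
  expect_identical(glance(slim)$outcome, "fixed")
})
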