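test_that("default grids have 200 strictly increasing values per axis", {
  g <- default_grids()
  expect_length(g$L_grid, 200L)
  expect_length(g$s_grid, 200L)
  expect_length(g$k_grid, 200L)
  expect_identical(g$L_grid[1], 0)
  expect_identical(g$L_grid[2], 25e3)
  expect_lt(max(g$L_grid), 5e6)
  expect_equal(max(g$s_grid), 0.5)
  expect_equal(max(g$k_grid), 0.05)
  expect_gt(min(g$s_grid), 0)
  expect_gt(min(g$k_grid), 0)
  for (axis in g) expect_true(all(diff(axis) > 0))
})

test_that("the factorial design materializes with the published counts", {
  full <- build_design()
  expect_identical(nrow(full), 480000L)
  # Condition count identity |loc| * |L| * (|s| * |h| + |k|).
  expect_identical(
    nrow(full),
    3L * 200L * (200L * 3L + 200L)
  )
  # The location-by-divergence layer alone.
  expect_identical(
    nrow(dplyr::distinct(full, location, L)),
    600L
  )
  # Exclusivity: antagonism conditions have k = 0, aneuploidy ones s = 0.
  expect_true(all(full$k[full$model == "sexual_antagonism"] == 0))
  expect_true(all(full$s[full$model == "aneuploidy"] == 0))
  # Autosomal conditions force independent assortment.
  expect_true(all(full$R2[full$location == "autosome"] == 0.5))
  expect_true(all(full$R2[full$location != "autosome"] == 0.1))
  # Deterministic ordering and ids.
  expect_identical(full$condition, seq_len(480000L))

  expect_identical(nrow(build_design(locations = character(0))), 0L)
  expect_error(build_design(s_grid = c(-0.1, 0.2)), "negative")
  expect_error(build_design(k_grid = c(0.5, 1)), "< 1")
})

test_that("small sweeps are deterministic and respect neutral invariance", {
  g <- default_grids(n = 3)
  d <- build_design(
    locations = c("Y", "X"), L_grid = c(0, 1e6), s_grid = g$s_grid,
    k_grid = g$k_grid, h_values = 0.5
  )
  expect_identical(nrow(d), 2L * 2L * (3L + 3L))
  r1 <- run_sweep(d)
  r2 <- run_sweep(d)
  expect_identical(r1, r2)
  expect_true(all(r1$final_frequency >= 0 & r1$final_frequency <= 1))
  expect_true(all(is.na(r1$error)))

  # s = 0, k = 0 rows keep their initial frequency exactly.
  d0 <- build_design(
    locations = "Y", L_grid = 0, s_grid = 0, k_grid = 0,
    h_values = 0
  )
  r0 <- run_sweep(d0)
  expect_equal(r0$final_frequency, rep(4e-4, 2), tolerance = 1e-10)
})

test_that("sweep outcomes match single-run oracles", {
  d <- build_design(
    locations = "Y", L_grid = 0, s_grid = 0.1, k_grid = 0.05,
    h_values = 0.5
  )
  r <- run_sweep(d)
  row <- r[r$model == "aneuploidy", ]
  oracle <- scalar_y_recursion(4e-4, k = 0.05, fixation_threshold = 0.99)
  expect_identical(row$outcome, "fixed")
  expect_identical(row$generations_to_fixation, oracle$fixed_at)
})

test_that("heatmap matrices are dense, labelled, and error on gaps", {
  g <- default_grids(n = 2)
  d <- build_design(
    locations = "Y", L_grid = c(0, 1e6), s_grid = g$s_grid,
    k_grid = g$k_grid, h_values = 0.5
  )
  r <- run_sweep(d)
  m <- heatmap_matrix(r, "Y", "sexual_antagonism")
  expect_identical(dim(unclass(m)), c(2L, 2L))
  expect_true(all(unclass(m) >= 0 & unclass(m) <= 1))
  # Cells equal the individual runs.
  one <- iterate_model(
    modifyList_params(
      attr(d, "defaults"),
      location = "Y", s = g$s_grid[2], h = 0.5, k = 0, L = 1e6
    ),
    record_trajectory = FALSE
  )
  expect_equal(unclass(m)[2, 2], one$final_frequency)

  expect_error(heatmap_matrix(r, "X", "aneuploidy"), "not present")
  # Dropping a cell makes the slice incomplete.
  drop <- which(r$model == "aneuploidy")[1]
  r_cut <- structure(r[-drop, ],
    class = class(r),
    defaults = attr(r, "defaults")
  )
  expect_error(heatmap_matrix(r_cut, "Y", "aneuploidy"), "incomplete")
})

test_that("final frequency responds monotonically to k and L", {
  base <- model_params(location = "Y", s = 0, L = 1e6, p0 = 1e-4)
  finals_k <- vapply(c(0.005, 0.015, 0.03, 0.05), function(k) {
    iterate_model(modifyList_params(base, k = k),
      record_trajectory = FALSE
    )$final_frequency
  }, 0)
  expect_true(all(diff(finals_k) >= 0))

  finals_l <- vapply(c(0, 1e6, 3e6, 5e6), function(L) {
    iterate_model(modifyList_params(base, k = 0.02, L = L),
      record_trajectory = FALSE
    )$final_frequency
  }, 0)
  expect_true(all(diff(finals_l) <= 0))
})

test_that("heatmap autoplot returns a raster ggplot", {
  g <- default_grids(n = 2)
  d <- build_design(
    locations = "Y", L_grid = c(0, 1e6), s_grid = g$s_grid,
    k_grid = g$k_grid, h_values = 0.5, models = "aneuploidy"
  )
  m <- heatmap_matrix(run_sweep(d), "Y", "aneuploidy")
  expect_s3_class(autoplot(m), "ggplot")
})
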