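test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(101)
  p <- matrix(rnorm(18), 6, 3)
  # identity case
  fit <- superpose(p, p)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  # 90 degrees about z plus a shift
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- p %*% t(rz) + matrix(c(3, -2, 7), 6, 3, byrow = TRUE)
  fit2 <- superpose(moved, p)
  expect_lt(max(abs(fit2$coords - p)), 1e-8)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
  # degenerate (collinear) fit geometry is refused
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line + rnorm(15, sd = 1e-12), line), "collinear")
  expect_error(superpose(p[1:2, ], p[1:2, ]), "at least 3")
})

test_that("fitted RMSD matches the rotation-search oracle on random pairs", {
  set.seed(202)
  for (i in 1:5) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    expect_equal(rmsd(a, b, fit = TRUE), grid_search_min_rmsd(a, b),
                 tolerance = 1e-6)
    # independent library cross-check of the least-squares fit
    lib <- matrix(bio3d::rot.lsq(as.vector(t(a)), as.vector(t(b))),
                  5, 3, byrow = TRUE)
    expect_equal(rmsd(a, b, fit = TRUE), sqrt(mean(rowSums((lib - b)^2))),
                 tolerance = 1e-8)
  }
})

test_that("rmsd obeys its arithmetic and optimality contracts", {
  set.seed(303)
  a <- matrix(rnorm(12), 4, 3)
  expect_identical(rmsd(a, a), 0)
  # one of four atoms displaced by 2 A: sqrt(4/4) = 1
  b <- a
  b[2, 1] <- b[2, 1] + 2
  expect_equal(rmsd(a, b), 1.0)
  expect_equal(rmsd(a, b), rmsd(b, a))
  # fitting never increases the deviation
  for (i in 1:10) {
    x <- matrix(rnorm(24), 8, 3)
    y <- matrix(rnorm(24), 8, 3)
    expect_lte(rmsd(x, y, fit = TRUE), rmsd(x, y) + 1e-12)
  }
  expect_error(rmsd(a, b, indices = integer(0)), "empty")
})

test_that("RMSF is zero for static ensembles and scales with displacements", {
  toy <- make_toy_structure(seed = 21)
  static <- make_toy_trajectory(toy, n_frames = 5, sigma = 0, seed = 1)
  expect_true(all(rmsf(static) < 1e-12))
  expect_error(rmsf(make_toy_trajectory(toy, n_frames = 1, sigma = 0.1,
                                        seed = 1)),
               "two frames")
  # same seed, doubled jitter amplitude: every RMSF doubles
  t1 <- make_toy_trajectory(toy, n_frames = 200, sigma = 0.25, seed = 5)
  t2 <- make_toy_trajectory(toy, n_frames = 200, sigma = 0.50, seed = 5)
  r1 <- calpha_rmsf(t1)
  r2 <- calpha_rmsf(t2)
  expect_true(all(r1 >= 0))
  expect_equal(r2 / r1, rep(2, length(r1)), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("sheet order parameters track sheet geometry after a global fit", {
  toy <- make_toy_structure(seed = 31)
  ref <- toy$structure
  static <- make_toy_trajectory(toy, n_frames = 4, sigma = 0, seed = 1)
  ops <- sheet_order_parameters(static, toy$sheets, ref)
  expect_true(all(abs(ops$rmsd_a$value) < 1e-10))
  expect_true(all(abs(ops$rmsd_b$value) < 1e-10))
  expect_equal(diff(range(ops$com_distance$value)), 0, tolerance = 1e-10)

  # rigidly translating set_b by +3 A along the inter-sheet axis in one
  # frame raises the centre-of-mass distance by exactly 3 A (the global
  # fit is rigid, so internal distances are preserved)
  shifted <- ref$xyz
  bmask <- ref$atoms$res_index %in% toy$sheets$set_b
  shifted[bmask, 3] <- shifted[bmask, 3] + 3
  traj <- manual_trajectory(ref, list(ref$xyz, shifted))
  ops2 <- sheet_order_parameters(traj, toy$sheets, ref)
  expect_equal(ops2$com_distance$value[2] - ops2$com_distance$value[1], 3,
               tolerance = 1e-8)

  # a common rigid motion of the whole frame leaves the distance unchanged
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- ref$xyz %*% t(rz) + matrix(c(5, 5, 5), nrow(ref$xyz), 3,
                                      byrow = TRUE)
  traj3 <- manual_trajectory(ref, list(ref$xyz, moved))
  ops3 <- sheet_order_parameters(traj3, toy$sheets, ref)
  expect_equal(ops3$com_distance$value[1], ops3$com_distance$value[2],
               tolerance = 1e-8)

  bad <- list(set_a = 1:12, set_b = 10:24)
  expect_error(sheet_order_parameters(static, bad, ref), "overlap")
})

test_that("running averages are centered, truncated means", {
  const <- new_ts <- vhhscreen:::new_timeseries(0:9, rep(4, 10), "x")
  expect_equal(running_average(const, 5)$value, rep(4, 10))
  # a centered odd window leaves the interior of a linear ramp unchanged
  ramp <- vhhscreen:::new_timeseries(0:19, seq(0, 38, by = 2), "x")
  sm <- running_average(ramp, 5)
  expect_equal(sm$value[3:18], ramp$value[3:18])
  expect_equal(running_average(ramp, 1)$value, ramp$value)
  expect_error(running_average(ramp, 21), "exceeds")
  # plain numeric vectors are accepted too
  expect_equal(running_average(c(1, 2, 3), 3), c(1.5, 2, 2.5))
})
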