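test_that("construction: regular weights in [0,1], context weights zero, seeded", {
  m1 <- msom(n = 4, m = 5, seed = 9)
  m2 <- msom(n = 4, m = 5, seed = 9)
  expect_true(all(m1$Wt >= 0 & m1$Wt <= 1))
  expect_true(all(m1$Ct == 0))
  expect_identical(m1$Wt, m2$Wt)
  expect_false(identical(m1$Wt, msom(n = 4, m = 5, seed = 10)$Wt))
  expect_error(msom(n = 4, m = 5, zeta = 1.2), "zeta")
})

test_that("blended distance matches hand arithmetic and a scalar re-implementation", {
  map <- msom(n = 1, m = 2, zeta = 0.4, seed = 1)
  map$Wt[, 1] <- c(0, 0)
  map$Ct[, 1] <- c(0, 1)
  map$c_map <- c(0, 0)
  # (1-0.4)*||(1,0)-(0,0)||^2 + 0.4*||(0,0)-(0,1)||^2 = 0.6 + 0.4 = 1
  expect_equal(msom_distances(map, c(1, 0)), 1.0)
  expect_equal(msom_distances(map, c(1, 0)),
               scalar_blend_distance(c(1, 0), c(0, 0), c(0, 0), c(0, 1), 0.4))
  # random cross-check of the vectorized form against the scalar loop
  set.seed(5)
  map2 <- msom(n = 3, m = 7, zeta = 0.3, seed = 2)
  map2$Ct <- matrix(runif(63), 7, 9)
  cm <- runif(7); x <- runif(7)
  d <- msom_distances(map2, x, cm)
  for (i in 1:9) {
    expect_equal(d[i], scalar_blend_distance(x, map2$Wt[, i], cm, map2$Ct[, i], 0.3))
  }
  # zeta = 0 limit: pure content distance
  map2$zeta <- 0
  expect_equal(msom_distances(map2, x, cm), colSums((map2$Wt - x)^2))
  expect_error(msom_distances(map2, c(1, 2)), "width")
})

test_that("activity and pattern follow the exponential/normalized forms", {
  expect_equal(msom_activity(0), 1)
  expect_equal(msom_activity(1, nu = 1), exp(-1))
  expect_equal(msom_activity(c(2, 2, 2)), rep(exp(-2), 3))  # equal d -> equal a
  ap <- activity_pattern(c(1, 1, 2))
  expect_equal(ap$p, c(0.25, 0.25, 0.5))
  expect_equal(ap$bmu, 3L)
  apu <- activity_pattern(rep(3, 9))
  expect_equal(apu$p, rep(1 / 9, 9))
  expect_equal(apu$bmu, 1L)          # ties break to the lowest index
  expect_equal(sum(activity_pattern(runif(100))$p), 1, tolerance = 1e-12)
})

test_that("map context recursion matches hand arithmetic", {
  map <- msom(n = 2, m = 2, iota = 0.5, seed = 3)
  expect_equal(msom_context(map), c(0, 0))  # before any input
  map$Wt[, 2] <- c(1, 0); map$Ct[, 2] <- c(0, 1); map$last_bmu <- 2L
  expect_equal(msom_context(map), c(0.5, 0.5))
  # first step after init: c = (1 - iota) * w_bmu since all context weights are 0
  map$Ct[, 2] <- 0
  expect_equal(msom_context(map), 0.5 * c(1, 0))
  map$iota <- 1e-9                       # iota -> 0 limit: pure regular weight
  expect_equal(msom_context(map), c(1, 0), tolerance = 1e-6)
  expect_equal(msom_context(msom_reset_context(map)), c(0, 0))
})

test_that("training updates move weights as convex steps with neighbourhood decay", {
  map <- msom(n = 3, m = 4, seed = 1, lr_start = 1, lr_end = 1,
              sigma_start = 100, sigma_end = 100, t_max = 10)
  x <- c(1, 0, 0.5, 0.2)
  res <- msom_step(map, x)
  # l = 1 and h ~ 1 everywhere: the BMU weight lands exactly on x
  expect_equal(res$map$Wt[, res$bmu], x, tolerance = 1e-6)
  # l = 0: nothing moves
  map0 <- msom(n = 3, m = 4, seed = 1, lr_start = 1e-300, lr_end = 1e-300)
  res0 <- msom_step(map0, x)
  expect_equal(res0$map$Wt, map0$Wt, tolerance = 1e-12)
  # Gaussian neighbourhood: a unit 3 grid steps away moves strictly less than the BMU
  map2 <- msom(n = 10, m = 4, seed = 2, sigma_start = 1, sigma_end = 1)
  before <- map2$Wt
  r2 <- msom_step(map2, x)
  disp <- sqrt(colSums((r2$map$Wt - before)^2))
  far <- which(map2$grid_d2[, r2$bmu] == 9)[1]
  expect_lt(disp[far], disp[r2$bmu])
  # returned pattern is the pre-update pattern
  d_pre <- msom_distances(map2, x, numeric(4))
  expect_equal(r2$pattern, exp(-map2$nu * d_pre) / sum(exp(-map2$nu * d_pre)))
})

test_that("weights stay in [0,1]^m under inputs in [0,1]^m (convexity)", {
  set.seed(11)
  map <- msom(n = 5, m = 6, seed = 4, t_max = 500)
  for (t in 1:500) {
    map <- msom_step(map, runif(6))$map
  }
  expect_true(all(map$Wt >= 0 & map$Wt <= 1))
  expect_true(all(map$Ct >= 0 & map$Ct <= 1))
})

test_that("with zeta = 0 the BMU trajectory equals an independent plain SOM", {
  n <- 6; m <- 8; steps <- 10000
  map <- msom(n = n, m = m, zeta = 0, seed = 21, t_max = steps)
  set.seed(33)
  X <- matrix(runif(steps * m), steps, m)
  oracle <- plain_som_bmus(map$Wt, X, map$lr_start, map$lr_end,
                           map$sigma_start, map$sigma_end, map$t_max, n)
  got <- integer(steps)
  for (t in seq_len(steps)) {
    r <- msom_step(map, X[t, ])
    got[t] <- r$bmu
    map <- r$map
  }
  expect_identical(got, oracle)
})

test_that("identical seeds and input streams give bit-identical trajectories", {
  run <- function() {
    map <- msom(n = 4, m = 3, seed = 5, t_max = 50)
    set.seed(8)
    for (t in 1:50) map <- msom_step(map, runif(3))$map
    map
  }
  expect_identical(run()$Wt, run()$Wt)
  expect_identical(run()$Ct, run()$Ct)
})
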