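test_that("empty and short runs respect the trace contract", {
  obj <- cube_fixture()
  r0 <- explore(obj, steps = 0, seed = 1)
  expect_equal(nrow(r0$trace), 0)
  expect_true(all(r0$hitmap == 0))
  r <- explore(obj, steps = 50, seed = 1)
  expect_equal(nrow(r$trace), 50)
  expect_equal(sum(r$hitmap), 50)        # one increment per successful step
  expect_true(all(r$trace$alpha %in% 1:24))
  expect_true(all(r$trace$beta %in% 1:24))
})

test_that("identical seeds give identical traces, different seeds differ", {
  obj <- place_landmarks(cube_fixture(), 3, seed = 2)
  a <- explore(obj, steps = 300, seed = 5)
  b <- explore(obj, steps = 300, seed = 5)
  expect_identical(a$trace, b$trace)
  expect_identical(a$map$Wt, b$map$Wt)
  c <- explore(obj, steps = 300, seed = 6)
  expect_false(identical(a$trace$action, c$trace$action))
})

test_that("location posterior follows the mixture arithmetic of the hit map", {
  # single observed unit: conditional row (2,0,2)/4
  H <- matrix(0, 3, 3)
  H[1, ] <- c(2, 0, 2)
  pat <- c(1, 0, 0)
  expect_equal(location_posterior(H, pat), c(0.5, 0, 0.5))
  # pattern concentrated on an unobserved unit: uniform ignorance
  expect_equal(location_posterior(H, c(0, 1, 0)), rep(1 / 3, 3))
  # mixture of observed and unobserved rows still sums to 1
  H[2, ] <- c(0, 5, 0)
  pat2 <- c(0.3, 0.5, 0.2)
  post <- location_posterior(H, pat2)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_equal(post, 0.3 * c(0.5, 0, 0.5) + 0.5 * c(0, 1, 0) + 0.2 * rep(1 / 3, 3))
})

test_that("normalization holds at every step of a seeded 10^4-step run", {
  obj <- place_landmarks(cube_fixture(), 2, seed = 7)
  run <- explore(obj, steps = 10000, seed = 7)
  # activity patterns: recompute at spot-check steps from the stored map state
  # is impossible mid-run, so verify via the invariant carriers: the recorded
  # posterior-weighted geodesic distances are finite and the stored final
  # pattern is normalized
  expect_equal(sum(run$pattern), 1, tolerance = 1e-12)
  expect_true(all(is.finite(run$trace$dgeo)))
  # posterior normalization for a range of patterns against the final hit map
  set.seed(1)
  for (i in 1:50) {
    pat <- as.vector(rmultinom(1, 40, runif(100))) / 40
    expect_equal(sum(location_posterior(run$hitmap, pat)), 1, tolerance = 1e-12)
  }
  # per-step pattern normalization at full precision, checked on a fresh map
  map <- msom(n = 10, m = 15, seed = 1, t_max = 100)
  set.seed(2)
  for (t in 1:100) {
    r <- msom_step(map, runif(15))
    expect_equal(sum(r$pattern), 1, tolerance = 1e-12)
    map <- r$map
  }
})

test_that("window metrics match their definitions", {
  tr <- tibble::tibble(
    step = 1:10,
    match = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    alpha_rank = c(1, 3, 2, 1, 5, 2, 4, 1, 2, 3),
    dgeo = rep(2, 10)
  )
  expect_equal(p_max(tr, 10), 0.3)          # 3 matches in a window of 10
  expect_equal(p_max(tr[tr$match, ], 3), 1) # perfect decoder upper bound
  expect_equal(top_h_accuracy(tr, 10, h = 1), p_max(tr, 10))
  expect_equal(top_h_accuracy(tr, 10, h = 24), 1)
  hs <- vapply(1:5, function(h) top_h_accuracy(tr, 10, h), numeric(1))
  expect_true(all(diff(hs) >= 0))           # monotone in h
  expect_error(p_max(tr[0, ]), "empty")
  wm <- window_metrics(tr, phi = 5)
  expect_equal(nrow(wm), 6)
  expect_equal(wm$pmax[1], mean(tr$match[1:5]))
  expect_equal(wm$dgeo, rep(2, 6))
})

test_that("posterior-weighted geodesic distance matches direct sums", {
  obj <- cube_fixture()
  delta <- rep(0, 24); delta[5] <- 1
  expect_equal(d_geodesic(obj, delta, 5), 0)
  far <- which(geodesic_matrix(obj)[5, ] == 2)[1]
  delta2 <- rep(0, 24); delta2[far] <- 1
  expect_equal(d_geodesic(obj, delta2, 5), 2)
  # uniform posterior: mean of all BFS distances from alpha
  adj <- adj_list(obj)
  expect_equal(d_geodesic(obj, rep(1 / 24, 24), 7), mean(bfs_distances(adj, 7)))
})

test_that("chance baselines equal the uniform-null expectations", {
  obj <- cube_fixture()
  expect_equal(chance_p_max(obj), 1 / 24)
  adj <- adj_list(obj)
  expect_equal(chance_d_geodesic(obj),
               mean(vapply(1:24, function(a) mean(bfs_distances(adj, a)), numeric(1))))
  # Monte-Carlo under the uniform null: random argmax among 24 tied cells
  set.seed(4)
  hits <- replicate(20000, sample.int(24, 1) == sample.int(24, 1))
  expect_lt(abs(mean(hits) - chance_p_max(obj)), 3 * sqrt((1/24) * (23/24) / 20000))
})

test_that("episodic structure anchors decoding above chance on the unmarked cube", {
  obj <- cube_fixture()
  run <- explore(obj, steps = 8000, seed = 3)
  expect_gt(p_max(run$trace, 1000), chance_p_max(obj))
  expect_lt(mean(utils::tail(run$trace$dgeo, 1000)), chance_d_geodesic(obj))
  expect_gt(max(run$trace$episode), 1)
})

test_that("tidy/glance/autoplot methods work on exploration runs", {
  obj <- place_landmarks(cube_fixture(), 2, seed = 1)
  run <- explore(obj, steps = 500, seed = 2)
  td <- tidy(run)
  expect_true(all(c("face", "x", "y", "bmu", "beta") %in% names(td)))
  gl <- glance(run, phi = 200)
  expect_equal(gl$steps, 500)
  expect_s3_class(autoplot(run, phi = 200), "ggplot")
})
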