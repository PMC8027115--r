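test_that("the articulated repertoire has exactly 10 actions, the unarticulated 6", {
  expect_length(hand_actions(TRUE), 10)
  expect_length(unique(hand_actions(TRUE)), 10)
  expect_length(hand_actions(FALSE), 6)
})

test_that("reset is deterministic and picks the right finger situation", {
  obj <- cube_fixture()
  # heading toward the face interior: ahead cell exists
  st <- hand_reset(obj, c(1, 1, 1), heading = "N")
  expect_equal(st$config, "on")
  # heading toward the near boundary: finger extends over the edge
  st2 <- hand_reset(obj, c(1, 1, 1), heading = "S")
  expect_equal(st2$config, "over")
  expect_identical(hand_reset(obj, c(1, 1, 1), "N"), hand_reset(obj, c(1, 1, 1), "N"))
  expect_error(hand_reset(obj, 99), "invalid")
})

test_that("bend/unbend constraints follow the finger state machine", {
  obj <- cube_fixture()
  on <- hand_reset(obj, c(1, 1, 1), "N")       # straight, finger on surface
  over <- hand_reset(obj, c(1, 1, 1), "S")     # straight, over the edge
  expect_false("bend" %in% feasible_actions(obj, on))
  expect_true("bend" %in% feasible_actions(obj, over))
  expect_false("unbend" %in% feasible_actions(obj, on))
  bent <- apply_action(obj, over, "bend")$state
  expect_equal(bent$config, "bent")
  feas_bent <- feasible_actions(obj, bent)
  expect_true("unbend" %in% feas_bent)
  expect_false("bend" %in% feas_bent)
  # a bent finger anchors the hand: no translations or rotations
  expect_equal(feas_bent, "unbend")
  # unbend in a straight state signals infeasibility and leaves state unchanged
  res <- apply_action(obj, on, "unbend")
  expect_false(res$success)
  expect_identical(res$state, on)
})

test_that("the three-step edge transition lands the palm on the adjacent face", {
  obj <- cube_fixture()
  st <- hand_reset(obj, c(1, 1, 1), "N")
  r1 <- apply_action(obj, st, "fwd_over")      # to the boundary, finger over
  expect_true(r1$success)
  expect_equal(r1$state$config, "over")
  r2 <- apply_action(obj, r1$state, "bend")
  expect_true(r2$success)
  r3 <- apply_action(obj, r2$state, "unbend")
  expect_true(r3$success)
  expect_equal(obj$cells$face[r3$state$cell], 4)  # crossed from top to back
  # heading continues in the direction of travel (tangent to the new face)
  expect_equal(sum(r3$state$dir == 1:6), 1)
  expect_true(all(obj$dirs[r3$state$dir, ] * obj$normals[r3$state$cell, ] == 0))
})

test_that("translation moves one cell and preserves heading", {
  obj <- build_cuboid(c(3, 2, 1))
  st <- hand_reset(obj, c(1, 2, 1), "N")   # interior-ish cell on the 3x2 top
  res <- apply_action(obj, st, "fwd_on")
  if (res$success) {
    expect_equal(res$state$dir, st$dir)
    expect_equal(geodesic(obj, st$cell, res$state$cell), 1)
  }
  # exactly one of fwd_on / fwd_over succeeds from any straight-on state
  r2 <- apply_action(obj, st, "fwd_over")
  expect_equal(sum(res$success, r2$success), 1)
})

test_that("every reachable state has a feasible action and valid transitions", {
  for (articulated in c(TRUE, FALSE)) {
    obj <- cube_fixture()
    sg <- state_graph(obj, articulated)
    # exhaustive: every enumerated state offers at least one feasible action
    expect_true(all(rowSums(sg$trans > 0) >= 1))
    # transitions stay inside the enumeration
    expect_true(all(sg$trans >= 0 & sg$trans <= nrow(sg$states)))
    # reachability from the canonical start covers the whole state space
    reach <- rep(FALSE, nrow(sg$states))
    frontier <- state_id(sg = sg, state = hand_reset(obj, articulated = articulated))
    reach[frontier] <- TRUE
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(as.vector(sg$trans[frontier, ])), 0)
      nxt <- nxt[!reach[nxt]]
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    expect_true(all(reach))
  }
})

test_that("all 10 actions are executable somewhere on the cuboid", {
  # the 3-cell-long faces of the 3x2x1 cuboid afford every slip signature;
  # on the all-2x2-face cube fwd_on and back_on are unaffordable (any
  # straight-on palm sits one cell from the edge it faces, so forward always
  # ends in overhang and there is never a cell behind)
  sg <- state_graph(cuboid_fixture(), TRUE)
  expect_true(all(colSums(sg$trans > 0) > 0))
  sgc <- state_graph(cube_fixture(), TRUE)
  used <- colSums(sgc$trans > 0) > 0
  expect_true(all(used[!hand_actions() %in% c("fwd_on", "back_on")]))
  expect_false(any(used[hand_actions() %in% c("fwd_on", "back_on")]))
})

test_that("percepts have width 13 + L and the advertised bit layout", {
  obj <- place_landmarks(cube_fixture(), 5, seed = 1)
  st <- hand_reset(obj, c(1, 1, 1), "N")
  x <- hand_percept(obj, st, "rot_cw")
  expect_length(x, 18)
  expect_equal(sum(x[1:10]), 1)
  expect_equal(x[which(hand_actions() == "rot_cw")], 1)
  expect_equal(x[13], 1)                      # palm contact always on
  lm_cell <- which(obj$landmarks == 3)
  st_lm <- hand_reset(obj, lm_cell, "N")
  x2 <- hand_percept(obj, st_lm, "rot_cw")
  expect_equal(x2[13 + 3], 1)
  expect_equal(sum(x2[14:18]), 1)
  # bent states report bent shape plus finger contact
  over <- hand_reset(obj, c(1, 1, 1), "S")
  bent <- apply_action(obj, over, "bend")$state
  xb <- hand_percept(obj, bent, "bend")
  expect_equal(xb[11:13], c(1, 1, 1))
  xo <- hand_percept(obj, over, "rot_cw")
  expect_equal(xo[11:12], c(0, 0))            # straight, finger in the air
})

test_that("contact with the object is maintained after every feasible action", {
  obj <- cube_fixture()
  sg <- state_graph(obj, TRUE)
  for (s in seq_len(nrow(sg$states))) {
    for (a in which(sg$trans[s, ] > 0)) {
      s2 <- sg$trans[s, a]
      cfg <- sg$states$config[s2]
      x <- hand_percept(obj, new_state <- structure(
        list(cell = sg$states$cell[s2], dir = sg$states$dir[s2],
             config = cfg, articulated = TRUE), class = "hand_state"),
        sg$actions[a])
      expect_true(x[12] == 1 || x[13] == 1)
    }
  }
})

test_that("unarticulated translations cross edges as plain moves", {
  obj <- cube_fixture()
  st <- hand_reset(obj, c(1, 1, 1), "S", articulated = FALSE)
  res <- apply_action(obj, st, "fwd")   # walks off the top face southward
  expect_true(res$success)
  expect_equal(obj$cells$face[res$state$cell], 2)
  # all six actions are feasible everywhere: fewer sequence constraints
  sg <- state_graph(obj, FALSE)
  expect_true(all(sg$trans > 0))
})

test_that("the BFS action-path bound from start to goal on the cube is attainable and > geodesic", {
  obj <- cube_fixture()
  st <- hand_reset(obj, c(1, 1, 1), "N")
  goal <- cell_index(obj, 3, 1, 2)
  bound <- shortest_action_path(obj, st, goal)
  # crossing each of at least 2 edges costs fwd_over+bend+unbend
  expect_gte(bound, geodesic(obj, st$cell, goal))
  expect_lte(bound, 100)
  expect_equal(shortest_action_path(obj, st, st$cell), 0)
})
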