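# Trajectory termination, cycle classification, and the exhaustive
# attractor oracle.

test_that("a monotone approach to a constant target is a fixed point", {
  m <- qn_model(list(qn_node("A", c(0, 4), "2")))
  traj <- simulate_qn(m, c(A = 0))
  expect_equal(traj$terminal, "fixed_point")
  expect_equal(traj$steps_taken, 3)  # 0 -> 1 -> 2 -> 2 (repeat confirms)
  expect_equal(as.vector(traj$states[, "A"]), c(0, 1, 2, 2))
  expect_equal(unname(final_state(traj)["A"]), 2)
})

test_that("the toggle settles at a saturated fixed point from a biased start", {
  m <- toggle_model()
  traj <- simulate_qn(m, c(A = 4L, B = 0L))
  expect_equal(traj$terminal, "fixed_point")
  expect_equal(unname(final_state(traj)), c(4L, 0L))
})

test_that("negative feedback from the centre state yields a cycle", {
  m <- make_fixture("negative_feedback")$model
  traj <- simulate_qn(m, c(A = 2L, B = 2L))
  expect_equal(traj$terminal, "cycle")
  expect_gt(traj$cycle_length, 1)
})

test_that("attractor enumeration partitions the toggle's 25 states", {
  m <- toggle_model()
  att <- find_attractors(m)
  expect_equal(att$state_space_size, 25)
  expect_equal(sum(att$basin_sizes), 25)
  sizes <- vapply(att$attractors, nrow, integer(1))
  fps <- att$attractors[sizes == 1L]
  expect_length(fps, 2)
  fp_states <- lapply(fps, function(a) as.integer(a[1L, ]))
  expect_true(any(vapply(fp_states, identical, logical(1), c(4L, 0L))))
  expect_true(any(vapply(fp_states, identical, logical(1), c(0L, 4L))))
  expect_true(any(sizes > 1L))  # the symmetric cycle
})

test_that("a model of only input nodes has every state as a fixed point", {
  m <- qn_model(list(qn_node("A", c(0, 2)), qn_node("B", c(0, 1))))
  att <- find_attractors(m)
  expect_length(att$attractors, 6)
  expect_true(all(att$basin_sizes == 1))
})

test_that("one driven node funnels its whole range to the constant", {
  m <- qn_model(list(qn_node("A", c(0, 4), "2")))
  att <- find_attractors(m)
  expect_length(att$attractors, 1)
  expect_equal(as.integer(att$attractors[[1]]), 2L)
  expect_equal(att$basin_sizes, 5L)
})

test_that("enumeration refuses oversized state spaces with the size", {
  m <- qn_model(list(qn_node("A", c(0, 100)), qn_node("B", c(0, 100))))
  expect_error(find_attractors(m, limit = 1000), "10201")
})

test_that("simulate endpoints lie in enumerated attractors (oracle equivalence)", {
  set.seed(5)
  for (rep in 1:10) {
    fx <- make_fixture("random", size = sample(2:4, 1), seed = 300 + rep)
    m <- fx$model
    att <- find_attractors(m)
    expect_equal(sum(att$basin_sizes), att$state_space_size)
    for (j in 1:3) {
      s <- random_state(m)
      endpoint <- final_state(simulate_qn(m, s))
      expect_false(is.na(attractor_of(att, endpoint)))
      # and the endpoint agrees with the independent recursive orbit walker
      expect_identical(endpoint, oracle_orbit_end(m, s))
    }
  }
})

test_that("trajectories repeat within the pigeonhole bound and are deterministic", {
  m <- make_fixture("negative_feedback")$model
  n_states <- 25
  set.seed(8)
  for (j in 1:10) {
    s <- random_state(m)
    t1 <- simulate_qn(m, s)
    t2 <- simulate_qn(m, s)
    expect_lte(t1$steps_taken, n_states + 1)
    expect_identical(t1, t2)
  }
})

test_that("is_fixed_point agrees with step self-mapping", {
  m <- qn_model(list(qn_node("A", c(0, 4), "2")))
  expect_true(is_fixed_point(m, c(A = 2)))
  expect_false(is_fixed_point(m, c(A = 1)))
})
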