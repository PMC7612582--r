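# Core update semantics: default targets, the synchronous +/-1 step,
# clamping, and model validation.

test_that("default targets follow the avg(activators) - avg(inhibitors) rule", {
  m <- qn_model(
    list(qn_node("A"), qn_node("B"), qn_node("C"), qn_node("X")),
    rbind(qn_edge("A", "X", "activator"),
          qn_edge("B", "X", "activator"),
          qn_edge("C", "X", "inhibitor"))
  )
  expect_equal(deparse_target(default_target("X", m)), "avg(A, B) - avg(C)")
  # no incoming edges: the node holds its value
  expect_equal(deparse_target(default_target("A", m)), "A")
  expect_error(default_target("Nope", m), "unknown node")
})

test_that("a node with only an inhibitor is driven to its range floor", {
  m <- qn_model(
    list(qn_node("C", target = "4"), qn_node("X")),
    qn_edge("C", "X", "inhibitor")
  )
  expect_equal(eval_target(default_target("X", m), c(C = 4, X = 2)), -4)
  s <- c(C = 4L, X = 2L)
  for (i in 1:5) s <- qn_step(m, s)
  expect_equal(unname(s["X"]), 0)
})

test_that("a step moves each node by at most one level toward its target", {
  m <- qn_model(list(qn_node("A", target = "2")))
  expect_equal(unname(qn_step(m, c(A = 2))["A"]), 2)   # at target: no change
  m2 <- qn_model(list(qn_node("A", c(0, 4), "37 / 10")))  # target value 3.7
  expect_equal(unname(qn_step(m2, c(A = 0))["A"]), 1)  # distant target: +1 only
  # held driver relay: B climbs one level per step
  m3 <- two_node_relay()
  s <- c(A = 4L, B = 0L)
  for (i in 1:4) s <- qn_step(m3, s)
  expect_equal(unname(s["B"]), 4)
  expect_equal(unname(qn_step(m3, s)), c(4L, 4L))       # then holds
})

test_that("range safety and bounded motion hold on random models and states", {
  set.seed(42)
  for (rep in 1:30) {
    fx <- make_fixture("random", size = sample(2:5, 1), seed = rep)
    m <- fx$model
    lo <- vapply(m$nodes, `[[`, integer(1), "range_lo")
    hi <- vapply(m$nodes, `[[`, integer(1), "range_hi")
    for (j in 1:5) {
      s <- random_state(m)
      nxt <- qn_step(m, s)
      expect_true(all(nxt >= lo & nxt <= hi))
      expect_true(all(abs(nxt - s) <= 1))
    }
  }
})

test_that("step is synchronous: node declaration order does not matter", {
  nodes <- list(qn_node("A", target = "B"), qn_node("B", target = "4 - A"),
                qn_node("C", target = "avg(A, B)"))
  m1 <- qn_model(nodes)
  m2 <- qn_model(rev(nodes))
  set.seed(7)
  for (i in 1:20) {
    s <- random_state(m1)
    n1 <- qn_step(m1, s)
    n2 <- qn_step(m2, s[node_names(m2)])
    expect_identical(n1[sort(names(n1))], n2[sort(names(n2))])
  }
})

test_that("step agrees with the independent single-state oracle", {
  set.seed(99)
  models <- c(
    list(toggle_model(), two_node_relay(), make_fixture("negative_feedback")$model),
    lapply(1:10, function(i) make_fixture("random", size = 4, seed = 1000 + i)$model)
  )
  for (m in models) {
    for (j in 1:10) {
      s <- random_state(m)
      expect_identical(qn_step(m, s), oracle_step(m, s))
    }
  }
})

test_that("a constant target within range is reached in exactly |v0 - c| steps", {
  m <- qn_model(list(qn_node("A", c(0, 4), "3")))
  for (v0 in 0:4) {
    s <- c(A = v0)
    need <- abs(v0 - 3L)
    if (need > 0) {
      for (i in seq_len(need - 1L)) {
        s <- qn_step(m, s)
        expect_false(s[["A"]] == 3L)   # not there one step early
      }
      s <- qn_step(m, s)
    }
    expect_equal(s[["A"]], 3L)
    expect_true(is_fixed_point(m, s))
  }
})

test_that("clamping forces levels after the move", {
  m <- two_node_relay()
  s <- qn_step(m, c(A = 4L, B = 0L), clamp = c(B = 0L))
  expect_equal(unname(s["B"]), 0)
})

test_that("validation reports all violations and accepts well-formed models", {
  good <- two_node_relay()
  expect_length(validate_qn_model(good), 0)

  bad <- good
  bad$edges <- rbind(bad$edges, data.frame(from = "X", to = "B",
                                           sign = "activator"))
  expect_match(validate_qn_model(bad), "unknown source 'X'", all = FALSE)

  expect_error(qn_model(list(qn_node("A", c(3, 1)))), "inverted range")
  expect_error(qn_model(list(qn_node("A"), qn_node("A"))), "duplicate node")
  expect_error(qn_model(list(qn_node("A", target = "Ghost + 1"))),
               "undeclared node 'Ghost'")
})

test_that("states are validated against node ranges and coverage", {
  m <- two_node_relay()
  expect_error(qn_state(m, c(A = 1L)), "exactly the model's nodes")
  expect_error(qn_state(m, c(A = 9L, B = 0L)), "out of range")
  s <- qn_state(m, c(B = 1L, A = 2L))
  expect_identical(names(s), c("A", "B"))  # normalised to declaration order
})
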