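# Synthetic fixtures are self-certifying: every "expected" fact is
# re-derived here by the simulation engine or the brute-force oracle.

test_that("fixture expectations are reproduced by the attractor oracle", {
  for (kind in c("toggle", "negative_feedback", "relay")) {
    fx <- make_fixture(kind, size = 2)
    att <- find_attractors(fx$model)
    sizes <- vapply(att$attractors, nrow, integer(1))
    fps <- lapply(att$attractors[sizes == 1L],
                  function(a) stats::setNames(as.integer(a[1L, ]), colnames(a)))
    exp_fps <- fx$expected$fixed_points
    expect_equal(length(fps), length(exp_fps), info = kind)
    for (fp in exp_fps) {
      expect_true(any(vapply(fps, function(x) all(x == fp[names(x)]),
                             logical(1))), info = kind)
    }
    expect_identical(any(sizes > 1L), fx$expected$has_cycle, info = kind)
  }
})

test_that("the constant chain converges to the driven level within its bound", {
  fx <- make_fixture("constant_chain", size = 3)
  m <- fx$model
  init <- stats::setNames(rep(0L, 3), node_names(m))
  traj <- simulate_qn(m, init)
  expect_equal(traj$terminal, "fixed_point")
  expect_lte(traj$steps_taken, fx$expected$convergence_bound)
  expect_true(all(final_state(traj) == fx$expected$driven_level))
})

test_that("random fixtures are seed-reproducible and oracle-checkable", {
  a <- make_fixture("random", size = 5, seed = 7)
  b <- make_fixture("random", size = 5, seed = 7)
  expect_identical(a$model[c("nodes", "edges")], b$model[c("nodes", "edges")])
  widths <- vapply(a$model$nodes, function(n) n$range_hi - n$range_lo + 1L,
                   integer(1))
  expect_lte(prod(widths), 1e5)
  expect_error(make_fixture("random", size = 3), "requires a seed")
})

test_that("noiseless synthetic traces recover their phase levels exactly", {
  p <- stress_protocol()
  for (levels in list(c(4, 2, 8, 0), c(5, 3, 10, 1), c(7, 7, 7, 7))) {
    m <- compute_metrics(make_synthetic_trace(levels, 0, p), p)
    expect_equal(m$basal, levels[1])
    expect_equal(m$atp_linked, levels[1] - levels[2])
    expect_equal(m$maximal, levels[3])
    expect_equal(m$spare, levels[3] - levels[1])
    expect_equal(m$non_mito, levels[4])
  }
})

test_that("noisy traces are reproducible from the seed", {
  t1 <- make_synthetic_trace(c(4, 2, 8, 0), noise_sd = 0.4, seed = 31)
  t2 <- make_synthetic_trace(c(4, 2, 8, 0), noise_sd = 0.4, seed = 31)
  expect_identical(t1$OCR, t2$OCR)
  expect_error(make_synthetic_trace(c(4, 2, 8, 0), noise_sd = -1), ">= 0")
})

test_that("recovered basal is unbiased under moderate noise", {
  set.seed(19)
  basals <- replicate(50, {
    tr <- make_synthetic_trace(c(4, 2, 8, 0), noise_sd = 0.4)
    compute_metrics(tr)$basal
  })
  se <- stats::sd(basals) / sqrt(length(basals))
  expect_lt(abs(mean(basals) - 4), 2 * max(se, 1e-8))
})

test_that("flat phase levels give near-zero spare capacity regardless of noise", {
  # spare = (max over the FCCP window) - (mean basal): one discretisation
  # level of headroom plus the sampling jitter of the basal mean
  jitter <- 2 * 0.3 / sqrt(15)
  for (seed in 1:5) {
    tr <- make_synthetic_trace(c(5, 5, 5, 5), noise_sd = 0.3, seed = seed)
    m <- compute_metrics(tr)
    expect_lte(abs(m$spare), 1 + jitter)
  }
})
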