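radial_like <- function() straight_element("ra", 1, linear_law(7), 0.2)

test_that("effective elongation subtracts own and transmitted slack", {
  el <- straight_element("s", 1, linear_law(1), 1)
  expect_equal(effective_elongation(el, 0.2), 0.2)
  el$accumulated_slack <- 0.3
  expect_equal(effective_elongation(el, 1.0), 0.7)
  cp <- straight_element("ax", 1, linear_law(1), 1,
                         coupling_source = "uf1", Cs = 0.999)
  cp$accumulated_slack <- 0.5
  expect_equal(effective_elongation(cp, 2.0, upstream_slack = 1.0), 0.501)
  # slack can exceed the applied strain: negative result is legal
  expect_lt(effective_elongation(cp, 0.1, upstream_slack = 1.0), 0)
})

test_that("element force follows the piecewise law with area scaling", {
  ra <- radial_like()
  expect_equal(element_force(ra, 0.1), 0.7) # 7 * 0.1 * 1^2
  expect_equal(element_force(ra, -0.05), 0) # slack carries no load
  expect_equal(element_force(ra, 0.25), 0)  # past critical strain
  thin <- straight_element("s", 0.2, linear_law(7), 1)
  expect_equal(element_force(thin, 0.1), 7 * 0.1 * 0.04)
  ra$failed <- TRUE
  expect_equal(element_force(ra, 0.1), 0)
})

test_that("failure predicate distinguishes straight and looped elements", {
  ra <- radial_like()
  expect_false(element_failed(ra, 0.19))
  expect_true(element_failed(ra, 0.25))
  lo <- looped_element("L", 1, linear_law(1), c(0.1, 0.2), c(0.05, 0.05),
                       post_loop_critical_strain = 0.5)
  expect_false(element_failed(lo, 10)) # cannot fail while loops remain
  opened <- open_next_loop(lo, 0.1)$element
  opened <- open_next_loop(opened, 0.4)$element
  expect_false(element_failed(opened, 0.49))
  expect_true(element_failed(opened, 0.51))
})

test_that("open_next_loop applies the reset rule in ascending threshold order", {
  lo <- looped_element("L", 1, linear_law(1), c(0.3, 0.1, 0.2),
                       c(0.05, 0.05, 0.05))
  r1 <- open_next_loop(lo, 0.1)
  expect_equal(r1$event$threshold, 0.1) # smallest first despite input order
  expect_equal(r1$element$accumulated_slack, 0.15)
  r2 <- open_next_loop(r1$element, 0.35)
  expect_equal(r2$event$threshold, 0.2)
  r3 <- open_next_loop(r2$element, 0.7)
  expect_equal(r3$element$accumulated_slack, 0.75)
  expect_error(open_next_loop(r3$element, 1), "no unopened loops")
  # hidden_only mode adds only the released length
  expect_equal(open_next_loop(lo, 0.1, slack_mode = "hidden_only")$element$
                 accumulated_slack, 0.05)
})

test_that("quasi-static ramp opens loops at the closed-form strains", {
  b <- single_loop_bundle(c(0.1, 0.2, 0.3), rep(0.05, 3))
  dx <- 0.001
  sim <- simulate_bundle(b, x_max = 2, dx = dx)
  op <- sim$events[sim$events$event == "loop_open", ]
  expect_true(all(abs(op$strain - c(0.10, 0.35, 0.70)) <= dx + 1e-12))
  # zero hidden length: re-engages immediately after opening
  b0 <- single_loop_bundle(0.2, 0)
  sim0 <- simulate_bundle(b0, x_max = 1, dx = dx)
  expect_lte(abs(sim0$events$strain[1] - 0.2), dx + 1e-12)
  i <- match(round(sim0$events$strain[1], 9), round(sim0$curve$strain, 9))
  # post-opening effective elongation is ~0, so the force is at most k * dx
  expect_lte(sim0$curve$force[i], dx + 1e-12)
})

test_that("stepping solver matches the closed-form opening strains (oracle)", {
  for (s in 1:5) {
    n <- 3 + (s %% 8)
    thr <- sample_pm(uniform_pm(0.5, 0.45), n, seed = s)
    hid <- sample_pm(uniform_pm(0.1, 0.05), n, seed = 100 + s)
    dx <- 0.002
    sim <- simulate_bundle(single_loop_bundle(thr, hid, post_xc = 1),
                           x_max = 20, dx = dx)
    op <- sim$events[sim$events$event == "loop_open", ]
    expected <- closed_form_openings(thr, hid)
    expect_equal(nrow(op), n)
    expect_true(all(abs(op$strain - expected) <= dx))
  }
})

test_that("accumulated slack of 200 sampled loops matches its expectation", {
  # E[slack] = 200 * (0.150 + 0.038) = 37.6 under the reset rule
  slacks <- vapply(1:20, function(s) {
    thr <- sample_pm(uniform_pm(0.150, 0.145), 200, seed = 1000 + s)
    hid <- sample_pm(uniform_pm(0.038, 0.002), 200, seed = 2000 + s)
    sum(thr) + sum(hid)
  }, 0)
  expect_lt(abs(mean(slacks) - 37.6), 0.8)
  expect_true(all(abs(slacks - 37.6) < 5))
})

test_that("slack and opened-loop count are non-decreasing through a run", {
  b <- equal_diameter_bundle(seed = 2)
  x_grid <- seq(0, 3, by = 0.05)
  slack <- 0
  for (x in x_grid) {
    st <- step_bundle(b, x)
    b <- st$bundle
    s_now <- sum(vapply(b$elements, `[[`, 0, "accumulated_slack"))
    expect_gte(s_now, slack)
    slack <- s_now
  }
  expect_error(step_bundle(b, 1), "non-monotone")
})

test_that("a looped element with zero loops reduces to a straight element", {
  lo <- bundle(list(looped_element("e", 0.5, linear_law(3), numeric(),
                                   numeric(), post_loop_critical_strain = 0.4)))
  st <- bundle(list(straight_element("e", 0.5, linear_law(3), 0.4)))
  sim_l <- simulate_bundle(lo, x_max = 1, dx = 0.005)
  sim_s <- simulate_bundle(st, x_max = 1, dx = 0.005)
  expect_equal(sim_l$curve, sim_s$curve)
  expect_equal(sim_l$events$event, "element_fail")
})

test_that("between events the force is continuous and rises; openings reset it", {
  thr <- c(0.3, 0.8)
  b <- single_loop_bundle(thr, rep(0.1, 2), post_xc = 1)
  sim <- simulate_bundle(b, x_max = 3, dx = 0.001)
  f <- sim$curve$force
  x <- sim$curve$strain
  op_idx <- match(round(sim$events$strain[sim$events$event == "loop_open"], 9),
                  round(x, 9))
  expect_equal(f[op_idx], c(0, 0)) # force resets to zero at each opening
  # strictly between events, increments are small (continuity on the grid)
  ev_idx <- match(round(sim$events$strain, 9), round(x, 9))
  ok <- setdiff(seq_len(length(f) - 1), c(ev_idx - 1, ev_idx))
  expect_true(all(abs(diff(f)[ok]) <= 1.5e-3)) # at most k * dx, k = 1
})
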