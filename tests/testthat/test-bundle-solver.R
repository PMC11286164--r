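test_that("classic FBM closed form evaluates and validates its CDF", {
  punif01 <- function(x) pmin(pmax(x, 0), 1)
  expect_equal(classic_fbm_force(10, 1, 0.5, punif01), 2.5)
  expect_equal(classic_fbm_force(10, 1, 0, punif01), 0)
  expect_equal(classic_fbm_force(10, 1, 1.2, punif01), 0) # all failed
  # tabulated CDF, interpolated
  tab <- data.frame(x = c(0, 0.5, 1), P = c(0, 0.5, 1))
  expect_equal(classic_fbm_force(10, 1, 0.25, tab), 10 * 0.25 * 0.75)
  expect_error(classic_fbm_force(10, 1, 0.5, data.frame(x = c(0, 1),
                                                        P = c(0.8, 0.2))),
               "invalid CDF")
})

test_that("bundle construction enforces unique ids and coupling integrity", {
  e1 <- straight_element("a", 1, linear_law(1), 1)
  expect_error(bundle(list(e1, e1)), "duplicate")
  cp <- straight_element("ax", 1, linear_law(1), 1,
                         coupling_source = "nope", Cs = 0.9)
  expect_error(bundle(list(e1, cp)), "nope")
  # coupling to a straight element is also rejected
  cp2 <- straight_element("ax", 1, linear_law(1), 1,
                          coupling_source = "a", Cs = 0.9)
  expect_error(bundle(list(e1, cp2)), "looped")
})

test_that("total force sums engaged elements; degenerate bundles carry none", {
  expect_equal(total_force(bundle(list()), 0.5), 0)
  b <- build_bundle(default_kukulcania_config(), seed = 1)
  f <- total_force(b, 0.1)
  expect_gt(f, 0.7) # radial alone contributes 7 * 0.1 * 1^2
  b_failed <- b
  for (i in seq_along(b_failed$elements)) b_failed$elements[[i]]$failed <- TRUE
  expect_equal(total_force(b_failed, 0.1), 0)
})

test_that("step resolves sub-threshold, opening and failure cases", {
  b <- single_loop_bundle(0.1, 0.05, post_xc = 0.5)
  st <- step_bundle(b, 0.05)
  expect_gt(st$force, 0)
  expect_equal(nrow(st$events), 0)
  st2 <- step_bundle(st$bundle, 0.1)
  expect_equal(st2$force, 0) # reset leaves x_e = -hidden < 0
  expect_equal(st2$events$event, "loop_open")
  ra <- bundle(list(straight_element("ra", 1, linear_law(7), 0.2)))
  st3 <- step_bundle(ra, 0.21)
  expect_equal(st3$force, 0)
  expect_equal(st3$events$event, "element_fail")
})

test_that("a single linear fibre peaks at its critical strain", {
  b <- bundle(list(straight_element("f", 1, linear_law(1), 0.5)))
  sim <- simulate_bundle(b, x_max = 1, dx = 0.01)
  expect_equal(max(sim$curve$force), 0.5, tolerance = 1e-9)
  expect_equal(sim$curve$strain[which.max(sim$curve$force)], 0.5,
               tolerance = 1e-9)
  expect_equal(sim$final_strain, 0.5, tolerance = 1e-9)
  after <- sim$curve$force[sim$curve$strain > 0.5 + 1e-12]
  expect_true(all(after == 0))
  expect_error(simulate_bundle(b, x_max = 1, dx = 0), "dx")
  expect_error(simulate_bundle(b, x_max = -1), "x_max")
})

test_that("simulation traces are well-formed on the default thread", {
  sim <- default_sim(1)
  expect_true(all(diff(sim$curve$strain) > 0))
  expect_true(all(sim$curve$force >= 0))
  expect_equal(sim$curve$force[nrow(sim$curve)], 0) # ends fully failed
  # every loop opens exactly once: 8 looped elements x 200 loops
  expect_equal(sum(sim$events$event == "loop_open"), 1600)
  expect_equal(sum(sim$events$event == "element_fail"), 11)
  expect_true(all(diff(sim$events$strain) >= 0))
})

test_that("openings interleave across looped structures", {
  sim <- default_sim(1)
  op <- sim$events[sim$events$event == "loop_open", ]
  expect_true(is.unsorted(op$element_id)) # not grouped element by element
  # each looped element contributes exactly its own 200 loops
  expect_true(all(table(op$element_id) == 200))
})

test_that("near-identical thresholds create zero-force plateaus", {
  els <- lapply(1:3, function(i)
    looped_element(paste0("L", i), 1, linear_law(1),
                   rep(0.15, 5), rep(0.038, 5), post_loop_critical_strain = 0.5))
  sim <- simulate_bundle(bundle(els), x_max = 3, dx = 0.002)
  f <- sim$curve$force
  r <- rle(f == 0)
  longest <- max(r$lengths[r$values])
  # all elements reset together, then their hidden length (0.038 strain,
  # ~19 grid steps) must straighten before any force returns
  expect_gte(longest * 0.002, 0.038 - 0.002)
})

test_that("with loops removed the thread reduces to a plain nonlinear FBM", {
  cfg <- default_kukulcania_config()
  cfg <- set_config_value(cfg, "groups.uf.loops.count", 0L)
  cfg <- set_config_value(cfg, "groups.pc.loops.count", 0L)
  sim <- simulate_thread(cfg, seed = 3)
  expect_equal(sum(sim$events$event == "loop_open"), 0)
  expect_lte(sim$final_strain, 0.5) # max critical strain in the bundle
  last_fail <- max(sim$events$strain)
  expect_true(all(sim$curve$force[sim$curve$strain >= last_fail] == 0))
})

test_that("halving the step size barely moves the final strain", {
  s1 <- default_sim(1)
  s2 <- simulate_thread(default_kukulcania_config(), seed = 1, dx = 0.0025)
  expect_lt(abs(s2$final_strain - s1$final_strain) / s1$final_strain, 0.01)
})

test_that("hidden_only slack mode shortens the run", {
  cfg <- mini_coupled_config(n_loops = 20)
  sim_reset <- simulate_thread(cfg, seed = 5)
  cfg$settings$slack_mode <- "hidden_only"
  sim_bare <- simulate_thread(cfg, seed = 5)
  # bare slack omits the opening strain contribution, so far less length
  # is released and the structure fails much earlier
  expect_lt(sim_bare$final_strain, 0.6 * sim_reset$final_strain)
})

test_that("simulation outputs round-trip through files", {
  sim <- default_sim(1)
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_simulation(sim, prefix)
  expect_true(all(file.exists(paths)))
  cv <- read_curve(paths[1])
  expect_equal(cv$strain, sim$curve$strain)
  expect_equal(cv$force, sim$curve$force)
  expect_equal(cv$units, "relative")
  meta <- jsonlite::read_json(paths[3])
  expect_equal(meta$n_elements, 11)
  expect_equal(meta$n_loop_open, 1600)
  expect_equal(meta$final_strain, sim$final_strain)
})
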