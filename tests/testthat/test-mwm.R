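test_that("route efficiency closed forms hold", {
  g <- pool_geometry(platform_center = c(50, 0), platform_radius = 0.05,
                     drop_point = c(-50, 0))
  # straight path
  straight <- trajectory(seq(0, 5, length.out = 500),
                         seq(-50, 50, length.out = 500),
                         rep(0, 500), g)
  expect_equal(route_efficiency(straight), 100)

  # path exactly twice the direct length (50-cm out-and-back detour)
  leg1 <- seq(-50, 0, length.out = 100)
  path_x <- c(leg1, rev(leg1)[-1], seq(-50, 50, length.out = 300))
  zig <- trajectory(seq(0, 10, length.out = length(path_x)), path_x,
                    rep(0, length(path_x)),
                    pool_geometry(platform_center = c(50, 0),
                                  platform_radius = 1e-6,
                                  drop_point = c(-50, 0)))
  expect_equal(route_efficiency(zig), 50, tolerance = 1e-3)

  # semicircular arc: 100 * 2 / pi
  th <- seq(pi, 0, length.out = 1001)
  arc <- trajectory(seq(0, 10, length.out = 1001),
                    50 * cos(th), 50 * sin(th), g)
  expect_equal(route_efficiency(arc), 200 / pi, tolerance = 200 / pi * 1e-3)
})

test_that("adding a detour strictly decreases route efficiency", {
  g <- pool_geometry(platform_center = c(50, 0), platform_radius = 0.5,
                     drop_point = c(-50, 0))
  base_x <- seq(-50, 50, length.out = 200)
  base <- trajectory(seq(0, 5, length.out = 200), base_x, rep(0, 200), g)
  loop_t <- seq(0, 2 * pi, length.out = 60)
  det_x <- c(base_x[1:100], 0 + 10 * sin(loop_t), base_x[101:200])
  det_y <- c(rep(0, 100), 10 - 10 * cos(loop_t), rep(0, 100))
  detour <- trajectory(seq(0, 7, length.out = length(det_x)), det_x, det_y, g)
  expect_lt(route_efficiency(detour), route_efficiency(base))
})

test_that("route efficiency is nearly invariant to resampling rate", {
  trj25 <- generate_trajectory("directed_search", seed = 3)
  idx <- seq(1, length(trj25$t), by = 2)   # 12.5 Hz resample
  trj12 <- trajectory(trj25$t[idx], trj25$x[idx], trj25$y[idx],
                      trj25$geometry)
  expect_lt(abs(route_efficiency(trj25) - route_efficiency(trj12)) /
              route_efficiency(trj25), 0.01)
})

test_that("trial metrics capture kinematics, censoring and quadrants", {
  g <- pool_geometry(platform_center = c(50, 0), platform_radius = 0.05,
                     drop_point = c(-50, 0))
  tt <- seq(0, 5, length.out = 501)        # 100 cm at 20 cm/s
  straight <- trajectory(tt, seq(-50, 50, length.out = 501), rep(0, 501), g)
  m <- trial_metrics(straight)
  expect_equal(m$time_to_target, 5, tolerance = 0.02)
  expect_equal(m$mean_speed, 20, tolerance = 0.1)
  expect_false(m$censored)

  # never reaching the platform -> censored at the cap
  circ <- generate_trajectory("thigmotaxis", seed = 2)
  mc <- trial_metrics(circ)
  expect_true(mc$censored)
  expect_equal(mc$time_to_target, 120)
  expect_equal(sum(mc$quadrant_time), 1, tolerance = 1e-9)

  # path confined to the target quadrant
  gq <- pool_geometry(platform_center = c(50, 50), platform_radius = 1,
                      drop_point = c(20, 20))
  conf <- trajectory(seq(0, 3, length.out = 100),
                     seq(20, 40, length.out = 100),
                     seq(20, 40, length.out = 100), gq)
  expect_equal(unname(trial_metrics(conf)$quadrant_time["target"]), 1)
})

test_that("archetypes built to satisfy a rule are classified as that rule", {
  direct <- generate_trajectory("direct_swimming", jitter = 0, seed = 1)
  cd <- classify_strategy(direct)
  expect_equal(cd$strategy, "direct_swimming")
  expect_equal(cd$strategy_score, 3L)
  expect_equal(route_efficiency(direct), 100)

  th <- classify_strategy(generate_trajectory("thigmotaxis", seed = 5))
  expect_equal(th$strategy, "thigmotaxis")
  expect_equal(th$strategy_score, 0L)
})

test_that("classifier recovers generating archetypes with exact score mapping", {
  archetypes <- c("thigmotaxis", "random_search", "scanning", "chaining",
                  "directed_search", "focal_search", "direct_swimming")
  scores <- c(0L, 0L, 0L, 0L, 1L, 2L, 3L)
  hits <- 0; total <- 0
  for (i in seq_along(archetypes)) for (s in 1:6) {
    cl <- classify_strategy(generate_trajectory(archetypes[i], seed = s))
    total <- total + 1
    if (cl$strategy == archetypes[i]) hits <- hits + 1
    expect_equal(cl$strategy_score,
                 unname(somnotools:::strategy_scores[cl$strategy]))
  }
  expect_gte(hits / total, 0.9)
  # the 0-3 mapping itself
  expect_equal(unname(somnotools:::strategy_scores[archetypes]), scores)
})

test_that("strategy config validation and ranking arithmetic", {
  expect_error(strategy_config(thigmo_min_frac = 1.2),
               "invalid strategy config")
  expect_error(strategy_config(chaining_halfwidth = -2),
               "invalid strategy config")

  r <- strategy_ranking(c(0, 0, 1, 1, 2, 3), rep(1, 6))
  expect_equal(r$mean_score, 7 / 6)
  r2 <- strategy_ranking(c(0, 0, 0, 3, 3, 3), c(1, 1, 1, 2, 2, 2))
  expect_equal(r2$mean_score, c(0, 3))
  expect_equal(r2$n_trials, c(3L, 3L))
  expect_error(strategy_ranking(c(0, 5), c(1, 1)), "0-3")
})
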