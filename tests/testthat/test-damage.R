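test_that("daily damage is bounded with the configured uniform mean", {
  cfg <- ds_config()
  x <- daily_damage(1e5, cfg, seed = 1)
  expect_true(all(x >= 0 & x <= cfg$damage$d_max))
  # uniform on [0, d_max]: mean d_max/2, sd d_max/sqrt(12)
  se <- cfg$damage$d_max / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(x) - cfg$damage$d_max / 2), 3 * se)
  expect_identical(daily_damage(10, cfg, seed = 3), daily_damage(10, cfg, seed = 3))
  expect_equal(daily_damage(100, ds_config(damage = list(d_max = 0))), rep(0, 100))
})

test_that("repair clears damage up to capacity and never goes negative", {
  cfg <- ds_config()
  r <- cfg$damage$repair_capacity
  expect_equal(repair_damage(c(0, r / 2, r), config = cfg), c(0, 0, 0))
  expect_equal(repair_damage(r + 0.02, config = cfg), 0.02, tolerance = 1e-12)
  expect_true(all(repair_damage(seq(0, 3, by = 0.1), config = cfg) >= 0))
})

test_that("repair deficits raise steady-state damage (two-arm simulation)", {
  cfg <- ds_config()
  sim_arm <- function(brca1_copies, seed) {
    inc <- daily_damage(1e4, cfg, seed = seed)
    d <- 0
    traj <- numeric(1e4)
    for (i in seq_along(inc)) {
      d <- repair_damage(min(d + inc[i], cfg$damage$damage_ceiling),
                         brca1_copies = brca1_copies, config = cfg)
      traj[i] <- d
    }
    traj
  }
  wt <- sim_arm(2L, seed = 11)
  het <- sim_arm(1L, seed = 11)
  null <- sim_arm(0L, seed = 11)
  expect_gt(mean(het), mean(wt))
  expect_gt(mean(null), mean(het))
  # wild-type steady state stays below the senescence threshold
  expect_lt(mean(wt), cfg$damage$senescence_threshold)
})

test_that("division hits follow the capped-linear-plus-replication-error law", {
  cfg <- ds_config()
  # null case: no damage, no replication errors
  cfg0 <- ds_config(damage = list(epsilon = 0))
  expect_equal(mutation_count_at_division(1e4, 0, cfg0, seed = 1), rep(0L, 1e4))
  # monotone in damage
  p_hat <- vapply(c(0, 0.4, 0.9, 2), function(d) {
    mean(mutation_count_at_division(2e4, d, cfg, seed = 5) >= 1L)
  }, numeric(1))
  expect_true(all(diff(p_hat) >= -0.01))
  # saturation: at the cap the damage-dependent hit is certain
  d_cap <- 1 / cfg$damage$beta
  at_cap <- mutation_count_at_division(1e4, d_cap, cfg, seed = 9)
  expect_true(all(at_cap >= 1L))
  # expected P(>=1 hit) at moderate damage: 1-(1-min(1,beta*d))(1-eps)
  d <- 0.5
  p_theory <- 1 - (1 - min(1, cfg$damage$beta * d)) * (1 - cfg$damage$epsilon)
  p_mc <- mean(mutation_count_at_division(1e5, d, cfg, seed = 2) >= 1L)
  expect_lt(abs(p_mc - p_theory), 3 * sqrt(p_theory * (1 - p_theory) / 1e5))
})

test_that("damage checkpoint orders senescence below apoptosis; P53 bypasses", {
  cfg <- ds_config()
  s <- cfg$damage$senescence_threshold
  a <- cfg$damage$apoptosis_threshold
  chk <- damage_checkpoint(c(s / 2, (s + a) / 2, a + 0.1), config = cfg)
  expect_equal(chk$senescence_flagged, c(FALSE, TRUE, FALSE))
  expect_equal(chk$apoptosis_flagged, c(FALSE, FALSE, TRUE))
  expect_false(any(chk$senescence_flagged & chk$apoptosis_flagged))
  bypass <- damage_checkpoint(c(s / 2, (s + a) / 2, a + 0.1), p53_null = TRUE,
                              config = cfg)
  expect_false(any(bypass$senescence_flagged | bypass$apoptosis_flagged))
  expect_error(ds_config(damage = list(senescence_threshold = 2,
                                       apoptosis_threshold = 1.5)))
})
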