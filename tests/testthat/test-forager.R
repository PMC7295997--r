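test_that("sensors log-scale local concentration with a floor", {
  cfg <- small_config()
  fp <- cfg$forager
  n <- cfg$world$arena_size
  fields <- make_odor_fields(n)
  fg <- make_forager(cfg)

  r <- sense(fields, fg, fp)
  expect_true(all(r == 0))

  # uniform concentration: both sensors read the same on every signature
  fields$hermi[] <- 1e-3
  fields$betaine[] <- 2e-4
  r <- sense(fields, fg, fp)
  expect_equal(r["left", ], r["right", ])
  # k_log = 7, c_floor = 1e-7: c = 1e-3 reads just above 4
  expect_equal(unname(r["left", "hermi"]), 7 + log10(1e-3 + 1e-7),
               tolerance = 1e-12)
  expect_equal(unname(r["left", "hermi"]), 4.0, tolerance = 1e-3)

  # at or below the floor the reading clamps to zero
  fields$flab[] <- 1e-8
  r <- sense(fields, fg, fp)
  expect_true(all(r[, "flab"] >= 0))

  # monotone non-decreasing in concentration
  lo <- hi <- make_odor_fields(n)
  lo$hermi[] <- 1e-4
  hi$hermi[] <- 1e-2
  expect_true(all(sense(hi, fg, fp)[, "hermi"] >=
                  sense(lo, fg, fp)[, "hermi"]))
})

test_that("somatic map picks the stronger side and caps amplitude", {
  fp <- small_config()$forager
  fp$gain_turn <- 5
  fp$max_turn <- 20

  tie <- somatic_map(reading_with(left = c(1, 2, 0, 0),
                                  right = c(2, 1, 0, 0)), fp)
  expect_equal(tie$side, "center")
  expect_equal(tie$amplitude, 0)

  m <- somatic_map(reading_with(left = c(3, 0, 0, 0),
                                right = c(1, 0, 0, 0)), fp)
  expect_equal(m$side, "left")
  expect_equal(m$amplitude, 10) # gain 5 x difference 2

  big <- somatic_map(reading_with(left = c(100, 0, 0, 0)), fp)
  expect_equal(big$amplitude, fp$max_turn)

  # pain routes an input of strength P onto the side of its bearing
  pr <- somatic_map(reading_with(), fp, pain = list(P = 10, site = -45))
  expect_equal(pr$side, "right")
  expect_equal(pr$amplitude, fp$max_turn)
})

test_that("incentive sums learned values and the resource signal", {
  V <- make_associations()
  r0 <- reading_with()
  expect_equal(compute_incentive(r0, V, 0.5), 0)

  V$pos["hermi"] <- 1
  r <- reading_with(left = c(betaine = 1, hermi = 3, flab = 0, drug = 0))
  # V+ = 1 on s_hermi = 3 plus 0.5 * s_betaine = 0.5
  expect_equal(compute_incentive(r, V, 0.5), 3.5)

  Vf <- make_associations()
  Vf$neg["flab"] <- 1
  rf <- reading_with(left = c(betaine = 0, hermi = 0, flab = 3, drug = 0))
  expect_equal(compute_incentive(rf, Vf, 0.5), -3)
})

test_that("appetitive state sits at 1/2 when the drive vanishes and moves the
           right way with satiation, incentive, and reward experience", {
  cfg <- small_config()
  fp <- cfg$forager
  ap <- cfg$affect
  S <- 0.5
  I0 <- fp$c_s * S + fp$theta - fp$h0 * (1 - S) # zeroes the drive at RE=P=0
  expect_equal(compute_appetitive_state(I0, S, 0, 0, fp, ap), 0.5,
               tolerance = 1e-12)

  # satiation suppresses, hunger in withdrawal disinhibits
  expect_lt(compute_appetitive_state(2, 0.9, 0, 0, fp, ap),
            compute_appetitive_state(2, 0.1, 0, 0, fp, ap))
  expect_gt(compute_appetitive_state(2, 0.5, -5, 0, fp, ap),
            compute_appetitive_state(2, 0.5, 0, 0, fp, ap))

  expect_error(compute_appetitive_state(NaN, 0.5, 0, 0, fp, ap),
               "non-finite")

  # monotonicity over random draws: non-increasing in S, non-decreasing in I
  set.seed(11)
  for (i in 1:1000) {
    I <- runif(1, -15, 15)
    S <- runif(1, 0.01, 0.99)
    RE <- runif(1, -20, 20)
    P <- runif(1, 0, 10)
    as0 <- compute_appetitive_state(I, S, RE, P, fp, ap)
    expect_lte(compute_appetitive_state(I, S + 0.01, RE, P, fp, ap), as0)
    expect_gte(compute_appetitive_state(I + 0.1, S, RE, P, fp, ap), as0)
    expect_true(as0 >= 0 && as0 <= 1) # saturates in floating point
  }
})

test_that("turn direction inverts exactly once as appetitive state crosses
           the approach threshold", {
  fp <- small_config()$forager
  smap <- list(side = "left", amplitude = 10)
  expect_equal(decide_turn(0.9, smap, 0.5), 10)
  expect_equal(decide_turn(0.1, smap, 0.5), -10)
  expect_equal(decide_turn(0.9, list(side = "center", amplitude = 0), 0.5), 0)
  expect_equal(decide_turn(0.2, list(side = "right", amplitude = 0), 0.5), 0)

  as_sweep <- seq(0.01, 0.99, by = 0.01)
  turns <- vapply(as_sweep, decide_turn, 0, smap = smap,
                  approach_threshold = 0.5)
  expect_equal(sum(diff(sign(turns)) != 0), 1)
})

test_that("stepping moves only when mobile and consumption respects reach and
           appetite", {
  cfg <- small_config()
  fp <- cfg$forager
  n <- cfg$world$arena_size
  items <- data.frame(species = "hermi", x = 30, y = 30, alive = TRUE)

  fg <- make_forager(cfg, x = 30.5, y = 30.5, heading = 90)
  fg$AS <- 0.9
  fixed <- step_and_consume(fg, items, 15, FALSE, fp, cfg$species, n)
  expect_equal(fixed$forager$x, 30.5) # immobilized: turns but does not move
  expect_equal(fixed$forager$heading, 105)
  expect_equal(nrow(fixed$events), 1)
  expect_equal(fixed$events$species, "hermi")
  expect_equal(fixed$events$reward, cfg$species$hermi$reward_magnitude)
  expect_equal(fixed$events$nutrition, cfg$species$hermi$nutrition_value)
  expect_false(fixed$items$alive[1])

  # below the bite threshold nothing is consumed even in reach
  fg$AS <- 0.3
  expect_equal(nrow(step_and_consume(fg, items, 0, FALSE, fp, cfg$species,
                                     n)$events), 0)

  # out of reach
  far <- data.frame(species = "hermi", x = 50, y = 50, alive = TRUE)
  fg$AS <- 0.9
  expect_equal(nrow(step_and_consume(fg, far, 0, FALSE, fp, cfg$species,
                                     n)$events), 0)

  # mobile step advances along the heading
  fg <- make_forager(cfg, x = 10, y = 10, heading = 0)
  fg$AS <- 0.1
  mv <- step_and_consume(fg, far, 0, TRUE, fp, cfg$species, n)
  expect_equal(mv$forager$x, 10 + fp$speed)
  expect_equal(mv$forager$y, 10)
})

test_that("satiation follows the saturating nutrition readout and ignores
           drug 'meals'", {
  cfg <- small_config()
  fp <- cfg$forager
  no_events <- data.frame(species = character(0), reward = numeric(0),
                          nutrition = numeric(0))

  fg <- make_forager(cfg, N = 0)
  fg <- update_satiation(fg, no_events, fp)
  expect_equal(fg$S, fp$s_floor)

  # N = K_half reads satiation one half
  fg <- make_forager(cfg, N = fp$K_half)
  expect_equal(fg$S, 0.5)

  # a drug event adds no nutrition: N changes only by its decay
  fg <- make_forager(cfg, N = 2)
  drug_ev <- data.frame(species = "drug", reward = 4, nutrition = 0)
  fg2 <- update_satiation(fg, drug_ev, fp)
  expect_equal(fg2$N, 2 * (1 - fp$k_N))
  hermi_ev <- data.frame(species = "hermi", reward = 0.5, nutrition = 3)
  fg3 <- update_satiation(fg, hermi_ev, fp)
  expect_equal(fg3$N, 2 * (1 - fp$k_N) + 3)

  # bounds under arbitrary event streams
  set.seed(5)
  fg <- make_forager(cfg, N = 1)
  for (i in 1:500) {
    k <- rpois(1, 0.3)
    ev <- data.frame(species = rep("hermi", k), reward = rep(0.5, k),
                     nutrition = runif(k, 0, 5))
    fg <- update_satiation(fg, ev, fp)
    expect_true(fg$S >= fp$s_floor && fg$S <= 1)
  }
})

test_that("a mobile forager climbs the odor gradient to the source", {
  cfg <- small_config(arena = 60L)
  fp <- cfg$forager
  ap <- cfg$affect
  w <- cfg$world
  n <- w$arena_size
  V <- make_associations()
  V$pos["hermi"] <- 1

  reached <- 0
  for (run in 1:10) {
    set.seed(300 + run)
    items <- make_items("hermi", n)
    fields <- make_odor_fields(n)
    fg <- make_forager(cfg, x = runif(1, 0, n), y = runif(1, 0, n),
                       heading = runif(1, 0, 360))
    d0 <- torus_distance(fg$x, fg$y, items$x, items$y, n)
    budget <- ceiling(5 * d0 / fp$speed) + 400 # field spin-up margin
    for (t in seq_len(budget)) {
      fields <- deposit_odors(items, fields, cfg$species)
      fields$hermi <- diffuse_decay(fields$hermi, w$diffusion_fraction,
                                    w$evaporation_fraction)
      fields$betaine <- diffuse_decay(fields$betaine, w$diffusion_fraction,
                                      w$evaporation_fraction)
      r <- sense(fields, fg, fp)
      smap <- somatic_map(r, fp)
      turn <- decide_turn(0.9, smap, fp$approach_threshold) +
        rnorm(1, 0, fp$heading_jitter_sd)
      fg$AS <- 0.9
      st <- step_and_consume(fg, items, turn, TRUE, fp, cfg$species, n)
      fg <- st$forager
      if (nrow(st$events)) break
    }
    if (torus_distance(fg$x, fg$y, items$x, items$y, n) <= fp$capture_radius)
      reached <- reached + 1
  }
  expect_gte(reached, 9)
})
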