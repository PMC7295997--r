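test_that("fixation clamps exactly the requested variables", {
  cfg <- small_config()
  fp <- cfg$forager
  expect_error(validate_fixation(list(S = 1.5), fp), "fixation S")
  expect_error(validate_fixation(list(RE = 30), fp), "fixation RE")
  expect_error(validate_fixation(list(Z = 1), fp), "unknown fixation key")

  fg <- make_forager(cfg, N = 2)
  hrc <- make_hrc(cfg$affect)

  # empty fixation leaves dynamics untouched
  fx <- fix_variables(fg, hrc, list())
  expect_identical(fx$forager, fg)
  expect_identical(fx$hrc, hrc)

  # S clamped through a consumption-heavy sequence
  set.seed(3)
  for (t in 1:100) {
    k <- rpois(1, 0.5)
    ev <- data.frame(species = rep("hermi", k), reward = rep(0.5, k),
                     nutrition = rep(3, k))
    fg <- update_satiation(fg, ev, fp)
    fx <- fix_variables(fg, hrc, list(S = 0.4))
    fg <- fx$forager
    expect_equal(fg$S, 0.4)
  }

  # RE clamped while the circuit's internals keep evolving
  hrc <- make_hrc(cfg$affect)
  u_seen <- numeric(50)
  for (t in 1:50) {
    hrc <- hrc_step(hrc, cfg$affect, input = 0.2)
    hrc <- fix_variables(fg, hrc, list(RE = -10))$hrc
    u_seen[t] <- hrc$u
    expect_equal(hrc$RE, -10)
  }
  expect_gt(max(u_seen), 1) # internal pulse integrated freely
})

test_that("net turns classify with a dead zone", {
  expect_equal(classify_turn(20, 5), "approach")
  expect_equal(classify_turn(-20, 5), "avoid")
  expect_equal(classify_turn(2, 5), "none")
  expect_equal(classify_turn(5, 5), "approach")
  expect_error(classify_turn(1, 0), "dead_zone")
})

test_that("presentation trials produce the hallmark outcomes", {
  cfg <- default_config()
  # benign prey approached by a fed, drug-free forager at neutral RE
  Vdf <- state_associations("drug_free")
  expect_equal(run_presentation("hermi", list(S = 0.89, RE = 0), cfg,
                                Vdf)$outcome, "approach")
  # everything avoided when both satiation and reward experience peak
  expect_equal(run_presentation("hermi", list(S = 1, RE = 20), cfg,
                                Vdf)$outcome, "avoid")
  Vad <- state_associations("addicted")
  expect_equal(run_presentation("drug", list(S = 1, RE = 20), cfg,
                                Vad)$outcome, "avoid")
  # addicted forager approaches the drug at moderate satiation and high RE
  expect_equal(run_presentation("drug", list(S = 0.45, RE = 10), cfg,
                                Vad)$outcome, "approach")
})

test_that("cycle trials are bit-identical under the same seed and cumulative
           counts never decrease", {
  cfg <- small_config(arena = 50L)
  a <- run_addiction_cycle(42, cfg)
  b <- run_addiction_cycle(42, cfg)
  expect_identical(a[setdiff(names(a), "trace")],
                   b[setdiff(names(b), "trace")])
  c2 <- run_addiction_cycle(43, cfg)
  expect_false(identical(a$RE, c2$RE))

  expect_true(all(diff(a$counts[, "hermi"]) >= 0))
  expect_true(all(diff(a$counts[, "flab"]) >= 0))
  expect_true(all(diff(a$counts[, "drug"]) >= 0))
  # drug absent before introduction and during removal
  expect_true(all(a$counts[a$phase == 1, "drug"] == 0))
  p3 <- which(a$phase == 3)
  expect_equal(length(unique(a$counts[p3, "drug"])), 1)
  expect_equal(length(a$RE), sum(cfg$experiments$phase_ticks))
  expect_equal(sort(unique(a$phase)), 1:4)
})

test_that("trial aggregation computes mean and SEM per tick", {
  fake_trial <- function(seed, re, counts) {
    structure(list(seed = seed, phase_names = c("a", "b"),
                   phase = rep(1:2, each = length(re) / 2), RE = re,
                   S = re, V_drug = re * 0,
                   counts = counts,
                   events = data.frame(tick = integer(0),
                                       species = character(0)),
                   V = make_associations(), trace = NULL),
              class = "cycle_trial")
  }
  cts <- function(x) matrix(x, nrow = 4, ncol = 3,
                            dimnames = list(NULL, c("hermi", "flab", "drug")))
  t1 <- fake_trial(1, c(1, 2, 3, 4), cts(10))
  t2 <- fake_trial(2, c(3, 2, 1, 0), cts(14))

  agg <- aggregate_trials(list(t1, t2))
  expect_equal(unname(agg$mean[, "RE"]), c(2, 2, 2, 2))
  expect_equal(unname(agg$mean[1, "hermi"]), 12)
  # counts {10, 14}: sd = sqrt(8), SEM = sd/sqrt(2) = 2
  expect_equal(unname(agg$sem[1, "hermi"]), 2)
  expect_equal(unname(agg$sem[1, "RE"]), stats::sd(c(1, 3)) / sqrt(2))

  # identical trials: SEM exactly zero
  agg2 <- aggregate_trials(list(t1, t1))
  expect_true(all(agg2$sem == 0))

  # a single trial: mean is the trial, SEM undefined (missing)
  agg1 <- aggregate_trials(list(t1))
  expect_equal(unname(agg1$mean[, "RE"]), t1$RE)
  expect_true(all(is.na(agg1$sem)))

  t3 <- fake_trial(3, c(1, 2), cts(1)[1:2, ])
  expect_error(aggregate_trials(list(t1, t3)), "mismatched")
})

test_that("selectivity grids are complete and reproducible", {
  cfg <- small_config(arena = 40L)
  cfg$experiments$s_axis <- c(0.01, 0.5, 1.0)
  cfg$experiments$re_axis_map <- c(-10, 0, 20)
  cfg$experiments$T_present <- 150L
  cfg$experiments$T_equil <- 120L
  g1 <- build_selectivity_map("drug_free", cfg, seed = 5)
  g2 <- build_selectivity_map("drug_free", cfg, seed = 5)
  expect_identical(g1, g2)
  expect_named(g1$items, c("hermi", "flab", "drug"))
  for (m in g1$items) {
    expect_false(any(is.na(m)))
    expect_true(all(m %in% c(-1, 0, 1)))
    expect_equal(dim(m), c(3, 3))
  }
  expect_error(build_selectivity_map("stoned", cfg), "state_label")
})
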