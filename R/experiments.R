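.empty_events <- data.frame(species = character(0), reward = numeric(0),
                            nutrition = numeric(0), stringsAsFactors = FALSE)

#' Validate a fixation specification
#'
#' Fixation clamps satiation and/or reward experience to fixed values,
#' re-imposed every tick before the decision step; unset quantities evolve
#' freely.
#'
#' @param fixation List with optional elements `S` (in `[s_floor, 1]`) and
#'   `RE` (in `[-20, 20]`).
#' @param fp Forager parameter block.
#' @return The validated fixation list.
#' @export
validate_fixation <- function(fixation, fp) {
  if (is.null(fixation)) return(list())
  bad <- setdiff(names(fixation), c("S", "RE"))
  if (length(bad)) config_error("unknown fixation key: '%s'", bad[1])
  if (!is.null(fixation$S) &&
      (fixation$S < fp$s_floor || fixation$S > 1)) {
    config_error("fixation S = %g outside [%g, 1]", fixation$S, fp$s_floor)
  }
  if (!is.null(fixation$RE) && abs(fixation$RE) > 20) {
    config_error("fixation RE = %g outside [-20, 20]", fixation$RE)
  }
  fixation
}

#' Impose fixed satiation / reward experience on the running state
#'
#' Overwrites the forager's satiation and/or the reward-experience readout of
#' the circuit with the fixed values. The circuit's internal states (input
#' trace, rates, weight) keep evolving; only the readout used by the decision
#' is clamped.
#'
#' @param forager Forager state.
#' @param hrc HRC state.
#' @param fixation Validated fixation list.
#' @return List with the updated `forager` and `hrc`.
#' @export
fix_variables <- function(forager, hrc, fixation) {
  if (!is.null(fixation$S)) forager$S <- fixation$S
  if (!is.null(fixation$RE)) hrc$RE <- fixation$RE
  list(forager = forager, hrc = hrc)
}

#' Classify a net turn as approach, none, or avoid
#'
#' @param net_turn Net turn in degrees toward the stimulus (signed).
#' @param dead_zone Positive dead zone in degrees.
#' @return `"approach"`, `"none"`, or `"avoid"`.
#' @export
classify_turn <- function(net_turn, dead_zone) {
  if (dead_zone <= 0) config_error("dead_zone must be > 0")
  if (net_turn >= dead_zone) "approach"
  else if (net_turn <= -dead_zone) "avoid"
  else "none"
}

active_signatures <- function(item) {
  switch(item,
         hermi = c("betaine", "hermi"),
         flab = c("betaine", "flab"),
         drug = "drug",
         character(0))
}

equilibrate_item_fields <- function(item, config) {
  w <- config$world
  n <- w$arena_size
  fields <- make_odor_fields(n)
  if (item == "pain") {
    return(list(fields = fields, items = NULL, active = character(0)))
  }
  ex <- config$experiments
  b <- deg2rad(ex$item_bearing)
  items <- data.frame(species = item,
                      x = n / 2 + ex$item_distance * cos(b),
                      y = n / 2 + ex$item_distance * sin(b),
                      alive = TRUE, stringsAsFactors = FALSE)
  act <- active_signatures(item)
  for (t in seq_len(ex$T_equil)) {
    fields <- deposit_odors(items, fields, config$species)
    for (k in act) {
      fields[[k]] <- diffuse_decay(fields[[k]], w$diffusion_fraction,
                                   w$evaporation_fraction)
    }
  }
  list(fields = fields, items = items, active = act)
}

#' Present a single item (or a pain stimulus) to an immobilized forager
#'
#' The forager sits at the arena center with the item placed at a fixed
#' bearing and distance ahead; odor fields equilibrate before the trial clock
#' starts. The forager is immobilized but turns freely; satiation and reward
#' experience are clamped per the fixation. For `item = "pain"` no odor item
#' is placed; instead a sustained pain stimulus of the configured strength is
#' applied at the configured body-relative bearing throughout (held at its
#' strength via leak-compensated per-tick application). The net heading
#' change toward the stimulus' initial side, accumulated over the trial, is
#' classified with the configured dead zone.
#'
#' @param item `"hermi"`, `"flab"`, `"drug"`, or `"pain"`.
#' @param fixation Fixation list with `S` and/or `RE` (see
#'   [validate_fixation()]).
#' @param config Configuration list.
#' @param V Associative strengths (preset per experiment state).
#' @param equil Optional pre-equilibrated state from an internal cache (used
#'   by the grid builders to share field equilibration across cells).
#' @return A list of class `trial_outcome`: `item`, `outcome`, `net_turn`.
#' @export
run_presentation <- function(item, fixation, config = default_config(),
                             V = make_associations(), equil = NULL) {
  fp <- config$forager
  ap <- config$affect
  ex <- config$experiments
  w <- config$world
  n <- w$arena_size
  fixation <- validate_fixation(fixation, fp)
  if (is.null(equil)) equil <- equilibrate_item_fields(item, config)
  fields <- equil$fields
  forager <- make_forager(config, x = n / 2, y = n / 2, heading = 0)
  hrc <- make_hrc(ap)
  pain <- make_pain()
  is_pain <- item == "pain"
  pain_drive <- ex$pain_strength / ap$tau_P
  if (is_pain) {
    # equilibrate the pain center the way fields are equilibrated
    for (t in seq_len(ex$T_equil)) {
      pain <- pain_step(pain, pain_drive, ap, site = ex$pain_bearing)
    }
  }
  # +1 if the stimulus starts on the left (counterclockwise turns approach it)
  toward_sign <- if (is_pain) sign(ex$pain_bearing) else sign(ex$item_bearing)
  if (toward_sign == 0) toward_sign <- 1
  net <- 0
  for (t in seq_len(ex$T_present)) {
    if (!is_pain) {
      fields <- deposit_odors(equil$items, fields, config$species)
      for (k in equil$active) {
        fields[[k]] <- diffuse_decay(fields[[k]], w$diffusion_fraction,
                                     w$evaporation_fraction)
      }
    } else {
      pain <- pain_step(pain, pain_drive, ap, site = ex$pain_bearing)
    }
    reading <- sense(fields, forager, fp)
    smap <- somatic_map(reading, fp, pain = if (is_pain) pain else NULL)
    I <- compute_incentive(reading, V, fp$w_betaine)
    hrc <- hrc_step(hrc, ap)
    fx <- fix_variables(forager, hrc, fixation)
    forager <- fx$forager
    hrc <- fx$hrc
    forager$AS <- compute_appetitive_state(I, forager$S, hrc$RE, pain$P,
                                           fp, ap)
    turn <- decide_turn(forager$AS, smap, fp$approach_threshold)
    forager$heading <- (forager$heading + turn) %% 360
    net <- net + toward_sign * turn
  }
  structure(list(item = item, outcome = classify_turn(net, ex$dead_zone),
                 net_turn = net),
            class = "trial_outcome")
}

#' Associative strengths defining the drug-free and addicted states
#'
#' Drug-free: maximal learned positive value for hermi and negative value for
#' flab, naive to the drug. Addicted: additionally a maximal positive value
#' for the drug signature.
#'
#' @param state_label `"drug_free"` or `"addicted"`.
#' @return Associative strengths as from [make_associations()].
#' @export
state_associations <- function(state_label) {
  V <- make_associations()
  V$pos["hermi"] <- 1
  V$neg["flab"] <- 1
  if (state_label == "addicted") V$pos["drug"] <- 1
  else if (state_label != "drug_free") {
    config_error("state_label must be 'drug_free' or 'addicted'")
  }
  V
}

outcome_code <- c(avoid = -1, none = 0, approach = 1)

#' Build a selectivity map over satiation and reward experience
#'
#' For one experiment state (`"drug_free"`: learned hermi-positive and
#' flab-negative values at maximum, naive to drug; `"addicted"`: additionally
#' the drug value at maximum), each prey/drug item is presented separately to
#' the immobilized forager at every grid cell of fixed (satiation, reward
#' experience), and the classified outcome recorded. Cells hold `1`
#' (approach), `0` (no net turn), `-1` (avoid).
#'
#' @param state_label `"drug_free"` or `"addicted"`.
#' @param config Configuration list.
#' @param seed Integer seed (the protocol is deterministic; recorded for the
#'   manifest).
#' @return A list of class `selectivity_grid`: `state`, `items` (named list
#'   of `S x RE` outcome matrices), `s_axis`, `re_axis`, `seed`.
#' @export
build_selectivity_map <- function(state_label, config = default_config(),
                                  seed = config$world$rng_seed) {
  ex <- config$experiments
  V <- state_associations(state_label)
  grids <- list()
  for (item in SPECIES_NAMES) {
    equil <- equilibrate_item_fields(item, config)
    m <- matrix(NA_real_, length(ex$s_axis), length(ex$re_axis_map),
                dimnames = list(S = format(ex$s_axis),
                                RE = format(ex$re_axis_map)))
    for (i in seq_along(ex$s_axis)) {
      for (j in seq_along(ex$re_axis_map)) {
        out <- run_presentation(item,
                                list(S = ex$s_axis[i], RE = ex$re_axis_map[j]),
                                config, V, equil = equil)
        m[i, j] <- outcome_code[[out$outcome]]
      }
    }
    grids[[item]] <- m
  }
  structure(list(state = state_label, items = grids, s_axis = ex$s_axis,
                 re_axis = ex$re_axis_map, seed = seed),
            class = "selectivity_grid")
}

#' Map turn responses to a sustained pain stimulus
#'
#' A sustained pain stimulus of the configured strength is applied to the
#' immobilized forager's right anterior region at every grid cell of fixed
#' (satiation, reward experience); the reward-experience axis spans the
#' narrower pain band. Cells hold `1` (approach), `0` (none), `-1` (avoid).
#'
#' @param config Configuration list.
#' @param seed Integer seed (deterministic protocol; recorded).
#' @return A `selectivity_grid` with the single item `pain`.
#' @export
run_pain_map <- function(config = default_config(),
                         seed = config$world$rng_seed) {
  ex <- config$experiments
  V <- make_associations()
  m <- matrix(NA_real_, length(ex$s_axis), length(ex$re_axis_pain),
              dimnames = list(S = format(ex$s_axis),
                              RE = format(ex$re_axis_pain)))
  for (i in seq_along(ex$s_axis)) {
    for (j in seq_along(ex$re_axis_pain)) {
      out <- run_presentation("pain",
                              list(S = ex$s_axis[i], RE = ex$re_axis_pain[j]),
                              config, V)
      m[i, j] <- outcome_code[[out$outcome]]
    }
  }
  structure(list(state = "pain", items = list(pain = m), s_axis = ex$s_axis,
                 re_axis = ex$re_axis_pain, seed = seed),
            class = "selectivity_grid")
}

#' Run one trial of the four-phase addiction cycle
#'
#' A free-running simulation (mobility and learning on, reward circuit free)
#' through four phases: prey only (3 hermi + 3 flab, respawning when eaten);
#' drug introduced (6 respawning drug items with full reward); drug removed;
#' and drug without reward (drug present with unchanged odor signature but
#' zero reward, extinguishing its learned value). Per-tick reward experience,
#' satiation, the drug's positive associative strength, and cumulative
#' consumption counts per species are recorded with phase labels.
#'
#' @param seed Integer seed for this trial.
#' @param config Configuration list.
#' @param record_trace Also record position, heading, incentive, and
#'   appetitive state per tick.
#' @return A list of class `cycle_trial` with per-tick vectors (`RE`, `S`,
#'   `V_drug`, cumulative count matrix `counts`), `phase` labels, the
#'   consumption-event log `events`, the final associative strengths `V`,
#'   and `seed`.
#' @export
run_addiction_cycle <- function(seed, config = default_config(),
                                record_trace = FALSE) {
  set.seed(seed)
  w <- config$world
  fp <- config$forager
  ap <- config$affect
  lp <- config$learning
  ex <- config$experiments
  n <- w$arena_size
  phase_names <- names(ex$phase_ticks)
  total <- sum(ex$phase_ticks)

  fields <- make_odor_fields(n)
  items <- make_items(c(rep("hermi", ex$n_hermi), rep("flab", ex$n_flab)), n)
  forager <- make_forager(config, heading = stats::runif(1, 0, 360),
                          N = ex$N_init)
  hrc <- make_hrc(ap)
  V <- make_associations()

  RE <- numeric(total)
  S <- numeric(total)
  V_drug <- numeric(total)
  counts <- matrix(0L, total, 3, dimnames = list(NULL, SPECIES_NAMES))
  phase <- integer(total)
  ev_tick <- integer(0)
  ev_species <- character(0)
  trace <- if (record_trace) {
    list(x = numeric(total), y = numeric(total), heading = numeric(total),
         AS = numeric(total), I = numeric(total))
  } else NULL

  cum <- c(hermi = 0L, flab = 0L, drug = 0L)
  escape <- 0L
  t <- 0L
  for (ph in seq_along(phase_names)) {
    ph_name <- phase_names[ph]
    if (ph_name == "drug_introduced" || ph_name == "drug_without_reward") {
      items <- rbind(items, make_items(rep("drug", ex$n_drug), n))
    } else if (ph_name == "drug_removed") {
      items <- items[items$species != "drug", , drop = FALSE]
    }
    drug_reward <- if (ph_name == "drug_without_reward") 0 else
      config$species$drug$reward_magnitude
    act <- c("betaine", "hermi", "flab",
             if (any(items$species == "drug")) "drug")
    for (k in seq_len(ex$phase_ticks[ph])) {
      t <- t + 1L
      fields <- deposit_odors(items, fields, config$species)
      for (f in act) {
        fields[[f]] <- diffuse_decay(fields[[f]], w$diffusion_fraction,
                                     w$evaporation_fraction)
      }
      reading <- sense(fields, forager, fp)
      smap <- somatic_map(reading, fp)
      I <- compute_incentive(reading, V, fp$w_betaine)
      hrc <- hrc_step(hrc, ap)
      forager$AS <- compute_appetitive_state(I, forager$S, hrc$RE, 0, fp, ap)
      # an aversive decision near a stimulus launches a ballistic escape
      # bout: the forager keeps its avoidance orientation long enough to
      # clear the plume instead of stalling at the radius where approach
      # and avoidance balance
      if (forager$AS < fp$approach_threshold && smap$amplitude > 0) {
        escape <- fp$escape_ticks
      }
      if (escape > 0L) {
        turn <- decide_turn(0, smap, fp$approach_threshold)
        escape <- escape - 1L
      } else {
        turn <- decide_turn(forager$AS, smap, fp$approach_threshold)
      }
      # locomotor heading noise: free-running search is stochastic, so the
      # forager neither runs on perfectly straight rails when nothing is
      # sensed nor stalls on a deterministic orbit at a plume rim
      if (fp$heading_jitter_sd > 0) {
        turn <- turn + stats::rnorm(1, 0, fp$heading_jitter_sd)
      }
      st <- step_and_consume(forager, items, turn, TRUE, fp, config$species, n)
      forager <- st$forager
      items <- st$items
      events <- st$events
      if (nrow(events)) {
        for (e in seq_len(nrow(events))) {
          sp <- events$species[e]
          r <- if (sp == "drug") drug_reward else events$reward[e]
          if (r != 0) hrc <- inject_reward(hrc, r, ap)
          V <- apply_learning_event(V, sp, r, lp)
          cum[sp] <- cum[sp] + 1L
        }
        ev_tick <- c(ev_tick, rep(t, nrow(events)))
        ev_species <- c(ev_species, events$species)
        # respawn before the next tick
        dead <- which(!items$alive)
        for (d in dead) items[d, ] <- respawn_prey(items[d, ], n)
      }
      forager <- update_satiation(forager, events, fp)
      RE[t] <- hrc$RE
      S[t] <- forager$S
      V_drug[t] <- V$pos[["drug"]]
      counts[t, ] <- cum
      phase[t] <- ph
      if (record_trace) {
        trace$x[t] <- forager$x
        trace$y[t] <- forager$y
        trace$heading[t] <- forager$heading
        trace$AS[t] <- forager$AS
        trace$I[t] <- I
      }
    }
  }
  structure(list(seed = seed, phase_names = phase_names, phase = phase,
                 RE = RE, S = S, V_drug = V_drug, counts = counts,
                 events = data.frame(tick = ev_tick, species = ev_species,
                                     stringsAsFactors = FALSE),
                 V = V, trace = trace),
            class = "cycle_trial")
}

#' Summary metrics of one addiction-cycle trial
#'
#' Computes the quantities the cycle is judged on: per-phase prey and drug
#' consumption rates (items per 1000 ticks), ticks to first drug consumption
#' after first introduction and after reward-free reintroduction, the number
#' of reward-experience zero crossings in the second half of the
#' drug-introduced phase, drug consumption rates in the first and last
#' quarter of the reward-free phase, and the drug's positive associative
#' strength at the end of that phase.
#'
#' @param trial A `cycle_trial`.
#' @return A named list of metrics.
#' @export
cycle_metrics <- function(trial) {
  ph <- trial$phase
  ev <- trial$events
  phase_len <- tabulate(ph, nbins = length(trial$phase_names))
  rate <- function(species, phase_id, tick_range = NULL) {
    sel <- ev$species %in% species & ph[ev$tick] == phase_id
    if (!is.null(tick_range)) {
      sel <- sel & ev$tick >= tick_range[1] & ev$tick <= tick_range[2]
    }
    len <- if (is.null(tick_range)) phase_len[phase_id] else
      diff(tick_range) + 1
    1000 * sum(sel) / len
  }
  first_drug <- function(phase_id) {
    tks <- ev$tick[ev$species == "drug" & ph[ev$tick] == phase_id]
    if (length(tks)) min(tks) - match(phase_id, ph) + 1L else NA_integer_
  }
  p2 <- which(ph == 2)
  half2 <- p2[p2 > p2[1] + length(p2) %/% 2]
  re2 <- trial$RE[half2]
  crossings <- sum(diff(sign(re2[re2 != 0])) != 0)
  p4 <- which(ph == 4)
  q <- length(p4) %/% 4
  list(
    prey_rate_prey_only = rate(c("hermi", "flab"), 1),
    prey_rate_drug_removed = rate(c("hermi", "flab"), 3),
    drug_rate_introduced = rate("drug", 2),
    first_drug_intro = first_drug(2),
    first_drug_reintro = first_drug(4),
    re_zero_crossings = crossings,
    drug_rate_q1 = rate("drug", 4, c(p4[1], p4[1] + q - 1)),
    drug_rate_q4 = rate("drug", 4, c(p4[length(p4)] - q + 1, p4[length(p4)])),
    v_drug_end = trial$V_drug[p4[length(p4)]]
  )
}

#' Aggregate addiction-cycle trials into mean and SEM timecourses
#'
#' Trials must be equal-length and phase-aligned. The mean and standard
#' error of the mean (sample standard deviation over the square root of the
#' trial count) are computed per tick for reward experience and for the
#' cumulative consumption count of each species. With a single trial the SEM
#' is reported as missing rather than zero.
#'
#' @param trials List of `cycle_trial` objects.
#' @return A list of class `cycle_result`: `phase`, `phase_names`, per-tick
#'   `mean` and `sem` matrices (columns `RE`, `hermi`, `flab`, `drug`),
#'   `n_trials`, and the per-trial `seeds`.
#' @export
aggregate_trials <- function(trials) {
  if (!length(trials)) config_error("no trials to aggregate")
  len <- vapply(trials, function(tr) length(tr$RE), 0L)
  if (length(unique(len)) != 1) {
    stop("trials have mismatched lengths; cannot aggregate", call. = FALSE)
  }
  ph <- trials[[1]]$phase
  if (!all(vapply(trials, function(tr) identical(tr$phase, ph), TRUE))) {
    stop("trials are not phase-aligned", call. = FALSE)
  }
  nt <- length(trials)
  vars <- c("RE", SPECIES_NAMES)
  pull <- function(tr) cbind(RE = tr$RE, tr$counts)
  arr <- vapply(trials, pull, matrix(0, len[1], length(vars)))
  mean_m <- apply(arr, c(1, 2), mean)
  sem_m <- if (nt > 1) {
    apply(arr, c(1, 2), stats::sd) / sqrt(nt)
  } else {
    matrix(NA_real_, len[1], length(vars), dimnames = dimnames(mean_m))
  }
  colnames(mean_m) <- colnames(sem_m) <- vars
  structure(list(phase = ph, phase_names = trials[[1]]$phase_names,
                 mean = mean_m, sem = sem_m, n_trials = nt,
                 seeds = vapply(trials, function(tr) tr$seed, 0)),
            class = "cycle_result")
}
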