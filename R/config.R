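#' Default run configuration
#'
#' Returns the full default configuration for the simulator: world geometry,
#' species parameters, forager decision constants, homeostatic reward circuit
#' constants, learning rates, and experiment protocol settings. Every tunable
#' constant in the package lives here; experiment functions take a config and
#' never consult hidden globals.
#'
#' The decision constants (`h0`, `c_s`, `c_w`, `c_re`, `theta`) are calibrated
#' jointly so that the selectivity-map, pain-map, and addiction-cycle pattern
#' suites hold at the shipped values; see the methods vignette for the
#' calibration reasoning.
#'
#' @return A nested list with components `world`, `species`, `forager`,
#'   `affect`, `learning`, `experiments`, and `output`.
#' @export
default_config <- function() {
  list(
    world = list(
      arena_size = 200L,          # patches per side, toroidal
      dt = 1,                     # tick duration
      diffusion_fraction = 0.5,   # share of cell content spread to 8 neighbors
      evaporation_fraction = 0.05,# per-tick multiplicative loss
      rng_seed = 1L
    ),
    species = list(
      hermi = list(signature_deposit = 0.5, betaine_deposit = 0.5,
                   nutrition_value = 3.0, reward_magnitude = 0.5),
      flab  = list(signature_deposit = 0.5, betaine_deposit = 0.5,
                   nutrition_value = 3.0, reward_magnitude = -0.5),
      # drug: strong signature plume, no resource signal, no nutrition,
      # reward 8x hermi
      drug  = list(signature_deposit = 5.0, betaine_deposit = 0.0,
                   nutrition_value = 0.0, reward_magnitude = 4.0)
    ),
    forager = list(
      sensor_angle = 40,     # deg off heading, one sensor each side
      sensor_reach = 3,      # patches from body center
      k_log = 7,             # log-scaling offset: s = max(0, k_log + log10(c + c_floor))
      c_floor = 1e-7,        # concentration floor of the log transform
      w_betaine = 0.02,      # innate weight of the resource (betaine) signal
      gain_turn = 5,         # deg/tick per unit left-right sensor difference
      max_turn = 30,         # turn amplitude cap, deg/tick
      beta = 1,              # logistic slope of appetitive state
      theta = 1,             # logistic offset (decision threshold drive)
      h0 = 12,               # hunger drive gain on (1 - S)
      c_s = 2,               # satiation suppression gain
      c_w = 0.9,             # withdrawal (negative RE) amplification of hunger
      c_re = 0.1,            # positive-RE amplification of satiation suppression
      approach_threshold = 0.5, # AS at/above which turns orient toward stimuli
      bite_threshold = 0.6,  # AS needed to consume an item in reach
      capture_radius = 1.5,  # patches
      speed = 0.75,          # patches/tick when mobile
      heading_jitter_sd = 4, # deg/tick locomotor heading noise (free runs only)
      escape_ticks = 50,     # length of a ballistic avoidance bout, ticks
      k_N = 0.002,           # per-tick nutrition decay
      K_half = 1,            # nutrition at which satiation = 0.5
      s_floor = 0.01         # lower clamp of satiation
    ),
    affect = list(
      r0 = 1,        # tonic presynaptic baseline of neuron R
      M_set = 1,     # homeostatic setpoint of neuron M activity
      W_min = 0.05, W_max = 2, W_init = 1,
      eta_W = 0.0005,# homeostatic learning rate of W, per tick
      tau_u = 50,    # decay time constant of the reward-input pulse, ticks
      g_pulse = 1,   # pulse gain per unit reward magnitude
      k_RE = 10,     # reward-experience readout gain on (x_M - M_set)
      tau_P = 30,    # pain decay time constant, ticks
      k_rp = 1,      # pain suppression of positive reward experience
      k_pr = 1,      # positive-RE suppression of pain
      c_p = 1.2      # negative-RE amplification of pain
    ),
    learning = list(
      alpha = 0.3,            # Rescorla-Wagner acquisition rate
      alpha_extinction = 0.3, # extinction rate (same by default)
      r_norm = 0.5            # reward magnitude mapping to asymptote 1
    ),
    experiments = list(
      T_present = 300L,   # presentation trial length, ticks
      T_equil = 200L,     # odor-field equilibration before the trial clock
      item_bearing = 30,  # deg left of heading, presented item
      item_distance = 5,  # patches ahead
      dead_zone = 5,      # deg; |net turn| below this classifies as "none"
      pain_bearing = -45, # right anterior region
      pain_strength = 10, # sustained pain stimulus strength
      s_axis = seq(0.01, 1, length.out = 10),
      re_axis_map = seq(-20, 20, by = 5),
      re_axis_pain = seq(-10, 10, by = 2),
      phase_ticks = c(prey_only = 5000L, drug_introduced = 10000L,
                      drug_removed = 5000L, drug_without_reward = 10000L),
      n_hermi = 3L, n_flab = 3L, n_drug = 6L,
      N_init = 4,         # starting nutrition (fed baseline, satiation 0.8)
      trials = 10L
    ),
    output = list(dir = "results")
  )
}

SPECIES_NAMES <- c("hermi", "flab", "drug")
SIGNATURES <- c("betaine", "hermi", "flab", "drug")

config_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      config_error("unknown configuration key: '%s'", here)
    }
    if (is.list(base[[key]]) && !is.null(override[[key]])) {
      if (!is.list(override[[key]])) {
        config_error("configuration key '%s' must be a block", here)
      }
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else if (!is.list(base[[key]]) && is.list(override[[key]])) {
      # named atomic vectors (e.g. phase tick counts) come back from YAML
      # as maps; flatten them to match the default's shape
      base[[key]] <- unlist(override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

check_range <- function(x, key, lo = -Inf, hi = Inf, lo_open = FALSE,
                        hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
    all(if (lo_open) x > lo else x >= lo) &&
    all(if (hi_open) x < hi else x <= hi)
  if (!ok) {
    config_error("configuration key '%s' must lie in %s%s, %s%s", key,
                 if (lo_open) "(" else "[", format(lo), format(hi),
                 if (hi_open) ")" else "]")
  }
  invisible(x)
}

#' Validate a run configuration
#'
#' Checks structural and scientific constraints: arena size, diffusion and
#' evaporation fractions, satiation bounds, learning-rate range, the
#' weight-bound ordering of the reward circuit, and the species contracts
#' (the drug item provides no nutrition unless explicitly overridden; hermi
#' reward is positive, flab negative, and drug reward exceeds hermi's).
#'
#' @param config A configuration list as produced by [default_config()] or
#'   [load_config()].
#' @param allow_drug_nutrition Set `TRUE` to permit a nutritive drug item
#'   (normally rejected).
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config, allow_drug_nutrition = FALSE) {
  w <- config$world
  if (w$arena_size < 20) config_error("world.arena_size must be >= 20")
  check_range(w$diffusion_fraction, "world.diffusion_fraction", 0, 1)
  check_range(w$evaporation_fraction, "world.evaporation_fraction", 0, 1,
              hi_open = TRUE)
  sp <- config$species
  if (!setequal(names(sp), SPECIES_NAMES)) {
    config_error("species block must define exactly: %s",
                 paste(SPECIES_NAMES, collapse = ", "))
  }
  if (sp$drug$nutrition_value != 0 && !allow_drug_nutrition) {
    config_error(paste0("species.drug.nutrition_value must be 0 (the drug ",
                        "item provides no nutrition); pass ",
                        "allow_drug_nutrition = TRUE to override"))
  }
  if (sp$hermi$reward_magnitude <= 0)
    config_error("species.hermi.reward_magnitude must be > 0")
  if (sp$flab$reward_magnitude >= 0)
    config_error("species.flab.reward_magnitude must be < 0")
  if (sp$drug$reward_magnitude <= sp$hermi$reward_magnitude)
    config_error("species.drug.reward_magnitude must exceed hermi's")
  fp <- config$forager
  check_range(fp$s_floor, "forager.s_floor", 0, 1, lo_open = TRUE)
  check_range(fp$approach_threshold, "forager.approach_threshold", 0, 1)
  check_range(fp$bite_threshold, "forager.bite_threshold", 0, 1)
  lp <- config$learning
  check_range(lp$alpha, "learning.alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_range(lp$alpha_extinction, "learning.alpha_extinction", 0, 1,
              lo_open = TRUE, hi_open = TRUE)
  ap <- config$affect
  if (ap$W_min >= ap$W_max) config_error("affect.W_min must be < affect.W_max")
  check_range(ap$W_init, "affect.W_init", ap$W_min, ap$W_max)
  ex <- config$experiments
  check_range(ex$s_axis, "experiments.s_axis", fp$s_floor, 1)
  if (is.unsorted(ex$s_axis, strictly = TRUE) ||
      is.unsorted(ex$re_axis_map, strictly = TRUE) ||
      is.unsorted(ex$re_axis_pain, strictly = TRUE)) {
    config_error("experiment axes must be strictly increasing")
  }
  check_range(ex$dead_zone, "experiments.dead_zone", 0, Inf, lo_open = TRUE)
  invisible(config)
}

#' Load a run configuration from a YAML (or JSON) file
#'
#' Reads a plain-text config, merges it over the package defaults (unknown
#' keys are rejected with the offending key named), and validates the result.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @param allow_drug_nutrition Passed to [validate_config()].
#' @return A validated configuration list.
#' @export
load_config <- function(path, allow_drug_nutrition = FALSE) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) config_error("config file must contain a mapping")
  config <- merge_config(default_config(), user)
  validate_config(config, allow_drug_nutrition = allow_drug_nutrition)
  config
}

#' Write a configuration to a YAML file
#'
#' @param config A configuration list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  # YAML serializes named atomic vectors as bare sequences; write them as
  # maps so names (e.g. the phase tick counts) survive the round trip
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(namify(config), path)
  invisible(path)
}

#' Derive a child RNG seed for trial `k`
#'
#' One root seed drives the whole run; per-trial streams are derived by a
#' fixed offset so trial `k` is invariant to the total trial count.
#'
#' @param seed Root integer seed.
#' @param k Trial index (1-based).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647L) + 1L
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}
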