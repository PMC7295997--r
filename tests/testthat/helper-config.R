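# A reduced configuration for fast unit tests: small arena, short phases.
# The acceptance suite uses the shipped defaults instead.
small_config <- function(arena = 60L, phases = c(prey_only = 300L,
                                                 drug_introduced = 600L,
                                                 drug_removed = 300L,
                                                 drug_without_reward = 600L)) {
  cfg <- default_config()
  cfg$world$arena_size <- arena
  cfg$experiments$phase_ticks <- phases
  cfg
}

field_with_point_mass <- function(n, i, j, mass) {
  f <- matrix(0, n, n)
  f[i, j] <- mass
  f
}

# sensor reading with prescribed side-summed values, zero elsewhere
reading_with <- function(left = c(betaine = 0, hermi = 0, flab = 0, drug = 0),
                         right = c(betaine = 0, hermi = 0, flab = 0,
                                   drug = 0)) {
  rbind(left = left, right = right)
}
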