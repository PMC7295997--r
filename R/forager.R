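#' Create a forager state
#'
#' @param config Full configuration list.
#' @param x,y Initial position (defaults to arena center).
#' @param heading Initial heading in degrees (counterclockwise positive, 0 =
#'   +x axis).
#' @param N Initial nutrition level.
#' @return A forager state list: position, heading, nutrition `N`, satiation
#'   `S`, and the decision parameter block.
#' @export
make_forager <- function(config, x = config$world$arena_size / 2,
                         y = config$world$arena_size / 2,
                         heading = 0, N = 1) {
  fp <- config$forager
  list(x = x, y = y, heading = heading, N = N,
       S = satiation_from_nutrition(N, fp),
       AS = NA_real_, I = NA_real_)
}

satiation_from_nutrition <- function(N, fp) {
  min(max(N / (N + fp$K_half), fp$s_floor), 1)
}

deg2rad <- function(d) d * pi / 180

#' Sense the odor fields at the two lateral sensors
#'
#' Two sensors sit at `sensor_reach` patches from the body center, at
#' `heading +/- sensor_angle`. Each returns a log-scaled non-negative value
#' per odor signature: `s = max(0, k_log + log10(c + c_floor))`, zero when
#' the local concentration is at or below the floor.
#'
#' @param fields Odor fields.
#' @param forager Forager state.
#' @param fp Forager parameter block (`config$forager`).
#' @return A `2 x 4` matrix, rows `left`/`right`, columns the signatures.
#' @export
sense <- function(fields, forager, fp) {
  n <- nrow(fields$betaine)
  ang <- deg2rad(forager$heading + c(fp$sensor_angle, -fp$sensor_angle))
  sx <- forager$x + fp$sensor_reach * cos(ang)
  sy <- forager$y + fp$sensor_reach * sin(ang)
  ix <- cell_index(sx, n)
  iy <- cell_index(sy, n)
  out <- matrix(0, 2, length(SIGNATURES),
                dimnames = list(c("left", "right"), SIGNATURES))
  for (k in seq_along(SIGNATURES)) {
    f <- fields[[SIGNATURES[k]]]
    conc <- c(f[ix[1], iy[1]], f[ix[2], iy[2]])
    out[, k] <- pmax(0, fp$k_log + log10(conc + fp$c_floor))
  }
  out
}

#' Somatic map: stimulus side and turn amplitude
#'
#' A body-referenced place code of total stimulation. The side with the
#' greater summed input (over all odor signatures, plus any pain input routed
#' to its side) is the stimulus side; ties map to `center`. Turn amplitude is
#' `gain_turn * |left - right|`, capped at `max_turn` degrees per tick. Turn
#' direction is set elsewhere, by appetitive state.
#'
#' @param reading Sensor matrix from [sense()].
#' @param fp Forager parameter block.
#' @param pain Optional pain state list (`P`, `site` bearing in degrees);
#'   pain contributes an input of strength `P` on the side of its bearing.
#' @return List with `side` (`"left"`, `"right"`, `"center"`) and `amplitude`
#'   (degrees/tick, non-negative).
#' @export
somatic_map <- function(reading, fp, pain = NULL) {
  left <- sum(reading["left", ])
  right <- sum(reading["right", ])
  if (!is.null(pain) && pain$P > 0 && is.finite(pain$site)) {
    b <- ((pain$site + 180) %% 360) - 180
    if (b > 0) left <- left + pain$P
    if (b < 0) right <- right + pain$P
  }
  d <- left - right
  side <- if (d > 0) "left" else if (d < 0) "right" else "center"
  list(side = side, amplitude = min(fp$gain_turn * abs(d), fp$max_turn))
}

#' Incentive: summed stimulus value of current sensory input
#'
#' `I = sum_k V+_k * s_k + w_betaine * s_betaine - sum_k V-_k * s_k`, where
#' `s_k` is the side-summed (left + right) sensed value of signature `k` and
#' `V+`, `V-` are the learned positive and negative associative strengths.
#'
#' @param reading Sensor matrix from [sense()].
#' @param V Associative strengths from [make_associations()].
#' @param w_betaine Innate weight of the betaine resource signal.
#' @return Signed incentive (scalar).
#' @export
compute_incentive <- function(reading, V, w_betaine) {
  s <- colSums(reading)
  sum(V$pos[SPECIES_NAMES] * s[SPECIES_NAMES]) + w_betaine * s[["betaine"]] -
    sum(V$neg[SPECIES_NAMES] * s[SPECIES_NAMES])
}

#' Appetitive state: the logistic decision drive
#'
#' Integrates incentive `I`, satiation `S`, reward experience `RE`, and pain
#' `P` into the excitation of the feeding network:
#' \deqn{AS = \sigma(\beta (I + h_0 (1-S)(1 + c_w \max(0,-RE))
#'   - c_s S (1 + c_{re} \max(0,RE)) - Q(RE, P) - \theta))}
#' where `Q` is the net suppression from the reciprocal inhibition of reward
#' experience and pain ([mutual_inhibition()]). Hunger (`1 - S`) drives
#' appetitive state up, and is amplified in withdrawal (negative `RE`);
#' satiation suppresses it, more strongly under positive `RE`; large positive
#' `RE` or unopposed pain suppresses it directly.
#'
#' @param I Incentive.
#' @param S Satiation in `[s_floor, 1]`.
#' @param RE Signed reward experience.
#' @param P Non-negative pain-center output.
#' @param fp Forager parameter block.
#' @param ap Affect parameter block (for the reciprocal-inhibition constants).
#' @return Appetitive state in `(0, 1)`.
#' @export
compute_appetitive_state <- function(I, S, RE, P, fp, ap) {
  if (!all(is.finite(c(I, S, RE, P)))) {
    stop("non-finite input to appetitive state", call. = FALSE)
  }
  Q <- mutual_inhibition(RE, P, ap$k_rp, ap$k_pr, ap$c_p)$Q
  drive <- I +
    fp$h0 * (1 - S) * (1 + fp$c_w * max(0, -RE)) -
    fp$c_s * S * (1 + fp$c_re * max(0, RE)) -
    Q - fp$theta
  1 / (1 + exp(-fp$beta * drive))
}

#' Turn decision: approach or avoid along the somatic map
#'
#' At or above `approach_threshold`, the turn is directed toward the stimulus
#' side; below it, away. The amplitude comes from the somatic map; a centered
#' stimulus yields no turn regardless of appetitive state.
#'
#' @param AS Appetitive state.
#' @param smap Somatic map from [somatic_map()].
#' @param approach_threshold Threshold on `AS`.
#' @return Signed turn angle in degrees/tick (positive = counterclockwise,
#'   i.e., toward the left sensor).
#' @export
decide_turn <- function(AS, smap, approach_threshold) {
  if (smap$side == "center" || smap$amplitude == 0) return(0)
  toward <- if (smap$side == "left") 1 else -1
  if (AS >= approach_threshold) toward * smap$amplitude else -toward * smap$amplitude
}

#' Apply a turn, move, and consume items in reach
#'
#' The heading always changes by the commanded turn; the position advances by
#' `speed * dt` along the new heading only when `mobility` is `TRUE` (in
#' presentation mode the forager is immobilized but retains free turning).
#' Any live item within `capture_radius` is consumed when appetitive state is
#' at or above `bite_threshold`: the item is marked dead and a consumption
#' event carrying its species, reward magnitude, and nutrition value is
#' emitted.
#'
#' @param forager Forager state (with `AS` set for this tick).
#' @param items Item data frame.
#' @param turn Signed turn angle from [decide_turn()].
#' @param mobility Logical; `FALSE` immobilizes translation.
#' @param fp Forager parameter block.
#' @param species_params The `species` block of the configuration.
#' @param arena_size Integer patches per side.
#' @return List with updated `forager`, `items`, and `events` (a data frame
#'   with columns `species`, `reward`, `nutrition`; zero rows if nothing was
#'   consumed).
#' @export
step_and_consume <- function(forager, items, turn, mobility, fp,
                             species_params, arena_size) {
  forager$heading <- (forager$heading + turn) %% 360
  if (mobility) {
    a <- deg2rad(forager$heading)
    forager$x <- (forager$x + fp$speed * cos(a)) %% arena_size
    forager$y <- (forager$y + fp$speed * sin(a)) %% arena_size
  }
  events <- .empty_events
  if (nrow(items) > 0 && !is.na(forager$AS) &&
      forager$AS >= fp$bite_threshold) {
    d <- torus_distance(forager$x, forager$y, items$x, items$y, arena_size)
    hit <- which(items$alive & d <= fp$capture_radius)
    if (length(hit)) {
      items$alive[hit] <- FALSE
      sp <- items$species[hit]
      events <- data.frame(
        species = sp,
        reward = vapply(sp, function(s) species_params[[s]]$reward_magnitude,
                        0.0),
        nutrition = vapply(sp, function(s) species_params[[s]]$nutrition_value,
                           0.0),
        stringsAsFactors = FALSE)
    }
  }
  list(forager = forager, items = items, events = events)
}

#' Update nutrition and satiation after a tick
#'
#' Nutrition decays multiplicatively and gains the summed nutrition of the
#' tick's consumption events (the drug item carries zero nutrition, so
#' consuming it leaves `N` unchanged). Satiation is the saturating readout
#' `S = clamp(N / (N + K_half), s_floor, 1)`.
#'
#' @param forager Forager state.
#' @param events Consumption events from [step_and_consume()].
#' @param fp Forager parameter block.
#' @return The updated forager.
#' @export
update_satiation <- function(forager, events, fp) {
  gain <- if (nrow(events)) sum(events$nutrition) else 0
  forager$N <- forager$N * (1 - fp$k_N) + gain
  forager$S <- satiation_from_nutrition(forager$N, fp)
  forager
}
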