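#' Create naive associative strengths
#'
#' Positive (`pos`) and negative (`neg`) learned values per odor signature,
#' all zero in the naive state and bounded in `[0, 1]`.
#'
#' @return List with named numeric vectors `pos` and `neg`.
#' @export
make_associations <- function() {
  z <- stats::setNames(numeric(length(SPECIES_NAMES)), SPECIES_NAMES)
  list(pos = z, neg = z)
}

#' Rescorla-Wagner update of one associative strength
#'
#' `V' = V + alpha (lambda - V)`. With `V` and `lambda` in `[0, 1]` the
#' update stays in `[0, 1]`; `lambda = 0` gives geometric extinction.
#'
#' @param V Current strength in `[0, 1]`.
#' @param lambda Asymptote in `[0, 1]`.
#' @param alpha Learning rate in `(0, 1)`.
#' @return The updated strength.
#' @export
rw_update <- function(V, lambda, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    config_error("learning rate alpha must lie in (0, 1)")
  }
  V + alpha * (lambda - V)
}

#' Apply one consumption event to the associative strengths
#'
#' Learning mode follows the feeding network's operation: rewarding
#' consumption (reward > 0, approach/feeding mode) drives the positive
#' strength of the consumed species toward `min(1, reward / r_norm)`;
#' noxious consumption (reward < 0, avoidance mode) drives the negative
#' strength toward `min(1, |reward| / r_norm)`; consumption without reward
#' extinguishes the positive strength (asymptote 0). Untouched species are
#' unchanged (single-cue updates: each event names exactly one signature).
#'
#' @param V Associative strengths from [make_associations()].
#' @param species Species tag of the consumed item.
#' @param reward Signed reward magnitude of the event.
#' @param lp Learning parameter block (`config$learning`).
#' @param mode Optional override, `"feeding"` or `"avoidance"`; by default
#'   inferred from the reward sign.
#' @return The updated strengths.
#' @export
apply_learning_event <- function(V, species, reward, lp, mode = NULL) {
  if (!species %in% SPECIES_NAMES) {
    config_error("unknown species tag: %s", species)
  }
  if (is.null(mode)) mode <- if (reward < 0) "avoidance" else "feeding"
  if (mode == "avoidance") {
    V$neg[species] <- rw_update(V$neg[species],
                                min(1, abs(reward) / lp$r_norm), lp$alpha)
  } else if (reward > 0) {
    V$pos[species] <- rw_update(V$pos[species],
                                min(1, reward / lp$r_norm), lp$alpha)
  } else {
    V$pos[species] <- rw_update(V$pos[species], 0, lp$alpha_extinction)
  }
  V
}
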