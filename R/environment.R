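#' Create an empty set of odor fields
#'
#' One non-negative concentration matrix per odor signature: the betaine
#' resource signal plus one signature per species. Fields for absent species
#' stay identically zero until something deposits into them.
#'
#' @param arena_size Integer patches per side.
#' @return Named list of `arena_size x arena_size` zero matrices, one per
#'   signature (`betaine`, `hermi`, `flab`, `drug`).
#' @export
make_odor_fields <- function(arena_size) {
  z <- matrix(0, arena_size, arena_size)
  stats::setNames(lapply(SIGNATURES, function(s) z), SIGNATURES)
}

#' Create prey/drug items at uniform-random arena positions
#'
#' Positions are drawn from the current RNG stream (seed it for
#' reproducibility). Items are represented as a data frame with one row per
#' item: `species`, continuous coordinates `x`, `y`, and an `alive` flag.
#'
#' @param species Character vector of species tags, one per item.
#' @param arena_size Integer patches per side.
#' @return A data frame of items.
#' @export
make_items <- function(species, arena_size) {
  bad <- setdiff(unique(species), SPECIES_NAMES)
  if (length(bad)) config_error("unknown species tag: %s", bad[1])
  n <- length(species)
  data.frame(species = species,
             x = stats::runif(n, 0, arena_size),
             y = stats::runif(n, 0, arena_size),
             alive = rep(TRUE, n),
             stringsAsFactors = FALSE)
}

cell_index <- function(coord, n) {
  as.integer(floor(coord %% n)) + 1L
}

#' Deposit odors from live items into the fields
#'
#' Each live item adds its `signature_deposit` to its own signature field and
#' its `betaine_deposit` to the betaine (resource signal) field, in the cell
#' containing the item. Dead items deposit nothing; no other cells change.
#'
#' @param items Item data frame from [make_items()].
#' @param fields Odor fields from [make_odor_fields()].
#' @param species_params The `species` block of the configuration.
#' @return The updated fields.
#' @export
deposit_odors <- function(items, fields, species_params) {
  if (nrow(items) == 0) return(fields)
  bad <- setdiff(unique(items$species), SPECIES_NAMES)
  if (length(bad)) config_error("unknown species tag: %s", bad[1])
  n <- nrow(fields$betaine)
  live <- which(items$alive)
  for (i in live) {
    sp <- items$species[i]
    ix <- cell_index(items$x[i], n)
    iy <- cell_index(items$y[i], n)
    fields[[sp]][ix, iy] <- fields[[sp]][ix, iy] +
      species_params[[sp]]$signature_deposit
    bd <- species_params[[sp]]$betaine_deposit
    if (bd > 0) fields$betaine[ix, iy] <- fields$betaine[ix, iy] + bd
  }
  fields
}

#' One diffusion and evaporation step on a toroidal odor field
#'
#' Each cell shares `diffusion_fraction` of its content equally among its 8
#' toroidal neighbors, then every cell is scaled by
#' `1 - evaporation_fraction`. Mass is conserved exactly when evaporation is
#' zero, and the result is non-negative for non-negative input.
#'
#' @param field A numeric matrix (one odor signature).
#' @param diffusion_fraction Fraction in `[0, 1]` shared with neighbors.
#' @param evaporation_fraction Fraction in `[0, 1)` lost per tick.
#' @return The updated matrix.
#' @export
diffuse_decay <- function(field, diffusion_fraction, evaporation_fraction) {
  if (!is.numeric(diffusion_fraction) || diffusion_fraction < 0 ||
      diffusion_fraction > 1) {
    config_error("diffusion_fraction must lie in [0, 1]")
  }
  if (!is.numeric(evaporation_fraction) || evaporation_fraction < 0 ||
      evaporation_fraction >= 1) {
    config_error("evaporation_fraction must lie in [0, 1)")
  }
  .diffuse_decay_cpp(field, diffusion_fraction, evaporation_fraction)
}

#' Respawn a dead item at a uniform-random arena position
#'
#' Draws exactly one position (two uniform deviates) from the current RNG
#' stream and returns the item alive at that position. Respawn of live items
#' is an error; phases with respawning disabled simply never call this.
#'
#' @param item A one-row item data frame (or list) with `alive = FALSE`.
#' @param arena_size Integer patches per side.
#' @return The item, alive at the new position.
#' @export
respawn_prey <- function(item, arena_size) {
  if (isTRUE(item$alive)) config_error("cannot respawn a live item")
  pos <- stats::runif(2, 0, arena_size)
  item$x <- pos[1]
  item$y <- pos[2]
  item$alive <- TRUE
  item
}

#' Sample an odor field at a continuous arena position
#'
#' Coordinates wrap toroidally; the value of the containing cell is returned.
#'
#' @param field A numeric odor matrix.
#' @param x,y Continuous arena coordinates.
#' @return The concentration in the containing cell (non-negative).
#' @export
sample_odor <- function(field, x, y) {
  n <- nrow(field)
  field[cell_index(x, n), cell_index(y, n)]
}

#' Toroidal distance between points
#'
#' @param x1,y1 Coordinates of the first point (scalars).
#' @param x2,y2 Coordinates of the second point(s) (vectorized).
#' @param arena_size Integer patches per side.
#' @return Euclidean distance on the torus.
#' @export
torus_distance <- function(x1, y1, x2, y2, arena_size) {
  dx <- (x2 - x1) %% arena_size
  dx <- pmin(dx, arena_size - dx)
  dy <- (y2 - y1) %% arena_size
  dy <- pmin(dy, arena_size - dy)
  sqrt(dx^2 + dy^2)
}
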