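write_csv_stable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

grid_long <- function(grid) {
  do.call(rbind, lapply(names(grid$items), function(item) {
    m <- grid$items[[item]]
    data.frame(item = item,
               S = rep(grid$s_axis, times = length(grid$re_axis)),
               RE = rep(grid$re_axis, each = length(grid$s_axis)),
               outcome = as.vector(m), stringsAsFactors = FALSE)
  }))
}

plot_grid_png <- function(m, s_axis, re_axis, title, path) {
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  graphics::image(x = s_axis, y = re_axis, z = m,
                  col = c("#b2182b", "#f7f7f7", "#2166ac"),
                  breaks = c(-1.5, -0.5, 0.5, 1.5),
                  xlab = "satiation", ylab = "reward experience",
                  main = title)
}

cycle_long <- function(result) {
  vars <- colnames(result$mean)
  do.call(rbind, lapply(vars, function(v) {
    data.frame(tick = seq_along(result$phase),
               phase = result$phase_names[result$phase],
               variable = v, mean = result$mean[, v],
               sem = result$sem[, v], stringsAsFactors = FALSE)
  }))
}

plot_cycle_png <- function(result, path) {
  grDevices::png(path, width = 900, height = 640)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  tk <- seq_along(result$phase)
  graphics::plot(tk, result$mean[, "RE"], type = "l",
                 xlab = "tick", ylab = "reward experience",
                 main = "addiction cycle")
  graphics::abline(v = tk[c(diff(result$phase) != 0, FALSE)], lty = 3)
  graphics::abline(h = 0, col = "grey")
  graphics::matplot(tk, result$mean[, SPECIES_NAMES], type = "l", lty = 1,
                    xlab = "tick", ylab = "cumulative consumed",
                    col = c("#2166ac", "#b2182b", "#4d4d4d"))
  graphics::legend("topleft", SPECIES_NAMES, lty = 1, bty = "n",
                   col = c("#2166ac", "#b2182b", "#4d4d4d"))
}

#' Write experiment outputs and a manifest
#'
#' Writes CSV artifacts (plus PNG figures when `plots = TRUE`) for a
#' selectivity/pain grid or an aggregated cycle result, together with a JSON
#' manifest listing every artifact, the configuration hash, and the seed.
#' Re-running with the same configuration and seed reproduces byte-identical
#' CSVs.
#'
#' @param result A `selectivity_grid` or `cycle_result`.
#' @param out_dir Output directory (created if missing).
#' @param config The configuration that produced the result.
#' @param seed The root seed of the run.
#' @param plots Whether to render PNG figures alongside the CSVs.
#' @return Character vector of written file paths (the manifest last),
#'   invisibly.
#' @export
write_outputs <- function(result, out_dir, config, seed = NULL,
                          plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) config_error("cannot create directory %s", out_dir)
  files <- character(0)
  if (inherits(result, "selectivity_grid")) {
    for (item in names(result$items)) {
      m <- result$items[[item]]
      p <- file.path(out_dir, sprintf("grid_%s_%s.csv", result$state, item))
      df <- data.frame(S = result$s_axis, m, check.names = FALSE)
      colnames(df) <- c("S", format(result$re_axis))
      files <- c(files, write_csv_stable(df, p))
      if (plots) {
        pp <- file.path(out_dir, sprintf("grid_%s_%s.png", result$state, item))
        plot_grid_png(m, result$s_axis, result$re_axis,
                      paste(result$state, item), pp)
        files <- c(files, pp)
      }
    }
    p <- file.path(out_dir, sprintf("grid_%s_long.csv", result$state))
    files <- c(files, write_csv_stable(grid_long(result), p))
    if (is.null(seed)) seed <- result$seed
  } else if (inherits(result, "cycle_result")) {
    p <- file.path(out_dir, "cycle_timecourse.csv")
    files <- c(files, write_csv_stable(cycle_long(result), p))
    final <- nrow(result$mean)
    summ <- data.frame(variable = colnames(result$mean),
                       final_mean = result$mean[final, ],
                       final_sem = result$sem[final, ],
                       row.names = NULL)
    p <- file.path(out_dir, "cycle_summary.csv")
    files <- c(files, write_csv_stable(summ, p))
    if (plots) {
      pp <- file.path(out_dir, "cycle_timecourse.png")
      plot_cycle_png(result, pp)
      files <- c(files, pp)
    }
    if (is.null(seed)) seed <- result$seeds[1]
  } else {
    config_error("write_outputs: unsupported result class '%s'",
                 class(result)[1])
  }
  manifest <- list(
    artifacts = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    config_md5 = config_hash(config),
    seed = seed)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, mp))
}

#' Write a per-tick trace of a cycle trial as CSV
#'
#' @param trial A `cycle_trial` run with `record_trace = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trial, path) {
  if (is.null(trial$trace)) {
    config_error("trial was run without record_trace = TRUE")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(tick = seq_along(trial$RE),
                   phase = trial$phase_names[trial$phase],
                   x = trial$trace$x, y = trial$trace$y,
                   heading = trial$trace$heading,
                   S = trial$S, AS = trial$trace$AS, I = trial$trace$I,
                   RE = trial$RE, V_drug = trial$V_drug)
  invisible(write_csv_stable(df, path))
}
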