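# Allowed configuration schema: NULL marks a scalar leaf, a list a block.
config_schema <- function() {
  list(
    seed = NULL, output_dir = NULL, log_level = NULL,
    growth = list(alpha = NULL, betas = NULL, lower_bound = NULL,
                  increment = NULL, increment_mode = NULL, factors = NULL),
    lumen = list(A0 = NULL, Amax = NULL, rate = NULL),
    simulate = list(P0 = NULL, n_visits = NULL),
    markov = list(base = NULL, w1 = NULL, w2 = NULL, w3 = NULL, w4 = NULL,
                  w5 = NULL, p_us = NULL, hazard_su = NULL, link = NULL),
    spatial = list(height = NULL, width = NULL, kernel = NULL,
                   range = NULL, adjacency = NULL, periodic = NULL),
    mrf = list(v_u = NULL, J = NULL, beta = NULL, sweeps = NULL,
               burn_in = NULL),
    fixtures = list(n_visits = NULL, P0 = NULL, r = NULL,
                    increment = NULL, noise_sd = NULL, height = NULL,
                    width = NULL, corr_range = NULL, sd = NULL)
  )
}

config_defaults <- function() {
  list(
    seed = 1L, output_dir = ".", log_level = "info",
    growth = list(alpha = 1, betas = c(0, 0, 0, 0), lower_bound = 1,
                  increment = 0, increment_mode = "additive"),
    lumen = list(A0 = 10, Amax = 14, rate = 0.25),
    simulate = list(P0 = 0.1, n_visits = 20),
    markov = list(base = 0.05, w1 = 0, w2 = 0, w3 = 0, w4 = 0, w5 = 0,
                  p_us = 0.1, hazard_su = 0.1, link = "linear"),
    spatial = list(height = 10, width = 10, kernel = "uniform", range = 1,
                   adjacency = "von_neumann", periodic = FALSE),
    mrf = list(v_u = 0, J = 0.2, beta = 1, sweeps = 5000, burn_in = 1000),
    fixtures = list(n_visits = 20, P0 = 0.1, r = 1.8, increment = 0,
                    noise_sd = 0.01, height = 10, width = 10,
                    corr_range = 0, sd = 0.3)
  )
}

collect_unknown_keys <- function(cfg, schema, path = "") {
  bad <- character(0)
  for (nm in names(cfg)) {
    full <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(schema)) {
      bad <- c(bad, full)
    } else if (is.list(schema[[nm]]) && is.list(cfg[[nm]])) {
      bad <- c(bad, collect_unknown_keys(cfg[[nm]], schema[[nm]], full))
    }
  }
  bad
}

merge_defaults <- function(cfg, defaults) {
  applied <- character(0)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
      applied <- c(applied, nm)
    } else if (is.list(defaults[[nm]]) && is.list(cfg[[nm]])) {
      sub <- merge_defaults(cfg[[nm]], defaults[[nm]])
      cfg[[nm]] <- sub$cfg
      applied <- c(applied, paste(nm, sub$applied, sep = "."))
    }
  }
  list(cfg = cfg, applied = applied)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file,
#' rejects any key not in the documented schema (strict parsing, so a
#' misspelled key can never silently fall back to a default), fills in
#' defaults for everything omitted, and reports which defaults were
#' applied. Recognized blocks: `growth`, `lumen`, `simulate`, `markov`,
#' `spatial`, `mrf`, `fixtures`, plus top-level `seed`, `output_dir` and
#' `log_level`.
#'
#' @param path Path to the configuration file.
#' @return A validated configuration list of class `run_config`, with the
#'   key paths that received defaults in attribute `"defaults_applied"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON, got extension: ", ext,
         call. = FALSE)
  )
  if (!is.list(cfg)) stop("config must parse to a mapping", call. = FALSE)
  bad <- collect_unknown_keys(cfg, config_schema())
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  merged <- merge_defaults(cfg, config_defaults())
  cfg <- merged$cfg
  if (identical(cfg$log_level, "debug") && length(merged$applied)) {
    message("config defaults applied for: ",
            paste(merged$applied, collapse = ", "))
  }
  attr(cfg, "defaults_applied") <- merged$applied
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration
#'
#' Serializes a configuration back to YAML or JSON (by extension), such
#' that re-loading parses to an equivalent configuration.
#'
#' @param cfg A `run_config` or plain list.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(cfg)
  attr(plain, "defaults_applied") <- NULL
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(plain, path),
    json = jsonlite::write_json(plain, path, auto_unbox = TRUE,
                                digits = NA),
    stop("config must be written as YAML or JSON", call. = FALSE)
  )
  invisible(path)
}

#' Read serial plaque measurements
#'
#' Reads the measurement CSV dialect: comma-separated, UTF-8, mandatory
#' header `patient_id,visit_index,P`, with `P` a decimal fraction in
#' \[0, 1\] (not a percentage).
#'
#' @param path CSV path.
#' @return A data frame with the three columns, ordered by patient and
#'   visit.
#' @export
read_measurement_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "visit_index", "P")
  if (!identical(names(df), need)) {
    stop(sprintf(
      "%s: header must be exactly '%s' (found '%s')",
      path, paste(need, collapse = ","), paste(names(df), collapse = ",")
    ), call. = FALSE)
  }
  if (!is.numeric(df$P) || anyNA(df$P) || any(df$P < 0 | df$P > 1)) {
    bad <- which(!is.finite(df$P) | df$P < 0 | df$P > 1)[1]
    stop(sprintf("%s: column P, row %d: value outside [0, 1]",
                 path, bad), call. = FALSE)
  }
  df[order(df$patient_id, df$visit_index), , drop = FALSE]
}

#' @rdname read_measurement_csv
#' @param df Data frame with columns `patient_id`, `visit_index`, `P`.
#' @export
write_measurement_csv <- function(df, path) {
  utils::write.csv(df[c("patient_id", "visit_index", "P")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-patient growth-rate estimates from a measurement table
#'
#' Applies [estimate_r_series()] within each patient of a measurement data
#' frame and assembles the estimate table written by
#' [write_r_estimates_csv()].
#'
#' @param measurements Data frame as returned by [read_measurement_csv()].
#' @return Data frame with columns `patient_id`, `interval_index`
#'   (1-based), `r_hat` and `flag`.
#' @export
estimate_r_table <- function(measurements) {
  pieces <- lapply(split(measurements, measurements$patient_id),
    function(d) {
      d <- d[order(d$visit_index), ]
      r_hat <- estimate_r_series(d$P)
      data.frame(
        patient_id = d$patient_id[1],
        interval_index = seq_along(r_hat),
        r_hat = as.numeric(r_hat),
        flag = attr(r_hat, "flag")
      )
    })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' @rdname estimate_r_table
#' @param estimates Data frame from [estimate_r_table()].
#' @param path CSV path.
#' @export
write_r_estimates_csv <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a simulated trajectory
#'
#' Writes a [simulate_trajectory()] result as CSV with columns
#' `visit,P,r,A,stenosis_vs_baseline`.
#'
#' @param traj A `plaque_trajectory`.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "plaque_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an instability heatmap
#'
#' Writes a per-site probability field as `<prefix>.csv` (the
#' authoritative artifact: matrix layout, header row, 12 significant
#' digits — enough to round-trip doubles for testing) and `<prefix>.png`
#' (presentation render: blue-to-red color ramp on a fixed \[0, 1\] scale
#' so heatmaps from different models are directly comparable; warm colors
#' mark sites at elevated risk of destabilization).
#'
#' @param field Numeric matrix with all values in \[0, 1\], e.g. from
#'   [instability_heatmap()] or [marginal_instability()].
#' @param out_prefix Output path prefix (without extension).
#' @param png Also render the PNG? Default `TRUE`.
#' @return Character vector of the files written, invisibly.
#' @export
write_heatmap <- function(field, out_prefix, png = TRUE) {
  if (!is.matrix(field) || !is.numeric(field) || anyNA(field) ||
      any(field < 0 | field > 1)) {
    stop("`field` must be a numeric matrix with values in [0, 1]",
         call. = FALSE)
  }
  csv_path <- paste0(out_prefix, ".csv")
  fmt <- matrix(formatC(field, digits = 12, format = "g"),
                nrow = nrow(field))
  colnames(fmt) <- paste0("col_", seq_len(ncol(field)))
  utils::write.table(fmt, csv_path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  files <- csv_path
  if (png) {
    png_path <- paste0(out_prefix, ".png")
    ramp <- grDevices::colorRampPalette(
      c("#2166AC", "#F7F7F7", "#B2182B")
    )(256)
    grDevices::png(png_path, width = 480, height = 480)
    op <- graphics::par(mar = c(2, 2, 2, 1))
    # transpose/reverse so the image matches the matrix orientation
    graphics::image(
      t(field[rev(seq_len(nrow(field))), , drop = FALSE]),
      col = ramp, zlim = c(0, 1), axes = FALSE,
      main = "P(stable -> unstable)"
    )
    graphics::par(op)
    grDevices::dev.off()
    files <- c(files, png_path)
  }
  invisible(files)
}

#' @rdname write_heatmap
#' @param path Path of a heatmap CSV written by [write_heatmap()].
#' @export
read_heatmap_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}
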