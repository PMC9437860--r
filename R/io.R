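# Run configuration, CSV readers/writers and the output manifest.

CONFIG_RANGES <- list(
  erosion_radius  = c(0, 50),
  connectivity    = c(4, 8),
  min_area        = c(0, Inf),
  epsilon_rel     = c(1e-6, 0.5),
  increments      = c(2, 100),
  stationary_px   = c(0, Inf),
  path_width      = c(1, 51),
  threshold_method = NA,   # categorical
  threshold_value  = c(-Inf, Inf),
  background       = c(0, Inf),
  seed             = c(-2^31 + 1, 2^31 - 1)
)

#' Default run configuration
#'
#' Tunables with their defaults: `erosion_radius` 3 px, `connectivity` 8,
#' `min_area` 500 px, `epsilon_rel` 0.009, `increments` 10,
#' `stationary_px` 2, `path_width` 3, `threshold_method` "otsu",
#' `threshold_value` NA, `background` 0, `seed` 1.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(erosion_radius = 3, connectivity = 8, min_area = 500,
       epsilon_rel = 0.009, increments = 10, stationary_px = 2,
       path_width = 3, threshold_method = "otsu", threshold_value = NA,
       background = 0, seed = 1)
}

#' Validate a configuration list
#'
#' Unknown keys are rejected; every value must fall in its documented range.
#'
#' @param config named list (possibly partial; missing keys take defaults).
#' @return completed, validated configuration.
#' @export
validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(base, config)
  if (!cfg$threshold_method %in% c("otsu", "fixed"))
    stop("threshold_method must be 'otsu' or 'fixed'", call. = FALSE)
  if (cfg$threshold_method == "fixed" && is.na(cfg$threshold_value))
    stop("threshold_method 'fixed' requires threshold_value", call. = FALSE)
  if (!cfg$connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  for (key in setdiff(names(CONFIG_RANGES), c("threshold_method", "connectivity"))) {
    v <- cfg[[key]]
    if (is.na(v) && key == "threshold_value") next
    rng <- CONFIG_RANGES[[key]]
    if (!is.numeric(v) || v < rng[1L] || v > rng[2L])
      stop(sprintf("config key %s = %s outside its range [%g, %g]",
                   key, v, rng[1L], rng[2L]), call. = FALSE)
  }
  cfg
}

#' Load configuration from a JSON file
#' @param path JSON file with a flat object of config keys.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

# --- CSV writers (RFC-4180 via write.csv, '.' decimal separator) ---------

#' Write contour CSV (cell_label, vertex_index, x, y)
#' @param contours list of `cell_contour`.
#' @param path output CSV path.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- do.call(rbind, lapply(contours, function(ct)
    data.frame(cell_label = ct$source_label,
               vertex_index = seq_len(nrow(ct$vertices)) - 1L,
               x = ct$vertices[, 1L], y = ct$vertices[, 2L])))
  if (is.null(rows))
    rows <- data.frame(cell_label = integer(0), vertex_index = integer(0),
                       x = numeric(0), y = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write per-cell profile CSV
#' (cell_id, fraction, shell_intensity, cumulative, valid_flag)
#' @param profiles list of `radial_profile`.
#' @param path output CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(cell_id = p$cell_id, fraction = p$fractions,
               shell_intensity = p$shell_intensity,
               cumulative = p$cumulative, valid_flag = p$valid)))
  if (is.null(rows))
    rows <- data.frame(cell_id = integer(0), fraction = numeric(0),
                       shell_intensity = numeric(0), cumulative = numeric(0),
                       valid_flag = logical(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a profile CSV back into `radial_profile` objects
#' @param path CSV written by [write_profiles_csv()].
#' @return list of `radial_profile`.
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$cell_id), function(s) {
    s <- s[order(s$fraction), ]
    structure(list(cell_id = s$cell_id[1L], fractions = s$fraction,
                   shell_intensity = s$shell_intensity,
                   cumulative = s$cumulative,
                   valid = isTRUE(as.logical(s$valid_flag[1L])),
                   n_pixels = NA_integer_, flagged = FALSE),
              class = "radial_profile")
  })
}

#' Write a group comparison CSV
#' @param cmp a `group_comparison`.
#' @param path output CSV path.
#' @export
write_comparison_csv <- function(cmp, path) {
  d <- data.frame(group = cmp$groups, n = as.integer(cmp$n),
                  mean_auc = cmp$mean_auc,
                  test = cmp$test, statistic = cmp$statistic,
                  p_value = cmp$p_value, shift = cmp$shift)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a path CSV (ordered columns x, y)
#' @param path CSV path.
#' @param width path width in pixels.
#' @return a `path_spec`.
#' @export
read_path_csv <- function(path, width = 3) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    stop("path CSV needs columns x, y", call. = FALSE)
  path_spec(cbind(d$x, d$y), width = width)
}

#' Write tracks CSV (track_id, frame, position | x, y)
#' @param tracks list of `org_track`.
#' @param path output CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    if (!is.null(tr$positions))
      data.frame(track_id = tr$id, frame = tr$frames,
                 position = tr$positions)
    else
      data.frame(track_id = tr$id, frame = tr$frames,
                 x = tr$xy[, 1L], y = tr$xy[, 2L])
  }))
  if (is.null(rows))
    rows <- data.frame(track_id = integer(0), frame = integer(0),
                       position = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks CSV
#' @param path CSV with track_id, frame and position (or x, y) columns.
#' @return list of `org_track`.
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("track_id", "frame") %in% names(d)))
    stop("tracks CSV needs columns track_id, frame", call. = FALSE)
  lapply(split(d, d$track_id), function(s) {
    s <- s[order(s$frame), ]
    if ("position" %in% names(s))
      org_track(s$frame, positions = s$position, id = s$track_id[1L])
    else
      org_track(s$frame, xy = cbind(s$x, s$y), id = s$track_id[1L])
  })
}

#' Write a run manifest
#'
#' JSON listing of outputs with the configuration, its hash, package
#' version, seed and any collected warnings.
#'
#' @param out_dir output directory.
#' @param outputs character vector of files written.
#' @param config the run configuration.
#' @param warnings character vector of warnings raised during the run.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, outputs, config, warnings = character(0)) {
  manifest <- list(
    package = "orgaprof",
    version = as.character(utils::packageVersion("orgaprof")),
    seed = config$seed,
    config = config,
    config_hash = digest_config(config),
    outputs = as.list(basename(outputs)),
    warnings = as.list(warnings)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Plot mean cumulative curves to PNG
#'
#' @param cmp a `group_comparison`.
#' @param path PNG output path.
#' @export
plot_comparison <- function(cmp, path) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "distance fraction from cell center",
                 ylab = "cumulative normalized intensity",
                 main = sprintf("%s (p = %.3g)", cmp$test, cmp$p_value))
  for (i in seq_along(cmp$groups))
    graphics::lines(cmp$fractions, cmp$mean_curves[[i]], col = i, lwd = 2)
  graphics::legend("bottomright", legend = cmp$groups,
                   col = seq_along(cmp$groups), lwd = 2)
  invisible(path)
}
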