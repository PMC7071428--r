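# Run configuration: every tunable constant of the pipeline in one
# validated list, serializable as a flat key=value file so each run's
# settings are auditable.

configDefaults <- function() {
  list(
    pixel_threshold = 1400L,     # per-pixel |difference| threshold
    frame_threshold = 14000L,    # max foreground count for evaluable frame
    min_component = 375L,        # smallest conserved blob (px)
    disk_radius = 9L,            # closing structuring element radius
    square_width = 25L,          # geodesic dilation structuring element
    depth_window = 21L,          # max depth search window (odd, px)
    gate_px = 50,                # association gate (px/frame)
    max_misses = 15L,            # frames before a track closes
    kalman_process_noise = 1,    # px^2
    kalman_measurement_noise = 4,# px^2
    v_max = c(x = 4, y = 2.8, z = 4),  # max expected speed (m/s)
    K = 30L,                     # frames per velocity window
    epoch_s = 5L,                # epoch length (s)
    epoch_statistic = "mean",    # or "sum"
    use_smoothed = FALSE,        # Fourier input: smoothed vs raw centroid
    cut_sed = 2,                 # CARS score cut points
    cut_mvpa = 3,
    n_boot = 2000L,              # bootstrap replicates
    seed = 1L,
    debug_stages = FALSE
  )
}

#' Default pipeline configuration
#'
#' Returns the full set of tunables with their defaults; supplied
#' overrides are validated against the known keys (unknown keys are an
#' error).
#'
#' @param ... named overrides of individual keys
#' @return named list of configuration values
#' @export
defaultConfig <- function(...) {
  cfg <- configDefaults()
  over <- list(...)
  if (length(over) > 0L) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a key=value configuration file
#'
#' Lines are \code{key=value}; blank lines and lines starting with
#' \code{#} are ignored. Values are parsed as numbers where possible;
#' the \code{v_max} key accepts \code{x:4,y:2.8,z:4}.
#'
#' @param path configuration file
#' @return validated configuration list
#' @export
readConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- configDefaults()
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg))
      stop("unknown configuration key(s): ", key)
    over[[key]] <- parseConfigValue(key, val, cfg[[key]])
  }
  do.call(defaultConfig, over)
}

parseConfigValue <- function(key, val, template) {
  if (key == "v_max") {
    parts <- strsplit(val, ",", fixed = TRUE)[[1L]]
    kv <- do.call(rbind, strsplit(trimws(parts), ":", fixed = TRUE))
    out <- as.numeric(kv[, 2L]); names(out) <- kv[, 1L]
    return(out[c("x", "y", "z")])
  }
  if (is.logical(template)) return(as.logical(val))
  if (is.character(template)) return(val)
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) stop("non-numeric value for key ", key, ": ", val)
  if (is.integer(template)) as.integer(num) else num
}

#' Write a configuration snapshot
#'
#' @param config configuration list
#' @param path output file
#' @export
writeConfig <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    vs <- if (k == "v_max")
      paste(sprintf("%s:%g", names(v), v), collapse = ",")
    else as.character(v)
    paste0(k, "=", vs)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
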