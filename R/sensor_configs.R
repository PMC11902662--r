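#' Sensor-subset configurations
#'
#' The ablation study compares 23 combinations of pressure-sensor subsets
#' and inertial-sensor subsets per foot. Pressure subsets are restricted to
#' the six studied sites: none (`0P`), the three two-sensor pairs
#' (`2P.1m5m`, `2P.1mH`, `2P.5mH`), the three-sensor set (`3P.1m5mH`) and
#' all four (`4P`). Inertial subsets form the nested chain none, `A`,
#' `AG`, `AGM` (accelerometer, + gyroscope, + magnetometer). The empty-empty
#' combination is forbidden, leaving 6 x 4 - 1 = 23 configurations.
#'
#' @param pressure character subset of [pressure_sites()] (one of the six
#'   allowed subsets).
#' @param inertial character subset of `c("A", "G", "M")`, restricted to
#'   the nested chain.
#' @return a `sensor_config` with fields `pressure`, `inertial`, `name`.
#' @export
#' @examples
#' sensor_config(c("1m", "5m"), "A")$name
sensor_config <- function(pressure = character(), inertial = character()) {
  pressure <- as.character(pressure)
  inertial <- as.character(inertial)
  allowed_p <- .pressure_subsets()
  key <- paste(sort(pressure), collapse = "|")
  ok <- vapply(allowed_p, function(s) identical(paste(sort(s), collapse = "|"), key),
               logical(1))
  if (!any(ok)) {
    stop("disallowed pressure subset: {", paste(pressure, collapse = ","),
         "}; allowed: ", paste(names(allowed_p), collapse = ", "), call. = FALSE)
  }
  pressure <- allowed_p[[which(ok)]]          # canonical site order
  allowed_i <- list(character(), "A", c("A", "G"), c("A", "G", "M"))
  keyi <- paste(inertial, collapse = "")
  oki <- vapply(allowed_i, function(s) identical(paste(s, collapse = ""), keyi),
                logical(1))
  if (!any(oki)) {
    stop("disallowed inertial subset: {", paste(inertial, collapse = ","),
         "}; allowed: none, A, AG, AGM", call. = FALSE)
  }
  if (length(pressure) == 0 && length(inertial) == 0) {
    stop("a configuration must use at least one sensor (0P with no inertial sensors is forbidden)",
         call. = FALSE)
  }
  cfg <- structure(list(pressure = pressure, inertial = inertial, name = NULL),
                   class = "sensor_config")
  cfg$name <- config_name(cfg)
  cfg
}

# the six allowed pressure subsets, in ablation-table row order,
# each in canonical site order (BT, 1m, 5m, H)
.pressure_subsets <- function() {
  list("0P"       = character(),
       "2P.1m5m"  = c("1m", "5m"),
       "2P.1mH"   = c("1m", "H"),
       "2P.5mH"   = c("5m", "H"),
       "3P.1m5mH" = c("1m", "5m", "H"),
       "4P"       = c("BT", "1m", "5m", "H"))
}

# pressure-block label for a canonical pressure subset
.pressure_label <- function(pressure) {
  subsets <- .pressure_subsets()
  key <- paste(sort(pressure), collapse = "|")
  for (nm in names(subsets)) {
    if (identical(paste(sort(subsets[[nm]]), collapse = "|"), key)) return(nm)
  }
  stop("disallowed pressure subset", call. = FALSE)
}

#' @rdname sensor_config
#' @param config a `sensor_config`.
#' @export
config_name <- function(config) {
  p <- .pressure_label(config$pressure)
  i <- paste(config$inertial, collapse = "")
  if (nzchar(i)) paste0(p, " + ", i) else p
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf("<sensor_config> %s (%d channels)\n", x$name,
              length(channels_for(x))))
  invisible(x)
}

#' Enumerate the 23 canonical sensor configurations
#'
#' Stable ablation-table order: the `0P` block first (A, AG, AGM), then each
#' pressure block (`2P.1m5m`, `2P.1mH`, `2P.5mH`, `3P.1m5mH`, `4P`) with
#' inertial subsets none, A, AG, AGM.
#'
#' @return list of 23 `sensor_config` objects with unique names.
#' @export
#' @examples
#' length(enumerate_configs())
enumerate_configs <- function() {
  out <- list()
  inertials <- list(character(), "A", c("A", "G"), c("A", "G", "M"))
  for (p in .pressure_subsets()) {
    for (i in inertials) {
      if (length(p) == 0 && length(i) == 0) next
      out[[length(out) + 1L]] <- sensor_config(p, i)
    }
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Parse a canonical configuration name
#'
#' Whitespace-tolerant inverse of [config_name()]: `"4P + AGM"`,
#' `"2P.1m5m"`, `"0P+A"` all parse; disallowed subsets (e.g. `"2P.BT1m"`),
#' the forbidden bare `"0P"` and unknown tokens raise a parse error.
#'
#' @param name configuration name string.
#' @return a `sensor_config`.
#' @export
parse_config <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  s <- gsub("\\s+", "", name)
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  if (length(parts) < 1 || length(parts) > 2 || any(!nzchar(parts))) {
    stop("parse error: malformed configuration name: ", name, call. = FALSE)
  }
  subsets <- .pressure_subsets()
  if (!parts[1] %in% names(subsets)) {
    stop("parse error: unknown pressure subset token: ", parts[1], call. = FALSE)
  }
  pressure <- subsets[[parts[1]]]
  inertial <- character()
  if (length(parts) == 2) {
    if (!parts[2] %in% c("A", "AG", "AGM")) {
      stop("parse error: unknown inertial subset token: ", parts[2], call. = FALSE)
    }
    inertial <- strsplit(parts[2], "")[[1]]
  }
  sensor_config(pressure, inertial)
}

#' Channels selected by a configuration
#'
#' Expands a configuration to its canonical channel list: both feet always,
#' pressure sites plus 3 axes per selected inertial sensor, in the order of
#' [ski_channels()]. `4P + AGM` yields all 26 channels; `2P.1m5m + A`
#' yields 10.
#'
#' @param config a `sensor_config`.
#' @return character vector of channel names (subset of [ski_channels()]).
#' @export
channels_for <- function(config) {
  stopifnot(inherits(config, "sensor_config"))
  suffixes <- config$pressure
  for (s in config$inertial) {
    suffixes <- c(suffixes, paste0(s, c("x", "y", "z")))
  }
  all <- ski_channels()
  all[sub("^[RL]_", "", all) %in% suffixes]
}
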