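#' Canonical insole channel set
#'
#' Each instrumented insole carries four piezoresistive plantar-pressure
#' sensors -- big toe (`BT`), first metatarsal head (`1m`), fifth metatarsal
#' head (`5m`) and heel (`H`) -- plus a 9-DoF inertial measurement unit:
#' accelerometer (`Ax`,`Ay`,`Az`, in g), gyroscope (`Gx`,`Gy`,`Gz`, in
#' degrees per second) and magnetometer (`Mx`,`My`,`Mz`, in gauss).
#' Channels are prefixed `R_` / `L_` for the right and left foot, right foot
#' first, giving a fixed 26-name vocabulary and a deterministic tensor
#' layout.
#'
#' @return Character vector of the 26 canonical channel names, in canonical
#'   order.
#' @export
#' @examples
#' ski_channels()
ski_channels <- function() {
  base <- c("BT", "1m", "5m", "H",
            "Ax", "Ay", "Az",
            "Gx", "Gy", "Gz",
            "Mx", "My", "Mz")
  c(paste0("R_", base), paste0("L_", base))
}

#' Gear class labels in canonical order
#'
#' The three skating sub-techniques classified here: G2R and G2L are the
#' asymmetric uphill gears (poles angled to the right / left), G3 the
#' symmetric gear with a pole plant on every ski push. The order matches the
#' confusion-matrix row order used throughout.
#'
#' @return `c("G2R", "G3", "G2L")`
#' @export
gear_levels <- function() c("G2R", "G3", "G2L")

#' Pressure sensor site codes
#' @return `c("BT", "1m", "5m", "H")`
#' @export
pressure_sites <- function() c("BT", "1m", "5m", "H")

#' Modality of each channel
#'
#' @param channels character vector of canonical channel names.
#' @return factor with levels `pressure`, `acc`, `gyro`, `mag`.
#' @export
channel_modality <- function(channels) {
  stopifnot(all(channels %in% ski_channels()))
  suffix <- sub("^[RL]_", "", channels)
  mod <- rep("pressure", length(suffix))
  mod[grepl("^A", suffix)] <- "acc"
  mod[grepl("^G", suffix)] <- "gyro"
  mod[grepl("^M", suffix)] <- "mag"
  factor(mod, levels = c("pressure", "acc", "gyro", "mag"))
}

#' Pressure channel names (both feet) among a channel set
#' @param channels character vector of canonical channel names.
#' @return the subset that are plantar-pressure channels, input order kept.
#' @export
pressure_channels <- function(channels = ski_channels()) {
  channels[channel_modality(channels) == "pressure"]
}

# internal: coerce gear tokens to the canonical factor, error on unknowns
as_gear <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), gear_levels())
  if (length(bad) > 0) {
    stop("unknown gear label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = gear_levels())
}
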