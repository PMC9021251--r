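#' Pulse protocol
#'
#' Electrical pulse schedule for one treatment. The duty cycle
#' `D = pulse_duration_s * repetition_rate_hz` is the fraction of time pulses
#' are on during a burst; the duty-cycle bioheat solver scales the Joule
#' source by `D`.
#'
#' @param voltage_V pulse amplitude, V (> 0).
#' @param pulses_per_pair number of pulses delivered per electrode pair.
#' @param pulse_duration_s single pulse duration, s.
#' @param repetition_rate_hz pulse repetition rate, Hz.
#' @param electrode_spacing_mm nominal electrode spacing of the intended
#'   layout, mm (used for the voltage-to-distance ratio; optional).
#' @return object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(voltage_V, pulses_per_pair, pulse_duration_s,
                           repetition_rate_hz, electrode_spacing_mm = NA_real_) {
  check_number(voltage_V, "voltage_V", lower = 1e-9)
  check_number(pulses_per_pair, "pulses_per_pair", lower = 1)
  check_number(pulse_duration_s, "pulse_duration_s", lower = 1e-12)
  check_number(repetition_rate_hz, "repetition_rate_hz", lower = 1e-12)
  D <- pulse_duration_s * repetition_rate_hz
  if (D <= 0 || D > 1) stopf("duty cycle D = %g outside (0, 1]", D)
  structure(list(voltage_V = voltage_V,
                 pulses_per_pair = pulses_per_pair,
                 pulse_duration_s = pulse_duration_s,
                 repetition_rate_hz = repetition_rate_hz,
                 duty_cycle = D,
                 burst_duration_s = pulses_per_pair / repetition_rate_hz,
                 electrode_spacing_mm = electrode_spacing_mm),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<protocol: %g V, %g x %g us pulses per pair at %g Hz (D = %g, burst %.4g s)>\n",
              x$voltage_V, x$pulses_per_pair, x$pulse_duration_s * 1e6,
              x$repetition_rate_hz, x$duty_cycle, x$burst_duration_s))
  invisible(x)
}

#' Standard ECT protocol presets
#'
#' `"hexagonal_ect"`: 7-needle hexagonal array at 7.3 mm spacing; 730 V,
#' 96 pulses of 100 us in total (8 per pair over 12 pairs) at 5000 Hz
#' (duty cycle 0.5, 1.6 ms burst per pair).
#' `"linear_ect"`: two needles 20 mm apart; 2000 V, 8 pulses of 100 us at
#' 1 Hz (duty cycle 1e-4, 8 s schedule).
#' Both deliver a nominal voltage-to-distance ratio of 1000 V/cm.
#'
#' @param name preset name.
#' @return a [pulse_protocol()].
#' @export
protocol_presets <- function(name) {
  presets <- list(
    hexagonal_ect = function() pulse_protocol(730, 8, 100e-6, 5000, electrode_spacing_mm = 7.3),
    linear_ect    = function() pulse_protocol(2000, 8, 100e-6, 1, electrode_spacing_mm = 20)
  )
  if (!is.character(name) || length(name) != 1L || is.na(match(name, names(presets))))
    stopf("unknown protocol preset '%s'; available: %s",
          as.character(name)[1], paste(names(presets), collapse = ", "))
  presets[[name]]()
}

#' Nominal voltage-to-distance ratio of a protocol (V/cm)
#' @param protocol a [pulse_protocol()] with a known electrode spacing.
#' @export
voltage_to_distance_ratio <- function(protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  if (is.na(protocol$electrode_spacing_mm))
    stopf("protocol has no nominal electrode spacing")
  protocol$voltage_V / (protocol$electrode_spacing_mm / 10)
}
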