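#' Detect a droplet event in a sensor voltage trace
#'
#' Finds the meniscus spikes by their prominence above a rolling-median
#' baseline, takes the first and last qualifying spikes as the front and back
#' caps, and time-averages the interior voltage over the inter-spike window
#' shrunk by a guard fraction on each side (the guard excludes meniscus
#' lensing from the optical average).
#'
#' @param trace A tibble with columns `time_s` and `voltage_au`
#'   (uniformly sampled, as produced by [simulate_transit()]).
#' @param prominence_factor Spikes must rise this many robust noise SDs above
#'   the rolling baseline.
#' @param prominence_floor Absolute minimum prominence, a.u.; guards the
#'   detector in (near-)noise-free traces.
#' @param baseline_window_s Width of the rolling-median baseline window, s.
#' @param guard_fraction Fraction of the inter-spike interval discarded at
#'   each end before averaging.
#' @param min_interior_samples Minimum interior samples for a valid event.
#' @return A one-row tibble of class `dv_event`: `sensor_id`,
#'   `front_spike_time_s`, `back_spike_time_s`, `interior_start_s`,
#'   `interior_end_s`, `integrated_signal_au`, `n_interior_samples`.
#' @export
detect_event <- function(trace,
                         prominence_factor = 4,
                         prominence_floor = 0.02,
                         baseline_window_s = 0.1,
                         guard_fraction = 0.1,
                         min_interior_samples = 20) {
  if (nrow(trace) < 2) abort("Trace must contain at least 2 samples.")
  time_s <- trace$time_s
  v <- trace$voltage_au
  rate <- 1 / median(diff(time_s))

  k <- floor(baseline_window_s * rate / 2) * 2 + 1
  k <- min(k, floor((length(v) - 1) / 2) * 2 + 1)
  baseline <- runmed(v, k, endrule = "median")
  resid <- v - baseline
  noise <- mad(resid)
  threshold <- max(prominence_factor * noise, prominence_floor)

  above <- resid > threshold
  if (!any(above)) abort("No droplet found: no spike exceeds the prominence threshold.")
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  spike_runs <- which(runs$values)
  # Peak of each contiguous above-threshold run; ties go to the earliest sample.
  peaks <- vapply(spike_runs, function(i) {
    idx <- starts[i]:ends[i]
    idx[which.max(resid[idx])]
  }, integer(1))
  if (length(peaks) < 2) {
    abort("No droplet found: need two meniscus spikes, got one.")
  }
  if (length(peaks) > 2) {
    warn(sprintf("Multiplet: %d spike candidates; using the outermost pair.",
                 length(peaks)))
  }
  t_front <- time_s[peaks[1]]
  t_back <- time_s[peaks[length(peaks)]]

  span <- t_back - t_front
  w_start <- t_front + guard_fraction * span
  w_end <- t_back - guard_fraction * span
  inside <- time_s > w_start & time_s < w_end
  n_in <- sum(inside)
  if (n_in < min_interior_samples) {
    abort(sprintf("Only %d interior samples (need >= %d).", n_in,
                  min_interior_samples))
  }

  out <- tibble(
    sensor_id = if ("sensor_id" %in% names(trace)) trace$sensor_id[1] else NA_character_,
    front_spike_time_s = t_front,
    back_spike_time_s = t_back,
    interior_start_s = w_start,
    interior_end_s = w_end,
    integrated_signal_au = mean(v[inside]),
    n_interior_samples = n_in
  )
  class(out) <- c("dv_event", class(out))
  out
}

#' Passage time between the two sensors
#'
#' Leading-edge convention: the difference of the front-spike times of the
#' same transit seen at sensors A and B. Front-to-front timing is insensitive
#' to droplet-length changes.
#'
#' @param event_a,event_b [detect_event()] results for sensors A and B.
#' @return Passage time, s.
#' @export
passage_time_between <- function(event_a, event_b) {
  dt <- event_b$front_spike_time_s - event_a$front_spike_time_s
  if (dt <= 0) {
    abort("Sensor-order error: sensor B's event does not follow sensor A's.")
  }
  dt
}

#' Along-droplet scan profile
#'
#' Partitions the interior window of an event into equal time bins and maps
#' the time fraction of the spike-to-spike interval to the axial position
#' `s` under the constant-speed assumption; `s = 0` is the droplet front.
#'
#' @param trace The voltage trace the event was detected in.
#' @param event A [detect_event()] result.
#' @param n_bins Number of bins (>= 1; 5 or more for a useful profile).
#' @return A tibble with one row per bin: `s` (bin centre) and `voltage_au`
#'   (mean voltage in the bin).
#' @export
scan_profile <- function(trace, event, n_bins = 20) {
  if (n_bins < 1) abort("`n_bins` must be at least 1.")
  inside <- trace$time_s > event$interior_start_s &
    trace$time_s < event$interior_end_s
  if (sum(inside) < n_bins) {
    abort("Fewer interior samples than bins.")
  }
  span <- event$back_spike_time_s - event$front_spike_time_s
  tibble(
    time_s = trace$time_s[inside],
    voltage_au = trace$voltage_au[inside]
  ) |>
    dplyr::mutate(
      bin = pmin(n_bins, 1 + floor(
        n_bins * (.data$time_s - event$interior_start_s) /
          (event$interior_end_s - event$interior_start_s)
      ))
    ) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      s = (mean(.data$time_s) - event$front_spike_time_s) / span,
      voltage_au = mean(.data$voltage_au),
      .groups = "drop"
    ) |>
    dplyr::select("s", "voltage_au")
}
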