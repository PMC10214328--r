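#' Define a mobility scenario
#'
#' A scenario bundles the behavioural parameters of the synthetic mobility
#' model: each device, each day, makes one inter-zone round trip
#' (home -> destination -> home) with probability `p_move * intensity(date)`,
#' the destination drawn with probability proportional to
#' `population_j / max(dist(home, j), 1)^gravity_gamma` over zones `j != home`.
#' Devices that do not travel emit all their pings at their home zone.
#'
#' @param start,end inclusive calendar date range of the simulation.
#' @param p_move per-device daily probability of an inter-zone trip, in
#'   \[0, 1\]. Default 0.25: roughly a quarter of observed devices leaving
#'   their home municipality on a given day.
#' @param gravity_gamma distance-decay exponent (>= 0) of the gravity kernel;
#'   default 1, a decay in the low range of empirical intercity gravity fits,
#'   which reproduces the qualitative mesoscale structure of national travel
#'   networks (a dominant community spanning about half the localities plus
#'   smaller regional ones). Larger values confine travel to nearby zones and
#'   sharpen state-block structure.
#' @param pings_per_device_day pings emitted per device per day (default 4,
#'   enough to resolve the full round trip).
#' @param intensity named numeric vector mapping ISO dates to multipliers in
#'   \[0, 1\] applied to `p_move`; dates not listed default to 1. This is the
#'   lockdown dial: dropping the multiplier emulates a mobility restriction.
#' @param seed master integer seed; per-day seeds are derived from it with
#'   [derive_seed()] so any day can be regenerated independently.
#' @param tz_offset fixed UTC offset (hours) defining the day boundary;
#'   default -6 (central Mexico).
#' @return an object of class `mobility_scenario`.
#' @export
mobility_scenario <- function(start, end, p_move = 0.25, gravity_gamma = 1,
                              pings_per_device_day = 4L, intensity = NULL,
                              seed = 1L, tz_offset = -6) {
  start <- as_date1(start)
  end <- as_date1(end)
  if (end < start) abort("empty date range: end %s before start %s", end, start)
  if (p_move < 0 || p_move > 1) abort("p_move must be in [0, 1]")
  if (gravity_gamma < 0) abort("gravity_gamma must be >= 0")
  if (pings_per_device_day < 1) abort("pings_per_device_day must be >= 1")
  if (!is.null(intensity)) {
    if (is.null(names(intensity)) || any(is.na(as.Date(names(intensity))))) {
      abort("intensity must be a named numeric vector with ISO dates as names")
    }
    if (any(intensity < 0 | intensity > 1)) abort("intensity multipliers must be in [0, 1]")
  }
  structure(
    list(start = start, end = end, p_move = p_move,
         gravity_gamma = gravity_gamma,
         pings_per_device_day = as.integer(pings_per_device_day),
         intensity = intensity, seed = as.integer(seed), tz_offset = tz_offset),
    class = "mobility_scenario"
  )
}

#' @export
print.mobility_scenario <- function(x, ...) {
  cat(sprintf("Mobility scenario: %s .. %s (%d days)\n", x$start, x$end,
              as.integer(x$end - x$start) + 1L))
  cat(sprintf("  p_move=%.3g  gamma=%.3g  pings/device/day=%d  seed=%d\n",
              x$p_move, x$gravity_gamma, x$pings_per_device_day, x$seed))
  if (!is.null(x$intensity)) {
    cat(sprintf("  intensity overrides on %d day(s)\n", length(x$intensity)))
  }
  invisible(x)
}

#' Intensity multiplier in force on a date
#'
#' @param scenario a [mobility_scenario()].
#' @param date a date.
#' @return the multiplier in \[0, 1\]; 1 when the date has no override.
#' @export
intensity_at <- function(scenario, date) {
  if (is.null(scenario$intensity)) return(1)
  m <- scenario$intensity[as.character(as_date1(date))]
  if (is.na(m)) 1 else unname(m)
}

#' Read an intensity file
#'
#' CSV with columns `date,multiplier`; returns the named vector form used by
#' [mobility_scenario()].
#' @param path CSV path.
#' @export
read_intensity <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d$multiplier), as.character(as.Date(d$date)))
}

#' Assign home zones to a device panel
#'
#' Homes are sampled with probability proportional to zone population, so the
#' synthetic panel mirrors the population distribution of the registry.
#'
#' @param registry a zone registry.
#' @param n_devices number of devices (>= 1).
#' @param seed integer seed.
#' @return `data.frame` with columns `device_id`, `home_zone`.
#' @export
generate_device_panel <- function(registry, n_devices, seed = 1L) {
  validate_zone_registry(registry)
  if (nrow(registry) == 0) abort("empty registry")
  if (n_devices < 1) abort("n_devices must be >= 1")
  with_seed(seed, {
    homes <- sample(registry$zone_id, n_devices, replace = TRUE,
                    prob = registry$population)
    data.frame(device_id = sprintf("D%06d", seq_len(n_devices)),
               home_zone = homes, stringsAsFactors = FALSE)
  })
}

# Destination-choice probabilities from one home zone under the gravity kernel.
# Distance floored at 1 so coincident centroids cannot blow up the kernel.
gravity_probs <- function(registry, home_idx, gamma) {
  dx <- registry$x - registry$x[home_idx]
  dy <- registry$y - registry$y[home_idx]
  dist <- pmax(sqrt(dx^2 + dy^2), 1)
  p <- registry$population / dist^gamma
  p[home_idx] <- 0
  p
}

# Split k pings into home/destination/home segments for a round trip.
# k >= 3 resolves the full trip; k = 2 yields the outbound leg only; k = 1
# leaves the device at home.
trip_segments <- function(k) {
  if (k < 2) return(c(h1 = k, d = 0L, h2 = 0L))
  d <- max(1L, ceiling(k / 3))
  h1 <- max(1L, ceiling((k - d) / 2))
  h2 <- k - h1 - d
  c(h1 = h1, d = d, h2 = h2)
}

#' Simulate one day of pings
#'
#' Every device emits `pings_per_device_day` pings at random times inside the
#' calendar day (under the scenario's UTC offset). With probability
#' `p_move * intensity(date)` the device makes one round trip: its pings are
#' split chronologically into home, destination and home segments; otherwise
#' all pings sit at the home zone. With a single-zone registry there is no
#' possible destination and all pings stay home regardless of `p_move`.
#'
#' @param panel device panel from [generate_device_panel()].
#' @param registry zone registry.
#' @param date calendar date inside the scenario range.
#' @param scenario a [mobility_scenario()].
#' @param seed optional override; by default the day seed is derived from
#'   `scenario$seed` and the date.
#' @return `data.frame` of pings: `device_id`, `timestamp` (POSIXct, UTC),
#'   `zone_id`, ordered by timestamp.
#' @export
simulate_day <- function(panel, registry, date, scenario, seed = NULL) {
  date <- as_date1(date)
  if (date < scenario$start || date > scenario$end) {
    abort("date %s outside scenario range %s..%s", date, scenario$start, scenario$end)
  }
  validate_zone_registry(registry)
  seed <- seed %||% derive_seed(scenario$seed, date)
  n <- nrow(panel)
  k <- scenario$pings_per_device_day
  p <- scenario$p_move * intensity_at(scenario, date)
  zone_index <- stats::setNames(seq_len(nrow(registry)), registry$zone_id)
  if (anyNA(zone_index[panel$home_zone])) abort("panel home zone not in registry")

  with_seed(seed, {
    moves <- runif(n) < p
    if (nrow(registry) < 2) moves[] <- FALSE  # no destination exists
    dest <- rep(NA_character_, n)
    if (any(moves)) {
      mov_idx <- which(moves)
      homes <- panel$home_zone[mov_idx]
      for (hz in unique(homes)) {
        sel <- mov_idx[homes == hz]
        pr <- gravity_probs(registry, zone_index[[hz]], scenario$gravity_gamma)
        dest[sel] <- sample(registry$zone_id, length(sel), replace = TRUE, prob = pr)
      }
    }
    # k sorted times per device within the local day
    secs <- matrix(runif(n * k, 0, 86400), nrow = n)
    if (k > 1) secs <- t(apply(secs, 1, sort))
    day_start <- as.POSIXct(as.character(date), tz = "UTC") - scenario$tz_offset * 3600
    zones <- matrix(rep(panel$home_zone, k), nrow = n)
    seg <- trip_segments(k)
    if (seg["d"] > 0 && any(moves)) {
      dcols <- seq.int(seg[["h1"]] + 1L, seg[["h1"]] + seg[["d"]])
      zones[moves, dcols] <- dest[moves]
    }
    out <- data.table(
      device_id = rep(panel$device_id, times = k),
      timestamp = day_start + as.vector(secs),
      zone_id = as.vector(zones)
    )
    setorder(out, timestamp, device_id)
    setDF(out)
    out
  })
}

#' Simulate a period of daily ping tables
#'
#' One ping table per calendar day, both endpoints included. Each day uses a
#' seed derived from the scenario seed and the date, so reruns (and single-day
#' regenerations) are reproducible.
#'
#' @inheritParams simulate_day
#' @return named list (ISO date -> ping `data.frame`).
#' @export
simulate_period <- function(panel, registry, scenario) {
  dates <- seq(scenario$start, scenario$end, by = "day")
  out <- lapply(dates, function(d) simulate_day(panel, registry, d, scenario))
  names(out) <- as.character(dates)
  out
}
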