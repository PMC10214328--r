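#' Generate a synthetic zone registry
#'
#' Creates a registry of municipality-like zones laid out on a planar grid,
#' partitioned into contiguous state blocks, with a subset of zones grouped
#' into metropolitan zones (each spanning at least two municipalities) and
#' populations drawn from a heavy-tailed log-normal law.
#'
#' Zones are placed on a near-square grid with a small positional jitter and
#' ordered column-major, so consecutive index ranges are spatially contiguous;
#' states are consecutive blocks of that ordering. Metropolitan zones pair a
#' zone with its immediate grid neighbour inside the same state, mirroring
#' conurbations that straddle municipal boundaries.
#'
#' @param n_zones number of municipalities (>= 1).
#' @param n_states number of states; `n_zones >= n_states >= 1`.
#' @param n_metros number of metropolitan zones; requires `2 * n_metros <= n_zones`.
#' @param pop_meanlog,pop_sdlog log-normal population parameters. The defaults
#'   (`meanlog = log(2e4)`, `sdlog = 1.5`) give a median population of 20,000
#'   with a heavy upper tail, the shape typical of national municipality
#'   population registers.
#' @param seed integer seed; the registry is a pure function of the arguments.
#' @return a `data.frame` with columns `zone_id`, `name`, `state_id`,
#'   `metro_id` (`NA` for non-metro zones), `population`, `x`, `y`.
#' @examples
#' reg <- generate_zone_registry(20, n_states = 2, n_metros = 2, seed = 1)
#' table(reg$state_id)
#' @export
generate_zone_registry <- function(n_zones, n_states, n_metros = 0,
                                   pop_meanlog = log(2e4), pop_sdlog = 1.5,
                                   seed = 1L) {
  if (n_zones < 1 || n_states < 1 || n_zones < n_states) {
    abort("need n_zones >= n_states >= 1 (got n_zones=%d, n_states=%d)", n_zones, n_states)
  }
  if (n_metros < 0 || 2 * n_metros > n_zones) {
    abort("need 2 * n_metros <= n_zones (got n_metros=%d, n_zones=%d)", n_metros, n_zones)
  }
  with_seed(seed, {
    # states sit on their own coarse grid; each state's zones form a compact
    # sub-grid inside the state cell, so intra-state distances are short and
    # inter-state distances longer — the block structure that makes
    # state-aligned communities recoverable downstream
    sizes <- rep(n_zones %/% n_states, n_states)
    extra <- n_zones %% n_states
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    state_of <- rep(seq_len(n_states), times = sizes)
    state_cols <- ceiling(sqrt(n_states))
    side <- ceiling(sqrt(max(sizes)))
    pitch <- side * 10 * 2  # gap between neighbouring state blocks
    local_idx <- unlist(lapply(sizes, seq_len)) - 1L
    sgx <- (state_of - 1L) %% state_cols
    sgy <- (state_of - 1L) %/% state_cols
    x <- sgx * pitch + (local_idx %/% side) * 10 + runif(n_zones, -1, 1)
    y <- sgy * pitch + (local_idx %% side) * 10 + runif(n_zones, -1, 1)

    population <- pmax(1L, as.integer(ceiling(rlnorm(n_zones, pop_meanlog, pop_sdlog))))
    zone_id <- sprintf("Z%04d", seq_len(n_zones))
    metro_id <- rep(NA_character_, n_zones)
    if (n_metros > 0) {
      # pair each metro seat with the next zone in the same state block
      free <- seq_len(n_zones)
      m <- 0L
      for (i in seq_len(n_zones - 1L)) {
        if (m == n_metros) break
        if (is.na(metro_id[i]) && is.na(metro_id[i + 1L]) &&
            state_of[i] == state_of[i + 1L]) {
          m <- m + 1L
          metro_id[c(i, i + 1L)] <- sprintf("M%03d", m)
        }
      }
      if (m < n_metros) {
        abort("could not place %d metro zones within state blocks", n_metros)
      }
    }
    reg <- data.frame(
      zone_id = zone_id,
      name = sprintf("Municipality %d", seq_len(n_zones)),
      state_id = sprintf("S%02d", state_of),
      metro_id = metro_id,
      population = population,
      x = x,
      y = y,
      stringsAsFactors = FALSE
    )
    validate_zone_registry(reg)
    reg
  })
}

#' Validate a zone registry
#'
#' Checks the registry invariants: unique zone ids, positive integer
#' populations, coordinates present, and every metropolitan zone grouping at
#' least two municipalities.
#'
#' @param registry a zone-registry `data.frame`.
#' @return the registry, invisibly, if valid; otherwise an error.
#' @export
validate_zone_registry <- function(registry) {
  needed <- c("zone_id", "name", "state_id", "metro_id", "population", "x", "y")
  missing <- setdiff(needed, names(registry))
  if (length(missing)) abort("registry missing columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(registry$zone_id)) abort("zone_id values must be unique")
  if (any(registry$population < 1)) abort("populations must be >= 1")
  metros <- registry$metro_id[!is.na(registry$metro_id)]
  if (length(metros)) {
    sz <- table(metros)
    bad <- names(sz)[sz < 2]
    if (length(bad)) {
      abort("metropolitan zone(s) with fewer than 2 member municipalities: %s",
            paste(bad, collapse = ", "))
    }
  }
  invisible(registry)
}

#' Read / write a zone registry as CSV
#'
#' Plain CSV with columns `zone_id,name,state_id,metro_id,population,x,y`;
#' an empty `metro_id` field means the zone is not part of a metropolitan zone.
#'
#' @param registry a zone registry.
#' @param path file path.
#' @return `read_zone_registry` returns the registry `data.frame`.
#' @export
write_zone_registry <- function(registry, path) {
  validate_zone_registry(registry)
  out <- registry
  out$metro_id[is.na(out$metro_id)] <- ""
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_zone_registry
#' @export
read_zone_registry <- function(path) {
  reg <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(zone_id = "character", name = "character",
                                 state_id = "character", metro_id = "character"))
  reg$metro_id[!is.na(reg$metro_id) & reg$metro_id == ""] <- NA_character_
  validate_zone_registry(reg)
  reg
}
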