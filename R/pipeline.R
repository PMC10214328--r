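# End-to-end orchestration: simulate (or load) -> build -> analyze over a
# date range, from a single config, with a reproducible output manifest.

#' Key pandemic event dates
#'
#' Nine representative dates spanning 2020-2021 pandemic events in Mexico
#' (first reported case, start of national lockdowns, the epidemiological
#' stoplight program, contagion-wave peaks and the local minima between
#' them), used as the default reporting dates.
#'
#' @return `data.frame` with columns `date`, `event`.
#' @export
event_dates <- function() {
  data.frame(
    date = as.Date(c("2020-02-24", "2020-03-23", "2020-06-01", "2020-07-30",
                     "2020-09-21", "2021-01-19", "2021-05-24", "2021-08-16",
                     "2021-12-27")),
    event = c("First reported COVID-19 case",
              "Beginning of official lockdowns",
              "Beginning of Epidemiological Stoplight Program",
              "First national peak of daily contagions",
              "Local minimum between first and second wave",
              "Second national peak of daily contagions",
              "Local minimum between second and third wave",
              "Third national peak of daily contagions",
              "Local minimum just before fourth wave"),
    stringsAsFactors = FALSE
  )
}

#' Per-date summary report over a collection
#'
#' For each requested date, computes the global, distributional and mesoscale
#' summary of that day's network: total weight S_G, node and edge counts,
#' excess kurtosis of log strengths, Beta Rank Function exponents of the
#' strength distribution, and community statistics from a seeded
#' label-propagation run.
#'
#' @param collection named, date-sorted list of networks.
#' @param dates dates to report (must all be present in the collection).
#' @param registry zone registry (for interstate community statistics).
#' @param seed master seed for the community-detection substream.
#' @return `data.frame`, one row per date: `date`, `s_g`, `n_nodes`,
#'   `n_edges`, `g2`, `brf_a`, `brf_b`, `n_communities`, `giant_fraction`,
#'   `interstate_fraction`.
#' @export
imtn_report <- function(collection, dates, registry, seed = 1L) {
  dates <- as.Date(dates)
  missing <- setdiff(as.character(dates), names(collection))
  if (length(missing)) {
    abort("date(s) not in collection: %s", paste(missing, collapse = ", "))
  }
  rows <- lapply(as.character(dates), function(d) {
    net <- collection[[d]]
    diag <- log_strength_normality(net)
    brf_a <- brf_b <- NA_real_
    s <- centrality(net, "strength", "total")
    pos <- s[s > 0]
    if (length(pos) >= 3) {
      brf <- fit_beta_rank(pos)
      brf_a <- brf$a
      brf_b <- brf$b
    }
    if (length(net$nodes)) {
      part <- label_propagation(net, seed = derive_seed(seed, net$date))
      ps <- partition_stats(part, registry)
    } else {
      ps <- list(n_communities = 0L, giant_fraction = NA_real_,
                 interstate_fraction = NA_real_)
    }
    data.frame(date = net$date, s_g = total_weight(net),
               n_nodes = length(net$nodes), n_edges = nrow(net$edges),
               g2 = diag$g2, brf_a = brf_a, brf_b = brf_b,
               n_communities = ps$n_communities,
               giant_fraction = ps$giant_fraction,
               interstate_fraction = ps$interstate_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate (or load) -> build -> feature / distribution / community
#' analysis and writes every stage output plus a manifest with the seeds,
#' parameters and MD5 checksums of all written files, so identical configs
#' yield identical manifests.
#'
#' The config is a named list (or path to a YAML file) with fields:
#' * `mode`: `"synthetic"` (default), `"ping-dir"` or `"network-dir"`;
#' * `start`, `end`: date range;
#' * `out_dir`: output directory;
#' * `seed`: master seed — stage substreams (registry, panel, per-day
#'   simulation, per-day community detection) are derived from it;
#' * synthetic mode: `n_zones`, `n_states`, `n_metros`, `n_devices`,
#'   `p_move`, `gravity_gamma`, `pings_per_device_day`, optional
#'   `intensity` (named multipliers) or `intensity_file` (CSV
#'   `date,multiplier`);
#' * `ping_dir` / `network_dir` and `registry_file` for the load modes;
#' * `report_dates` (default: the [event_dates()] that fall in range),
#'   `top_n` (default `c(10, 50, 100)` clipped to the node count),
#'   `ma_window` (default 30).
#'
#' @param config named list or YAML file path.
#' @return invisibly, a list with `collection`, `registry`, `report`,
#'   `manifest`.
#' @export
imtn_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% "synthetic"
  out_dir <- config$out_dir %||% abort("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[imtn] %-12s %s", stage, sprintf(...)))
  }

  if (mode == "synthetic") {
    start <- as_date1(config$start); end <- as_date1(config$end)
    intensity <- config$intensity
    if (!is.null(config$intensity_file)) intensity <- read_intensity(config$intensity_file)
    if (!is.null(intensity)) intensity <- unlist(intensity)
    scenario <- mobility_scenario(
      start, end,
      p_move = config$p_move %||% 0.25,
      gravity_gamma = config$gravity_gamma %||% 1,
      pings_per_device_day = config$pings_per_device_day %||% 4L,
      intensity = intensity,
      seed = derive_seed(seed, 1001L)
    )
    registry <- generate_zone_registry(
      config$n_zones %||% 60L, config$n_states %||% 6L,
      config$n_metros %||% 4L, seed = derive_seed(seed, 1002L)
    )
    panel <- generate_device_panel(registry, config$n_devices %||% 1000L,
                                   seed = derive_seed(seed, 1003L))
    write_zone_registry(registry, file.path(out_dir, "registry.csv"))
    dates <- seq(start, end, by = "day")
    log_stage("simulate", "%d days, %d devices, %d zones", length(dates),
              nrow(panel), nrow(registry))
    collection <- lapply(dates, function(d) {
      pings <- simulate_day(panel, registry, d, scenario)
      build_daily_network(pings, registry, d, tz_offset = scenario$tz_offset)
    })
    names(collection) <- as.character(dates)
  } else if (mode == "ping-dir") {
    registry <- read_zone_registry(config$registry_file)
    files <- sort(list.files(config$ping_dir,
                             pattern = "^pings_\\d{4}-\\d{2}-\\d{2}\\.csv$",
                             full.names = TRUE))
    if (!length(files)) abort("no ping files under '%s'", config$ping_dir)
    collection <- lapply(files, function(f) {
      d <- as.Date(sub("^pings_(.*)\\.csv$", "\\1", basename(f)))
      build_daily_network(read_pings(f), registry, d,
                          tz_offset = config$tz_offset %||% -6)
    })
    names(collection) <- vapply(collection, function(n) as.character(n$date),
                                character(1))
  } else if (mode == "network-dir") {
    registry <- read_zone_registry(config$registry_file)
    collection <- read_collection(config$network_dir)
  } else {
    abort("unknown mode '%s'", mode)
  }

  log_stage("build", "%d daily networks", length(collection))
  write_collection(collection, file.path(out_dir, "networks"))

  ws <- weight_sum_series(collection, window = config$ma_window %||% 30L)
  write.csv(ws, file.path(out_dir, "weight_sum.csv"), row.names = FALSE)

  measures <- config$measures %||% c("degree", "strength", "betweenness")
  summaries <- lapply(measures, function(m) {
    cs <- centrality_series(collection, m, "total")
    cbind(measure = m, direction = "total", cs$summary)
  })
  cent_summary <- do.call(rbind, summaries)
  write.csv(cent_summary, file.path(out_dir, "centrality_summary.csv"),
            row.names = FALSE)
  log_stage("features", "centrality summaries for %s",
            paste(measures, collapse = ", "))

  strength_series <- centrality_series(collection, "strength", "total")
  n_nodes_total <- ncol(strength_series$values)
  top_ns <- (config$top_n %||% c(10L, 50L, 100L))
  top_ns <- unique(pmin(as.integer(top_ns), n_nodes_total))
  turnover <- do.call(rbind, lapply(top_ns, function(N) {
    cbind(top_n = N, rank_turnover(strength_series, N))
  }))
  write.csv(turnover, file.path(out_dir, "turnover.csv"), row.names = FALSE)

  diagnostics <- distribution_diagnostics(collection)
  write.csv(diagnostics, file.path(out_dir, "distribution_diagnostics.csv"),
            row.names = FALSE)

  report_dates <- as.Date(config$report_dates %||%
                            event_dates()$date[event_dates()$date %in%
                                                 as.Date(names(collection))])
  if (!length(report_dates)) {
    report_dates <- as.Date(names(collection)[[1]])
  }
  report <- imtn_report(collection, report_dates, registry, seed = seed)
  write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  log_stage("report", "%d report date(s)", nrow(report))

  # community partitions and flows along the report dates
  parts <- lapply(as.character(report_dates), function(d) {
    label_propagation(collection[[d]], seed = derive_seed(seed, as.Date(d)))
  })
  names(parts) <- as.character(report_dates)
  part_csv <- do.call(rbind, lapply(parts, function(p) {
    if (!length(p$membership)) return(NULL)
    data.frame(date = p$date, node = names(p$membership),
               community = unname(p$membership))
  }))
  if (!is.null(part_csv)) {
    write.csv(part_csv, file.path(out_dir, "communities.csv"), row.names = FALSE)
  }
  if (length(parts) >= 2) {
    flows <- do.call(rbind, lapply(seq_len(length(parts) - 1L), function(i) {
      fl <- community_flows(parts[[i]], parts[[i + 1L]])$flows
      if (!nrow(fl)) return(NULL)
      cbind(date_from = names(parts)[i], date_to = names(parts)[i + 1L], fl)
    }))
    if (!is.null(flows)) {
      write.csv(flows, file.path(out_dir, "community_flows.csv"),
                row.names = FALSE)
    }
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  checksums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "imtn",
    version = as.character(utils::packageVersion("imtn")),
    igraph = as.character(utils::packageVersion("igraph")),
    mode = mode,
    seed = seed,
    parameters = config[setdiff(names(config), "out_dir")],
    n_networks = length(collection),
    checksums = as.list(stats::setNames(unname(checksums), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done", "outputs under %s", out_dir)
  invisible(list(collection = collection, registry = registry,
                 report = report, manifest = manifest))
}
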