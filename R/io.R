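# Readers and writers for the plain-text interchange formats: ping tables,
# daily edge lists, and network collections (one edge-list CSV per day).

#' Write / read a ping table
#'
#' CSV with columns `device_id`, `timestamp` (ISO-8601, UTC), `zone_id`.
#' With `format = "parquet"` (requires the arrow package) an equivalent
#' columnar binary file is written instead.
#'
#' @param pings ping `data.frame`.
#' @param path output path.
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `read_pings` returns the ping `data.frame` with POSIXct timestamps.
#' @export
write_pings <- function(pings, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the arrow package is required for parquet output")
    }
    arrow::write_parquet(pings, path)
  } else {
    out <- data.frame(
      device_id = pings$device_id,
      timestamp = format(pings$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
      zone_id = pings$zone_id,
      stringsAsFactors = FALSE
    )
    data.table::fwrite(out, path)
  }
  invisible(path)
}

#' @rdname write_pings
#' @export
read_pings <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the arrow package is required for parquet input")
    }
    d <- as.data.frame(arrow::read_parquet(path))
  } else {
    d <- as.data.frame(data.table::fread(path, colClasses = list(
      character = c("device_id", "timestamp", "zone_id"))))
    d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                              tz = "UTC")
  }
  d
}

#' Write / read one daily network as an edge-list CSV
#'
#' Columns `date,source,target,weight,movers,panel_size`; weights are written
#' with 12 significant digits. The edge-list format cannot represent isolated
#' nodes; on reading, the node set is the set of edge endpoints.
#'
#' @param network an [imtn_network()].
#' @param path file path.
#' @return `read_network` returns an [imtn_network()].
#' @export
write_network <- function(network, path) {
  e <- network$edges
  out <- data.frame(
    date = rep(as.character(network$date), nrow(e)),
    source = e$source, target = e$target,
    weight = formatC(e$weight, digits = 12, format = "g"),
    movers = e$movers,
    panel_size = rep(network$panel_size, nrow(e)),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  d <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("date", "source", "target"))))
  if (nrow(d) == 0) {
    abort("network file '%s' has no edges; the date cannot be recovered", path)
  }
  date <- as_date1(d$date[[1]])
  panel <- as.integer(d$panel_size[[1]])
  # recompute the exact weight from the integer counts; the text form is a
  # 12-digit decimal approximation
  edges <- data.frame(source = d$source, target = d$target,
                      weight = d$movers / panel, movers = as.integer(d$movers),
                      stringsAsFactors = FALSE)
  imtn_network(date, sort(unique(c(edges$source, edges$target))), edges, panel)
}

#' Write / read a network collection
#'
#' One edge-list CSV per day (`net_YYYY-MM-DD.csv`) in a directory. Days with
#' no edges are written as a header-only file and read back as empty networks.
#'
#' @param collection named list of [imtn_network()] (names: ISO dates).
#' @param dir directory path (created if needed).
#' @return `read_collection` returns the named, date-sorted list.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (net in collection) {
    write_network(net, file.path(dir, sprintf("net_%s.csv", net$date)))
  }
  invisible(dir)
}

#' @rdname write_collection
#' @export
read_collection <- function(dir) {
  files <- sort(list.files(dir, pattern = "^net_\\d{4}-\\d{2}-\\d{2}\\.csv$",
                           full.names = TRUE))
  if (!length(files)) abort("no network files found under '%s'", dir)
  nets <- lapply(files, function(f) {
    date <- as.Date(sub("^net_(.*)\\.csv$", "\\1", basename(f)))
    d <- as.data.frame(data.table::fread(f))
    if (nrow(d) == 0) {
      imtn_network(date, character(),
                   data.frame(source = character(), target = character(),
                              weight = numeric(), movers = integer()), 0L)
    } else {
      read_network(f)
    }
  })
  names(nets) <- vapply(nets, function(n) as.character(n$date), character(1))
  nets[order(names(nets))]
}

#' Export a daily network as GraphML
#'
#' Vertices carry `state` and `population` attributes when a registry is
#' supplied; edges carry `weight` and `movers`.
#'
#' @param network an [imtn_network()].
#' @param path output path.
#' @param registry optional zone registry for node attributes.
#' @export
export_graphml <- function(network, path, registry = NULL) {
  igraph::write_graph(as_igraph(network, registry), path, format = "graphml")
  invisible(path)
}
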