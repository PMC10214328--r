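#' Daily travel network constructor
#'
#' Container for one day's intermunicipal travel network: a directed weighted
#' graph whose nodes are municipalities or metropolitan zones and whose edge
#' weight is the fraction of the day's device panel observed to move between
#' the two endpoints,
#' \deqn{W_{ij} = |D_{ij}| / |D|,}
#' where \eqn{|D_{ij}|} is the number of unique devices whose consecutive
#' pings took them from node i to node j and \eqn{|D|} the number of unique
#' devices observed that day. Weights lie in (0, 1]: 1 would mean every
#' observed device in the country made that trip; an edge is absent when no
#' device made the trip.
#'
#' @param date calendar date.
#' @param nodes character vector of node ids present that day (including
#'   isolated nodes that were observed but did not travel).
#' @param edges `data.frame` with columns `source`, `target`, `weight`,
#'   `movers`; no self-loops.
#' @param panel_size `|D|`, the day's unique device count.
#' @return an object of class `imtn_network`.
#' @export
imtn_network <- function(date, nodes, edges, panel_size) {
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) abort("self-loop edges are not allowed")
    if (any(edges$weight <= 0 | edges$weight > 1)) abort("weights must be in (0, 1]")
    if (!all(c(edges$source, edges$target) %in% nodes)) {
      abort("every edge endpoint must be a node")
    }
    if (panel_size < 1) abort("panel_size must be >= 1 when edges are present")
    if (any(abs(edges$weight * panel_size - edges$movers) > 1e-9)) {
      abort("weight * panel_size must equal the mover count exactly")
    }
  }
  structure(
    list(date = as_date1(date), nodes = as.character(nodes), edges = edges,
         panel_size = as.integer(panel_size)),
    class = "imtn_network"
  )
}

#' @export
print.imtn_network <- function(x, ...) {
  cat(sprintf("Intermunicipal travel network  %s\n", x$date))
  cat(sprintf("  %d nodes, %d edges, panel size |D| = %d, S_G = %.6g\n",
              length(x$nodes), nrow(x$edges), x$panel_size, total_weight(x)))
  invisible(x)
}

#' Resolve a zone to its network node
#'
#' Municipalities belonging to a metropolitan zone are aggregated into a
#' single node (the metro id); all other municipalities map to themselves.
#' Vectorized over `zone_id`.
#'
#' @param zone_id character vector of zone ids.
#' @param registry zone registry.
#' @return character vector of node ids.
#' @export
resolve_node <- function(zone_id, registry) {
  i <- match(zone_id, registry$zone_id)
  if (anyNA(i)) {
    abort("unknown zone id(s): %s",
          paste(unique(zone_id[is.na(i)]), collapse = ", "))
  }
  m <- registry$metro_id[i]
  ifelse(is.na(m), registry$zone_id[i], m)
}

# Calendar date of each ping under a fixed UTC offset (hours).
ping_date <- function(timestamp, tz_offset = -6) {
  as.Date(floor((as.numeric(timestamp) + tz_offset * 3600) / 86400),
          origin = "1970-01-01")
}

#' Extract directed transitions from one device's pings
#'
#' Pings are sorted by timestamp (ties broken by zone id for determinism) and
#' resolved to nodes; every consecutive pair with distinct nodes emits one
#' directed transition, in order of occurrence. Consecutive pings at the same
#' node (including two municipalities of the same metropolitan zone) emit
#' nothing.
#'
#' @param device_pings pings of a single device for a single day
#'   (`device_id`, `timestamp`, `zone_id`).
#' @param registry zone registry.
#' @return `data.frame` with columns `source`, `target` (possibly 0 rows).
#' @export
extract_transitions <- function(device_pings, registry) {
  if (NROW(device_pings) == 0) {
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(unique(device_pings$device_id)) > 1) {
    abort("extract_transitions expects pings from a single device")
  }
  o <- order(device_pings$timestamp, device_pings$zone_id)
  nodes <- resolve_node(device_pings$zone_id[o], registry)
  n <- length(nodes)
  if (n < 2) {
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  keep <- nodes[-n] != nodes[-1]
  data.frame(source = nodes[-n][keep], target = nodes[-1][keep],
             stringsAsFactors = FALSE)
}

#' Build the daily travel network from a day's ping table
#'
#' Implements the device-normalized construction: the panel `|D|` is the
#' number of unique device ids in the table (movers and non-movers alike — it
#' is the denominator that makes weights comparable across days);
#' `|D_ij|` counts unique devices with at least one i -> j transition that
#' day (a device contributes at most once per directed pair, but may
#' contribute to several pairs); `W_ij = |D_ij| / |D|`. Nodes observed in at
#' least one ping are retained even when isolated, so daily centrality series
#' are defined for every observed locality.
#'
#' @param ping_table pings for one calendar day (`device_id`, `timestamp`,
#'   `zone_id`).
#' @param registry zone registry.
#' @param date the day being built; all pings must fall on it under
#'   `tz_offset`.
#' @param tz_offset fixed UTC offset (hours) of the day boundary; default -6.
#' @param check_date set `FALSE` to skip the per-ping date check (useful when
#'   the caller has already grouped pings by day).
#' @return an [imtn_network()].
#' @export
build_daily_network <- function(ping_table, registry, date,
                                tz_offset = -6, check_date = TRUE) {
  date <- as_date1(date)
  if (NROW(ping_table) == 0) {
    return(imtn_network(date, character(),
                        data.frame(source = character(), target = character(),
                                   weight = numeric(), movers = integer()),
                        panel_size = 0L))
  }
  dt <- as.data.table(ping_table)
  if (check_date && !all(ping_date(dt$timestamp, tz_offset) == date)) {
    abort("ping_table contains pings outside %s (tz offset %+d h)", date, tz_offset)
  }
  dt[, node := resolve_node(zone_id, registry)]
  setorder(dt, device_id, timestamp, zone_id)
  dt[, nxt := shift(node, -1L), by = device_id]
  trans <- unique(dt[!is.na(nxt) & node != nxt,
                     .(device_id, source = node, target = nxt)])
  panel <- uniqueN(dt$device_id)
  edges <- trans[, .(movers = .N), by = .(source, target)]
  edges[, weight := movers / panel]
  setorder(edges, source, target)
  nodes <- sort(unique(c(dt$node, edges$source, edges$target)))
  imtn_network(date, nodes,
               as.data.frame(edges[, .(source, target, weight, movers)]),
               panel_size = panel)
}

#' Keep only the highest-weight edges
#'
#' Retains exactly `ceiling(fraction * |E|)` edges of highest weight; ties are
#' broken deterministically by (weight descending, source id, target id).
#' Mover counts and the panel size are preserved, as is the node set (nodes
#' whose edges are all filtered out become isolated).
#'
#' @param network an [imtn_network()].
#' @param fraction fraction of edges to keep, in (0, 1].
#' @return an [imtn_network()] with the filtered edge set.
#' @export
filter_top_edges <- function(network, fraction) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  e <- network$edges
  if (nrow(e) == 0) return(network)
  keep <- ceiling(fraction * nrow(e))
  o <- order(-e$weight, e$source, e$target)
  sel <- sort(o[seq_len(keep)])
  imtn_network(network$date, network$nodes, e[sel, , drop = FALSE],
               network$panel_size)
}

#' Convert a daily network to an igraph object
#'
#' @param network an [imtn_network()].
#' @param registry optional registry used to attach `state` and `population`
#'   vertex attributes (metro nodes get the summed member population and the
#'   state of their most populous member).
#' @return a directed weighted `igraph` graph including isolated nodes.
#' @export
as_igraph <- function(network, registry = NULL) {
  verts <- data.frame(name = network$nodes, stringsAsFactors = FALSE)
  if (!is.null(registry)) {
    st <- node_states(network$nodes, registry)
    pop <- node_populations(network$nodes, registry)
    verts$state <- st
    verts$population <- pop
  }
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "weight", "movers")],
    directed = TRUE, vertices = verts
  )
}

# State of each network node: a municipality's own state, or for a metro node
# the state of its most populous member municipality (metros can straddle
# state lines).
node_states <- function(nodes, registry) {
  zs <- stats::setNames(registry$state_id, registry$zone_id)
  out <- zs[nodes]
  metro <- is.na(out)
  if (any(metro)) {
    mreg <- registry[!is.na(registry$metro_id), , drop = FALSE]
    for (nd in nodes[metro]) {
      mem <- mreg[mreg$metro_id == nd, , drop = FALSE]
      if (nrow(mem) == 0) abort("node '%s' not resolvable via registry", nd)
      out[nodes == nd] <- mem$state_id[which.max(mem$population)]
    }
  }
  unname(out)
}

# Population of each network node (metro nodes: sum over members).
node_populations <- function(nodes, registry) {
  zp <- stats::setNames(registry$population, registry$zone_id)
  out <- zp[nodes]
  metro <- is.na(out)
  if (any(metro)) {
    agg <- tapply(registry$population, registry$metro_id, sum)
    out[metro] <- agg[nodes[metro]]
    if (anyNA(out)) {
      abort("node(s) not resolvable via registry: %s",
            paste(nodes[metro][is.na(out[metro])], collapse = ", "))
    }
  }
  unname(out)
}
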