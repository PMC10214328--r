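# Shared fixtures and independent oracles used across the suite.

# Minimal registry: zones with given states / metros / populations, centroids
# on a line so distances are easy to reason about.
make_registry <- function(zone_id, state_id = "S01", metro_id = NA_character_,
                          population = 1000L, x = NULL, y = 0) {
  n <- length(zone_id)
  data.frame(
    zone_id = zone_id,
    name = zone_id,
    state_id = rep_len(state_id, n),
    metro_id = rep_len(metro_id, n),
    population = rep_len(population, n),
    x = if (is.null(x)) seq_len(n) * 10 else rep_len(x, n),
    y = rep_len(y, n),
    stringsAsFactors = FALSE
  )
}

# Ping table at explicit second offsets within a day (under the default
# UTC-6 day boundary: local midnight is 06:00 UTC).
make_pings <- function(device_id, zone_id, secs, date = "2020-03-01") {
  day_start <- as.POSIXct(as.character(date), tz = "UTC") + 6 * 3600
  data.frame(device_id = device_id, timestamp = day_start + secs,
             zone_id = zone_id, stringsAsFactors = FALSE)
}

# Brute-force network construction: enumerate every device's sorted ping
# sequence and every ordered node pair, independently of the data.table path.
oracle_network <- function(pings, registry) {
  devs <- sort(unique(pings$device_id))
  D <- length(devs)
  node_of <- function(z) {
    i <- match(z, registry$zone_id)
    ifelse(is.na(registry$metro_id[i]), registry$zone_id[i], registry$metro_id[i])
  }
  seqs <- lapply(devs, function(d) {
    pp <- pings[pings$device_id == d, , drop = FALSE]
    pp <- pp[order(pp$timestamp, pp$zone_id), , drop = FALSE]
    node_of(pp$zone_id)
  })
  all_nodes <- sort(unique(unlist(seqs)))
  rows <- list()
  for (i in all_nodes) {
    for (j in all_nodes) {
      if (i == j) next
      cnt <- 0L
      for (s in seqs) {
        moved <- FALSE
        if (length(s) >= 2) {
          for (k in seq_len(length(s) - 1L)) {
            if (s[k] == i && s[k + 1L] == j) moved <- TRUE
          }
        }
        if (moved) cnt <- cnt + 1L
      }
      if (cnt > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = i, target = j, weight = cnt / D, movers = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               weight = numeric(), movers = integer())
  list(nodes = all_nodes, edges = edges, panel_size = D)
}

# Exhaustive betweenness: enumerate all simple paths per ordered pair, keep
# the shortest, accumulate fractional pass-through counts. Only for tiny
# graphs (<= 8 nodes).
oracle_betweenness <- function(network) {
  nodes <- network$nodes
  adj <- lapply(setNames(nodes, nodes), function(s) {
    network$edges$target[network$edges$source == s]
  })
  bc <- setNames(numeric(length(nodes)), nodes)
  paths_from <- function(cur, tgt, visited) {
    if (cur == tgt) return(list(visited))
    out <- list()
    for (nb in adj[[cur]]) {
      if (!(nb %in% visited)) out <- c(out, paths_from(nb, tgt, c(visited, nb)))
    }
    out
  }
  for (s in nodes) {
    for (t in nodes) {
      if (s == t) next
      ps <- paths_from(s, t, s)
      if (!length(ps)) next
      lens <- vapply(ps, length, integer(1))
      sp <- ps[lens == min(lens)]
      for (p in sp) {
        for (v in p[-c(1, length(p))]) bc[v] <- bc[v] + 1 / length(sp)
      }
    }
  }
  bc
}

# Adjusted Rand index between two labelings of the same elements.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  c2 <- function(x) sum(x * (x - 1) / 2)
  si <- c2(tab)
  sa <- c2(rowSums(tab))
  sb <- c2(colSums(tab))
  n <- length(a)
  ex <- sa * sb / (n * (n - 1) / 2)
  (si - ex) / ((sa + sb) / 2 - ex)
}

# A network built directly from an edge table (weights = movers / panel).
net_from_edges <- function(edges, panel_size, date = "2020-03-01",
                           nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$source, edges$target)))
  edges$weight <- edges$movers / panel_size
  edges <- edges[, c("source", "target", "weight", "movers")]
  imtn_network(as.Date(date), nodes, edges, panel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
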