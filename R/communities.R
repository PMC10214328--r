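# Mesoscale structure: label-propagation communities on the symmetrized
# daily network, partition statistics (giant community, interstate share),
# and alluvial flow tables between dates.

#' Symmetrize a daily network
#'
#' The undirected edge \{i, j\} carries weight `W_ij + W_ji` (the total
#' two-way flow). Label propagation is defined on undirected graphs, so
#' community detection runs on this view.
#'
#' @param network an [imtn_network()].
#' @return an undirected weighted `igraph` graph over `network$nodes`.
#' @export
to_undirected <- function(network) {
  g <- as_igraph(network)
  igraph::as_undirected(g, mode = "collapse",
                        edge.attr.comb = list(weight = "sum", movers = "sum"))
}

#' Weighted asynchronous label propagation
#'
#' Seeded variant of the label-propagation community-detection algorithm on
#' an undirected weighted graph: every node starts with its own label; nodes
#' are visited in a seeded random order; each node adopts the label with the
#' largest summed weight over its incident edges, ties broken uniformly at
#' random from the same seeded generator; sweeps repeat until no label
#' changes or `max_iter` sweeps have run. Labels are then canonicalized:
#' communities are numbered 0, 1, 2, ... by decreasing size, ties by smallest
#' member node id, so partitions are comparable across days.
#'
#' @param graph an undirected weighted `igraph` graph (e.g. from
#'   [to_undirected()]) or an [imtn_network()] (symmetrized automatically).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param max_iter maximum number of full sweeps (default 100).
#' @return object of class `community_partition`: list with `membership`
#'   (named integer vector, labels from 0), `date` (when the input was a
#'   daily network), `seed`, `n_iterations`, `converged`.
#' @export
label_propagation <- function(graph, seed = 1L, max_iter = 100L) {
  date <- NULL
  if (inherits(graph, "imtn_network")) {
    date <- graph$date
    graph <- to_undirected(graph)
  }
  if (max_iter < 1) abort("max_iter must be >= 1")
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  nbr <- vector("list", n)
  wts <- vector("list", n)
  if (nrow(el)) {
    idx <- c(el[, 1], el[, 2])
    oth <- c(el[, 2], el[, 1])
    ww <- c(w, w)
    sp <- split(seq_along(idx), idx)
    for (v in names(sp)) {
      vi <- as.integer(v)
      nbr[[vi]] <- oth[sp[[v]]]
      wts[[vi]] <- ww[sp[[v]]]
    }
  }
  labels <- seq_len(n)
  iter <- 0L
  converged <- FALSE
  with_seed(seed, {
    while (iter < max_iter) {
      iter <- iter + 1L
      changed <- FALSE
      for (v in sample.int(n)) {
        if (!length(nbr[[v]])) next
        score <- tapply(wts[[v]], labels[nbr[[v]]], sum)
        best <- as.integer(names(score)[score == max(score)])
        new_lab <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
        if (new_lab != labels[v]) {
          labels[v] <- new_lab
          changed <- TRUE
        }
      }
      if (!changed) {
        converged <- TRUE
        break
      }
    }
  })
  membership <- canonical_labels(labels, nodes)
  structure(
    list(membership = membership, date = date, seed = as.integer(seed),
         n_iterations = iter, converged = converged),
    class = "community_partition"
  )
}

# Relabel raw community labels to 0, 1, ... by decreasing community size,
# ties by the smallest member node id.
canonical_labels <- function(labels, nodes) {
  groups <- split(nodes, labels)
  sizes <- lengths(groups)
  smallest <- vapply(groups, min, character(1))
  o <- order(-sizes, smallest)
  new_of_old <- stats::setNames(seq_along(o) - 1L, names(groups)[o])
  stats::setNames(unname(new_of_old[as.character(labels)]), nodes)
}

#' @export
print.community_partition <- function(x, ...) {
  k <- length(unique(x$membership))
  cat(sprintf("Community partition%s: %d nodes, %d communities (seed %d, %d sweep(s)%s)\n",
              if (!is.null(x$date)) paste0(" ", x$date) else "",
              length(x$membership), k, x$seed, x$n_iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Partition statistics
#'
#' Summary of one day's community structure: the number of communities, the
#' giant-community share of nodes, the fraction of communities whose members
#' span at least two states, and a per-state fragmentation count (how many
#' distinct communities contain that state's municipalities). A metropolitan
#' node is attributed to the state of its most populous member municipality.
#'
#' @param partition a [label_propagation()] partition.
#' @param registry zone registry resolving every node to a state.
#' @return list with `n_communities`, `giant_fraction`,
#'   `interstate_fraction`, `state_fragmentation` (`data.frame`).
#' @export
partition_stats <- function(partition, registry) {
  memb <- partition$membership
  if (!length(memb)) abort("empty partition")
  states <- node_states(names(memb), registry)
  comm_states <- split(states, memb)
  sizes <- lengths(comm_states)
  n_comm <- length(comm_states)
  interstate <- vapply(comm_states, function(s) length(unique(s)) >= 2, logical(1))
  frag <- tapply(memb, states, function(lbl) length(unique(lbl)))
  list(
    n_communities = n_comm,
    giant_fraction = max(sizes) / length(memb),
    interstate_fraction = mean(interstate),
    state_fragmentation = data.frame(state_id = names(frag),
                                     n_communities = as.integer(frag),
                                     row.names = NULL)
  )
}

#' Community flows between two partitions
#'
#' Counts nodes by their (label at t, label at u) pair — the input for
#' alluvial diagrams of community evolution. Nodes present on only one side
#' are tallied separately.
#'
#' @param partition_t,partition_u two [label_propagation()] partitions.
#' @return list with `flows` (`data.frame`: `from`, `to`, `count`),
#'   `n_shared`, `n_only_t`, `n_only_u`.
#' @export
community_flows <- function(partition_t, partition_u) {
  mt <- partition_t$membership
  mu <- partition_u$membership
  shared <- intersect(names(mt), names(mu))
  if (!length(shared)) {
    warning("partitions share no nodes; flow table is empty")
    return(list(flows = data.frame(from = integer(), to = integer(),
                                   count = integer()),
                n_shared = 0L, n_only_t = length(mt), n_only_u = length(mu)))
  }
  tab <- table(from = mt[shared], to = mu[shared])
  d <- as.data.frame(tab, stringsAsFactors = FALSE)
  d <- d[d$Freq > 0, , drop = FALSE]
  flows <- data.frame(from = as.integer(d$from), to = as.integer(d$to),
                      count = as.integer(d$Freq))
  flows <- flows[order(flows$from, flows$to), , drop = FALSE]
  rownames(flows) <- NULL
  list(flows = flows, n_shared = length(shared),
       n_only_t = length(setdiff(names(mt), shared)),
       n_only_u = length(setdiff(names(mu), shared)))
}
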