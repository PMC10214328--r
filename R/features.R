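# Global and local network features over a collection of daily networks:
# total edge weight S_G, centrality time series and their coefficients of
# variation, log-log population regressions, and rank turnover.

#' Total edge weight of a network
#'
#' \eqn{S_G = \sum_i w_i} over all edges — the day's global intermunicipal
#' mobility. Higher values mean more of the observed device panel moved
#' between localities.
#'
#' @param network an [imtn_network()].
#' @return a single number, 0 for an edgeless network.
#' @export
total_weight <- function(network) {
  sum(network$edges$weight)
}

#' Daily weight-sum series with a trailing moving average
#'
#' @param collection named, date-sorted list of networks.
#' @param window moving-average window in days (default 30). The window is
#'   trailing and shrinks at the start of the series (day t averages the most
#'   recent `min(window, t)` days).
#' @return `data.frame` with columns `date`, `s_g`, `s_g_ma`.
#' @export
weight_sum_series <- function(collection, window = 30L) {
  if (!length(collection)) {
    return(data.frame(date = as.Date(character()), s_g = numeric(),
                      s_g_ma = numeric()))
  }
  dates <- as.Date(vapply(collection, function(n) as.character(n$date), character(1)))
  o <- order(dates)
  raw <- vapply(collection, total_weight, numeric(1))[o]
  n <- length(raw)
  cs <- cumsum(raw)
  lo <- pmax(seq_len(n) - window, 0L)
  ma <- (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
  data.frame(date = dates[o], s_g = unname(raw), s_g_ma = ma)
}

#' Node centrality for one daily network
#'
#' Three measures:
#' * `degree` — number of inbound, outbound or total adjacent edges (a single
#'   observed trip is enough to establish an edge);
#' * `strength` — sum of the weights of inbound, outbound or total adjacent
#'   edges;
#' * `betweenness` — number of shortest paths through the node (directed,
#'   unnormalized). By default paths are unweighted; `bc_distance =
#'   "inverse-weight"` uses 1/W as the edge length instead. `direction` is
#'   ignored for betweenness.
#'
#' Isolated nodes score 0 on every measure.
#'
#' @param network an [imtn_network()].
#' @param measure `"degree"`, `"strength"` or `"betweenness"`.
#' @param direction `"in"`, `"out"` or `"total"`.
#' @param bc_distance `"unweighted"` (default) or `"inverse-weight"`.
#' @return named numeric vector over `network$nodes`.
#' @export
centrality <- function(network, measure = c("degree", "strength", "betweenness"),
                       direction = c("total", "in", "out"),
                       bc_distance = c("unweighted", "inverse-weight")) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  bc_distance <- match.arg(bc_distance)
  if (!length(network$nodes)) return(stats::setNames(numeric(), character()))
  g <- as_igraph(network)
  mode <- c(total = "all", "in" = "in", out = "out")[[direction]]
  v <- switch(measure,
    degree = igraph::degree(g, mode = mode, loops = FALSE),
    strength = igraph::strength(g, mode = mode, loops = FALSE,
                                weights = igraph::E(g)$weight),
    betweenness = {
      w <- if (bc_distance == "inverse-weight") 1 / igraph::E(g)$weight else NA
      igraph::betweenness(g, directed = TRUE, weights = w, normalized = FALSE)
    }
  )
  v[network$nodes]
}

#' Per-node centrality time series over a collection
#'
#' Builds the full day-by-node value matrix over the union of nodes ever
#' observed; a node absent from a day's network contributes 0 for that day
#' (it had no observed intermunicipal travel). Per-node summaries report the
#' mean, the sample standard deviation (denominator n - 1) and the
#' coefficient of variation `cv = 100 * sd / mean` (in percent); `cv` is `NA`
#' and flagged when the mean is 0.
#'
#' @inheritParams centrality
#' @param collection named, date-sorted list of networks.
#' @return object of class `centrality_series`: list with `measure`,
#'   `direction`, `dates`, `values` (dates x nodes matrix) and `summary`
#'   (`data.frame`: `node`, `mean`, `sd`, `cv`, `cv_defined`).
#' @export
centrality_series <- function(collection,
                              measure = c("degree", "strength", "betweenness"),
                              direction = c("total", "in", "out"),
                              bc_distance = c("unweighted", "inverse-weight")) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  dates <- as.Date(vapply(collection, function(n) as.character(n$date), character(1)))
  o <- order(dates)
  collection <- collection[o]
  dates <- dates[o]
  nodes <- sort(unique(unlist(lapply(collection, `[[`, "nodes"))))
  values <- matrix(0, nrow = length(collection), ncol = length(nodes),
                   dimnames = list(as.character(dates), nodes))
  for (i in seq_along(collection)) {
    v <- centrality(collection[[i]], measure, direction, bc_distance)
    if (length(v)) values[i, names(v)] <- v
  }
  mu <- colMeans(values)
  sdev <- apply(values, 2, stats::sd)
  cv <- ifelse(mu > 0, 100 * sdev / mu, NA_real_)
  structure(
    list(measure = measure, direction = direction, dates = dates,
         values = values,
         summary = data.frame(node = nodes, mean = unname(mu), sd = unname(sdev),
                              cv = unname(cv), cv_defined = unname(mu > 0),
                              stringsAsFactors = FALSE)),
    class = "centrality_series"
  )
}

#' @export
print.centrality_series <- function(x, ...) {
  cat(sprintf("Centrality series: %s (%s), %d days x %d nodes\n",
              x$measure, x$direction, length(x$dates), ncol(x$values)))
  invisible(x)
}

#' Log-log linear fit between two positive node statistics
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`, e.g. mean centrality
#' (or its coefficient of variation) against census population. Pairs with a
#' nonpositive value on either side are excluded before the log transform and
#' counted.
#'
#' @param x,y paired numeric vectors.
#' @return list with `slope`, `intercept`, `r_squared`, `n_used`, `n_dropped`.
#'   `r_squared` is 0 when `y` carries no variance.
#' @export
loglog_fit <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_used <- sum(ok)
  if (n_used < 3) abort("need at least 3 positive pairs, got %d", n_used)
  lx <- log10(x[ok]); ly <- log10(y[ok])
  fit <- stats::lm(ly ~ lx)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n_used = n_used, n_dropped = length(x) - n_used)
}

#' Rank turnover of the daily top-N list
#'
#' For each day, nodes are ranked by that day's value (ties broken by node id
#' ascending); `F(t)` is the number of distinct nodes that have ever entered
#' the top-N through day t, divided by N. A perfectly stable ranking keeps
#' `F(t) = 1`; under the null of independent uniform daily rankings the
#' expectation is the closed form
#' \deqn{E[F(t)] = (M/N)\,(1 - (1 - N/M)^t)}
#' with M the total number of nodes.
#'
#' @param series a [centrality_series()] (or a dates x nodes value matrix).
#' @param top_n size N of the ranked list; must not exceed the node count.
#' @return `data.frame` with columns `date`, `t`, `f_obs`, `f_null`.
#' @export
rank_turnover <- function(series, top_n) {
  values <- if (inherits(series, "centrality_series")) series$values else series
  M <- ncol(values)
  if (top_n > M) abort("top_n (%d) exceeds the number of nodes (%d)", top_n, M)
  nodes <- colnames(values)
  seen <- character(0)
  f_obs <- numeric(nrow(values))
  for (t in seq_len(nrow(values))) {
    topset <- nodes[order(-values[t, ], nodes)][seq_len(top_n)]
    seen <- union(seen, topset)
    f_obs[t] <- length(seen) / top_n
  }
  tt <- seq_len(nrow(values))
  f_null <- (M / top_n) * (1 - (1 - top_n / M)^tt)
  data.frame(date = as.Date(rownames(values)), t = tt, f_obs = f_obs,
             f_null = f_null)
}
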