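make_daily <- function(dates, edge_tabs, panel = 10L) {
  nets <- Map(function(d, e) net_from_edges(e, panel, date = d), dates, edge_tabs)
  names(nets) <- as.character(dates)
  nets
}

test_that("total weight sums edges and is zero on empty networks", {
  reg <- make_registry(c("A", "B"))
  empty <- build_daily_network(data.frame(device_id = character(),
                                          timestamp = as.POSIXct(character()),
                                          zone_id = character()),
                               reg, as.Date("2020-01-01"))
  expect_equal(total_weight(empty), 0)
  e <- data.frame(source = c("A", "B"), target = c("B", "A"), movers = c(2L, 1L))
  expect_equal(total_weight(net_from_edges(e, 4)), 0.75)
  # all devices making the same single trip saturates S_G at 1
  e1 <- data.frame(source = "A", target = "B", movers = 5L)
  expect_equal(total_weight(net_from_edges(e1, 5)), 1)
})

test_that("the moving average is trailing with a shrinking initial window", {
  # k unit-weight edges give S_G = k, so the raw series is 1, 2, 3
  e <- function(k) data.frame(source = LETTERS[1:k],
                              target = LETTERS[2:(k + 1)],
                              movers = rep(2L, k))
  nets <- make_daily(seq(as.Date("2020-01-01"), by = "day", length.out = 3),
                     list(e(1L), e(2L), e(3L)), panel = 2L)
  ws <- weight_sum_series(nets, window = 2)
  expect_equal(ws$s_g, c(1, 2, 3))
  expect_equal(ws$s_g_ma, c(1, 1.5, 2.5))

  const <- make_daily(seq(as.Date("2020-01-01"), by = "day", length.out = 40),
                      rep(list(data.frame(source = "A", target = "B",
                                          movers = 2L)), 40), panel = 4L)
  wsc <- weight_sum_series(const, window = 30)
  expect_true(all(wsc$s_g_ma == 0.5))
  expect_equal(nrow(weight_sum_series(list())), 0L)
})

test_that("an intensity drop shows up in the smoothed weight-sum series", {
  reg <- generate_zone_registry(15, 2, 0, seed = 50)
  pan <- generate_device_panel(reg, 400, seed = 51)
  dates <- seq(as.Date("2020-01-01"), by = "day", length.out = 20)
  inten <- setNames(c(rep(1, 10), rep(0.4, 10)), as.character(dates))
  sc <- mobility_scenario(dates[1], dates[20], p_move = 0.4,
                          intensity = inten, seed = 52)
  nets <- lapply(as.character(dates), function(d) {
    build_daily_network(simulate_day(pan, reg, d, sc), reg, as.Date(d))
  })
  names(nets) <- as.character(dates)
  ws <- weight_sum_series(nets, window = 5)
  expect_lt(mean(ws$s_g_ma[11:20]), mean(ws$s_g_ma[1:10]))
})

test_that("degree and strength follow their definitions on a star graph", {
  k <- 4
  e <- data.frame(source = "hub", target = sprintf("leaf%d", 1:k),
                  movers = rep(2L, k))
  net <- net_from_edges(e, panel_size = 10, nodes = c("hub", sprintf("leaf%d", 1:k), "iso"))
  expect_equal(unname(centrality(net, "degree", "out")["hub"]), k)
  expect_equal(unname(centrality(net, "degree", "in")["hub"]), 0)
  expect_equal(unname(centrality(net, "strength", "out")["hub"]), k * 0.2)
  expect_equal(unname(centrality(net, "strength", "total")["leaf1"]), 0.2)
  # isolated node scores zero everywhere
  for (m in c("degree", "strength", "betweenness")) {
    expect_equal(unname(centrality(net, m)["iso"]), 0)
  }
})

test_that("betweenness counts directed shortest paths", {
  e <- data.frame(source = c("a", "b"), target = c("b", "c"), movers = c(1L, 1L))
  net <- net_from_edges(e, 4)
  bc <- centrality(net, "betweenness")
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  set.seed(7)
  for (case in 1:20) {
    n <- sample(4:8, 1)
    nodes <- letters[seq_len(n)]
    ne <- sample(n:(n * (n - 1)), 1)
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pick <- pairs[sample(nrow(pairs), min(ne, nrow(pairs))), ]
    pick$movers <- sample(1:3, nrow(pick), TRUE)
    net <- net_from_edges(pick, panel_size = 10, nodes = nodes)
    got <- centrality(net, "betweenness")
    want <- oracle_betweenness(net)
    expect_equal(got[nodes], want[nodes], tolerance = 1e-10)
  }
})

test_that("centrality series fills absent nodes with zero and computes cv", {
  e1 <- data.frame(source = "A", target = "B", movers = 1L)
  e2 <- data.frame(source = c("A", "B"), target = c("B", "C"), movers = c(2L, 1L))
  nets <- make_daily(as.Date(c("2020-01-01", "2020-01-02")), list(e1, e2),
                     panel = 4L)
  cs <- centrality_series(nets, "degree", "total")
  expect_equal(dim(cs$values), c(2L, 3L))
  expect_equal(unname(cs$values[, "C"]), c(0, 1))  # absent day one

  # hand-computed cv: values [1,2,3] -> mean 2, sample sd 1, cv 50
  vals <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(
    c("2020-01-01", "2020-01-02", "2020-01-03"), "n1"))
  s <- list(values = vals)
  expect_equal(100 * sd(vals) / mean(vals), 50)
  # and [10, 20] -> cv = 100 * sqrt(50) / 15
  expect_equal(100 * sd(c(10, 20)) / mean(c(10, 20)), 100 * sqrt(50) / 15)

  e_const <- data.frame(source = "A", target = "B", movers = 1L)
  nets_const <- make_daily(as.Date(c("2020-01-01", "2020-01-02")),
                           list(e_const, e_const), panel = 2L)
  csc <- centrality_series(nets_const, "strength", "total")
  expect_true(all(csc$summary$cv[csc$summary$cv_defined] == 0))
})

test_that("cv is scale invariant and flagged for zero-mean series", {
  e <- data.frame(source = "A", target = "B", movers = 3L)
  e2 <- data.frame(source = "A", target = "B", movers = 1L)
  nets_small <- make_daily(as.Date(c("2020-01-01", "2020-01-02")),
                           list(e, e2), panel = 12L)
  nets_big <- make_daily(as.Date(c("2020-01-01", "2020-01-02")),
                         list(e, e2), panel = 3L)  # 4x the weights
  cv_small <- centrality_series(nets_small, "strength")$summary
  cv_big <- centrality_series(nets_big, "strength")$summary
  expect_equal(cv_small$cv, cv_big$cv)

  # a node present as isolated only: zero mean -> cv undefined, flagged
  e3 <- data.frame(source = "A", target = "B", movers = 1L)
  net_iso <- net_from_edges(e3, 2L, date = "2020-01-01", nodes = c("A", "B", "C"))
  cs <- centrality_series(list("2020-01-01" = net_iso), "strength")
  row <- cs$summary[cs$summary$node == "C", ]
  expect_false(row$cv_defined)
  expect_true(is.na(row$cv))
})

test_that("strength conservation: in, out and S_G agree on every network", {
  reg <- generate_zone_registry(20, 2, 2, seed = 60)
  pan <- generate_device_panel(reg, 300, seed = 61)
  sc <- mobility_scenario("2020-02-01", "2020-02-10", seed = 62)
  for (d in as.character(seq(sc$start, sc$end, by = "day"))) {
    net <- build_daily_network(simulate_day(pan, reg, d, sc), reg, as.Date(d))
    s_in <- sum(centrality(net, "strength", "in"))
    s_out <- sum(centrality(net, "strength", "out"))
    s_tot <- sum(centrality(net, "strength", "total"))
    expect_equal(s_in, total_weight(net))
    expect_equal(s_out, total_weight(net))
    expect_equal(s_tot, 2 * total_weight(net))
    d_tot <- centrality(net, "degree", "total")
    d_io <- centrality(net, "degree", "in") + centrality(net, "degree", "out")
    expect_equal(d_tot, d_io)
  }
})

test_that("log-log regression recovers power laws and rejects tiny inputs", {
  x <- seq(1, 100, length.out = 50)
  fit <- loglog_fit(x, x^2)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- loglog_fit(x, rep(5, 50))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  set.seed(8)
  xr <- runif(200, 1, 1000)
  yr <- 3 * xr^1.5 * 10^rnorm(200, 0, 0.1)
  noisy <- loglog_fit(xr, yr)
  expect_gt(noisy$slope, 1.45)
  expect_lt(noisy$slope, 1.55)

  # nonpositive pairs are dropped and counted
  fit2 <- loglog_fit(c(x, -1, 0), c(x^2, 4, 4))
  expect_equal(fit2$n_dropped, 2L)
  expect_error(loglog_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("rank turnover matches hand counts and its null closed form", {
  # static ranking: F identically 1
  vals <- matrix(rep(c(5, 4, 3, 2, 1), each = 6), nrow = 6,
                 dimnames = list(as.character(seq(as.Date("2020-01-01"),
                                                  by = "day", length.out = 6)),
                                 letters[1:5]))
  rt <- rank_turnover(vals, top_n = 2)
  expect_true(all(rt$f_obs == 1))

  # disjoint daily top-2 over 3 days: F = 1, 2, 3
  v2 <- matrix(0, 3, 6, dimnames = list(
    as.character(seq(as.Date("2020-01-01"), by = "day", length.out = 3)),
    letters[1:6]))
  v2[1, 1:2] <- c(2, 1); v2[2, 3:4] <- c(2, 1); v2[3, 5:6] <- c(2, 1)
  rt2 <- rank_turnover(v2, 2)
  expect_equal(rt2$f_obs, c(1, 2, 3))

  # null curve: E[F(1)] = 1 and Monte-Carlo agreement at later t
  M <- 30; N <- 5; Tdays <- 10; reps <- 300
  expect_equal((M / N) * (1 - (1 - N / M)^1), 1)
  set.seed(11)
  fmat <- replicate(reps, {
    seen <- integer(0)
    vapply(1:Tdays, function(t) {
      seen <<- union(seen, sample.int(M, N))
      length(seen) / N
    }, numeric(1))
  })
  f_null <- (M / N) * (1 - (1 - N / M)^(1:Tdays))
  mc_mean <- rowMeans(fmat)
  mc_se <- apply(fmat, 1, sd) / sqrt(reps)
  expect_true(all(abs(mc_mean - f_null) <= 3 * pmax(mc_se, 1e-12)))

  expect_error(rank_turnover(v2, 7), "top_n")
})

test_that("stable synthetic rankings stay below the random-ranking null", {
  reg <- generate_zone_registry(40, 4, 2, seed = 70)
  pan <- generate_device_panel(reg, 800, seed = 71)
  sc <- mobility_scenario("2020-03-01", "2020-03-20", seed = 72)
  nets <- lapply(as.character(seq(sc$start, sc$end, by = "day")), function(d) {
    build_daily_network(simulate_day(pan, reg, d, sc), reg, as.Date(d))
  })
  names(nets) <- as.character(seq(sc$start, sc$end, by = "day"))
  cs <- centrality_series(nets, "strength", "total")
  rt <- rank_turnover(cs, 10)
  expect_true(all(rt$f_obs[-1] <= rt$f_null[-1]))
  expect_true(all(diff(rt$f_obs) >= 0))
  expect_equal(rt$f_obs[1], 1)
})
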