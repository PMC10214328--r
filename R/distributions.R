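# Heavy-tail diagnostics for node-strength (or degree/betweenness)
# distributions: excess kurtosis, log-normality testing, normal QQ data, and
# Beta Rank Function (discrete generalized beta) rank-size fits.

#' Excess kurtosis
#'
#' Fisher's excess kurtosis \eqn{g_2 = m_4 / m_2^2 - 3} with population
#' moments \eqn{m_k = n^{-1}\sum (x - \bar x)^k}. Positive values indicate
#' heavier-than-normal tails (a tendency to produce outliers). Invariant
#' under affine transforms of the data.
#'
#' @param x numeric vector, `n >= 4`, nonzero variance.
#' @param sample_corrected if `TRUE`, return the bias-corrected sample
#'   statistic \eqn{G_2} instead.
#' @return a single number.
#' @export
excess_kurtosis <- function(x, sample_corrected = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) abort("excess kurtosis needs at least 4 observations, got %d", n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) abort("excess kurtosis undefined for zero-variance data")
  g2 <- mean((x - m)^4) / m2^2 - 3
  if (sample_corrected) {
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else {
    g2
  }
}

#' Log-normality diagnostics for a day's node strengths
#'
#' Takes the natural logarithm of the positive total node strengths and runs
#' a Shapiro-Wilk normality test plus the excess kurtosis of the same log
#' values. Zero-strength (isolated) nodes are excluded and counted. A
#' rejection (small p) means the strength distribution is not well described
#' as log-normal.
#'
#' Degenerate days — fewer than 4 positive strengths, zero variance, or more
#' than 5000 values (beyond the Shapiro-Wilk implementation range) — are
#' returned flagged, with `NA` statistics and no test.
#'
#' @param network an [imtn_network()], or a bare numeric vector of node
#'   strengths (the date is then `NA`).
#' @return one-row `data.frame`: `date`, `shapiro_w`, `p_value`, `g2`, `n`,
#'   `zeros`, `degenerate`.
#' @export
log_strength_normality <- function(network) {
  if (is.numeric(network)) {
    s <- network
    date <- as.Date(NA)
  } else {
    s <- centrality(network, "strength", "total")
    date <- network$date
  }
  pos <- s[s > 0]
  zeros <- length(s) - length(pos)
  rec <- data.frame(date = date, shapiro_w = NA_real_,
                    p_value = NA_real_, g2 = NA_real_,
                    n = length(pos), zeros = zeros, degenerate = TRUE)
  if (length(pos) < 4 || length(pos) > 5000) return(rec)
  lx <- log(pos)
  if (stats::var(lx) == 0) return(rec)
  sw <- stats::shapiro.test(lx)
  rec$shapiro_w <- unname(sw$statistic)
  rec$p_value <- sw$p.value
  rec$g2 <- excess_kurtosis(lx)
  rec$degenerate <- FALSE
  rec
}

#' Rank-size table
#'
#' Sizes sorted descending; rank 1 is the largest. Ties keep a deterministic
#' order (by name when `values` is named, else by original position).
#'
#' @param values numeric vector, optionally named by node.
#' @return `data.frame` with columns `rank`, `size` (and `node` when named).
#' @export
rank_size <- function(values) {
  if (!length(values)) abort("rank_size needs a non-empty vector")
  ids <- names(values) %||% as.character(seq_along(values))
  o <- order(-values, ids)
  out <- data.frame(rank = seq_along(values), size = unname(values[o]))
  if (!is.null(names(values))) out$node <- ids[o]
  out
}

#' Fit the Beta Rank Function to a size distribution
#'
#' The Beta Rank Function (discrete generalized beta distribution) is the
#' two-exponent rank-size form
#' \deqn{X(r) = A\,(N + 1 - r)^b / r^a,}
#' with independent Paretian exponents for the two tails: `a` governs the
#' decay at the top ranks (large sizes), `b` the drop at the bottom ranks.
#' Unlike a pure power law it accommodates the asymmetric, smooth-peaked
#' log-size histograms typical of mobility-network node strengths.
#'
#' The fit is ordinary least squares in log space,
#' `ln X = ln A - a ln r + b ln(N + 1 - r)`, which recovers noiseless
#' profiles exactly. The `r = N` point, where `ln(N + 1 - r) = 0`, is kept:
#' it still informs `A` and `a`. Nonpositive sizes are excluded first.
#'
#' @param values positive sizes (at least 3 after exclusions), optionally
#'   named.
#' @return object of class `brf_fit`: list with `A`, `a`, `b`, `n`,
#'   `r_squared`, `ranks` (the rank-size table) and `fitted` values.
#' @export
fit_beta_rank <- function(values) {
  v <- values[is.finite(values) & values > 0]
  if (length(v) < 3) {
    abort("fit_beta_rank needs at least 3 positive values, got %d", length(v))
  }
  rs <- rank_size(v)
  n <- nrow(rs)
  lx <- log(rs$size)
  lr <- log(rs$rank)
  ls <- log(n + 1 - rs$rank)
  fit <- stats::lm(lx ~ lr + ls)
  cf <- coef(fit)
  tss <- sum((lx - mean(lx))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  a <- -unname(cf["lr"]); b <- unname(cf["ls"])
  # a zero-variance profile fits exactly with a = b = 0
  if (is.na(a)) a <- 0
  if (is.na(b)) b <- 0
  A <- exp(unname(cf["(Intercept)"]))
  structure(
    list(A = A, a = a, b = b, n = n, r_squared = r2, ranks = rs,
         fitted = A * (n + 1 - rs$rank)^b / rs$rank^a),
    class = "brf_fit"
  )
}

#' @export
print.brf_fit <- function(x, ...) {
  cat(sprintf("Beta Rank Function fit (N = %d): A = %.6g, a = %.4f, b = %.4f, R^2 = %.4f\n",
              x$n, x$A, x$a, x$b, x$r_squared))
  invisible(x)
}

#' QQ data against the standard normal
#'
#' Pairs sample quantiles of (optionally standardized) values with standard
#' normal quantiles at plotting positions `(i - 0.5) / n`. Standardization
#' uses the sample mean and sample standard deviation; pass
#' `standardize = FALSE` to compare raw values (useful when they are already
#' on the standard normal scale).
#'
#' @param log_values numeric vector (typically log strengths), `n >= 4`.
#' @param standardize center and scale before pairing (default `TRUE`).
#' @return `data.frame` with columns `theoretical`, `sample`.
#' @export
qq_against_normal <- function(log_values, standardize = TRUE) {
  x <- log_values[is.finite(log_values)]
  n <- length(x)
  if (n < 4) abort("qq_against_normal needs at least 4 values, got %d", n)
  if (standardize) {
    s <- stats::sd(x)
    if (s == 0) abort("zero-variance input cannot be standardized")
    x <- (x - mean(x)) / s
  }
  data.frame(theoretical = qnorm((seq_len(n) - 0.5) / n), sample = sort(x))
}

#' Per-day distribution diagnostics over a collection
#'
#' Applies [log_strength_normality()] to every network: Shapiro-Wilk
#' log-normality test and excess kurtosis of the log strengths, with
#' degenerate days flagged rather than dropped.
#'
#' @param collection named, date-sorted list of networks.
#' @return `data.frame`, one row per day: `date`, `shapiro_w`, `p_value`,
#'   `g2`, `n`, `zeros`, `degenerate`.
#' @export
distribution_diagnostics <- function(collection) {
  out <- do.call(rbind, lapply(collection, log_strength_normality))
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

#' Excess-kurtosis time series of log strengths
#'
#' Convenience view of [distribution_diagnostics()]: the per-day excess
#' kurtosis `g2` of the log node strengths.
#'
#' @inheritParams distribution_diagnostics
#' @return `data.frame` with columns `date`, `g2`, `degenerate`.
#' @export
kurtosis_series <- function(collection) {
  d <- distribution_diagnostics(collection)
  d[, c("date", "g2", "degenerate")]
}
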