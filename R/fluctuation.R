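#' Relative rate of change of a positive time series
#'
#' The logarithmic-derivative estimate `g(t_i) = (x_{i+1} - x_{i-1}) /
#' (2 dt x_i)` by central differences on a uniformly sampled positive
#' series; the two endpoints are dropped. Relative rates are scale free:
#' rescaling the series by any positive constant leaves them unchanged,
#' which is what makes arbitrary-unit fluorescence intensities comparable
#' with cell heights.
#'
#' @param x Positive numeric series (length >= 3), uniformly sampled.
#' @param dt Sampling interval.
#' @return Numeric vector of length `length(x) - 2`.
#' @export
relative_rate <- function(x, dt = 1) {
  n <- length(x)
  if (n < 3) abort("series must have length >= 3", class = "epifold_input_error")
  if (any(x <= 0)) abort("series must be strictly positive", class = "epifold_input_error")
  if (dt <= 0) abort("dt must be > 0", class = "epifold_input_error")
  (x[3:n] - x[1:(n - 2)]) / (2 * dt * x[2:(n - 1)])
}

#' Cross-correlation of two rate signals
#'
#' The unnormalised product-mean cross-correlation
#' `C(tau) = < g1(t) g2(t + tau) >`, evaluated on the lag grid `tau = k dt`,
#' `|k| <= max_lag/dt`, per cell and averaged across cells with equal
#' weight. Lags with fewer than 5 overlapping samples in a cell are reported
#' as missing for that cell. A Pearson-style normalised variant (each cell's
#' product divided by the two rate standard deviations) is available behind
#' `normalized = TRUE`.
#'
#' @param g1,g2 Numeric vectors (one cell) or lists of equal-length numeric
#'   vectors (one entry per cell) of aligned rate signals.
#' @param max_lag Largest lag magnitude, in time units.
#' @param dt Sampling interval of the rate signals.
#' @param normalized Use the Pearson-normalised variant.
#' @return An `xcorr_result`: list with `lags`, per-cell matrix `per_cell`
#'   (cells x lags), cell-averaged `average`, `n_cells`, `dt`.
#' @export
cross_correlation <- function(g1, g2, max_lag, dt = 1, normalized = FALSE) {
  if (is.numeric(g1)) g1 <- list(g1)
  if (is.numeric(g2)) g2 <- list(g2)
  if (length(g1) != length(g2)) {
    abort("g1 and g2 must have the same number of cells", class = "epifold_input_error")
  }
  kmax <- floor(max_lag / dt + 1e-9)
  if (kmax < 0) abort("max_lag must be >= 0", class = "epifold_input_error")
  lags <- (-kmax):kmax
  per_cell <- matrix(NA_real_, length(g1), length(lags))
  for (ci in seq_along(g1)) {
    a <- g1[[ci]]; b <- g2[[ci]]
    if (length(a) != length(b)) {
      abort("per-cell rate series must be aligned (equal length)",
            class = "epifold_input_error")
    }
    if (kmax >= length(a)) {
      abort("max_lag must be smaller than the series span", class = "epifold_input_error")
    }
    scale <- if (normalized) sd(a) * sd(b) else 1
    for (li in seq_along(lags)) {
      k <- lags[li]
      if (k >= 0) {
        ia <- seq_len(length(a) - k); ib <- ia + k
      } else {
        ib <- seq_len(length(a) + k); ia <- ib - k
      }
      if (length(ia) >= 5) {
        per_cell[ci, li] <- mean(a[ia] * b[ib]) / scale
      }
    }
  }
  avg <- colMeans(per_cell, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  structure(list(lags = lags * dt, per_cell = per_cell, average = avg,
                 n_cells = length(g1), dt = dt, normalized = normalized),
            class = "xcorr_result")
}

#' Lag of the cross-correlation minimum
#'
#' Grid argmin of the cell-averaged correlation; ties are broken towards the
#' smallest lag magnitude. A negative minimum at positive lag means the
#' first signal's increase precedes the second signal's decrease.
#'
#' @param result An `xcorr_result`.
#' @return One-row tibble: `tau_min`, `C_min`.
#' @export
min_lag <- function(result) {
  ok <- which(!is.na(result$average))
  if (length(ok) == 0) abort("correlation is empty", class = "epifold_input_error")
  cmin <- min(result$average[ok])
  cand <- ok[result$average[ok] == cmin]
  tau <- result$lags[cand]
  tibble(tau_min = tau[which.min(abs(tau))], C_min = cmin)
}

#' Cross-correlate lateral intensity and cell height fluctuations
#'
#' High-level pipeline for paired per-cell series of lateral F-actin
#' intensity `a_l` and cell height `h`: computes the relative rates
#' `(1/a_l) da_l/dt` and `(1/h) dh/dt` per cell by central differences and
#' their cross-correlation `C(tau) = <g_a(t) g_h(t + tau)>`. A pulsatile
#' intensity increase that precedes a height decrease shows up as a negative
#' minimum of `C` at a positive lag. The same pipeline applies unchanged to
#' (medial intensity, surface area) pairs.
#'
#' Slow trends (e.g. the long-term height decrease of fold cells) are part
#' of the signal by default; `detrend = TRUE` removes a per-cell linear
#' trend from the log-series first, as a sensitivity check.
#'
#' @param data Tibble with columns `cell_id`, `t`, `a_l`, `h` (uniform
#'   sampling per cell; positive values).
#' @param max_lag Largest lag magnitude in the units of `t` (default 60 s
#'   for a 10 s cadence).
#' @param detrend Remove per-cell linear trends of the log-series.
#' @param normalized Pearson-normalised variant (see [cross_correlation()]).
#' @return An `xcorr_result` with metadata (`conventions`) recording the
#'   derivative estimator and averaging order.
#' @export
actin_height_xcorr <- function(data, max_lag = 60, detrend = FALSE,
                               normalized = FALSE) {
  need <- c("cell_id", "t", "a_l", "h")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste("coupled series data is missing column(s):", paste(miss, collapse = ", ")),
          class = "epifold_schema_error")
  }
  cells <- split(as_tibble(data)[need], data$cell_id)
  dts <- vapply(cells, function(d) {
    dd <- diff(sort(d$t))
    if (length(dd) == 0 || max(abs(dd - dd[1])) > 1e-6 * dd[1]) {
      abort("each cell must be uniformly sampled", class = "epifold_input_error")
    }
    dd[1]
  }, numeric(1))
  dt <- dts[[1]]
  if (max(abs(dts - dt)) > 1e-6 * dt) {
    abort("all cells must share the sampling interval", class = "epifold_input_error")
  }
  strip_trend <- function(x, t) {
    lx <- log(x)
    exp(lx - stats::fitted(lm(lx ~ t)) + mean(lx))
  }
  g1 <- lapply(cells, function(d) {
    d <- d[order(d$t), ]
    x <- if (detrend) strip_trend(d$a_l, d$t) else d$a_l
    relative_rate(x, dt)
  })
  g2 <- lapply(cells, function(d) {
    d <- d[order(d$t), ]
    x <- if (detrend) strip_trend(d$h, d$t) else d$h
    relative_rate(x, dt)
  })
  res <- cross_correlation(g1, g2, max_lag = max_lag, dt = dt,
                           normalized = normalized)
  res$conventions <- list(derivative = "central difference, endpoints dropped",
                          averaging = "per cell, then unweighted mean across cells",
                          detrend = detrend, normalized = normalized)
  res
}

#' Bartlett-type null bound for a cross-correlation
#'
#' Standard deviation of `C(tau)` under the null hypothesis that the two
#' rate signals are independent stationary processes, estimated from the
#' pooled variances and empirical autocorrelations (the autocorrelation
#' product sum corrects for the serial correlation that central differencing
#' introduces). Useful to judge whether a correlation minimum is
#' distinguishable from noise.
#'
#' @param g1,g2 Rate signals as in [cross_correlation()].
#' @param z Number of null standard deviations (default 3).
#' @return Scalar bound on `|C(tau)|`.
#' @export
xcorr_null_bound <- function(g1, g2, z = 3) {
  if (is.numeric(g1)) g1 <- list(g1)
  if (is.numeric(g2)) g2 <- list(g2)
  pool1 <- unlist(g1); pool2 <- unlist(g2)
  n <- sum(lengths(g1))
  acf_sum <- function(x) {
    a <- stats::acf(x, lag.max = min(20, length(x) - 1), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }
  r1 <- acf_sum(pool1); r2 <- acf_sum(pool2)
  m <- min(length(r1), length(r2))
  corr_factor <- sum(r1[1:m] * r2[1:m]) * 2 - 1  # k = 0 counted once
  corr_factor <- max(corr_factor, 1)
  z * sqrt(var(pool1) * var(pool2) * corr_factor / n)
}

#' @export
print.xcorr_result <- function(x, ...) {
  ml <- min_lag(x)
  cat("<xcorr_result> ", x$n_cells, " cell(s), lags ",
      min(x$lags), "..", max(x$lags), " (dt ", x$dt, ")\n", sep = "")
  cat(sprintf("  minimum C = %.4g at tau = %g\n", ml$C_min, ml$tau_min))
  invisible(x)
}

#' @method tidy xcorr_result
#' @export
tidy.xcorr_result <- function(x, ...) {
  per_cell <- as_tibble(t(x$per_cell), .name_repair = ~ paste0("cell_", seq_along(.x)))
  dplyr::bind_cols(tibble(lag = x$lags, C = x$average), per_cell)
}

#' @method glance xcorr_result
#' @export
glance.xcorr_result <- function(x, ...) {
  dplyr::mutate(min_lag(x), n_cells = x$n_cells, dt = x$dt,
                normalized = x$normalized)
}
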