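# Statistical machinery shared by the trajectory and exchange modules:
# autocorrelation-based block sizing, BCa bootstrap over block averages,
# Monte-Carlo error propagation, and the normalized chi^2 curve metric.

#' Autocorrelation first-zero time
#'
#' Estimates the decorrelation time of a series as the first lag at which
#' the (biased) empirical autocorrelation function crosses zero or below.
#' Used to choose trajectory block sizes: blocks should exceed twice this
#' time so block averages are effectively independent.
#'
#' @param series Numeric vector.
#' @param dt Time per sample (any unit; the return value is in the same
#'   unit).  Default 1, i.e. the answer is in lags.
#' @return First zero-passage time (numeric).
#' @export
autocorrelation_time <- function(series, dt = 1) {
  stopifnot(length(series) >= 10L)
  if (stats::sd(series) == 0) {
    stop("constant series has no autocorrelation zero passage")
  }
  n <- length(series)
  ac <- stats::acf(series, lag.max = floor(n / 2), plot = FALSE,
                   demean = TRUE)$acf[-1]
  hit <- which(ac <= 0)
  if (!length(hit)) {
    stop("autocorrelation does not reach zero within half the series; ",
         "use a longer series")
  }
  hit[1] * dt
}

#' Partition a series into non-overlapping block averages
#'
#' @param x Numeric vector or matrix (rows = samples, columns = variables;
#'   column structure is preserved so that variables stay jointly blocked).
#' @param block_len Samples per block; trailing partial blocks are dropped.
#' @return Matrix of block means (rows = blocks).
#' @export
block_averages <- function(x, block_len) {
  x <- as.matrix(x)
  block_len <- as.integer(block_len)
  stopifnot(block_len >= 1L)
  n_blocks <- nrow(x) %/% block_len
  if (n_blocks < 1L) stop("series shorter than one block")
  idx <- rep(seq_len(n_blocks), each = block_len)
  out <- apply(x[seq_len(n_blocks * block_len), , drop = FALSE], 2,
               function(col) tapply(col, idx, mean))
  matrix(out, nrow = n_blocks, dimnames = list(NULL, colnames(x)))
}

#' BCa bootstrap over block averages
#'
#' Resamples whole blocks (rows of \code{blocks}) with replacement and
#' computes bias-corrected and accelerated (BCa) confidence intervals for
#' a statistic of the block averages.  Vector-valued statistics (e.g. one
#' mean per residue) are resampled jointly, preserving the dependence of
#' residues within a block.
#'
#' @param blocks Matrix (rows = blocks) or vector of block averages.
#' @param statistic Function mapping a block matrix to a numeric vector;
#'   default column means.
#' @param n Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return data.frame of class \code{bootstrap_result} with columns
#'   \code{estimate}, \code{lower}, \code{upper}, \code{flag}, plus
#'   attributes \code{n_resamples}, \code{level}, \code{seed}.
#' @export
bca_bootstrap <- function(blocks, statistic = NULL, n = 10000,
                          level = 0.95, seed = 1L) {
  blocks <- as.matrix(blocks)
  if (nrow(blocks) < 3L) stop("need at least 3 blocks")
  if (is.null(statistic)) statistic <- function(b) colMeans(b)
  stat_fun <- function(data, idx) statistic(data[idx, , drop = FALSE])
  set.seed(seed)
  bt <- boot::boot(blocks, stat_fun, R = n)
  p <- length(bt$t0)
  lower <- upper <- rep(NA_real_, p)
  flag <- rep("ok", p)
  for (j in seq_len(p)) {
    spread <- stats::sd(bt$t[, j])
    if (!is.finite(spread) || spread == 0) {
      lower[j] <- upper[j] <- bt$t0[j]
      flag[j] <- "degenerate"
      next
    }
    ci <- tryCatch(
      boot::boot.ci(bt, conf = level, type = "bca", index = j),
      error = function(e) NULL)
    if (is.null(ci)) {
      qs <- stats::quantile(bt$t[, j], c((1 - level) / 2, (1 + level) / 2))
      lower[j] <- qs[1]; upper[j] <- qs[2]
      flag[j] <- "percentile_fallback"
    } else {
      lower[j] <- ci$bca[4]; upper[j] <- ci$bca[5]
      if (bt$t0[j] < lower[j] || bt$t0[j] > upper[j]) flag[j] <- "skew"
    }
  }
  out <- data.frame(estimate = as.numeric(bt$t0),
                    lower = lower, upper = upper, flag = flag,
                    stringsAsFactors = FALSE)
  structure(out, n_resamples = n, level = level, seed = seed,
            n_blocks = nrow(blocks),
            class = c("bootstrap_result", "data.frame"))
}

#' Monte-Carlo error propagation
#'
#' Propagates independent Gaussian input uncertainties through an
#' arbitrary function.  Draws for which the function returns \code{NA}
#' (e.g. an exchange rate sampled above its chemical rate) are rejected
#' and counted; a result with more than 50 percent rejections is flagged
#' unreliable.
#'
#' @param fn Function of a numeric vector (same length as \code{mean}).
#' @param mean,se Numeric vectors of input means and standard errors.
#' @param n Number of draws.
#' @param level Confidence level for the percentile interval.
#' @param seed Integer seed.
#' @param log_normal If TRUE, sample strictly positive inputs from a
#'   log-normal matched to the given mean and se.
#' @return data.frame of class \code{bootstrap_result} (one row per
#'   element of \code{fn}'s output) with attribute
#'   \code{rejected_fraction}.
#' @export
mc_propagate <- function(fn, mean, se, n = 10000, level = 0.95, seed = 1L,
                         log_normal = FALSE) {
  stopifnot(length(mean) == length(se), all(se >= 0))
  set.seed(seed)
  p <- length(mean)
  draws <- matrix(stats::rnorm(n * p, rep(mean, each = n),
                               rep(se, each = n)), nrow = n)
  if (log_normal) {
    sdlog <- sqrt(log1p((se / mean)^2))
    mulog <- log(mean) - sdlog^2 / 2
    draws <- matrix(stats::rlnorm(n * p, rep(mulog, each = n),
                                  rep(sdlog, each = n)), nrow = n)
  }
  vals <- apply(draws, 1, fn)
  vals <- if (is.null(dim(vals))) matrix(vals, ncol = n) else vals
  ok <- colSums(is.na(vals)) == 0
  rejected <- 1 - mean(ok)
  point <- fn(mean)
  a <- (1 - level) / 2
  if (!any(ok)) {
    out <- data.frame(estimate = point, lower = NA_real_, upper = NA_real_,
                      flag = "all_rejected", stringsAsFactors = FALSE)
  } else {
    qs <- apply(vals[, ok, drop = FALSE], 1, stats::quantile,
                probs = c(a, 1 - a), na.rm = TRUE)
    out <- data.frame(
      estimate = point, lower = qs[1, ], upper = qs[2, ],
      flag = if (rejected > 0.5) "unreliable" else "ok",
      stringsAsFactors = FALSE)
  }
  structure(out, rejected_fraction = rejected, n_draws = n, level = level,
            seed = seed, class = c("bootstrap_result", "data.frame"))
}

#' Normalized mean-squared deviation between two curves
#'
#' \code{chi2 = mean((model - data)^2) / mean((data - mean(data))^2)}.
#' With this convention a model equal to the data gives 0 and a constant
#' model at the data mean gives exactly 1.  If the curves live on
#' different time grids the model is linearly interpolated (in log time
#' when all times are positive) onto the data grid.
#'
#' @param model Numeric vector of model values, or a two-column object
#'   (time, value).
#' @param data Numeric vector of data values, or a two-column object
#'   (time, value).
#' @return Dimensionless chi^2.
#' @export
chi2_norm <- function(model, data) {
  get_tv <- function(x) {
    if (is.null(dim(x))) list(t = NULL, v = as.numeric(x))
    else list(t = as.numeric(x[, 1]), v = as.numeric(x[, 2]))
  }
  m <- get_tv(model); d <- get_tv(data)
  if (!is.null(m$t) && !is.null(d$t) &&
      (length(m$t) != length(d$t) || any(m$t != d$t))) {
    tx <- function(t) if (all(t > 0)) log(t) else t
    m$v <- stats::approx(tx(m$t), m$v, xout = tx(d$t), rule = 2)$y
  }
  if (length(m$v) != length(d$v)) stop("curves have different lengths")
  denom <- mean((d$v - mean(d$v))^2)
  if (denom == 0) stop("constant data: normalized chi^2 undefined")
  mean((m$v - d$v)^2) / denom
}

#' @export
print.bootstrap_result <- function(x, ...) {
  lvl <- attr(x, "level")
  cat(sprintf("Bootstrap/MC result (%d rows, %.0f%% intervals)\n",
              nrow(x), 100 * lvl))
  if (!is.null(attr(x, "rejected_fraction"))) {
    cat(sprintf("  rejected draws: %.1f%%\n",
                100 * attr(x, "rejected_fraction")))
  }
  NextMethod()
}
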