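# internal helpers shared across modules

# Run code with a temporarily seeded RNG; restores the caller's RNG state.
# seed = NULL runs in the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stage label, kept < 2^31.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  (as.double(seed) * 48271 + h * 7919) %% 2147483587
}

# Closed-form OLS of x on t over an index window. Returns slope, intercept,
# residual SD. Centred formulas for numerical stability.
ols_line <- function(t, x) {
  n <- length(t)
  mt <- mean(t)
  mx <- mean(x)
  tc <- t - mt
  stt <- sum(tc^2)
  if (stt <= 0) {
    return(list(slope = 0, intercept = mx, resid_sd = stats::sd(x), n = n))
  }
  slope <- sum(tc * (x - mx)) / stt
  rss <- sum((x - mx - slope * tc)^2)
  list(
    slope = slope,
    intercept = mx - slope * mt,
    resid_sd = if (n > 2) sqrt(rss / (n - 2)) else 0,
    n = n
  )
}

# Centred local-linear smoother (first-order Savitzky-Golay): fits an OLS
# line over each window and evaluates it at the centre point. Unlike a plain
# moving average it is exact for linear trends at the record edges, where
# the window necessarily becomes asymmetric.
smooth_local_linear <- function(x, k) {
  k <- max(1L, as.integer(k))
  n <- length(x)
  if (k <= 2L || n < 3L) return(x)
  half <- k %/% 2
  out <- numeric(n)
  idx <- seq_len(n)
  for (i in idx) {
    lo <- max(i - half, 1L)
    hi <- min(i + half, n)
    tt <- lo:hi
    ol <- ols_line(tt, x[tt])
    out[i] <- ol$intercept + ol$slope * i
  }
  out
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L || length(x) < 2L) return(x)
  half <- k %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 95% chi-square interval for an exponential mean given the (possibly
# weighted) sufficient statistic S = sum of observations and count n.
exp_mean_ci <- function(S, n, level = 0.95) {
  a <- (1 - level) / 2
  c(
    lower = 2 * S / stats::qchisq(1 - a, df = 2 * n),
    upper = 2 * S / stats::qchisq(a, df = 2 * n)
  )
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
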