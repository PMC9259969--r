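# Internal numeric helpers shared across modules.

## centered moving average; window forced odd, edges use shrinking windows
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L || length(x) < 2L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

## indices of strict local maxima (plateaus take the first index)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

## topographic prominence of peak at index `at`: height above the higher of
## the two minima separating it from taller terrain (or the series edge)
peak_prominence <- function(x, at) {
  n <- length(x)
  h <- x[at]
  left_min <- h
  i <- at - 1L
  while (i >= 1L && x[i] <= h) {
    left_min <- min(left_min, x[i])
    i <- i - 1L
  }
  if (i < 1L) left_min <- min(x[seq_len(at)])
  right_min <- h
  i <- at + 1L
  while (i <= n && x[i] <= h) {
    right_min <- min(right_min, x[i])
    i <- i + 1L
  }
  if (i > n) right_min <- min(x[at:n])
  h - max(left_min, right_min)
}

## quadratic (three-point) refinement of an extremum location on a uniform grid
refine_vertex <- function(x, y, at) {
  n <- length(x)
  if (at <= 1L || at >= n) return(x[at])
  y0 <- y[at - 1L]; y1 <- y[at]; y2 <- y[at + 1L]
  denom <- y0 - 2 * y1 + y2
  if (abs(denom) < .Machine$double.eps) return(x[at])
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(-1, min(1, delta))
  x[at] + delta * (x[min(n, at + 1L)] - x[at])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
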