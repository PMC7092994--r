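# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

# Stop with a classed condition so tests can assert on error class.
stop_cvreact <- function(msg, class = "cvreact_error") {
  rlang::abort(msg, class = c(class, "cvreact_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_cvreact(sprintf("`%s` must be a single number.", name),
                 "cvreact_invalid_parameter")
  }
  ok_lower <- if (strict_lower) x > lower else x >= lower
  if (!ok_lower || x > upper) {
    stop_cvreact(sprintf("`%s` = %g is outside its valid range.", name, x),
                 "cvreact_invalid_parameter")
  }
  invisible(x)
}

# Local RNG scope: run `expr` under a seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed for a sub-process from a parent seed, staying below
# 2^31 so it remains a valid R integer.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483629)
}

#' Find local maxima with a prominence and separation constraint
#'
#' Strict local maxima of `x` are filtered by topographic prominence (height
#' above the higher of the two flanking saddle points) and by a minimum
#' index separation, keeping the higher peak when two are too close.
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence in the units of `x`.
#' @param min_separation minimum distance between kept peaks, in samples.
#' @return integer vector of peak indices, sorted.
#' @keywords internal
#' @noRd
find_peaks <- function(x, min_prominence = 0, min_separation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # strict rise then fall; plateaus resolved to the first sample of the run
  rising <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- rising[vapply(rising, function(i) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    j == n || x[j + 1L] < x[i]
  }, logical(1))]
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- if (i > 1L) min_before_higher(x, i, -1L) else x[i]
    right <- if (i < n) min_before_higher(x, i, +1L) else x[i]
    x[i] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1L || min_separation <= 1L) return(keep)
  # greedy: highest peaks first, drop any within min_separation of a kept one
  ord <- keep[order(x[keep], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_separation)) kept <- c(kept, i)
  }
  sort(kept)
}

# walk from peak i in direction dir until a sample higher than x[i] is met;
# return the minimum value encountered (the saddle).
min_before_higher <- function(x, i, dir) {
  n <- length(x)
  lo <- x[i]
  j <- i + dir
  while (j >= 1L && j <= n && x[j] <= x[i]) {
    if (x[j] < lo) lo <- x[j]
    j <- j + dir
  }
  lo
}

# Linear interpolation that errors instead of extrapolating.
interp_linear <- function(x, y, xout, what = "series") {
  if (length(x) < 2L) {
    stop_cvreact(sprintf("Need at least two points to interpolate %s.", what))
  }
  if (min(xout) < min(x) || max(xout) > max(x)) {
    stop_cvreact(sprintf(
      "Requested grid [%g, %g] extends beyond the support [%g, %g] of %s.",
      min(xout), max(xout), min(x), max(x), what))
  }
  approx(x, y, xout = xout, method = "linear", ties = "ordered")$y
}

# Moving average with reflected edges (odd window).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[length(x) - seq_len(h)]))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1L):(h + length(x))]
}
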