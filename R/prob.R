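# Core probability machinery for the multi-set intersection exact test.
#
# Model: t sets of fixed sizes s_1..s_t are drawn independently and uniformly
# without replacement from a background population of n elements.  The size X
# of their common intersection has a distribution obtained by chaining
# hypergeometric kernels: the overlap of the first two sets is hypergeometric,
# and conditional on a running overlap of size j, intersecting with the next
# set of size s yields an overlap k ~ Hypergeometric(j, n - j, s).  All
# intermediate overlap sizes are integrated out; only X is observed.

#' Natural log of a binomial coefficient
#'
#' Thin wrapper around [lchoose()] (log-gamma based) with the domain semantics
#' used throughout the package: impossible draws have log-coefficient `-Inf`
#' rather than raising an error.
#'
#' @param n Non-negative integer (vectorised).
#' @param k Integer number of draws (vectorised); values outside `[0, n]`
#'   give `-Inf`.
#' @return Numeric vector, `log(choose(n, k))`; exactly 0 when `k` is 0 or `n`.
#' @examples
#' log_binom(10, 4)   # log(210)
#' log_binom(10, 11)  # -Inf
#' @export
log_binom <- function(n, k) {
  if (any(n < 0)) stop("'n' must be non-negative")
  len <- max(length(n), length(k))
  n <- rep_len(n, len)
  k <- rep_len(k, len)
  out <- rep(-Inf, len)
  ok <- k >= 0 & k <= n
  out[ok] <- lchoose(n[ok], k[ok])
  out
}

## log(sum(exp(v))) without overflow; -Inf for empty or all -Inf input
logsumexp <- function(v) {
  v <- v[v > -Inf]
  if (!length(v)) return(-Inf)
  m <- max(v)
  m + log(sum(exp(v - m)))
}

## running log(cumsum(exp(v)))
cumlogsumexp <- function(v) {
  out <- numeric(length(v))
  acc <- -Inf
  for (i in seq_along(v)) {
    a <- acc; b <- v[i]
    acc <- if (a == -Inf && b == -Inf) -Inf else {
      m <- max(a, b); m + log1p(exp(min(a, b) - m))
    }
    out[i] <- acc
  }
  out
}

check_sized_sets <- function(sizes, n) {
  if (length(sizes) < 2L) stop("at least two set sizes are required")
  if (any(sizes != round(sizes)) || any(sizes < 0)) {
    stop("set sizes must be non-negative integers")
  }
  if (length(n) != 1L || n != round(n) || n < 1) {
    stop("'n' must be a single positive integer")
  }
  if (any(sizes > n)) stop("every set size must be <= the background size 'n'")
  invisible(TRUE)
}

## Forward pass: log-pmf of the common intersection size over the support
## x0..min(sizes).  Sets are processed in decreasing size order so the state
## table (indexed by the running overlap) shrinks as early as possible; the
## result is order-invariant.  Truncation at x0 is exact for all outputs >= x0
## because the running overlap never grows.  Attribute "ops" counts kernel
## evaluations (the unit of the O(t * m^2) complexity bound).
mset_forward <- function(sizes, n, x0 = 0L) {
  check_sized_sets(sizes, n)
  sizes <- sort(as.integer(sizes), decreasing = TRUE)
  t <- length(sizes)
  m <- sizes[t]
  if (x0 > m) {
    out <- numeric(0)
    attr(out, "support") <- integer(0)
    attr(out, "ops") <- 0
    return(out)
  }
  supp <- x0:sizes[2L]
  f <- stats::dhyper(supp, sizes[2L], n - sizes[2L], sizes[1L], log = TRUE)
  ops <- length(supp)
  if (t > 2L) {
    for (i in 3:t) {
      newsupp <- x0:min(sizes[i], max(supp))
      ## transition kernel: P(overlap k | previous overlap j)
      lk <- outer(newsupp, supp,
                  function(k, j) stats::dhyper(k, j, n - j, sizes[i], log = TRUE))
      ops <- ops + length(lk)
      lf <- sweep(lk, 2L, f, `+`)
      mx <- apply(lf, 1L, max)
      f <- ifelse(is.finite(mx), mx + log(rowSums(exp(lf - mx))), -Inf)
      supp <- newsupp
    }
  }
  attr(f, "support") <- supp
  attr(f, "ops") <- ops
  f
}

#' Distribution of the multi-set intersection size
#'
#' Density (`dmset`) and upper/lower tail (`pmset`) of the number of elements
#' shared by all of `length(sizes)` sets drawn independently and uniformly
#' without replacement from a background of `n` elements.  For two sets this
#' is the classical hypergeometric model; for three or more sets the nested
#' hypergeometric sums are evaluated with a forward dynamic-programming pass
#' in log space, at cost `O(t * m^2)` where `m = min(sizes)`.
#'
#' `pmset` with the default `lower.tail = FALSE` returns the one-tailed
#' enrichment probability `P(X >= q)` (note the inequality is inclusive,
#' unlike `phyper`'s convention): the significance of observing at least `q`
#' shared elements.  `lower.tail = TRUE` gives the depletion tail
#' `P(X <= q)`.  Use `log.p = TRUE` to recover tails far below the
#' double-precision underflow floor (around 1e-308).
#'
#' @param x,q Vector of intersection sizes (non-negative integers).
#' @param sizes Integer vector of at least two set cardinalities.
#' @param n Background population size; all sizes must be `<= n`.
#' @param log,log.p Logical; return natural-log probabilities.
#' @param lower.tail Logical; if `FALSE` (default) `pmset` returns
#'   `P(X >= q)`, otherwise `P(X <= q)`.
#' @return Numeric vector of (log) probabilities, one per element of `x`/`q`.
#'   Sizes above `min(sizes)` have density 0 (`-Inf` on the log scale).
#' @seealso [mset_exact_test()] for the full test with fold enrichment,
#'   [dmset_naive()] and [dmset_exhaustive()] for the reference oracles.
#' @examples
#' dmset(2, c(5, 4), n = 10)            # equals dhyper(2, 5, 5, 4)
#' pmset(9, c(125, 522, 107, 260, 137, 435, 114), n = 20687, log.p = TRUE)
#' @export
dmset <- function(x, sizes, n, log = FALSE) {
  check_sized_sets(sizes, n)
  if (any(x < 0) || any(x != round(x))) stop("'x' must be non-negative integers")
  m <- min(sizes)
  f <- mset_forward(sizes, n, 0L)
  lp <- rep(-Inf, length(x))
  inside <- x <= m
  lp[inside] <- f[x[inside] + 1L]
  if (log) lp else exp(lp)
}

#' @rdname dmset
#' @export
pmset <- function(q, sizes, n, lower.tail = FALSE, log.p = FALSE) {
  check_sized_sets(sizes, n)
  if (any(q < 0) || any(q != round(q))) stop("'q' must be non-negative integers")
  m <- min(sizes)
  f <- mset_forward(sizes, n, 0L)
  if (lower.tail) {
    cum <- cumlogsumexp(f)                      # P(X <= i), i = 0..m
    lp <- ifelse(q >= m, 0, cum[pmin(q, m) + 1L])
  } else {
    cum <- rev(cumlogsumexp(rev(f)))            # P(X >= i), i = 0..m
    lp <- ifelse(q > m, -Inf, cum[pmin(q, m) + 1L])
    lp[q == 0] <- 0
  }
  lp <- pmin(lp, 0)                             # clamp rounding above 1
  if (log.p) lp else exp(lp)
}

#' Expected intersection size and fold enrichment
#'
#' Under independent uniform sampling the expected number of elements common
#' to all sets is `n * prod(sizes / n)`.  Fold enrichment (FE) is the ratio
#' of the observed to the expected overlap fraction, `x / mset_expected()`;
#' values above 1 indicate over-representation.
#'
#' @inheritParams dmset
#' @param x Observed intersection size, `0 <= x <= min(sizes)`.
#' @return A single non-negative number.  `mset_fe` is 0 exactly when `x` is 0.
#' @examples
#' mset_expected(c(125, 522, 107, 260, 137, 435, 114), n = 20687)  # ~1.57e-10
#' mset_fe(9, c(125, 522, 107, 260, 137, 435, 114), n = 20687)     # ~5.7e10
#' @export
mset_expected <- function(sizes, n) {
  check_sized_sets(sizes, n)
  n * prod(sizes / n)
}

#' @rdname mset_expected
#' @export
mset_fe <- function(x, sizes, n) {
  check_sized_sets(sizes, n)
  if (any(sizes == 0)) stop("fold enrichment is undefined when a set is empty")
  if (length(x) != 1L || x < 0 || x > min(sizes)) {
    stop("'x' must be a single integer in [0, min(sizes)]")
  }
  x / mset_expected(sizes, n)
}

#' Exact test of a multi-set intersection
#'
#' One-tailed exact test that `x` observed shared elements among sets of the
#' given sizes is larger (default) or smaller than expected under independent
#' uniform sampling from a background of `n` elements.  This is the size-only
#' fast path: only the cardinalities enter the null distribution, so the test
#' can be run directly from published set sizes and overlap counts.
#'
#' @inheritParams dmset
#' @param x Observed intersection size.
#' @param alternative `"greater"` for enrichment (upper tail, the default) or
#'   `"less"` for depletion.
#' @return An object of class `"mset_exact_test"`: a list with elements
#'   `x` (observed), `expected`, `fe` (fold enrichment; `NA` when `x`
#'   exceeds `min(sizes)`), `p.value`, `log10.p` (finite whenever the tail is
#'   mathematically positive, even when `p.value` underflows to 0), `sizes`,
#'   `n` and `alternative`.
#' @examples
#' mset_exact_test(9, c(125, 522, 107, 260, 137, 435, 114), n = 20687)
#' @export
mset_exact_test <- function(x, sizes, n, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  check_sized_sets(sizes, n)
  if (length(x) != 1L || x < 0 || x != round(x)) {
    stop("'x' must be a single non-negative integer")
  }
  lp <- pmset(x, sizes, n, lower.tail = alternative == "less", log.p = TRUE)
  structure(list(
    x = as.integer(x),
    expected = mset_expected(sizes, n),
    fe = if (x <= min(sizes) && all(sizes > 0)) mset_fe(x, sizes, n) else NA_real_,
    p.value = exp(lp),
    log10.p = lp / log(10),
    sizes = as.integer(sizes),
    n = as.integer(n),
    alternative = alternative
  ), class = "mset_exact_test")
}

#' @export
print.mset_exact_test <- function(x, ...) {
  cat("Exact multi-set intersection test\n")
  cat(sprintf("  %d sets of sizes {%s} from a background of %d elements\n",
              length(x$sizes), paste(x$sizes, collapse = ", "), x$n))
  cat(sprintf("  observed overlap: %d   expected: %.6g   fold enrichment: %.4g\n",
              x$x, x$expected, x$fe))
  tail_lab <- if (x$alternative == "greater") "P(X >= x)" else "P(X <= x)"
  cat(sprintf("  one-tailed %s = %.6g   (log10 P = %.4f)\n",
              tail_lab, x$p.value, x$log10.p))
  invisible(x)
}

#' Reference oracles for the intersection density
#'
#' Two independent implementations of the intersection-size density, intended
#' for validation rather than production use.  `dmset_naive` evaluates the
#' nested hypergeometric sums by direct recursion, re-computing every inner
#' sum for each outer index (exponential cost; 2--6 sets only).
#' `dmset_exhaustive` enumerates every configuration of subsets of the stated
#' sizes by bitmask and counts those whose common intersection has exactly
#' `x` elements; counting is exact integer arithmetic (2 or 3 sets, small
#' backgrounds only).
#'
#' @inheritParams dmset
#' @param x Single non-negative integer intersection size.
#' @param log Logical; `dmset_naive` can return the natural-log density.
#' @return The probability (or log-probability) that all sets share exactly
#'   `x` elements.
#' @examples
#' dmset_exhaustive(1, c(2, 2), n = 4)  # 8/36
#' dmset_naive(2, c(3, 4, 5), n = 8)
#' @export
dmset_naive <- function(x, sizes, n, log = FALSE) {
  check_sized_sets(sizes, n)
  t <- length(sizes)
  if (t > 6L) stop("dmset_naive supports at most 6 sets")
  if (length(x) != 1L || x < 0 || x != round(x)) {
    stop("'x' must be a single non-negative integer")
  }
  rec <- function(x, sizes) {
    if (length(sizes) == 2L) {
      return(stats::dhyper(x, sizes[1L], n - sizes[1L], sizes[2L]))
    }
    hi <- min(sizes[1L], sizes[2L])
    if (x > hi) return(0)
    total <- 0
    for (j in x:hi) {
      total <- total +
        stats::dhyper(j, sizes[1L], n - sizes[1L], sizes[2L]) *
        rec(x, c(j, sizes[-(1:2)]))
    }
    total
  }
  p <- if (x > min(sizes)) 0 else rec(x, sizes)
  if (log) base::log(p) else p
}

#' @rdname dmset_naive
#' @export
dmset_exhaustive <- function(x, sizes, n) {
  check_sized_sets(sizes, n)
  t <- length(sizes)
  if (t > 3L) stop("dmset_exhaustive supports at most 3 sets")
  if (length(x) != 1L || x < 0 || x != round(x)) {
    stop("'x' must be a single non-negative integer")
  }
  n_conf <- prod(choose(n, sizes))
  if (n > 16L || n_conf > 2e6) {
    stop("enumeration budget exceeded (", format(n_conf), " configurations)")
  }
  popcount <- vapply(0:(2^n - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L), 1L)
  masks <- lapply(sizes, function(s) {
    if (s == 0L) return(0L)
    cols <- utils::combn(n, s)
    as.integer(colSums(matrix(bitwShiftL(1L, cols - 1L), nrow = s)))
  })
  ab <- as.vector(outer(masks[[1L]], masks[[2L]], bitwAnd))
  count <- 0
  if (t == 2L) {
    count <- sum(popcount[ab + 1L] == x)
  } else {
    for (cm in masks[[3L]]) {
      count <- count + sum(popcount[bitwAnd(ab, cm) + 1L] == x)
    }
  }
  count / n_conf
}
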