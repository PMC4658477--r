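# Weighted-sampling simulator for the type-I-error study, plus a synthetic
# collection generator with exactly planted overlaps.

#' Weighted sampling without replacement
#'
#' Draws `k` distinct elements from `1..n` where the first `n_pref` elements
#' carry sampling weight `w` and the rest weight 1, under the sequential
#' scheme: each successive draw picks an element with probability
#' proportional to the weights of the elements still available.  Implemented
#' with the exponential-key construction (the `k` smallest values of
#' `rexp(n) / weight`), which is distributionally identical to the sequential
#' draws and vectorises; with `w = 1` it reduces to uniform sampling.
#'
#' @param n Population size.
#' @param k Number of elements to draw (`k <= n`).
#' @param n_pref Number of preferentially weighted elements (the first
#'   `n_pref` indices).
#' @param w Weight ratio of preferential to ordinary elements (`w >= 1`).
#' @return Integer vector of `k` distinct indices in `1..n`.
#' @examples
#' set.seed(1)
#' weighted_sample(1000, 200, n_pref = 100, w = 2)
#' @export
weighted_sample <- function(n, k, n_pref = 0L, w = 1) {
  if (k > n) stop("cannot draw ", k, " elements from a population of ", n)
  if (w < 1) stop("'w' must be >= 1")
  if (n_pref > n) stop("'n_pref' cannot exceed 'n'")
  if (k == 0L) return(integer(0))
  keys <- stats::rexp(n)
  if (n_pref > 0L && w > 1) keys[seq_len(n_pref)] <- keys[seq_len(n_pref)] / w
  thr <- sort(keys, partial = k)[k]
  which(keys <= thr)[seq_len(k)]
}

## Exact outcome probabilities of the sequential weighted draw for tiny n:
## enumerates every ordered draw sequence.  Test oracle for weighted_sample.
seq_weighted_probs <- function(weights, k) {
  n <- length(weights)
  probs <- new.env()
  rec <- function(remaining, chosen, p) {
    if (length(chosen) == k) {
      key <- paste(sort(chosen), collapse = ",")
      probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) + p
      return(invisible())
    }
    tot <- sum(weights[remaining])
    for (i in remaining) {
      rec(setdiff(remaining, i), c(chosen, i), p * weights[i] / tot)
    }
  }
  rec(seq_len(n), integer(0), 1)
  out <- unlist(as.list(probs))
  out[order(names(out))]
}

#' Empirical false-positive rate of the multi-set exact test
#'
#' Monte-Carlo experiment probing type-I-error behaviour under (possibly
#' biased) sampling.  In each replicate, one set per entry of `set_sizes` is
#' drawn from a population of `n` elements by [weighted_sample()] (the first
#' `n_pref` elements having weight `w`); the one-tailed exact p-value of the
#' overlap among all sets is computed, and the false-positive rate is the
#' fraction of replicates with p below `alpha`.  With `w = 1` the null model
#' of the test holds exactly and the rate should not exceed `alpha`; `w > 1`
#' induces dependence among the sets.
#'
#' The null distribution of the overlap depends on the data only through the
#' observed size, so the full tail is precomputed once per configuration and
#' each replicate costs a lookup.  Replicates use seeds derived from `seed`
#' by one upfront draw, so the experiment is reproducible and replicates are
#' order-independent.
#'
#' @param n Population size.
#' @param set_sizes Integer vector of set cardinalities (default the study
#'   design 200, 300, 400).
#' @param n_pref Number of preferential elements (default 100).
#' @param w Sampling weight of the preferential elements (`>= 1`).
#' @param reps Number of replicates (default 1000).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A one-row data frame with columns `n`, `w`, `n_pref`, `reps`,
#'   `alpha`, `fpr`, and the 95% Wilson interval `ci_lo`, `ci_hi`.
#' @examples
#' fpr_experiment(n = 1000, w = 1, reps = 100, seed = 42)
#' @export
fpr_experiment <- function(n, set_sizes = c(200L, 300L, 400L), n_pref = 100L,
                           w = 1, reps = 1000L, alpha = 0.05, seed = NULL) {
  check_sized_sets(set_sizes, n)
  if (n_pref > n) stop("'n_pref' cannot exceed 'n'")
  if (w < 1) stop("'w' must be >= 1")
  if (reps < 1L) stop("'reps' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  f <- mset_forward(set_sizes, n, 0L)
  ltail <- rev(cumlogsumexp(rev(as.numeric(f))))   # log P(X >= i), i = 0..m
  m <- min(set_sizes)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  hits <- 0L
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    draws <- lapply(set_sizes, function(k) weighted_sample(n, k, n_pref, w))
    x <- length(Reduce(intersect, draws))
    lp <- if (x > m) -Inf else ltail[x + 1L]
    ## strict p < alpha, the study's significance rule; a level-1 test
    ## rejects every replicate (including those at p exactly 1)
    if (alpha >= 1 || lp < log(alpha)) hits <- hits + 1L
  }
  fpr <- hits / reps
  ## 95% Wilson score interval
  z <- stats::qnorm(0.975)
  centre <- (fpr + z^2 / (2 * reps)) / (1 + z^2 / reps)
  half <- z * sqrt(fpr * (1 - fpr) / reps + z^2 / (4 * reps^2)) / (1 + z^2 / reps)
  data.frame(n = n, w = w, n_pref = n_pref, reps = reps, alpha = alpha,
             fpr = fpr, ci_lo = max(0, centre - half), ci_hi = min(1, centre + half))
}

#' Synthetic set collections with exactly planted overlaps
#'
#' Generates a [set_collection()] over identifiers `e1..en` whose total
#' overlap ([count_overlap()]) for each planted combination equals the
#' requested count exactly.  Planted combinations are named by their set
#' names joined with `"&"` (e.g. `"S1&S3"`); counts are total overlaps, so a
#' planted superset combination contributes to its sub-combinations (e.g.
#' `planted = list("S1&S2&S3" = 2, "S1&S2" = 5)` yields a triple overlap of 2
#' contained in a pairwise overlap of 5).
#'
#' With no plants the sets are independent uniform draws.  With plants, the
#' remaining members of each set are filled from elements used by no other
#' set, so no overlap beyond the planted design can arise — the generator
#' trades marginal uniformity of the fills for exact overlap bookkeeping.
#'
#' @param n Background population size.
#' @param sizes Integer vector of set cardinalities; sets are named
#'   `S1..St` unless `sizes` is named.
#' @param planted Named list mapping combinations to total overlap counts.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [set_collection()] with background size `n`.
#' @examples
#' sc <- make_fixture_collection(100, c(10, 10), planted = list("S1&S2" = 4),
#'                               seed = 1)
#' count_overlap(sc, c("S1", "S2"))  # exactly 4
#' @export
make_fixture_collection <- function(n, sizes, planted = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- length(sizes)
  set_names <- names(sizes)
  if (is.null(set_names)) set_names <- paste0("S", seq_len(t))
  ids <- paste0("e", seq_len(n))
  if (!length(planted)) {
    sets <- lapply(sizes, function(s) sample(ids, s))
    names(sets) <- set_names
    return(set_collection(sets, background = n))
  }
  combos <- lapply(names(planted), function(key) {
    nms <- strsplit(key, "&", fixed = TRUE)[[1L]]
    unknown <- setdiff(nms, set_names)
    if (length(unknown)) stop("planted combination names unknown set(s): ",
                              paste(unknown, collapse = ", "))
    match(nms, set_names)
  })
  counts <- as.integer(unlist(planted))
  ## process by descending degree: a combination's exclusive block is its
  ## requested total minus what supersets already placed
  ord <- order(-lengths(combos))
  members <- replicate(t, character(0), simplify = FALSE)
  pool <- ids
  placed <- list()   # per planted combo: indices covered + element block
  for (ci in ord) {
    idx <- combos[[ci]]
    already <- 0L
    for (pl in placed) {
      if (all(idx %in% pl$idx)) already <- already + length(pl$block)
    }
    need <- counts[ci] - already
    if (need < 0L) {
      stop("infeasible plant for '", names(planted)[ci], "': supersets already ",
           "place ", already, " shared elements but only ", counts[ci],
           " were requested")
    }
    if (need > length(pool)) {
      stop("infeasible plant for '", names(planted)[ci], "': needs ", need,
           " fresh elements but only ", length(pool), " remain in the population")
    }
    block <- if (need > 0L) sample(pool, need) else character(0)
    pool <- setdiff(pool, block)
    for (i in idx) members[[i]] <- c(members[[i]], block)
    placed[[length(placed) + 1L]] <- list(idx = idx, block = block)
  }
  ## disjoint fills so planted totals stay exact
  fill_needed <- sizes - lengths(members)
  if (any(fill_needed < 0L)) {
    bad <- which(fill_needed < 0L)[1L]
    stop("infeasible plant: set '", set_names[bad], "' needs size ", sizes[bad],
         " but plants already give it ", lengths(members)[bad], " members")
  }
  if (sum(fill_needed) > length(pool)) {
    stop("infeasible plant: fills need ", sum(fill_needed),
         " distinct elements but only ", length(pool), " remain")
  }
  fills <- sample(pool, sum(fill_needed))
  at <- 0L
  for (i in seq_len(t)) {
    if (fill_needed[i] > 0L) {
      members[[i]] <- c(members[[i]], fills[at + seq_len(fill_needed[i])])
      at <- at + fill_needed[i]
    }
  }
  names(members) <- set_names
  set_collection(members, background = n)
}
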