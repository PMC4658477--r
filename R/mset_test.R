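# Enumeration of all set combinations with exact-test statistics, the
# "msetest" fitted object and its methods.

## barcode helpers ------------------------------------------------------------

barcode_of <- function(idx, t) {
  b <- integer(t)
  b[idx] <- 1L
  paste(b, collapse = "")
}

## All 2^t - 1 non-empty combinations, ordered by degree then combn order.
enumerate_combinations <- function(t) {
  out <- vector("list", 2^t - 1)
  pos <- 0L
  for (d in seq_len(t)) {
    for (idx in utils::combn(t, d, simplify = FALSE)) {
      pos <- pos + 1L
      out[[pos]] <- idx
    }
  }
  out
}

## p-value adjustment in log10 space (handles p underflowed to 0, i.e.
## log10 p < -308).  'l10' is the vector of log10 raw p-values; 'm' the size
## of the test family.
adjust_log10p <- function(l10, method = c("bonferroni", "bh"), m = length(l10)) {
  method <- match.arg(method)
  if (!length(l10)) return(l10)
  if (method == "bonferroni") {
    return(pmin(0, l10 + log10(m)))
  }
  ord <- order(l10)
  k <- length(l10)
  cand <- l10[ord] + log10(m / seq_len(k))
  adj <- rev(cummin(rev(cand)))      # step-up: min over ranks >= i
  adj <- pmin(adj, 0)
  out <- numeric(k)
  out[ord] <- adj
  out
}

## scientific-notation formatting straight from log10(p), so probabilities far
## below the double underflow floor still print (e.g. "1.04e-409")
format_p_log10 <- function(l10, digits = 3) {
  vapply(l10, function(l) {
    if (is.na(l)) return(NA_character_)
    if (l == -Inf) return("0")
    e <- floor(l)
    mant <- round(10^(l - e), digits)
    if (mant >= 10) { mant <- mant / 10; e <- e + 1 }
    sprintf("%.*fe%+03d", digits, mant, e)
  }, character(1))
}

## ---------------------------------------------------------------------------

#' Exact tests of all intersections among multiple sets
#'
#' Enumerates every non-empty combination of the sets in a collection and, for
#' each combination of two or more sets, computes the observed intersection
#' size, the size expected under independent uniform sampling from the
#' background, the fold enrichment, and the one-tailed exact probability of an
#' overlap at least as large ([pmset()]).  Raw p-values are adjusted for the
#' family of all `2^t - t - 1` combinations of degree two or more, whatever
#' `min_degree` is displayed.
#'
#' @param x A [set_collection()], or a named list of character vectors.
#' @param n Background population size (a single integer), required unless
#'   `x` already carries a background.  An explicit universe may instead be
#'   supplied via [set_collection()].
#' @param min_degree Smallest combination degree to retain in the result
#'   (degree-1 records carry set sizes for plotting but no statistics).
#' @param p_adjust Multiple-testing adjustment: `"bonferroni"` (default) or
#'   `"bh"` (Benjamini-Hochberg step-up), both carried out in log space so
#'   that p-values below the double underflow floor adjust correctly.
#' @param keep_elements Retain the identifiers of each intersection (capped at
#'   `max_elements` per record).
#' @param max_elements Per-record cap on retained identifiers.
#' @return An object of class `"msetest"`: a list with components
#'   \describe{
#'     \item{records}{data frame with one row per combination: `barcode`
#'       (membership pattern over the sets), `intersection` (names joined by
#'       `" & "`), `degree`, `observed`, `expected`, `fe`, `p`, `p_adjusted`,
#'       `log10_p`, `log10_p_adjusted`, and an `elements` list column.}
#'     \item{set_sizes}{named integer vector of set cardinalities.}
#'     \item{n}{background size.}
#'     \item{M}{size of the multiple-testing family (`2^t - t - 1`).}
#'     \item{p_adjust}{the adjustment method used.}
#'   }
#' @seealso [summary.msetest()], [plot.msetest()], [write_mset_summary()].
#' @examples
#' sets <- list(A = paste0("g", 1:40), B = paste0("g", 21:80),
#'              C = paste0("g", c(1:10, 51:90)))
#' fit <- mset_test(sets, n = 500)
#' fit
#' head(summary(fit)$Table)
#' @export
mset_test <- function(x, n = NULL, min_degree = 1L,
                      p_adjust = c("bonferroni", "bh"),
                      keep_elements = TRUE, max_elements = 10000L) {
  p_adjust <- match.arg(p_adjust)
  if (!inherits(x, "set_collection")) {
    if (!is.list(x)) stop("'x' must be a set_collection or a named list of sets")
    x <- set_collection(x, background = n)
  } else if (is.na(x$background_size) && !is.null(n)) {
    x <- set_collection(x$sets, background = n)
  }
  if (is.na(x$background_size)) {
    stop("a background population is required: supply 'n' or build the ",
         "collection with an explicit background")
  }
  t <- length(x$sets)
  if (t < 2L) stop("at least two sets are required")
  if (t > 30L) stop("more than 30 sets: full 2^t enumeration is not supported")
  n_bg <- x$background_size
  sizes <- set_sizes(x)
  combos <- enumerate_combinations(t)
  k <- length(combos)
  rec <- data.frame(
    barcode = character(k), intersection = character(k),
    degree = integer(k), observed = integer(k),
    expected = NA_real_, fe = NA_real_,
    p = NA_real_, p_adjusted = NA_real_,
    log10_p = NA_real_, log10_p_adjusted = NA_real_,
    stringsAsFactors = FALSE
  )
  elements <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- combos[[i]]
    nmv <- names(x$sets)[idx]
    inter <- Reduce(intersect, x$sets[idx])
    rec$barcode[i] <- barcode_of(idx, t)
    rec$intersection[i] <- paste(nmv, collapse = " & ")
    rec$degree[i] <- length(idx)
    rec$observed[i] <- length(inter)
    elements[[i]] <- if (keep_elements) utils::head(inter, max_elements) else character(0)
    if (length(idx) >= 2L) {
      sz <- sizes[idx]
      rec$expected[i] <- mset_expected(sz, n_bg)
      rec$fe[i] <- if (all(sz > 0)) mset_fe(rec$observed[i], sz, n_bg) else NA_real_
      lp <- pmset(rec$observed[i], sz, n_bg, log.p = TRUE)
      rec$log10_p[i] <- lp / log(10)
      rec$p[i] <- exp(lp)
    }
  }
  tested <- rec$degree >= 2L
  M <- 2^t - t - 1
  rec$log10_p_adjusted[tested] <-
    adjust_log10p(rec$log10_p[tested], method = p_adjust, m = M)
  rec$p_adjusted[tested] <- 10^rec$log10_p_adjusted[tested]
  rec$elements <- I(elements)
  rec <- rec[rec$degree >= min_degree, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, set_sizes = sizes, n = n_bg, M = M,
                 p_adjust = p_adjust, call = match.call()),
            class = "msetest")
}

#' Order intersection records
#'
#' Stable sort of an [mset_test()] record table.  `"size"` orders by observed
#' intersection size (largest first), `"degree"` by combination degree
#' (ascending), `"p_value"` by adjusted p-value (most significant first, on
#' the log scale so underflowed values order correctly), `"set_order"` keeps
#' the enumeration order.  Ties are broken by barcode lexicographic order.
#'
#' @param records The `records` data frame of an `"msetest"` object.
#' @param by One of `"size"`, `"degree"`, `"p_value"`, `"set_order"`.
#' @return The reordered data frame.
#' @export
sort_records <- function(records, by = c("size", "degree", "p_value", "set_order")) {
  by <- match.arg(by)
  ord <- switch(by,
    size = order(-records$observed, records$barcode),
    degree = order(records$degree, records$barcode),
    p_value = order(records$log10_p_adjusted, records$barcode),
    set_order = order(records$barcode)
  )
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.msetest <- function(x, ...) {
  t <- length(x$set_sizes)
  cat(sprintf("Exact multi-set intersection analysis: %d sets, background n = %d\n",
              t, x$n))
  cat(sprintf("  sets: %s\n",
              paste(sprintf("%s (%d)", names(x$set_sizes), x$set_sizes),
                    collapse = ", ")))
  tested <- x$records[x$records$degree >= 2L, , drop = FALSE]
  cat(sprintf("  %d combinations tested (%s-adjusted over M = %d)\n",
              nrow(tested), x$p_adjust, x$M))
  if (nrow(tested)) {
    top <- tested[which.min(tested$log10_p_adjusted), ]
    cat(sprintf("  most significant: %s (observed %d, FE %.3g, adjusted P %s)\n",
                top$intersection, top$observed, top$fe,
                format_p_log10(top$log10_p_adjusted)))
  }
  invisible(x)
}

#' Summarize a multi-set intersection analysis
#'
#' Builds the tabulation of all combinations: observed and expected sizes,
#' fold enrichment, raw and adjusted p-values.  The `Table` component is
#' suitable for `write.csv`; probabilities are formatted in scientific
#' notation from their log10 values, so entries below the double underflow
#' floor remain exact strings rather than `0`.
#'
#' @param object An `"msetest"` fit.
#' @param sort.by Row order, see [sort_records()].
#' @param ... Unused.
#' @return A list of class `"summary.msetest"` with components `Table`
#'   (data frame with columns `Intersections`, `Degree`, `Observed.Overlap`,
#'   `Expected.Overlap`, `FE`, `P.value`, `adjusted.P.value`, `log10.P`,
#'   `Elements`), `n`, `M` and `p_adjust`.
#' @export
summary.msetest <- function(object, sort.by = "p_value", ...) {
  rec <- sort_records(object$records, by = sort.by)
  tab <- data.frame(
    Intersections = rec$intersection,
    Degree = rec$degree,
    Observed.Overlap = rec$observed,
    Expected.Overlap = ifelse(is.na(rec$expected), "",
                              formatC(rec$expected, format = "g", digits = 6)),
    FE = ifelse(is.na(rec$fe), "", formatC(rec$fe, format = "g", digits = 4)),
    P.value = ifelse(is.na(rec$log10_p), "", format_p_log10(rec$log10_p)),
    adjusted.P.value = ifelse(is.na(rec$log10_p_adjusted), "",
                              format_p_log10(rec$log10_p_adjusted)),
    log10.P = ifelse(is.na(rec$log10_p), "",
                     formatC(rec$log10_p, format = "f", digits = 4)),
    Elements = vapply(rec$elements, paste, character(1), collapse = ", "),
    stringsAsFactors = FALSE
  )
  structure(list(Table = tab, n = object$n, M = object$M,
                 p_adjust = object$p_adjust, sort.by = sort.by),
            class = "summary.msetest")
}

#' @export
print.summary.msetest <- function(x, max_rows = 20L, ...) {
  cat(sprintf("Multi-set intersection summary (n = %d, M = %d, %s adjustment)\n",
              x$n, x$M, x$p_adjust))
  show <- utils::head(x$Table[, setdiff(names(x$Table), "Elements")], max_rows)
  print(show, right = FALSE)
  if (nrow(x$Table) > max_rows) {
    cat(sprintf("... %d more rows\n", nrow(x$Table) - max_rows))
  }
  invisible(x)
}

#' Write the intersection summary table to CSV
#'
#' Deterministic CSV export of [summary.msetest()]'s `Table`: same input,
#' byte-identical output.
#'
#' @param fit An `"msetest"` object.
#' @param path Output file path.
#' @param sort.by Row order, see [sort_records()].
#' @return `path`, invisibly.
#' @export
write_mset_summary <- function(fit, path, sort.by = "p_value") {
  tab <- summary(fit, sort.by = sort.by)$Table
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
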