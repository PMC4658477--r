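# Combination enumeration, statistics per record, multiple-testing
# adjustment, sorting and the summary table.

test_that("enumeration covers every combination with statistics for degree >= 2", {
  fit <- mset_test(seven_set_collection())
  expect_identical(nrow(fit$records), 127L)                 # 2^7 - 1
  tested <- fit$records[fit$records$degree >= 2, ]
  expect_identical(nrow(tested), 120L)                      # 2^7 - 7 - 1
  expect_identical(fit$M, 120)
  expect_true(all(is.finite(tested$log10_p)))
  expect_true(all(is.finite(tested$fe) | tested$observed == 0))
  # degree-1 records carry no statistics
  single <- fit$records[fit$records$degree == 1, ]
  expect_true(all(is.na(single$p)))
  expect_identical(single$observed[order(single$barcode, decreasing = TRUE)],
                   unname(fit$set_sizes))
  # min_degree filters the output but not the family
  fit2 <- mset_test(seven_set_collection(), min_degree = 2)
  expect_identical(nrow(fit2$records), 120L)
  expect_identical(fit2$M, 120)
})

test_that("identical sets share everything; fixtures reproduce planted overlaps", {
  s <- paste0("g", 1:12)
  fit <- mset_test(list(A = s, B = s, C = s), n = 100)
  deg2 <- fit$records[fit$records$degree >= 2, ]
  expect_true(all(deg2$observed == 12L))
  sc <- make_fixture_collection(200, c(30, 40, 50),
                                planted = list("S1&S2&S3" = 2, "S1&S2" = 5),
                                seed = 3)
  fit2 <- mset_test(sc)
  rec <- fit2$records
  expect_identical(rec$observed[rec$intersection == "S1 & S2 & S3"], 2L)
  expect_identical(rec$observed[rec$intersection == "S1 & S2"], 5L)
  # statistics agree with the standalone exact test on the same sizes
  one <- mset_exact_test(5, c(30, 40), 200)
  expect_equal(rec$p[rec$intersection == "S1 & S2"], one$p.value)
  expect_equal(rec$fe[rec$intersection == "S1 & S2"], one$fe)
})

test_that("observed sizes are monotone over nested combinations", {
  fit <- mset_test(seven_set_collection(seed = 21))
  rec <- fit$records
  bits <- strsplit(rec$barcode, "")
  set.seed(8)
  for (i in sample(nrow(rec), 30)) {
    for (j in sample(nrow(rec), 10)) {
      if (all(bits[[j]] >= bits[[i]]) && i != j) {
        # j's combination contains i's
        expect_lte(rec$observed[j], rec$observed[i])
      }
    }
  }
})

test_that("Bonferroni and BH adjustments operate correctly, including in log space", {
  # capped at one
  expect_equal(msetest:::adjust_log10p(log10(0.5), "bonferroni", m = 4), 0)
  # multiplier equals the family size when no cap binds
  fit <- mset_test(seven_set_collection())
  tested <- fit$records[fit$records$degree >= 2 &
                          fit$records$p_adjusted < 1, ]
  expect_true(all(abs(tested$log10_p_adjusted - tested$log10_p - log10(120)) < 1e-9))
  expect_true(all(fit$records$p_adjusted >= fit$records$p, na.rm = TRUE))
  # BH agrees with stats::p.adjust on non-underflowing inputs
  set.seed(5)
  p <- sort(runif(40)^3)
  got <- 10^msetest:::adjust_log10p(log10(p), "bh", m = 40)
  expect_equal(got, p.adjust(p, method = "BH"), tolerance = 1e-12)
  # bonferroni route against p.adjust as well
  got_b <- 10^msetest:::adjust_log10p(log10(p), "bonferroni", m = 40)
  expect_equal(got_b, p.adjust(p, method = "bonferroni"), tolerance = 1e-12)
  # log-space BH keeps underflowed values ordered and above the raw values
  lp <- c(-500, -400, -2, -0.5)
  adj <- msetest:::adjust_log10p(lp, "bh", m = 4)
  expect_true(all(adj >= lp))
  expect_true(!is.unsorted(adj))
})

test_that("sorting is stable with barcode tie-breaks", {
  fit <- mset_test(seven_set_collection())
  by_deg <- sort_records(fit$records, "degree")
  expect_true(!is.unsorted(by_deg$degree))
  by_p <- sort_records(fit$records, "p_value")
  finite <- by_p$log10_p_adjusted[!is.na(by_p$log10_p_adjusted)]
  expect_true(!is.unsorted(finite))
  by_size <- sort_records(fit$records, "size")
  expect_true(!is.unsorted(-by_size$observed))
  ties <- by_size[by_size$observed == by_size$observed[1], ]
  expect_true(!is.unsorted(ties$barcode))
})

test_that("the summary table matches the specified layout and is deterministic", {
  sc <- make_fixture_collection(100, c(10, 12, 15), seed = 9)
  fit <- mset_test(sc)
  tab <- summary(fit, sort.by = "degree")$Table
  expect_identical(names(tab),
                   c("Intersections", "Degree", "Observed.Overlap",
                     "Expected.Overlap", "FE", "P.value", "adjusted.P.value",
                     "log10.P", "Elements"))
  expect_identical(nrow(tab), 7L)
  expect_true(all(tab$P.value[tab$Degree == 1] == ""))
  expect_match(tab$P.value[tab$Degree == 2][1], "^\\d\\.\\d{3}e[-+]\\d+$")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_mset_summary(fit, f1)
  write_mset_summary(fit, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("probability formatting survives the underflow floor", {
  expect_identical(msetest:::format_p_log10(-Inf), "0")
  expect_identical(msetest:::format_p_log10(log10(0.05)), "5.000e-02")
  # a value far below 1e-308 keeps mantissa and exponent
  expect_identical(msetest:::format_p_log10(-408.1124 + log10(120) - log10(120)),
                   msetest:::format_p_log10(-408.1124))
  expect_match(msetest:::format_p_log10(-408.1124), "e-409$")
})

test_that("p-values are calibrated under the null", {
  # 500 independent uniform collections; the observed overlap follows the
  # exact pmf and the upper-tail p-values are super-uniform (discrete test)
  n <- 100; sizes <- c(20, 30, 40); reps <- 500
  theo <- dmset(0:min(sizes), sizes, n)
  tails <- pmset(0:min(sizes), sizes, n)
  set.seed(1234)
  xs <- integer(reps)
  for (r in seq_len(reps)) {
    draws <- lapply(sizes, function(k) sample.int(n, k))
    xs[r] <- length(Reduce(intersect, draws))
  }
  # chi-square goodness of fit, pooling the tail so expected counts >= 5
  cut <- max(which(theo * reps >= 5))
  probs <- c(theo[1:cut], sum(theo[-(1:cut)]))
  counts <- c(tabulate(xs + 1L, nbins = cut)[1:cut], sum(xs + 1L > cut))
  gof <- suppressWarnings(chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 0.001)
  # super-uniformity: P(p <= alpha) <= alpha within Monte-Carlo error
  pvals <- tails[xs + 1L]
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / reps))
  }
})

test_that("configuration errors are caught", {
  expect_error(mset_test(list(A = letters[1:3], B = letters[2:4])),
               "background")
  expect_error(mset_test(list(A = letters[1:3]), n = 10), "at least two sets")
  sc <- tiny_collection()
  expect_error(sort_records(mset_test(sc)$records, "bogus"))
})
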