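# Set collections: construction, file formats, overlap counting and
# exclusive regions.

test_that("GMT parsing follows the Broad dialect", {
  p <- write_tmp_gmt(c("S1\tdesc\ta\tb\tc", "S2\tdesc\tb\tc"))
  sc <- read_gmt(p)
  expect_named(sc$sets, c("S1", "S2"))
  expect_setequal(sc$sets$S1, c("a", "b", "c"))
  expect_setequal(sc$sets$S2, c("b", "c"))
  # duplicates within a line are removed with a warning
  p2 <- write_tmp_gmt("S1\tdesc\ta\ta\tb")
  expect_warning(sc2 <- read_gmt(p2), "duplicated")
  expect_setequal(sc2$sets$S1, c("a", "b"))
  # malformed and duplicated-name lines name the offending line
  p3 <- write_tmp_gmt(c("S1\tdesc\ta", "S1only2fields\tx"))
  expect_error(read_gmt(p3), "line 2")
  p4 <- write_tmp_gmt(c("S1\tdesc\ta", "S1\tdesc\tb"))
  expect_error(read_gmt(p4), "duplicated set name")
})

test_that("column files are parsed with ragged columns, trimming and empty cells", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "g1\tg4", "g2 \tg5", "g3\t"), p)
  sc <- read_set_columns(p)
  expect_equal(lengths(sc$sets), c(A = 3L, B = 2L))
  expect_true("g2" %in% sc$sets$A)  # trimmed
  # csv variant and empty column body
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "g1,", "g2,"), p2)
  expect_message(sc2 <- read_set_columns(p2), "empty set")
  expect_equal(lengths(sc2$sets), c(A = 2L, B = 0L))
  # empty header cell is an error
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t", "g1\tg2"), p3)
  expect_error(read_set_columns(p3), "header")
})

test_that("GMT round-trips through write_gmt", {
  sc <- tiny_collection()
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sc, p)
  back <- read_gmt(p, background = 10)
  expect_identical(back$sets, sc$sets)
})

test_that("explicit universes police foreign identifiers", {
  uni <- paste0("g", 1:10)
  expect_error(
    set_collection(list(A = c("g1", "zz")), background = uni),
    "absent from the background"
  )
  expect_warning(
    sc <- set_collection(list(A = c("g1", "zz")), background = uni,
                         drop_foreign = TRUE),
    "dropping"
  )
  expect_identical(sc$sets$A, "g1")
  expect_identical(sc$background_size, 10L)
  # background smaller than the union is rejected
  expect_error(set_collection(list(A = letters[1:5], B = letters[4:8]),
                              background = 7), "smaller than the union")
})

test_that("count_overlap uses total (non-exclusive) semantics", {
  sc <- tiny_collection()
  expect_identical(count_overlap(sc, c("A", "B", "C")), 1L)  # {c}
  expect_identical(count_overlap(sc, c("A", "B")), 2L)       # {b, c}
  expect_identical(count_overlap(sc, "A"), 3L)
  same <- set_collection(list(A = c("a", "b", "c"), B = c("a", "b", "c")),
                         background = 5)
  expect_identical(count_overlap(same, c("A", "B")), 3L)
  disj <- set_collection(list(A = "a", B = "b", C = "c"), background = 5)
  expect_identical(count_overlap(disj, c("A", "B")), 0L)
  expect_error(count_overlap(sc, c("A", "Z")), "unknown set")
})

test_that("overlap is monotone nonincreasing in the combination", {
  sc <- seven_set_collection()
  nms <- names(sc$sets)
  set.seed(4)
  for (i in 1:10) {
    small <- sample(nms, 2)
    big <- union(small, sample(nms, 2))
    expect_gte(count_overlap(sc, small), count_overlap(sc, big))
  }
})

test_that("exclusive regions partition the union and sum to total overlaps", {
  sc <- set_collection(list(A = c("a", "b"), B = c("b", "c")), background = 5)
  reg <- exclusive_region_counts(sc)
  expect_mapequal(as.list(reg), list(`10` = 1L, `01` = 1L, `11` = 1L))
  # single set: one region
  one <- set_collection(list(A = letters[1:4]), background = 5)
  expect_mapequal(as.list(exclusive_region_counts(one)), list(`1` = 4L))
  # disjoint sets populate only degree-1 barcodes
  disj <- set_collection(list(A = "a", B = "b", C = "c"), background = 5)
  expect_true(all(vapply(strsplit(names(exclusive_region_counts(disj)), ""),
                         function(b) sum(b == "1"), 1L) == 1L))
  # sum of regions containing a combination equals its total overlap
  sc7 <- seven_set_collection()
  reg7 <- exclusive_region_counts(sc7)
  bits <- strsplit(names(reg7), "")
  for (combo in list(c(1L, 3L), c(2L, 5L, 7L), c(1L, 2L, 3L, 4L))) {
    covered <- vapply(bits, function(b) all(b[combo] == "1"), TRUE)
    expect_identical(sum(reg7[covered]),
                     count_overlap(sc7, names(sc7$sets)[combo]))
  }
  expect_identical(sum(reg7), length(unique(unlist(sc7$sets))))
})
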