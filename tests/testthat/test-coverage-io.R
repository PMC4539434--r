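test_that("bedGraph intervals expand to 1-based inclusive per-base counts", {
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t103\t5", "chr1\t103\t105\t2"), bg)
  profs <- read_coverage(bg, sample_id = "s1")
  expect_length(profs, 1)
  expect_equal(profs[[1]]$positions, 101:105)
  expect_equal(profs[[1]]$counts, c(5, 5, 5, 2, 2))
})

test_that("empty input yields an empty collection; unsorted input is sorted", {
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_length(read_coverage(empty), 0)

  tsv <- withr::local_tempfile()
  writeLines(c("gene_id\tsample_id\tposition\tcount",
               "g1\ts1\t30\t7", "g1\ts1\t10\t1", "g1\ts1\t20\t4"), tsv)
  p <- read_coverage(tsv)[[1]]
  expect_equal(p$positions, c(10, 20, 30))
  expect_equal(p$counts, c(1, 4, 7))
})

test_that("malformed coverage and label inputs are hard errors", {
  tsv <- withr::local_tempfile()
  writeLines(c("gene_id\tsample_id\tposition\tcount",
               "g1\ts1\t10\t-2"), tsv)
  expect_error(read_coverage(tsv), "negative count")

  dup <- withr::local_tempfile()
  writeLines(c("gene_id\tsample_id\tposition\tcount",
               "g1\ts1\t10\t2", "g1\ts1\t10\t3"), dup)
  expect_error(read_coverage(dup), "duplicate")

  fx <- write_coverage_fixture()
  lab2 <- withr::local_tempfile()
  writeLines(c("sample_id\tgroup", "sampA\tnormal"), lab2)
  expect_error(read_coverage(fx$coverage, lab2), "sampB")
})

test_that("labels attach groups to profiles", {
  fx <- write_coverage_fixture()
  profs <- read_coverage(fx$coverage, fx$labels)
  grp <- vapply(profs, function(p) p$group, "")
  ids <- vapply(profs, function(p) p$sample_id, "")
  expect_equal(unname(grp[order(ids)]), c("normal", "tumor"))
})

test_that("normalization is log1p of scaled counts, zeros map to zero", {
  p <- read_coverage(write_coverage_fixture()$coverage)[[1]]
  cv <- normalize(p, scale_factor = 2)
  expect_equal(cv$y, log1p(p$counts / 2))
  expect_equal(cv$y[p$counts == 0], rep(0, sum(p$counts == 0)))
  # count (e-1)*s at scale s gives y = 1 exactly
  p2 <- p; p2$counts <- rep((exp(1) - 1) * 7, length(p2$counts))
  expect_equal(normalize(p2, 7)$y, rep(1, length(p2$counts)))
  # constant counts at scale 1 give a constant curve
  p3 <- p; p3$counts <- rep(4, length(p3$counts))
  expect_equal(normalize(p3, 1)$y, rep(log(5), length(p3$counts)))
  expect_error(normalize(p, 0), "positive")
  # monotone in count at fixed scale
  expect_true(all(diff(normalize(p, 3)$y[order(p$counts)]) >= 0))
})

test_that("explicit gene interval fills unobserved bases with zero counts", {
  tsv <- withr::local_tempfile()
  writeLines(c("gene_id\tsample_id\tposition\tcount",
               "g1\ts1\t12\t3", "g1\ts1\t13\t3", "g1\ts1\t15\t2",
               "g1\ts1\t18\t1"), tsv)
  cv <- normalize(read_coverage(tsv)[[1]], 1, interval = c(10, 19))
  expect_length(cv$t, 10)
  expect_equal(cv$t[1], 0)
  expect_equal(cv$t[10], 100)
  expect_equal(cv$y[c(1, 2, 5, 7, 8, 10)], rep(0, 6))
})

test_that("position rescaling is affine with exact endpoints and inverse", {
  expect_equal(rescale_positions(c(1000, 1250, 1500, 2000), 1000, 2000),
               c(0, 25, 50, 100))
  pos <- c(7, 19, 23, 40)
  t <- rescale_positions(pos, 5, 45)
  expect_equal(5 + t / 100 * 40, pos, tolerance = 1e-14)
  expect_error(rescale_positions(1:3, 5, 5), "b > a")
  expect_error(rescale_positions(1:3, 2, 9), "outside")
})

test_that("curve TSV round-trips bit-exactly", {
  curves <- inspan_curves(3, n_pos = 25, seed = 4)
  curves[[2]]$group <- "tumor"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curves(curves, path)
  back <- read_curves(path)
  ids <- vapply(back, function(cv) cv$sample_id, "")
  back <- back[order(ids)]
  for (i in seq_along(curves)) {
    expect_identical(back[[i]]$t, curves[[i]]$t)
    expect_identical(back[[i]]$y, curves[[i]]$y)
    expect_identical(back[[i]]$group, curves[[i]]$group)
  }
})

test_that("scale factors are O(1) ratios to the median library size", {
  profs <- read_coverage(write_coverage_fixture()$coverage)
  sf <- compute_scale_factors(profs)
  expect_equal(sort(unname(sf)), c(0.5, 1.5), tolerance = 1e-12)
  expect_equal(unname(sf["sampB"] / sf["sampA"]), 3)
})
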