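test_that("degenerate identical spores give zero spread and exact percentiles", {
  s <- summarize_spores(rep(11, 50), rep(6, 50))
  expect_equal(s$n, 50)
  expect_false(s$protocol_warning)
  expect_equal(s$mean_length, 11)
  expect_equal(s$mean_width, 6)
  expect_equal(s$median_length, 11)
  expect_equal(s$sd_length, 0)
  expect_equal(s$p5_length, 11)
  expect_equal(s$p95_length, 11)
  expect_equal(s$mean_q, 11 / 6, tolerance = 1e-10)
})

test_that("spore summary matches hand arithmetic on a four-spore set", {
  s <- summarize_spores(c(10, 11, 12, 13), c(5, 6, 5, 6))
  expect_equal(s$mean_length, 11.5)
  expect_equal(s$mean_width, 5.5)
  # per-spore Q = 2.0, 1.8333, 2.4, 2.1667; mean of ratios, not 11.5/5.5
  expect_equal(s$mean_q, mean(c(10 / 5, 11 / 6, 12 / 5, 13 / 6)))
  expect_equal(s$mean_q, 2.1, tolerance = 1e-4)
  expect_equal(s$sd_length, sd(c(10, 11, 12, 13)))
  expect_equal(s$sd_length, 1.2910, tolerance = 1e-4)
  expect_true(s$protocol_warning)  # n < 50
})

test_that("summary recovers the location of a seeded spore population", {
  # emulates a holotype measured at n = 102 with length location 11.9 and
  # scale 0.84: the sample mean must sit within 3 standard errors and the
  # 5/95 percentiles near the printed 10.4-13.2 envelope
  set.seed(42)
  n <- 102
  len <- qnorm(runif(n, pnorm(8, 11.9, 0.84), pnorm(16, 11.9, 0.84)),
               11.9, 0.84)
  wid <- qnorm(runif(n, pnorm(4, 6.5, 0.39), pnorm(9, 6.5, 0.39)), 6.5, 0.39)
  s <- summarize_spores(len, wid)
  expect_lt(abs(s$mean_length - 11.9), 3 * 0.84 / sqrt(n))
  expect_lt(abs(s$p5_length - 10.4), 0.5)
  expect_lt(abs(s$p95_length - 13.2), 0.5)
})

test_that("spore summary invariants hold on random samples", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(5:120, 1)
    len <- runif(n, 8, 16); wid <- runif(n, 4, 9)
    s <- summarize_spores(len, wid)
    expect_equal(s$n, n)
    # percentiles are order-statistic interpolations bounded by min/max
    expect_true(s$p5_length >= min(len) && s$p95_length <= max(len))
    expect_true(s$p5_length <= s$median_length)
    expect_true(s$median_length <= s$p95_length)
    expect_true(s$mean_length >= min(len) && s$mean_length <= max(len))
    expect_true(s$p5_q <= s$median_q && s$median_q <= s$p95_q)
    # sd is zero iff all values identical
    expect_identical(s$sd_width == 0, length(unique(wid)) == 1L)
    # permutation invariance
    p <- sample(n)
    expect_equal(unclass(summarize_spores(len[p], wid[p])), unclass(s))
  }
})

test_that("spore summaries reject empty and non-positive input", {
  expect_error(summarize_spores(numeric(), numeric()), "no measurements")
  expect_error(summarize_spores(c(10, -1), c(5, 5)), "invalid measurement")
  expect_error(summarize_spores(c(10, 11), c(5, 0)), "invalid measurement")
  expect_error(summarize_spores(c(10, 11), 5), "differ in length")
})

test_that("cystidium ratios are means of per-cystidium ratios", {
  one <- summarize_cheilocystidia(45, 7, 7, 7)
  expect_equal(one$mean_ratio_am, 1)
  expect_equal(one$mean_ratio_ab, 1)
  expect_equal(one$mean_ratio_bm, 1)
  two <- summarize_cheilocystidia(c(40, 60), c(8, 6), c(4, 4), c(4, 8))
  expect_equal(two$mean_ratio_am, (2.0 + 1.5) / 2)    # 1.75
  expect_equal(two$mean_ratio_ab, (2.0 + 0.75) / 2)   # 1.375
  expect_equal(two$mean_ratio_bm, (1.0 + 2.0) / 2)    # 1.5
  expect_true(two$protocol_warning_full)
})

test_that("ratio of mean widths is reported separately and can disagree", {
  # aggregate means 7.4 (apex), 5 (middle), 6.5 (base) give a ratio of
  # means A/M = 1.48, which may fall outside the mean-of-ratios range;
  # construct such a case explicitly
  cs <- summarize_cheilocystidia(c(45, 45), c(10, 4.8), c(4, 6), c(7, 6))
  expect_equal(cs$ratio_of_means_am, mean(c(10, 4.8)) / mean(c(4, 6)))
  expect_false(isTRUE(all.equal(cs$ratio_of_means_am, cs$mean_ratio_am)))
  expect_equal(7.4 / 5, 1.48)
})

test_that("apex-width survey is folded into apex statistics and flags", {
  cs <- summarize_cheilocystidia(c(40, 50), c(7, 8), c(5, 5), c(6, 6),
                                 apex_widths = c(7.5, 8.5, 7, 8))
  expect_equal(cs$n_apex_only, 4)
  expect_equal(cs$mean_a, mean(c(7, 8, 7.5, 8.5, 7, 8)))
  expect_true(cs$protocol_warning_apex)
  expect_error(summarize_cheilocystidia(numeric(), numeric(), numeric(),
                                        numeric()), "no measurements")
})

test_that("O/P/D code strings parse with parenthetical rare states", {
  a <- parse_opd("O1O2")
  expect_setequal(a$class, c("O1", "O2"))
  expect_false(any(a$parenthetical))
  b <- parse_opd("(D2) D3 (D4)")
  expect_setequal(b$class, c("D2", "D3", "D4"))
  expect_true(b$parenthetical[b$class == "D2"])
  expect_false(b$parenthetical[b$class == "D3"])
  expect_true(b$parenthetical[b$class == "D4"])
  expect_true(opd_has(b, "D2"))
  expect_false(opd_many(b, "D2"))
  expect_true(opd_many(b, "D3"))
  # order-insensitive
  expect_equal(sort(parse_opd("P1P0")$class), sort(parse_opd("P0P1")$class))
})

test_that("O/P/D parser rejects empty and unknown tokens", {
  expect_error(parse_opd(""), "empty")
  expect_error(parse_opd("O1X2"), "unknown token")
  expect_error(parse_opd("O9"), "unknown token")
  expect_error(parse_opd("Q1"), "unknown token")
})

test_that("measurement files round-trip through the documented formats", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("length,width", "11.2,6.0", "10.8,5.9"), f)
  d <- read_spore_measurements(f)
  expect_equal(d$length, c(11.2, 10.8))
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("length\tapex\tmiddle\tbase", "45\t7\t5\t8"), f2)
  d2 <- read_cystidia_measurements(f2)
  expect_equal(d2$base, 8)
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("apex", "7.5", "8"), f3)
  expect_equal(read_apex_widths(f3), c(7.5, 8))
  expect_error(read_spore_measurements(f3), "columns")
  # one-row-per-collection export
  s <- summarize_spores(d$length, d$width)
  row <- as.data.frame(s)
  expect_equal(nrow(row), 1L)
  expect_true(all(c("mean_length", "p95_q", "sd_width") %in% names(row)))
})

test_that("sample means land within 4 sigma/sqrt(n) across 200 seeds", {
  mu <- 11; sigma <- 0.6; n <- 60
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    len <- rnorm(n, mu, sigma)
    wid <- rnorm(n, 6, 0.3)
    abs(summarize_spores(len, wid)$mean_length - mu) <= 4 * sigma / sqrt(n)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
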