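test_that("count_matrix enforces its invariants and names offending cells", {
  expect_s3_class(tiny_cm(), "count_matrix")
  bad <- rbind(S1 = c(1, -1), S2 = c(2, 3))
  colnames(bad) <- c("a", "b")
  expect_error(count_matrix(bad, as.Date(c("2016-01-01", "2016-01-02"))),
               "S1.*b.*-1")
  expect_error(count_matrix(rbind(S1 = c(1.5, 2), S2 = c(1, 1)),
                            as.Date(c("2016-01-01", "2016-01-02"))),
               "non-negative integers")
  m <- rbind(S1 = c(1L, 2L), S1 = c(3L, 4L))
  expect_error(count_matrix(m, as.Date(c("2016-01-01", "2016-01-02"))),
               "duplicate sample ids")
  expect_error(count_matrix(tiny_cm()$counts, as.Date("2016-01-01")),
               "one date per sample")
})

test_that("count tables round-trip through tsv and csv", {
  cm <- tiny_cm()
  for (fmt in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_count_table(cm, path, fmt)
    back <- suppressMessages(read_count_table(path, fmt))
    expect_identical(back$counts, cm$counts)
    expect_identical(back$dates, cm$dates)
  }
})

test_that("biom-json input matches the delimited reader", {
  cm <- tiny_cm()
  b <- biomformat::make_biom(t(cm$counts))
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  back <- suppressMessages(
    read_count_table(path, "biom-json", dates = cm$dates))
  expect_equal(back$counts[cm$sample_ids, cm$asv_ids], cm$counts)
})

test_that("relative abundance normalises rows and flags zero samples", {
  cm <- tiny_cm()
  ra <- relative_abundance(cm)
  expect_equal(rowSums(ra$values), c(S1 = 1, S2 = 1, S3 = 1))
  expect_equal(unname(ra$values["S1", ]), c(0.6, 0.2, 0.2))
  z <- count_matrix(rbind(S1 = c(0L, 0L), S2 = c(0L, 7L)),
                    as.Date(c("2016-01-01", "2016-01-08")))
  raz <- relative_abundance(z)
  expect_identical(raz$zero_samples, "S1")
  expect_equal(unname(raz$values["S2", ]), c(0, 1))
})

test_that("ecotype collapsing is additive and conserves sample totals", {
  cm <- tiny_cm()
  tax <- c(asvA = "Ia.3", asvB = "Ia.3", asvC = "IV")
  col <- collapse_by_ecotype(cm, tax)
  expect_equal(unname(col$counts[, "Ia.3"]), c(8L, 4L, 7L))
  expect_equal(rowSums(col$counts), rowSums(cm$counts))
  # one ASV per label: identity up to renaming
  col2 <- collapse_by_ecotype(cm, tiny_tax())
  expect_equal(sort(colnames(col2$counts)), sort(unname(tiny_tax())))
  expect_error(collapse_by_ecotype(cm, tax[-1]), "asvA")
})

test_that("unknown ecotype labels map to 'other' with a warning", {
  expect_warning(tx <- taxonomy_map(c(a = "Ia.3", b = "weird")), "weird")
  expect_identical(unname(tx["b"]), "other")
})

test_that("sar11_fraction is the SAR11 read share per sample", {
  cm <- tiny_cm()
  frac <- sar11_fraction(cm, tiny_tax())
  expect_equal(unname(frac), c(8 / 10, 4 / 10, 7 / 10))
  all_sar <- c(asvA = "Ia.3", asvB = "Ib", asvC = "IIa.B")
  expect_equal(unname(sar11_fraction(cm, all_sar)), rep(1, 3))
  none <- c(asvA = "other", asvB = "other", asvC = "other")
  expect_equal(unname(sar11_fraction(cm, none)), rep(0, 3))
})

test_that("rarefaction subsamples to exact depth, deterministically by seed", {
  set.seed(99)
  counts <- matrix(rpois(60, 40), nrow = 4)
  rownames(counts) <- paste0("S", 1:4)
  cm <- count_matrix(counts, weekly_dates(4))
  r1 <- rarefy(cm, depth = 100, seed = 3, floor = 1)
  r2 <- rarefy(cm, depth = 100, seed = 3, floor = 1)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(rowSums(r1$counts) == 100))
  expect_true(all(r1$counts <= cm$counts))
  # sample total == depth leaves counts unchanged
  tot <- sum(cm$counts[1, ])
  rfull <- suppressMessages(rarefy(cm, depth = tot, seed = 1, floor = 1))
  expect_identical(rfull$counts["S1", ], cm$counts["S1", ])
  # depth = 1 forces a single read
  rone <- rarefy(cm, depth = 1, seed = 1, floor = 1)
  expect_true(all(rowSums(rone$counts) == 1))
  expect_error(rarefy(cm, depth = 10000, floor = 1), "no samples retained")
})

test_that("samples below depth are dropped and reported", {
  counts <- rbind(S1 = c(5L, 5L), S2 = c(500L, 500L))
  cm <- count_matrix(counts, weekly_dates(2))
  expect_message(r <- rarefy(cm, depth = 100, seed = 1, floor = 1), "S1")
  expect_identical(attr(r, "dropped"), "S1")
  expect_identical(rownames(r$counts), "S2")
})

test_that("rarefied counts match the hypergeometric expectation", {
  # one sample, N = 60 reads over 3 ASVs, depth 20: E[count] = c * d / N
  counts <- rbind(S1 = c(30L, 20L, 10L))
  cm <- count_matrix(counts, as.Date("2016-01-01"))
  n_draw <- 1500
  draws <- vapply(seq_len(n_draw), function(s)
    rarefy(cm, depth = 20, seed = s, floor = 1)$counts[1, ],
    numeric(3))
  expected <- c(30, 20, 10) * 20 / 60
  # multivariate hypergeometric variance for 3 Monte-Carlo SE bands
  v <- c(30, 20, 10) / 60
  se <- sqrt(20 * v * (1 - v) * (60 - 20) / (60 - 1) / n_draw)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se))
})
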