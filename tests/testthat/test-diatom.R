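mk_counts <- function() {
  count_matrix(as.Date(c("2011-06-15", "2011-12-15")),
               matrix(c(210, 30, 60, 30, 210, 60), nrow = 2, byrow = TRUE,
                      dimnames = list(NULL, c("ACHMIN", "AMPPED", "GOMPAR"))))
}

test_that("relative abundances are proportions that sum to one", {
  one <- count_matrix(as.Date("2011-06-15"),
                      matrix(300, 1, 1, dimnames = list(NULL, "ACHMIN")))
  expect_equal(relative_abundance(one)[1, 1], 1)
  two <- count_matrix(as.Date("2011-06-15"),
                      matrix(c(150, 150), 1, 2,
                             dimnames = list(NULL, c("ACHMIN", "AMPPED"))))
  expect_equal(unname(relative_abundance(two)[1, ]), c(0.5, 0.5))
  set.seed(3)
  for (rep in 1:10) {
    m <- matrix(rpois(24, 20) + 1, 4, 6,
                dimnames = list(NULL, paste0("T", 1:6)))
    expect_equal(unname(rowSums(relative_abundance(m))), rep(1, 4),
                 tolerance = 1e-12)
  }
  expect_error(relative_abundance(matrix(0, 1, 2,
                                         dimnames = list("2011-06-15", NULL))),
               "empty sample.*2011-06-15")
  expect_error(count_matrix(as.Date("2011-06-15"),
                            matrix(c(0, 0), 1, 2,
                                   dimnames = list(NULL, c("A", "B")))),
               "empty sample")
})

test_that("dominance ratios divide counts and flag undefined samples", {
  cm <- mk_counts()
  dr <- dominance_ratio(cm, "ACHMIN", "AMPPED")
  expect_equal(dr$ratio, c(7, 1 / 7))
  expect_equal(dominance_ratio(cm, "ACHMIN", "GOMPAR")$ratio, c(3.5, 0.5))
  expect_error(dominance_ratio(cm, "ACHMIN", "NOPE"), "unknown taxon")
  cm0 <- count_matrix(as.Date("2011-06-15"),
                      matrix(c(100, 0, 200), 1, 3,
                             dimnames = list(NULL, c("A", "B", "C"))))
  expect_warning(dr0 <- dominance_ratio(cm0, "A", "B"), "undefined")
  expect_true(is.na(dr0$ratio) && dr0$undefined)
})

test_that("weighted mean sensitivity is the abundance- and weight-averaged score", {
  traits <- data.frame(taxon = c("X", "Y", "Z"),
                       sensitivity = c(3, 1, 5),
                       indicator_weight = c(2, 2, 2),
                       guild = "unknown")
  expect_equal(weighted_mean_sensitivity(c(X = 1), traits)$wms, 3)
  expect_equal(weighted_mean_sensitivity(c(Y = 0.5, Z = 0.5), traits)$wms, 3)
  # brute-force hand summation over <= 5 taxa with unequal weights
  tr5 <- data.frame(taxon = paste0("T", 1:5),
                    sensitivity = c(1.2, 2.5, 3.1, 4.0, 4.9),
                    indicator_weight = c(1, 3, 2, 1, 2),
                    guild = "unknown")
  set.seed(9)
  for (rep in 1:10) {
    a <- runif(5)
    a <- a / sum(a)
    names(a) <- tr5$taxon
    res <- weighted_mean_sensitivity(a, tr5)
    expect_equal(res$wms,
                 sum(a * tr5$sensitivity * tr5$indicator_weight) /
                   sum(a * tr5$indicator_weight))
    expect_equal(res$coverage, 1)
    # boundedness by the present taxa's scores
    expect_true(res$wms >= min(tr5$sensitivity) && res$wms <= max(tr5$sensitivity))
  }
  # coverage reported for partially covered samples; zero coverage errors
  expect_equal(weighted_mean_sensitivity(c(X = 0.6, QQ = 0.4), traits)$coverage,
               0.6)
  expect_error(weighted_mean_sensitivity(c(QQ = 1), traits), "no taxa")
})

test_that("the index maps sensitivity 1-5 onto 0-100", {
  expect_equal(index_from_wms(1), 0)
  expect_equal(index_from_wms(5), 100)
  expect_equal(index_from_wms(3), 50)
})

test_that("EQR is the complement ratio with a flagged cap", {
  expect_equal(as.numeric(eqr(20, 20)), 1)
  expect_equal(as.numeric(eqr(100, 20)), 0)
  expect_equal(as.numeric(eqr(60, 20)), 0.5)
  expect_warning(e <- eqr(0, 25), "capped")
  expect_equal(as.numeric(e), 1.25)
  expect_true(attr(e, "capped"))
  expect_error(eqr(50, 100), "degenerate")
  expect_error(eqr(-5, 20), "observed index")
  # monotone decreasing in the observed index
  obs <- seq(0, 100, by = 5)
  vals <- suppressWarnings(as.numeric(eqr(obs, 25)))
  expect_true(all(diff(vals) <= 0))
})

test_that("status bands follow the printed boundaries with upward ties", {
  expect_equal(as.character(classify_status(0.85)), "high")
  expect_equal(as.character(classify_status(0.8)), "high")
  expect_equal(as.character(classify_status(0.6)), "good")
  expect_equal(as.character(classify_status(0.4)), "moderate")
  expect_equal(as.character(classify_status(0.2)), "poor")
  expect_equal(as.character(classify_status(0.05)), "bad")
  expect_error(classify_status(-0.1), ">= 0")
  expect_true(is.ordered(classify_status(0.5)))
})

test_that("sample invariances hold: column order and count scaling", {
  traits <- default_trait_table()
  cm <- gen_counts(gen_sample_dates(2, seed = 5), seed = 5)$counts
  res <- eqr_series(cm, traits, expected_index = 25)
  perm <- sample(ncol(cm$counts))
  cm_p <- count_matrix(cm$dates, cm$counts[, perm])
  res_p <- eqr_series(cm_p, traits, expected_index = 25)
  expect_equal(res_p$table$eqr, res$table$eqr, tolerance = 1e-12)
  cm_d <- count_matrix(cm$dates, cm$counts * 2)
  res_d <- eqr_series(cm_d, traits, expected_index = 25)
  expect_equal(res_d$table$eqr, res$table$eqr, tolerance = 1e-12)
})

test_that("EQR series chain: clean and tolerant end-members and seasonality", {
  dts <- as.Date(c("2011-06-15", "2011-07-15", "2011-08-15"))
  clean <- count_matrix(dts, matrix(300, 3, 1, dimnames = list(NULL, "ACHMIN")))
  res_c <- suppressWarnings(eqr_series(clean, expected_index = 25))
  expect_true(all(res_c$table$eqr == 1.25 & res_c$table$capped))
  expect_true(all(res_c$table$status == "high"))
  tol <- data.frame(taxon = "TOL", sensitivity = 5, indicator_weight = 1,
                    guild = "unknown")
  dirty <- count_matrix(dts, matrix(300, 3, 1, dimnames = list(NULL, "TOL")))
  res_t <- eqr_series(dirty, tol, expected_index = 25)
  expect_true(all(res_t$table$eqr == 0))
  expect_true(all(res_t$table$status == "bad"))
  # seasonal assemblage switching: summer EQR above winter EQR
  higher <- 0L
  for (seed in 1:20) {
    dates <- gen_sample_dates(1, seed = seed)
    cm <- gen_counts(dates, seed = seed)
    es <- suppressWarnings(eqr_series(cm$counts, expected_index = 25))
    mo <- as.integer(format(es$table$date, "%m"))
    if (mean(es$table$eqr[mo %in% 6:8]) > mean(es$table$eqr[mo %in% c(1, 2, 12)]))
      higher <- higher + 1L
    # the series slot feeds asdhr directly
    expect_s3_class(es$series, "irregular_series")
  }
  expect_gte(higher, 19L)
  # dominance ratio tracks the generator's summer state
  dates <- gen_sample_dates(1, seed = 3)
  g <- gen_counts(dates, seed = 3)
  dr <- suppressWarnings(dominance_ratio(g$counts, "ACHMIN", "AMPPED"))
  ok <- !dr$undefined
  expect_gt(cor(dr$ratio[ok], g$truth$mixing_weight[ok], method = "spearman"), 0)
})

test_that("count matrices round-trip through CSV", {
  cm <- gen_counts(gen_sample_dates(1, seed = 2), seed = 2)$counts
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_counts_csv(cm, tmp)
  cm2 <- read_counts_csv(tmp)
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$dates, cm$dates)
})

test_that("trait tables validate ranges and uniqueness", {
  tr <- default_trait_table()
  expect_true(all(tr$sensitivity >= 1 & tr$sensitivity <= 5))
  expect_true(all(tr$indicator_weight >= 1 & tr$indicator_weight <= 3))
  expect_false(anyDuplicated(tr$taxon) > 0)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  bad <- tr
  bad$sensitivity[1] <- 7
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_trait_table(tmp), "\\[1, 5\\]")
})
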