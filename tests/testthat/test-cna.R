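test_that("segment loader validates the major/minor convention", {
  ok <- data.frame(sample = "S1", chrom = "chr13",
                   startpos = 48000000L, endpos = 49000000L,
                   nMajor = 2L, nMinor = 1L)
  seg <- load_segments(write_segments_tsv(ok))
  expect_identical(seg$total, 3L)
  expect_identical(seg$sample_id, "S1")

  bad <- ok
  bad$nMajor <- 2L
  bad$nMinor <- 3L
  expect_error(load_segments(write_segments_tsv(bad)), "nMinor > nMajor")
  bad2 <- ok
  bad2$nMinor <- -1L
  expect_error(load_segments(write_segments_tsv(bad2)), "negative")
  expect_error(load_segments(write_segments_tsv(ok[, -3L])), "missing")

  empty <- load_segments(write_segments_tsv(ok[0L, ]))
  expect_identical(nrow(empty), 0L)
  # empty profile propagates to an empty copy-state table
  catalog <- make_catalog("D1", "chr13", 48500000L, 48500500L)
  expect_identical(nrow(resolve_copy_state(empty, catalog)), 0L)
})

test_that("copy-state resolution picks the largest-coverage segment", {
  catalog <- make_catalog("D1", "chr1", 1001L, 2000L)
  full <- data.frame(sample_id = "S1", chrom = "chr1", start = 1L,
                     end = 10000L, nMajor = 2L, nMinor = 0L, total = 2L,
                     stringsAsFactors = FALSE)
  cs <- resolve_copy_state(full, catalog)
  expect_equal(cs$coverage, 1)
  expect_identical(cs$nMinor, 0L)

  # 70% / 30% split: the 70% segment wins, coverage recorded
  split2 <- data.frame(sample_id = "S1", chrom = "chr1",
                       start = c(1L, 1701L), end = c(1700L, 9000L),
                       nMajor = c(3L, 1L), nMinor = c(1L, 1L),
                       total = c(4L, 2L), stringsAsFactors = FALSE)
  cs2 <- resolve_copy_state(split2, catalog)
  expect_identical(nrow(cs2), 1L)
  expect_equal(cs2$coverage, 0.7)
  expect_identical(cs2$nMajor, 3L)

  # no overlap: pair absent
  away <- data.frame(sample_id = "S1", chrom = "chr2", start = 1L,
                     end = 10000L, nMajor = 1L, nMinor = 1L, total = 2L,
                     stringsAsFactors = FALSE)
  expect_identical(nrow(suppressWarnings(
    resolve_copy_state(away, catalog))), 0L)
})

test_that("predicted methylation reproduces the allele-ratio identities", {
  # diploid 1+1: prediction 0.5 regardless of which side is methylated
  low <- predict_methylation(1L, 1L, c(0.2, 0.3))
  high <- predict_methylation(1L, 1L, c(0.7, 0.8))
  expect_equal(low$predicted, 0.5)
  expect_equal(high$predicted, 0.5)

  # 3+1 aneuploidy with hypomethylated probes: 25% predicted
  q <- predict_methylation(3L, 1L, c(0.2, 0.25, 0.3))
  expect_equal(q$predicted, 0.25)
  expect_identical(q$methylated_allele_side, "minor")
  expect_equal(q$minor_meth_value, 0.25)

  # copy-neutral LOH with hypermethylated probes: predicted 1
  loh <- predict_methylation(2L, 0L, c(0.9, 0.95))
  expect_equal(loh$predicted, 1)
  expect_identical(loh$methylated_allele_side, "major")

  # ties (beta exactly 0.5) fold into the minor-methylated branch
  tie <- predict_methylation(3L, 1L, c(0.5, 0.5))
  expect_identical(tie$methylated_allele_side, "minor")

  expect_warning(out <- predict_methylation(0L, 0L, 0.5), "deletion")
  expect_null(out)
  expect_error(predict_methylation(2L, 1L, NA_real_), "no observed")
})

test_that("flipping the methylated side mirrors the prediction", {
  set.seed(505)
  for (rep in 1:20) {
    nMinor <- sample(0:2, 1)
    nMajor <- nMinor + sample(0:2, 1)
    if (nMajor + nMinor == 0) nMajor <- 1L
    betas <- runif(5, 0, 0.49)  # strictly below 0.5: side = minor
    a <- predict_methylation(nMajor, nMinor, betas)
    b <- predict_methylation(nMajor, nMinor, 1 - betas)
    expect_identical(a$methylated_allele_side, "minor")
    expect_identical(b$methylated_allele_side, "major")
    expect_equal(a$predicted + b$predicted, 1)
    expect_true(a$predicted >= 0 && a$predicted <= 1)
    if (nMajor == nMinor) expect_equal(a$predicted, 0.5)
  }
})

test_that("regression matches closed-form OLS and its adjusted R2", {
  # perfect fit
  perf <- suppressWarnings(
    regress_observed_on_predicted(seq(0, 1, length.out = 10),
                                  seq(0, 1, length.out = 10)))
  expect_equal(perf$r2, 1)
  expect_equal(perf$adj_r2, 1)

  set.seed(606)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- runif(n)
    y <- 0.3 + 0.5 * x + rnorm(n, sd = 0.1)
    r <- regress_observed_on_predicted(y, x)
    # closed-form oracle
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ic <- mean(y) - sl * mean(x)
    ss_res <- sum((y - ic - sl * x)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- 1 - ss_res / ss_tot
    expect_equal(r$slope, sl, tolerance = 1e-10)
    expect_equal(r$intercept, ic, tolerance = 1e-10)
    expect_equal(r$r2, r2, tolerance = 1e-10)
    expect_equal(r$adj_r2, 1 - (1 - r2) * (n - 1) / (n - 2),
                 tolerance = 1e-10)
    se <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
    p <- 2 * pt(abs(sl / se), df = n - 2, lower.tail = FALSE)
    expect_equal(r$p_value, p, tolerance = 1e-10)
    expect_lte(r$adj_r2, r$r2)
  }

  # independent predictor: adjusted R2 near zero at n = 105
  set.seed(607)
  x <- sample(c(0, 1/3, 0.5, 2/3, 1), 105, replace = TRUE)
  y <- runif(105)
  r0 <- regress_observed_on_predicted(y, x)
  expect_lt(abs(r0$adj_r2), 0.05)

  expect_message(expect_null(regress_observed_on_predicted(1:2, 1:2)),
                 "fewer than 3")
  expect_message(
    expect_null(regress_observed_on_predicted(runif(5), rep(0.5, 5))),
    "constant")
})

test_that("cohort prediction joins copy states with observed betas", {
  copy_states <- data.frame(
    sample_id = c("S1", "S1", "S2"),
    dmr_name = c("D1", "D2", "D1"),
    nMajor = c(3L, 1L, 2L), nMinor = c(1L, 1L, 0L),
    total = c(4L, 2L, 2L), coverage = 1,
    stringsAsFactors = FALSE)
  probe_calls <- data.frame(
    sample_id = rep(c("S1", "S1", "S2"), each = 3),
    dmr_name = rep(c("D1", "D2", "D1"), each = 3),
    beta = c(0.2, 0.25, 0.3, 0.5, 0.52, 0.48, 0.9, 0.92, 0.94),
    stringsAsFactors = FALSE)
  pred <- predict_methylation_cohort(copy_states, probe_calls)
  expect_identical(nrow(pred), 3L)
  expect_equal(pred$predicted[pred$sample_id == "S1" &
                                pred$dmr_name == "D1"], 0.25)
  expect_equal(pred$observed_beta[pred$sample_id == "S2"], 0.92)
  expect_equal(pred$predicted[pred$sample_id == "S2"], 1)
  # mean summary is available as the alternative region scalar
  pred_mean <- predict_methylation_cohort(copy_states, probe_calls,
                                          observed_summary = "mean")
  expect_equal(pred_mean$observed_beta[pred_mean$sample_id == "S1" &
                                         pred_mean$dmr_name == "D1"], 0.25)
})
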