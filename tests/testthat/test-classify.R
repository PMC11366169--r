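test_that("probe thresholds are strict with strong-call precedence", {
  expect_identical(classify_probe(0.85, 0.5, 0.05), "GOM")
  expect_identical(classify_probe(0.15, 0.5, 0.05), "LOM")
  expect_identical(classify_probe(0.35, 0.5, 0.05), "INT_LOM")  # < 0.40
  # beta exactly 0.8 is not GOM, but above the control band
  expect_identical(classify_probe(0.80, 0.5, 0.05), "INT_GOM")
  expect_identical(classify_probe(0.20, 0.5, 0.05), "INT_LOM")
  expect_identical(classify_probe(0.55, 0.5, 0.05), "NO_CHANGE")
  # band edges are strict too
  expect_identical(classify_probe(0.60, 0.5, 0.05), "NO_CHANGE")
  expect_identical(classify_probe(0.40, 0.5, 0.05), "NO_CHANGE")
  # strong call wins even when also outside the band
  expect_identical(classify_probe(0.85, 0.5, 0.01), "GOM")
  # sd = 0 collapses the band to the mean
  expect_identical(classify_probe(0.501, 0.5, 0), "INT_GOM")
  expect_identical(classify_probe(0.499, 0.5, 0), "INT_LOM")
  expect_identical(classify_probe(NA_real_, 0.5, 0.05), NA_character_)
  expect_error(classify_probe(1.2, 0.5, 0.05), "\\[0, 1\\]")
  expect_error(classify_probe(0.5, NA_real_, 0.05), "control")
})

test_that("classification is a total partition, monotone in beta", {
  set.seed(202)
  for (rep in 1:20) {
    ctrl_mean <- runif(1, 0.1, 0.9)
    ctrl_sd <- runif(1, 0, 0.2)
    beta <- sort(runif(50))
    calls <- classify_probe(beta, ctrl_mean, ctrl_sd)
    # total partition: exactly one label, always one of the five
    expect_true(all(calls %in% status_labels()))
    # monotone: ordinal label index never decreases as beta rises
    idx <- match(calls, status_labels())
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("region aggregation applies the strict >60% majority rule", {
  r <- aggregate_region(c(rep("GOM", 7), rep("NO_CHANGE", 3)))
  expect_identical(r$call, "GOM")
  expect_equal(r$support, 0.7)
  expect_false(r$ambiguous)

  r1 <- aggregate_region("LOM")
  expect_identical(r1$call, "LOM")
  expect_equal(r1$support, 1)

  # 3/5 = 0.60 does not strictly exceed 0.60
  r2 <- aggregate_region(c(rep("LOM", 3), rep("NO_CHANGE", 2)))
  expect_identical(r2$call, "NO_CHANGE")
  expect_true(r2$ambiguous)
  expect_equal(r2$support, 0.6)

  # missing betas leave the denominator
  r3 <- aggregate_region(c("GOM", "GOM", "GOM", NA, NA))
  expect_identical(r3$call, "GOM")
  expect_identical(r3$n_probes_used, 3L)
  expect_null(aggregate_region(c(NA_character_, NA_character_)))
})

test_that("region calls equal a brute-force recount on random matrices", {
  set.seed(303)
  for (rep in 1:5) {
    n_p <- sample(3:20, 1)
    n_s <- sample(2:20, 1)
    probe_calls <- expand.grid(
      sample_id = sprintf("S%02d", seq_len(n_s)),
      probe_id = sprintf("p%02d", seq_len(n_p)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    probe_calls$dmr_name <- rep(c("D1", "D2"),
                                length.out = nrow(probe_calls))
    probe_calls$call <- sample(status_labels(), nrow(probe_calls),
                               replace = TRUE)
    probe_calls$beta <- runif(nrow(probe_calls))
    rc <- call_regions(probe_calls)
    # brute force: per (sample, dmr), recount fractions
    for (i in seq_len(nrow(rc))) {
      sub <- probe_calls$call[
        probe_calls$sample_id == rc$sample_id[i] &
          probe_calls$dmr_name == rc$dmr_name[i]]
      frac <- table(factor(sub, levels = status_labels())) / length(sub)
      winner <- names(frac)[which.max(frac)]
      if (max(frac) > 0.6) {
        expect_identical(rc$call[i], winner)
      } else {
        expect_identical(rc$call[i], "NO_CHANGE")
        expect_true(rc$ambiguous[i])
      }
      expect_equal(rc$support[i], max(frac), ignore_attr = TRUE)
    }
  }
})

test_that("most-altered rule is strict and intermediates do not count", {
  rc <- data.frame(
    sample_id = rep(sprintf("S%03d", 1:100), 2),
    dmr_name = rep(c("D_lom", "D_gom"), each = 100),
    call = c(rep("LOM", 35), rep("INT_LOM", 30), rep("NO_CHANGE", 35),
             rep("GOM", 30), rep("NO_CHANGE", 70)),
    support = 1, n_probes_used = 4L, ambiguous = FALSE,
    stringsAsFactors = FALSE)
  s <- summarize_cohort(rc)
  expect_true(s$most_altered[s$dmr_name == "D_lom"])   # 0.35 > 0.30
  expect_identical(s$dominant_event[s$dmr_name == "D_lom"], "LOM")
  expect_false(s$most_altered[s$dmr_name == "D_gom"])  # 0.30 not > 0.30
  expect_equal(sum(s[s$dmr_name == "D_lom",
                     c("p_gom", "p_lom", "p_int_gom", "p_int_lom",
                       "p_no_change")]), 1)
  # two-cohort rule: criterion must hold in both
  rc2 <- rc
  rc2$call[rc2$dmr_name == "D_lom"] <- "NO_CHANGE"
  s2 <- summarize_cohort(rc, region_calls2 = rc2)
  expect_false(s2$most_altered[s2$dmr_name == "D_lom"])
})

test_that("altered-DMR burden counts strong calls only", {
  rc <- data.frame(
    sample_id = "S1",
    dmr_name = sprintf("D%02d", 1:10),
    call = c("GOM", "GOM", "INT_LOM", "INT_LOM", "INT_LOM",
             rep("NO_CHANGE", 5)),
    stringsAsFactors = FALSE)
  b <- altered_dmr_burden(rc)
  expect_identical(b$n_gom, 2L)
  expect_identical(b$n_lom, 0L)

  rc$call <- "NO_CHANGE"
  b0 <- altered_dmr_burden(rc)
  expect_identical(unlist(b0[, c("n_gom", "n_lom")], use.names = FALSE),
                   c(0L, 0L))

  # independent recount on a random call table
  set.seed(404)
  rnd <- expand.grid(sample_id = sprintf("S%02d", 1:15),
                     dmr_name = sprintf("D%02d", 1:12),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rnd$call <- sample(status_labels(), nrow(rnd), replace = TRUE)
  b2 <- altered_dmr_burden(rnd)
  for (s in b2$sample_id) {
    expect_identical(b2$n_gom[b2$sample_id == s],
                     sum(rnd$call[rnd$sample_id == s] == "GOM"))
    expect_identical(b2$n_lom[b2$sample_id == s],
                     sum(rnd$call[rnd$sample_id == s] == "LOM"))
  }
})

test_that("control reference requires >= 2 controls and covers probes", {
  beta <- matrix(runif(12), nrow = 3,
                 dimnames = list(c("p1", "p2", "p3"),
                                 c("T1", "T2", "C1", "C2")))
  expect_error(build_control_reference(beta, "C1"), "at least 2")
  expect_error(build_control_reference(beta, c("C1", "C9")), "not in")
  ctrl <- build_control_reference(beta, c("C1", "C2"))
  expect_identical(ctrl$probe_id, rownames(beta))
  expect_equal(ctrl$mean, rowMeans(beta[, c("C1", "C2")]),
               ignore_attr = TRUE)
  # classify_probes refuses probes without a control reference
  pm <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                   pos = 1:3, dmr_name = "D1", stringsAsFactors = FALSE)
  expect_error(classify_probes(beta[, 1:2], ctrl[-2, ], pm), "p2")
})

test_that("status display labels use the report spellings", {
  expect_identical(status_display(c("GOM", "INT_LOM", "NO_CHANGE")),
                   c("GOM", "Intermediate LOM", "No change"))
})
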