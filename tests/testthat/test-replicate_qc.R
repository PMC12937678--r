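test_that("triage classifies the canonical example reactions", {
  s <- classify_triplicate(c(24.10, 24.20, 24.30))
  expect_equal(s$status, "GOLD")
  expect_equal(s$mean_cq, 24.20)
  expect_equal(s$spread, 0.20)

  # third replicate 24.90 deviates 0.85 from the (24.00, 24.10) pair mean
  s <- classify_triplicate(c(24.00, 24.10, 24.90))
  expect_equal(s$status, "OUTLIER_REMOVED")
  expect_equal(s$mean_cq, 24.05)
  expect_equal(sort(s$retained_cqs), c(24.00, 24.10))

  # closest pair differs by 0.95 > 0.8: no consistent pair at all
  s <- classify_triplicate(c(24.00, 24.95, 25.90))
  expect_equal(s$status, "INVALID")
  expect_true(is.na(s$mean_cq))

  # two-replicate reaction classified by pair difference alone
  s <- classify_triplicate(c(24.00, 24.60))
  expect_equal(s$status, "FFPE_ACCEPTED")
  expect_equal(s$mean_cq, 24.30)

  # all absent: invalid verdict with message, not an exception
  s <- classify_triplicate(c(NA, NA, NA))
  expect_equal(s$status, "INVALID")
  expect_match(s$message, "no amplification")
})

test_that("triage matches the brute-force rule oracle on gridded triplets", {
  set.seed(7)
  grid <- seq(20, 30, by = 0.05)
  for (i in 1:2000) {
    cqs <- sample(grid, 3L, replace = TRUE)
    expect_equal(classify_triplicate(cqs)$status, oracle_triage(cqs),
                 info = paste(cqs, collapse = ", "))
  }
})

test_that("triage is permutation-invariant and translation-equivariant", {
  set.seed(11)
  for (i in 1:200) {
    cqs <- round(runif(3, 22, 28), 2)
    base <- classify_triplicate(cqs)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      p <- classify_triplicate(cqs[perm])
      expect_equal(p$status, base$status)
      expect_equal(p$mean_cq, base$mean_cq)
    }
    shift <- classify_triplicate(cqs + 1.7)
    expect_equal(shift$status, base$status)
    if (!is.na(base$mean_cq)) {
      expect_equal(shift$mean_cq, base$mean_cq + 1.7)
    }
  }
})

test_that("accepted reactions never discard data; outlier removal drops one", {
  set.seed(13)
  for (i in 1:300) {
    cqs <- runif(3, 24, 24 + sample(c(0.4, 0.8, 2), 1L))
    s <- classify_triplicate(cqs)
    if (s$status %in% c("GOLD", "FFPE_ACCEPTED")) {
      expect_equal(length(s$retained_cqs), 3L)
    } else if (s$status == "OUTLIER_REMOVED") {
      expect_equal(length(s$retained_cqs), 2L)
    }
  }
})

test_that("control wells are judged by the acceptance rules", {
  meas <- rbind(
    data.frame(sample_id = "NTC", target_id = c("YAP1", "TBP"),
               replicate_index = 1L, cq = c(38.1, 36.0), plate_id = "P1",
               run_id = "r1", well_role = "NTC"),
    data.frame(sample_id = c("S1", "S2"), target_id = "YAP1",
               replicate_index = 1L, cq = c(NA, 35.0), plate_id = "P1",
               run_id = "r1", well_role = "NRT"),
    data.frame(sample_id = c("S1", "S2", "S3"), target_id = "IC",
               replicate_index = 1L, cq = c(25.0, 25.3, 27.6),
               plate_id = "P1", run_id = "r1", well_role = "IC"))
  meta <- data.frame(sample_id = c("S1", "S2", "S3"), group = "N",
                     is_calibrator = FALSE, is_excluded = FALSE,
                     exclusion_reason = "")
  rep <- qc_controls(cq_dataset(meas, meta))

  expect_equal(rep$ntc$pass, c(TRUE, FALSE))   # 38.1 late-signal ok, 36.0 not
  expect_equal(rep$nrt$pass, c(TRUE, FALSE))   # any NRT amplification fails
  # run-median IC Cq is 25.3; sample 3 deviates 2.3 >= 2
  expect_equal(rep$ic$pass, c(TRUE, TRUE, FALSE))
  expect_equal(rep$ic$delta, c(0.3, 0.0, 2.3))
})

test_that("absent control classes yield not-evaluated, never failure", {
  sim <- simulate_cohort(simulation_config(ntc_signal_prob = 0), seed = 3)
  only_samples <- sim$dataset
  keep <- only_samples$measurements$well_role == "SAMPLE"
  ds <- cq_dataset(only_samples$measurements[keep, ], only_samples$samples)
  rep <- qc_controls(ds)
  expect_equal(nrow(rep$ntc), 0L)
  expect_true(any(grepl("not evaluated", rep$messages)))
})

test_that("inter-run bridging passes within tolerance and fails beyond", {
  run_a <- data.frame(sample_id = c("S1", "S1", "S2"),
                      target_id = c("YAP1", "TBP", "YAP1"),
                      mean_cq = c(24.0, 26.0, 28.0))
  expect_true(bridge_check(run_a, run_a)$pass)
  expect_equal(bridge_check(run_a, run_a)$max_deviation, 0)

  run_b <- run_a; run_b$mean_cq <- run_a$mean_cq + c(0.9, -0.3, 0.2)
  expect_true(bridge_check(run_a, run_b, tolerance = 1.0)$pass)

  run_c <- run_a; run_c$mean_cq[1L] <- run_a$mean_cq[1L] + 1.2
  res <- bridge_check(run_a, run_c, tolerance = 1.0)
  expect_false(res$pass)
  expect_equal(res$max_deviation, 1.2)

  disjoint <- run_a; disjoint$sample_id <- "S9"
  expect_true(is.na(bridge_check(run_a, disjoint)$pass))
})

test_that("the Cq matrix aggregates triage means and flags invalid cells", {
  meas <- do.call(rbind, lapply(list(
    list("S1", "YAP1", c(24.0, 24.1, 24.2)),
    list("S2", "YAP1", c(25.0, 25.9, 26.9)),   # invalid: no pair within 0.8
    list("S1", "TBP", c(26.0, 26.1, 26.1)),
    list("S2", "TBP", c(26.5, 26.6, 26.7))),
    function(x) data.frame(sample_id = x[[1]], target_id = x[[2]],
                           replicate_index = 1:3, cq = x[[3]],
                           plate_id = "P1", run_id = "r1",
                           well_role = "SAMPLE")))
  meta <- data.frame(sample_id = c("S1", "S2"), group = "N",
                     is_calibrator = FALSE, is_excluded = FALSE,
                     exclusion_reason = "")
  mat <- build_cq_matrix(cq_dataset(meas, meta))
  expect_equal(mat$mean_cq["YAP1", "S1"], 24.1)
  expect_true(is.na(mat$mean_cq["YAP1", "S2"]))
  expect_equal(mat$status["YAP1", "S2"], "INVALID")
  expect_equal(mat$mean_cq["TBP", "S2"], 26.6)
})

test_that("a valid re-run on a later plate replaces a failed measurement", {
  meas <- rbind(
    data.frame(sample_id = "N1", target_id = "MOB1A", replicate_index = 1:3,
               cq = c(27.0, 28.0, 29.0), plate_id = "P1", run_id = "r1",
               well_role = "SAMPLE"),
    data.frame(sample_id = "N1", target_id = "MOB1A", replicate_index = 1:3,
               cq = c(27.4, 27.5, 27.6), plate_id = "P2_repeat",
               run_id = "r2", well_role = "SAMPLE"))
  meta <- data.frame(sample_id = "N1", group = "N", is_calibrator = TRUE,
                     is_excluded = FALSE, exclusion_reason = "")
  mat <- build_cq_matrix(cq_dataset(meas, meta))
  expect_equal(mat$mean_cq["MOB1A", "N1"], 27.5)
  expect_equal(mat$status["MOB1A", "N1"], "GOLD")

  # an invalid re-run must not erase an earlier valid measurement
  meas2 <- meas
  meas2$cq <- c(27.4, 27.5, 27.6, 27.0, 28.0, 29.0)
  mat2 <- build_cq_matrix(cq_dataset(meas2, meta))
  expect_equal(mat2$mean_cq["MOB1A", "N1"], 27.5)
})
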