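test_that("event ratio requires 3 reads of both kinds", {
  expect_equal(event_ratio(5L, 45L), 0.10)
  expect_true(is.na(event_ratio(2L, 50L)))
  expect_true(is.na(event_ratio(10L, 2L)))
  expect_equal(event_ratio(3L, 3L), 0.5)
})

test_that("background construction enforces cohort sizes and read minima", {
  mk_support <- function(n_norm, n_canc, normal_count = 30L) {
    rbind(
      data.table(sample_id = sprintf("N%d", seq_len(n_norm)),
                 cohort = "normal", normal_count = normal_count,
                 abnormal_count = 1L),
      data.table(sample_id = sprintf("C%d", seq_len(n_canc)),
                 cohort = "cancer", normal_count = normal_count,
                 abnormal_count = 1L))
  }
  expect_true(build_background(mk_support(600L, 610L))$testable)
  expect_false(build_background(mk_support(501L, 400L))$testable)
  # a sample with 2 normally spliced reads contributes no ratio
  s <- mk_support(600L, 600L)
  s[sample_id == "N1", normal_count := 2L]
  bg <- build_background(s)
  expect_equal(bg$n_normal, 599L)
  # flagged cancer samples are excluded from the cancer background
  bg2 <- build_background(s, flagged_cancer = c("C1", "C2"))
  expect_equal(bg2$n_cancer, 598L)
})

test_that("the Z transform and right-tail P match an independent computation", {
  ratios_n <- c(rep(0.01, 400), rep(0.02, 150), rep(0.03, 50))
  ratios_c <- ratios_n
  sup <- rbind(
    data.table(sample_id = sprintf("N%d", seq_along(ratios_n)),
               cohort = "normal", normal_count = 100L,
               abnormal_count = round(100 * ratios_n / (1 - ratios_n))),
    data.table(sample_id = sprintf("C%d", seq_along(ratios_c)),
               cohort = "cancer", normal_count = 100L,
               abnormal_count = round(100 * ratios_c / (1 - ratios_c))))
  bg <- build_background(sup)
  res <- test_event(bg$mean_normal, bg)
  expect_equal(res$z_normal, 0, tolerance = 1e-12)
  expect_equal(pnorm(res$z_normal, lower.tail = FALSE), 0.5)
  # synthetic check: mean 0.02, SD 0.01, observed 0.05 -> z = 3
  bg2 <- structure(list(normal_ratios = NA, cancer_ratios = NA,
                        mean_normal = 0.02, sd_normal = 0.01,
                        mean_cancer = 0.02, sd_cancer = 0.01,
                        testable = TRUE), class = "background_distribution")
  bg2$normal_ratios <- bg2$cancer_ratios <- rep(0.02, 600)
  res2 <- test_event(0.05, bg2)
  expect_equal(res2$z_normal, 3)
  # independent right-tail oracle via the error function
  p_oracle <- 0.5 * (1 - pracma::erf(3 / sqrt(2)))
  expect_equal(res2$p_value, p_oracle, tolerance = 1e-10)
  expect_lt(abs(res2$p_value - 0.00135), 1e-6)
  # degenerate zero-SD background
  bg3 <- bg2; bg3$sd_normal <- 0
  expect_equal(test_event(0.1, bg3)$reason, "zero_background_sd")
})

test_that("top-percentile gates use the strict empirical quantile", {
  x <- c(seq_len(599) / 1000, 0.9)
  sup <- rbind(
    data.table(sample_id = sprintf("N%d", 1:600), cohort = "normal",
               normal_count = 1000L, abnormal_count = round(1000 * x)),
    data.table(sample_id = sprintf("C%d", 1:600), cohort = "cancer",
               normal_count = 1000L, abnormal_count = round(1000 * x)))
  bg <- build_background(sup)
  q99 <- quantile(bg$normal_ratios, 0.99, type = 7, names = FALSE)
  eps <- 1e-9
  expect_false(test_event(q99, bg)$top1_normal)         # not strictly above
  expect_true(test_event(q99 + 1e-6, bg)$top1_normal)
})

test_that("BH q-values agree with the hand-applied step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # invariance to input order
  p <- runif(20)
  o <- sample(20)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
})

test_that("confounder filter rejects co-mutated and crowded genes", {
  expect_true(confounder_filter(1000L)$pass)
  gv <- data.table(pos = c(2000L), non_silent = TRUE)
  expect_equal(confounder_filter(1000L, gv)$reason, "non_silent_in_gene")
  gv2 <- data.table(pos = c(1010L), non_silent = FALSE)
  expect_equal(confounder_filter(1000L, gv2)$reason, "nearby_variant")
  gv3 <- data.table(pos = c(1100L), non_silent = FALSE)
  expect_true(confounder_filter(1000L, gv3)$pass)
  expect_equal(confounder_filter(1000L, sv_exonic_breakpoint = TRUE)$reason,
               "sv_breakpoint_in_gene")
})

test_that("candidate windows restrict deep intronic variants to BP/cryptic flanks", {
  prox <- list(category = "proximal_intronic", distance_bp = 7L, side = "donor")
  expect_true(candidate_window(prox))
  deep_far <- list(category = "deep_intronic", distance_bp = 200L,
                   side = "donor")
  expect_true(candidate_window(deep_far, dist_to_cryptic = 12L))
  expect_true(candidate_window(deep_far, bp_relative = 2L))
  expect_true(candidate_window(deep_far, bp_relative = -5L))
  expect_false(candidate_window(deep_far, bp_relative = 4L))
  expect_false(candidate_window(deep_far))
  # deep intronic 21-30 bp from a junction still needs a BP or cryptic site
  deep_near <- list(category = "deep_intronic", distance_bp = 25L,
                    side = "donor")
  expect_false(candidate_window(deep_near))
  exon31 <- list(category = "exonic", distance_bp = -31L, side = "donor")
  expect_false(candidate_window(exon31))
})
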