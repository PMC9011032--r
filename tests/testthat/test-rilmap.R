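test_that("map-function round trips are exact", {
  r0 <- seq(0.001, 0.449, length.out = 200)
  expect_lt(max(abs(ril_meiotic_r(ril_observed_R(r0)) - r0)), 1e-12)
  expect_lt(max(abs(haldane_r(haldane_cM(r0)) - r0)), 1e-9)
})

test_that("segregation-distortion filter applies the 1:1 chi-square with Bonferroni", {
  g <- geno_from_counts(99, c(50, 90, 47), marker_ids = c("bal", "bad", "bal2"))
  rep1 <- filter_segregation_distortion(g, alpha = 0.05)
  expect_identical(rep1$removed$marker_id, "bad")
  # the test statistic matches the closed form and stats::chisq.test
  chisq <- (90 - 9)^2 / 99
  expect_equal(chisq, 2 * (90 - 49.5)^2 / 49.5, tolerance = 1e-12)
  ref <- suppressWarnings(stats::chisq.test(c(90, 9), p = c(0.5, 0.5)))
  expect_equal(unname(ref$statistic), chisq, tolerance = 1e-12)

  g2 <- geno_from_counts(99, c(50, 49, 51))
  rep2 <- filter_segregation_distortion(g2)
  expect_identical(nrow(rep2$removed), 0L)
  expect_setequal(rep2$surviving, colnames(g2))

  # markers with no informative calls are reported separately, not tested
  g3 <- cbind(g2, blank = rep(NA_character_, 99))
  rep3 <- filter_segregation_distortion(g3)
  expect_identical(rep3$missing_only, "blank")
})

test_that("linkage grouping separates chromosomes and flags unlinked markers", {
  land <- rec_landscape(10e6, c(1e6, 9e6), c(0, 6, 0))
  mk <- rbind(marker_table("I", seq(5e5, 9.5e6, length.out = 12),
                           ids = sprintf("I_%02d", 1:12)),
              marker_table("II", seq(5e5, 9.5e6, length.out = 12),
                           ids = sprintf("II_%02d", 1:12)))
  pan <- simulate_ril_panel(list(I = land, II = land), mk, n_lines = 200,
                            seed = 23)
  lg <- form_linkage_groups(pan$genotypes)
  expect_identical(length(unique(lg$groups)), 2L)
  expect_identical(nrow(lg$report$removed), 0L)
  expect_true(all(lg$groups[sprintf("I_%02d", 1:12)] ==
                    lg$groups[["I_01"]]))

  # one marker re-randomized independently of the genome
  pan2 <- simulate_ril_panel(list(I = land, II = land), mk, n_lines = 200,
                             seed = 24,
                             artifacts = data.frame(marker_id = "I_06",
                                                    kind = "unlinked"))
  lg2 <- form_linkage_groups(pan2$genotypes)
  expect_identical(lg2$report$removed$marker_id, "I_06")
  expect_identical(lg2$report$removed$reason, "off_linkage_group")

  # a single simulated chromosome forms one group
  lg3 <- form_linkage_groups(pan$genotypes[, sprintf("I_%02d", 1:12)])
  expect_identical(length(unique(lg3$groups)), 1L)
})

test_that("the 4% local allele-frequency rule flags runs against unflagged flanks", {
  # 21 markers at 0.50 except marker 11 at 0.56 -> removed
  counts <- rep(50L, 21); counts[11] <- 56L
  g <- geno_from_counts(100, counts, sprintf("m%02d", 1:21))
  mk <- marker_table("I", seq(1e5, 21e5, by = 1e5), ids = colnames(g))
  rep1 <- filter_allele_frequency_deviation(g, mk, threshold = 0.04)
  expect_identical(rep1$removed$marker_id, "m11")
  expect_identical(rep1$removed$reason, "freq_deviation")

  # 0.53 amid 0.50 -> retained
  counts2 <- rep(50L, 21); counts2[11] <- 53L
  g2 <- geno_from_counts(100, counts2, sprintf("m%02d", 1:21))
  rep2 <- filter_allele_frequency_deviation(g2, mk)
  expect_identical(nrow(rep2$removed), 0L)

  # flat profile -> nothing removed
  g3 <- geno_from_counts(100, rep(50L, 21), sprintf("m%02d", 1:21))
  expect_identical(nrow(filter_allele_frequency_deviation(g3, mk)$removed), 0L)

  # a run of deviant markers is flagged together against its outer flanks
  counts4 <- rep(50L, 21); counts4[10:12] <- c(57L, 58L, 56L)
  g4 <- geno_from_counts(100, counts4, sprintf("m%02d", 1:21))
  rep4 <- filter_allele_frequency_deviation(g4, mk)
  expect_setequal(rep4$removed$marker_id, c("m10", "m11", "m12"))

  # iteration to fixpoint: once a spike is removed, a secondary spike relative
  # to the new flanks is caught too
  counts5 <- rep(50L, 21); counts5[11] <- 62L; counts5[12] <- 56L
  g5 <- geno_from_counts(100, counts5, sprintf("m%02d", 1:21))
  rep5 <- filter_allele_frequency_deviation(g5, mk)
  expect_setequal(rep5$removed$marker_id, c("m11", "m12"))

  # chromosome end uses the single available side
  counts6 <- rep(50L, 21); counts6[1:2] <- c(60L, 59L)
  g6 <- geno_from_counts(100, counts6, sprintf("m%02d", 1:21))
  expect_setequal(filter_allele_frequency_deviation(g6, mk)$removed$marker_id,
                  c("m01", "m02"))

  expect_warning(
    filter_allele_frequency_deviation(g[, 1:2], mk[1:2, ]),
    "fewer than 3")
})

test_that("adjacent-interval map estimation applies the selfed-RIL Haldane chain", {
  # 8 lines, R = 2/8 = 0.25 on the second interval, 0 on the first
  m1 <- c(rep("P1", 4), rep("P2", 4))
  m2 <- m1
  m3 <- m1; m3[4:5] <- c("P2", "P1")
  g <- cbind(m1 = m1, m2 = m2, m3 = m3)
  rownames(g) <- sprintf("L%d", 1:8)
  mk <- marker_table("I", c(1e6, 2e6, 3e6), ids = c("m1", "m2", "m3"))
  em <- estimate_genetic_map(g, mk)
  tab <- em$map$table
  expect_equal(tab$interval_cM[2], 0)
  expect_equal(tab$interval_r[3], 0.25 / (2 * 0.75), tolerance = 1e-12)
  expect_equal(tab$interval_cM[3], -50 * log(1 - 1 / 3), tolerance = 1e-12)
  expect_equal(tab$interval_cM[3], 20.27, tolerance = 1e-3)
  expect_true(all(diff(tab$pos_cM) >= 0))

  # zero informative lines on an interval is an error naming the interval
  g_bad <- g; g_bad[, "m2"] <- NA_character_
  expect_error(estimate_genetic_map(g_bad, mk), "m1 -- m2")
})

test_that("the high-local-recombination filter removes the offending marker and refits", {
  # a marker displaced so both flanking intervals show inflated recombination
  land <- rec_landscape(10e6, c(1e6, 9e6), c(0, 8, 0))
  mk <- marker_table("I", seq(2e5, 9.8e6, length.out = 40))
  pan <- simulate_ril_panel(list(I = land), mk, n_lines = 150, seed = 29)
  g <- pan$genotypes
  g[, "m20"] <- sample(c("P1", "P2"), 150, replace = TRUE)  # locally wild marker
  em <- estimate_genetic_map(g, mk, high_rec_rate_threshold = 50)
  expect_true("m20" %in% em$report$removed$marker_id)
  expect_true(all(em$report$removed$reason == "high_local_recombination"))
  expect_false("m20" %in% em$map$table$marker_id)
  rates <- with(em$map$table[-1, ], interval_cM / (diff(em$map$table$pos_bp) / 1e6))
  expect_true(all(rates <= 50, na.rm = TRUE))
})

test_that("monotonic cM positions and map-length recovery hold on simulated panels", {
  land <- chrom1_landscape()
  mk <- marker_table("I", round(seq(1, 15541e3, length.out = 150)))
  pan <- simulate_ril_panel(list(I = land), mk, n_lines = 99, seed = 31)
  em <- estimate_genetic_map(pan$genotypes, mk)
  expect_true(all(diff(em$map$table$pos_cM) >= 0))
  truth <- landscape_total_cM(land)
  expect_lt(abs(em$map$total_cM[["I"]] - truth) / truth, 0.15)
})

test_that("sliding-window allele frequencies follow the half-open window rule", {
  g <- geno_from_counts(10, c(4L, 5L, 6L), c("a", "b", "c"))
  mk <- marker_table("I", c(0, 50000, 100000), ids = c("a", "b", "c"))
  prof <- allele_frequency_profile(g, mk)
  w0 <- prof$freq[prof$window_start == 0]
  expect_equal(w0, mean(c(0.4, 0.5)))  # marker at 100 kb excluded from [0, 100 kb)
  w5 <- prof$freq[prof$window_start == 5000]
  expect_equal(w5, mean(c(0.5, 0.6)))
  expect_true(all(prof$n_markers >= 1))  # empty windows emit nothing

  gh <- matrix("P1", 4, 3, dimnames = list(paste0("L", 1:4), c("a", "b", "c")))
  expect_true(all(allele_frequency_profile(gh, mk)$freq == 1))

  empty <- allele_frequency_profile(gh[, 0, drop = FALSE], mk[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("HMM imputation calls dominant evidence, respects symmetry, matches enumeration", {
  mk <- marker_table("I", c(1e6, 2e6, 3e6), ids = c("a", "b", "c"))
  # overwhelming evidence: depth 30 all P1 everywhere
  counts <- structure(list(p1 = matrix(30L, 1, 3, dimnames = list("L1", mk$marker_id)),
                           p2 = matrix(0L, 1, 3, dimnames = list("L1", mk$marker_id))),
                      class = "allele_counts")
  out <- impute_genotypes_hmm(counts, mk, error_rate = 0.01,
                              expected_breakpoints_per_chrom = 1)
  expect_identical(unname(out[1, ]), c("P1", "P1", "P1"))

  # single marker, 1 vs 1 read: posterior exactly 0.5 -> missing
  mk1 <- marker_table("I", 1e6, ids = "a")
  c1 <- structure(list(p1 = matrix(1L, 1, 1, dimnames = list("L1", "a")),
                       p2 = matrix(1L, 1, 1, dimnames = list("L1", "a"))),
                  class = "allele_counts")
  expect_true(is.na(impute_genotypes_hmm(c1, mk1)[1, 1]))

  # 3-marker chain with a zero-depth middle marker: forward-backward equals
  # brute-force path enumeration, and the middle is imputed P1 confidently
  n1 <- c(5L, 0L, 5L); n2 <- c(0L, 0L, 0L)
  cc <- structure(list(p1 = matrix(n1, 1, 3, dimnames = list("L1", mk$marker_id)),
                       p2 = matrix(n2, 1, 3, dimnames = list("L1", mk$marker_id))),
                  class = "allele_counts")
  lambda <- 0.1
  q <- pmin(0.5, lambda * diff(mk$pos_bp) / (mk$pos_bp[3] - mk$pos_bp[1]))
  post <- hmm_posterior_enum(n1, n2, q, 0.01)
  expect_gt(post[2], 0.99)
  out3 <- impute_genotypes_hmm(cc, mk, error_rate = 0.01,
                               expected_breakpoints_per_chrom = lambda)
  expect_identical(unname(out3[1, ]), c("P1", "P1", "P1"))
  # the implementation's posterior threshold behaviour matches enumeration:
  # lower the threshold just above/below the enumerated posterior
  out_hi <- impute_genotypes_hmm(cc, mk, error_rate = 0.01,
                                 expected_breakpoints_per_chrom = lambda,
                                 min_posterior = post[2] + 1e-6)
  expect_true(is.na(out_hi[1, "b"]))

  expect_error(impute_genotypes_hmm(cc, marker_table("I", c(3e6, 2e6, 1e6),
                                                     ids = c("a", "b", "c"))),
               "sorted")
})

test_that("HMM imputation recovers simulated genotypes from 1x coverage", {
  land <- chrom1_landscape()
  mk <- rbind(marker_table("I", round(seq(1, 15541e3, length.out = 100)),
                           ids = sprintf("I_%03d", 1:100)),
              marker_table("II", round(seq(1, 15541e3, length.out = 100)),
                           ids = sprintf("II_%03d", 1:100)))
  pan <- simulate_ril_panel(list(I = land, II = land), mk, n_lines = 60,
                            seed = 37)
  tg <- pan$truth$true_genotypes
  counts <- simulate_marker_observations(tg, mean_coverage = 1,
                                         base_error = 0.01, seed = 38)
  imp <- impute_genotypes_hmm(counts, mk, error_rate = 0.01,
                              expected_breakpoints_per_chrom =
                                2 * landscape_total_cM(land) / 100)
  called <- !is.na(imp)
  expect_gt(mean(called), 0.9)
  expect_gte(mean(imp[called] == tg[called]), 0.98)
})
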