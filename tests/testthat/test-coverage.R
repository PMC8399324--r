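test_that("impact lookup sums matching strata and handles free blocks", {
  imp <- toy_impact()
  # free of stage and culture constraints -> 100
  expect_equal(impact_lookup(list(culture = "free", stage0h = "free",
                                  stage24h = "free"), imp), 100)
  # stage-free but culture-constrained -> culture total, also 100
  expect_equal(impact_lookup(list(culture = "BSA", stage0h = "free",
                                  stage24h = "free"), imp), 100)
  # single stratum
  expect_equal(impact_lookup(list(culture = "BSA", stage0h = "M",
                                  stage24h = "ExB"), imp), 10)
  # union stratum equals the sum of its parts (additivity)
  u <- impact_lookup(list(culture = "BSA", stage0h = "EB+B",
                          stage24h = "FEB"), imp)
  p1 <- impact_lookup(list(culture = "BSA", stage0h = "EB",
                           stage24h = "FEB"), imp)
  p2 <- impact_lookup(list(culture = "BSA", stage0h = "B",
                           stage24h = "FEB"), imp)
  expect_equal(u, p1 + p2)
  # culture-free: population-share weighted combination
  v <- impact_lookup(list(culture = "free", stage0h = "M",
                          stage24h = "ExB"), imp)
  expect_equal(v, 0.6 * 10 + 0.4 * 20)
  # absent stratum is an error naming it
  imp2 <- imp[!(imp$stage0h == "M" & imp$stage24h == "ExB" &
                  imp$culture == "BSA"), ]
  expect_error(impact_lookup(list(culture = "BSA", stage0h = "M",
                                  stage24h = "ExB"), imp2), "M\\|ExB")
})

test_that("predicted coverage is AUC times impact on the percent scale", {
  expect_equal(round(predicted_coverage(40 / 42, 100), 3), 95.238)
  expect_equal(predicted_coverage(1, 71.490), 71.490)
  expect_equal(predicted_coverage(0.5, 0), 0)
  expect_error(predicted_coverage(0.3, 50))
  expect_error(predicted_coverage(0.9, 120))
})

toy_hits <- function() {
  data.frame(
    feature_id = c("Fa", "Fb", "Fc", "Fd", "Fe"),
    auc = c(0.95, 0.818, 0.9, 1.0, 0.8),
    p1 = c(0.01, 0.003, 0.02, 0.001, 0.05),
    lfc = c(-99, -2.5, 3, -99, 2),
    p2 = c(0.02, 0.003, 0.03, 0.002, 0.06),
    endpoint = "D40", cryo = "Frozen", breed = "free", culture = "BSA",
    stage0h = c("free", "free", "M", "EB+B", "M"),
    stage24h = c("free", "free", "free", "FEB", "free"),
    age = "free",
    n_pos = c(6, 15, 8, 9, 5), n_neg = c(7, 11, 8, 9, 5),
    level1_class = "significant", small_n_exception = FALSE,
    block_id = 1:5
  )
}

test_that("single-biomarker selection filters and sorts like brute force", {
  imp <- toy_impact()
  singles <- select_single_biomarkers(toy_hits(), imp, min_predicted = 70)
  # brute force: predicted per hit, filter, sort
  h <- toy_hits()
  h$impact <- vapply(seq_len(nrow(h)), function(i) {
    impact_lookup(h[i, ], imp)
  }, numeric(1))
  h$predicted <- h$auc * h$impact
  h <- h[h$predicted >= 70, ]
  h <- h[order(-h$predicted, -(h$n_pos + h$n_neg), h$feature_id), ]
  expect_equal(singles$feature_id, h$feature_id)
  expect_equal(singles$predicted, h$predicted)
  # an AUC 0.95 hit on a low-impact stratum is excluded by the gate
  low <- toy_hits()[1, ]
  low$stage0h <- "B"; low$stage24h <- "ExB"   # impact 5 under BSA
  expect_equal(nrow(select_single_biomarkers(low, imp)), 0)
})

test_that("series building enumerates exactly the disjoint member sets", {
  imp <- toy_impact()
  h <- toy_hits()[c(3, 4, 5), ]   # strata: M/free, EB+B/FEB, M/free
  ser <- build_series(h, imp)
  # members must be pairwise stage-disjoint
  for (s in ser) {
    cells <- unlist(lapply(seq_len(nrow(s$members)), function(i) {
      embryoscreen:::stratum_cells(s$members$stage0h[i],
                                   s$members$stage24h[i])
    }))
    expect_equal(anyDuplicated(cells), 0)
  }
  # brute force: distinct strata are M/free and EB+B/FEB; they overlap in
  # no cell, so subsets are {1}, {2}, {1,2}
  expect_equal(length(ser), 3)
  # overlapping strata are never co-members
  h2 <- toy_hits()[c(1, 4), ]     # free/free overlaps EB+B/FEB
  ser2 <- build_series(h2, imp)
  expect_true(all(vapply(ser2, function(s) nrow(s$members) == 1,
                         logical(1))))
})

test_that("combined coverage reproduces reference arithmetic and guards", {
  # two perfectly separating stage-disjoint members, impacts 42.990/57.010
  m <- data.frame(stage0h = c("EB+B", "M"), stage24h = c("free", "free"),
                  auc = c(1, 1), impact = c(42.990, 57.010))
  expect_equal(combined_coverage(m), 100)
  # member A: 18/20 concordant pairs on impact 71.490; member B perfect
  a <- roc_auc(block_values_with_discordance(5, 4, 2)$pregnant,
               block_values_with_discordance(5, 4, 2)$open)
  m2 <- data.frame(stage0h = c("free", "free"), stage24h = c("FEB", "ExB"),
                   auc = c(a, 1), impact = c(71.490, 28.510))
  expect_equal(round(combined_coverage(m2), 4), 92.8510)
  # single-member series equals its own predicted coverage
  m3 <- data.frame(stage0h = "M", stage24h = "free", auc = 0.9, impact = 40)
  expect_equal(combined_coverage(m3), 36)
  # overlap is an error
  m4 <- data.frame(stage0h = c("EB+B", "B"), stage24h = c("free", "free"),
                   auc = c(1, 1), impact = c(50, 20))
  expect_error(combined_coverage(m4), "overlap")
})

test_that("combined coverage is monotone and bounded by 100 on partitions", {
  m <- data.frame(stage0h = "EB+B", stage24h = "free", auc = 0.9,
                  impact = 56.371)
  base <- combined_coverage(m)
  m2 <- rbind(m, data.frame(stage0h = "M", stage24h = "free", auc = 0.8,
                            impact = 43.629))
  expect_gt(combined_coverage(m2), base)
  # partition of the population with perfect AUCs caps at 100
  m3 <- m2
  m3$auc <- 1
  expect_lte(combined_coverage(m3), 100 + 1e-9)
})

test_that("best combination per series maximizes combined coverage", {
  imp <- toy_impact()
  # two metabolites in the same member block: the higher AUC wins
  h <- toy_hits()[c(3, 5), ]      # same stratum M/free, AUC 0.9 vs 0.8
  h$lfc <- c(3, 2)
  best <- best_combination_per_series(h, imp, min_combined = 0)
  expect_equal(nrow(best), 1)
  expect_equal(best$feature_id, "Fc")
  # exhaustive brute force over member sets and metabolite choices
  h2 <- toy_hits()[c(3, 4, 5), ]
  best2 <- best_combination_per_series(h2, imp, min_combined = 0)
  strata <- unique(h2[, c("stage0h", "stage24h")])
  best_per_stratum <- vapply(seq_len(nrow(strata)), function(i) {
    cand <- h2[h2$stage0h == strata$stage0h[i] &
                 h2$stage24h == strata$stage24h[i], ]
    max(cand$auc * vapply(seq_len(nrow(cand)), function(j) {
      impact_lookup(cand[j, ], imp)
    }, numeric(1)))
  }, numeric(1))
  # the two strata are disjoint, so the optimum takes both
  expect_equal(unique(best2$combined), sum(best_per_stratum))
  # empty hit set -> empty result
  expect_equal(nrow(best_combination_per_series(toy_hits()[0, ], imp)), 0)
})
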