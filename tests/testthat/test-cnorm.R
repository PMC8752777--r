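# Small helper: carrier matrix from a named list of carrier-id vectors.
make_carriers <- function(samples, events) {
  m <- matrix(FALSE, length(samples), length(events),
              dimnames = list(samples, names(events)))
  for (ev in names(events)) m[events[[ev]], ev] <- TRUE
  m
}

test_that("carrier frequencies count within current group membership", {
  samples <- sprintf("S%02d", 1:20)
  m <- make_carriers(samples, list(`8p_loss` = samples[1:10],
                                   `8q_gain` = samples[1:4]))
  group <- factor(rep(c("A", "B"), each = 10))
  fr <- cna_frequencies(m, group)
  expect_equal(unname(fr["8q_gain", ]), c(0.4, 0.0))
  # recount after removing one +8q carrier from group A
  keep <- setdiff(samples, "S01")
  fr2 <- cna_frequencies(m[keep, ], group[match(keep, samples)])
  expect_equal(unname(fr2["8q_gain", "freq_A"]), 3 / 9)
  expect_error(cna_frequencies(m, factor(rep("A", 20), levels = c("A", "B"))),
               "empty")
})

test_that("enrichment categorization uses a strict > margin", {
  fr <- rbind(e1 = c(freq_A = 0.30, freq_B = 0.24),   # diff 0.06 -> enriched
              e2 = c(freq_A = 0.30, freq_B = 0.25),   # diff exactly 0.05 -> balanced
              e3 = c(freq_A = 0.20, freq_B = 0.20),
              e4 = c(freq_A = 0.10, freq_B = 0.30))
  lab <- categorize_enrichment(fr, margin = 0.05)
  expect_equal(unname(lab),
               c("enriched_in_A", "balanced", "balanced", "enriched_in_B"))
})

test_that("overrepresentation scores count own-group enriched events only", {
  samples <- c("a1", "a2", "b1")
  m <- make_carriers(samples,
                     list(e1 = c("a1", "b1"), e2 = c("a1", "b1"),
                          e3 = c("a1"), e4 = c("b1"), e5 = c("b1")))
  group <- factor(c("A", "A", "B"))
  labels <- c(e1 = "enriched_in_A", e2 = "enriched_in_A", e3 = "enriched_in_A",
              e4 = "enriched_in_B", e5 = "balanced")
  sc <- score_samples(m, group, labels)
  expect_equal(unname(sc["a1"]), 3L)   # carries 3 A-enriched events
  expect_equal(unname(sc["a2"]), 0L)   # carries only balanced/none
  expect_equal(unname(sc["b1"]), 1L)   # e4 counts, the A-enriched ones do not
})

test_that("balanced cohorts converge with zero removals", {
  samples <- sprintf("S%02d", 1:40)
  carriers <- make_carriers(samples,
                            list(`8p_loss` = samples[1:20],
                                 `1q_gain` = samples[c(1:5, 21:25)],
                                 `5p_loss` = samples[c(6:9, 26:29)]))
  group <- factor(rep(c("A", "B"), each = 20))
  res <- run_cnorm(carriers, group, cnorm_config(rng_seed = 1))
  expect_true(res$achieved)
  expect_equal(nrow(res$removal_trace), 0)
  expect_equal(sort(res$retained), samples)
})

test_that("a 100%-vs-0% covariate stops unachieved at the removal cap", {
  samples <- sprintf("S%02d", 1:40)
  carriers <- make_carriers(samples,
                            list(`8p_loss` = samples[1:20],
                                 `8q_gain` = samples[1:20]))
  group <- factor(rep(c("A", "B"), each = 20))
  res <- run_cnorm(carriers, group, cnorm_config(rng_seed = 3))
  expect_false(res$achieved)
  removed_per_group <- table(factor(res$removal_trace$group, c("A", "B")))
  expect_lte(removed_per_group[["A"]], ceiling(0.5 * 20))
  expect_lte(removed_per_group[["B"]], ceiling(0.5 * 20))
  # removal cannot equalize 100% vs 0%
  expect_gt(res$final_max_diff, 0.05)
  expect_lte(res$final_max_diff, res$initial_max_diff)
})

test_that("the removal trace replays bit-identically under the same seed", {
  set.seed(99)
  samples <- sprintf("S%03d", 1:80)
  carriers <- make_carriers(samples, list(
    `8p_loss` = samples[1:40],
    `8q_gain` = samples[c(1:22, 41:48)],
    `3p_loss` = samples[c(5:25, 50:56)],
    `7q_gain` = samples[c(sample(1:40, 18), sample(41:80, 7))]))
  group <- factor(rep(c("A", "B"), each = 40))
  r1 <- run_cnorm(carriers, group, cnorm_config(rng_seed = 11))
  r2 <- run_cnorm(carriers, group, cnorm_config(rng_seed = 11))
  expect_identical(r1$removal_trace, r2$removal_trace)
  expect_identical(r1$retained, r2$retained)
  r3 <- run_cnorm(carriers, group, cnorm_config(rng_seed = 12))
  expect_false(identical(r1$removal_trace, r3$removal_trace) &&
                 nrow(r1$removal_trace) > 0)
})

test_that("run_cnorm matches an independent scalar reference implementation", {
  # 20-sample toy cohort, one covariate at 60% in A vs 20% in B
  samples <- sprintf("S%02d", 1:20)
  carriers <- make_carriers(samples,
                            list(`8p_loss` = samples[1:10],
                                 `8q_gain` = samples[c(1:6, 11:12)]))
  group <- factor(rep(c("A", "B"), each = 10))
  res <- run_cnorm(carriers, group, cnorm_config(rng_seed = 7))
  ref_trace <- oracle_cnorm_trace(carriers, group, "8p_loss", seed = 7)
  expect_equal(res$removal_trace$sample, ref_trace)
  expect_true(res$achieved)
  expect_lte(res$final_max_diff, 0.05)
})

test_that("monotone progress and cap invariants hold over random cohorts", {
  set.seed(7)
  for (rep in 1:8) {
    n <- 60
    samples <- sprintf("S%03d", 1:n)
    events <- c("8p_loss", sprintf("cov%d_%s", 1:6,
                                   sample(c("loss", "gain"), 6, TRUE)))
    carriers <- matrix(runif(n * length(events)) < runif(length(events), 0.1, 0.6),
                       n, length(events), byrow = TRUE,
                       dimnames = list(samples, events))
    carriers[, "8p_loss"] <- rep(c(TRUE, FALSE), each = n / 2)
    group <- factor(rep(c("A", "B"), each = n / 2))
    res <- run_cnorm(carriers, group, cnorm_config(rng_seed = rep))
    expect_lte(res$final_max_diff, res$initial_max_diff)
    removed <- table(factor(res$removal_trace$group, c("A", "B")))
    expect_lte(max(removed), ceiling(0.5 * n / 2))
    if (res$achieved) expect_lte(res$final_max_diff, 0.05)
  }
})

test_that("defining CNA must be present and groups preserved", {
  samples <- sprintf("S%02d", 1:10)
  carriers <- make_carriers(samples, list(e1 = samples[1:3]))
  group <- factor(rep(c("A", "B"), each = 5))
  expect_error(run_cnorm(carriers, group,
                         cnorm_config(defining_cna = "8p_loss")),
               "8p_loss")
})

test_that("association contrast refuses tiny retained groups", {
  scores <- matrix(rnorm(12), nrow = 6,
                   dimnames = list(sprintf("S%d", 1:6), c("CD8", "NK")))
  group <- factor(c("A", "A", "B", "B", "B", "B"))
  expect_error(association_after_cnorm(scores, group), "fewer than 3")
})

test_that("identical score distributions give a null-centered contrast", {
  set.seed(5)
  n <- 60
  scores <- matrix(rnorm(2 * n), nrow = n,
                   dimnames = list(sprintf("S%03d", 1:n), c("CD8", "NK")))
  group <- factor(rep(c("A", "B"), each = n / 2))
  res <- association_after_cnorm(scores, group)
  expect_true(all(res$p_value > 0.01))
  expect_true(all(res$fdr <= 1))
})
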