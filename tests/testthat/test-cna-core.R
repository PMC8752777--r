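test_that("purity correction is the identity for pure tumors and inverts mixing", {
  expect_equal(as.numeric(purity_correct(-0.3, 1)), -0.3)
  # forward-mix oracle: tumor ratio 2/3 diluted with normal at p = 0.5
  x <- log2(0.5 * (2 / 3) + 0.5)
  expect_equal(as.numeric(purity_correct(x, 0.5)), log2(2 / 3),
               tolerance = 1e-12)
  expect_error(purity_correct(0, 0), "0, 1")
  expect_error(purity_correct(0, 1.5), "0, 1")
})

test_that("deep losses below the purity floor hit the sentinel", {
  cc <- purity_correct(-2, 0.5)  # 2^-2 = 0.25 <= 1 - p
  expect_equal(as.numeric(cc), deep_loss_sentinel())
  expect_true(attr(cc, "floored"))
})

test_that("purity correction round-trips the forward mixture on a (c, p) grid", {
  grid <- expand.grid(c_true = seq(-2.5, 2.5, length.out = 60),
                      p = seq(0.05, 1, length.out = 60))
  x <- log2(grid$p * 2^grid$c_true + (1 - grid$p))
  back <- as.numeric(purity_correct(x, grid$p))
  expect_lt(max(abs(back - grid$c_true)), 1e-9)
})

test_that("purity correction is strictly increasing in x", {
  p <- 0.4
  xs <- seq(-0.7, 2, length.out = 200)  # all above the floor for p = 0.4
  cs <- as.numeric(purity_correct(xs, p))
  expect_true(all(diff(cs) > 0))
})

test_that("triploid thresholds correspond to a one-copy (33%) change", {
  thr <- loss_gain_thresholds()
  expect_equal(unname(thr["loss"]), log2(2 / 3))
  expect_equal(unname(thr["gain"]), log2(4 / 3))
  expect_equal(1 - 2^thr[["loss"]], 1 / 3)   # 33% decrease
  expect_equal(2^thr[["gain"]] - 1, 1 / 3)   # 33% increase
  # c = 0 is neutral; c = 0.5 is a gain
  seg <- make_segments("S1", "1", 0, 100, 0)
  gene <- list(chrom = "1", start = 10, end = 20, name = "G")
  expect_equal(call_gene_cna(seg, gene)$state, "neutral")
  seg$corrected_mean <- 0.5
  expect_equal(call_gene_cna(seg, gene)$state, "gain")
})

test_that("gene calls use the length-weighted mean of overlapping segments", {
  gene <- list(chrom = "1", start = 100, end = 200, name = "G")
  seg <- make_segments("S1", "1", 0, 1000, -0.7)
  call <- call_gene_cna(seg, gene)
  expect_equal(call$state, "loss")
  expect_equal(call$support_fraction, 1)
  expect_false(call$uncovered)

  # split 50/50 across c = -0.9 and c = -0.3: mean -0.6 -> loss
  seg2 <- make_segments("S1", "1", c(0, 150), c(150, 300), c(-0.9, -0.3))
  call2 <- call_gene_cna(seg2, gene)
  expect_equal(call2$mean_corrected, -0.6)
  expect_equal(call2$state, "loss")
  # only the c = -0.9 half individually qualifies as loss
  expect_equal(call2$support_fraction, 0.5)

  # uncovered gene: neutral with a flag
  call3 <- call_gene_cna(make_segments("S1", "2", 0, 100, -1), gene)
  expect_equal(call3$state, "neutral")
  expect_equal(call3$support_fraction, 0)
  expect_true(call3$uncovered)
})

test_that("arm calls require 75% of the arm affected", {
  arm <- list(chrom = "1", start = 0, end = 100e6, name = "1p")
  seg <- make_segments("S1", "1", 0, 80e6, -0.7)
  call <- call_arm_cna(seg, arm)
  expect_equal(call$state, "loss")
  expect_equal(call$support_fraction, 0.8)

  seg2 <- make_segments("S1", "1", 0, 50e6, -0.7)
  expect_equal(call_arm_cna(seg2, arm)$state, "neutral")

  empty <- make_segments(character(), character(), integer(), integer(), numeric())
  call3 <- call_arm_cna(empty, arm)
  expect_equal(call3$state, "neutral")
  expect_equal(call3$support_fraction, 0)

  expect_error(call_arm_cna(seg, list(chrom = "1", start = 5, end = 5, name = "z")),
               "positive length")
})

test_that("arm calls match a per-base majority oracle on small synthetic arms", {
  set.seed(41)
  for (rep in 1:25) {
    n_seg <- sample(1:5, 1)
    bounds <- sort(sample(0:10000, n_seg + 1))
    cval <- runif(n_seg, -1.2, 1.2)
    seg <- make_segments("S1", "1", bounds[-length(bounds)], bounds[-1], cval)
    arm <- list(chrom = "1", start = 0, end = 10000, name = "1p")
    expect_equal(call_arm_cna(seg, arm)$state,
                 oracle_arm_call(seg, 0, 10000))
  }
})

test_that("fraction genome altered sums altered length over surveyed length", {
  expect_equal(fraction_genome_altered(make_segments("S1", "1", 0, 100, 0)), 0)
  expect_equal(fraction_genome_altered(make_segments("S1", "1", 0, 100, -0.7)), 1)
  seg <- make_segments("S1", "1", c(0, 100), c(100, 200), c(-0.7, 0))
  expect_equal(fraction_genome_altered(seg), 0.5)
  expect_error(fraction_genome_altered(seg[0, ]), "empty")
})

test_that("fga is invariant under splitting a segment at the same c", {
  seg <- make_segments("S1", "1", c(0, 100, 250), c(100, 250, 400),
                       c(-0.8, 0.1, 0.6))
  split_seg <- make_segments("S1", "1", c(0, 40, 100, 250), c(40, 100, 250, 400),
                             c(-0.8, -0.8, 0.1, 0.6))
  expect_equal(fraction_genome_altered(seg), fraction_genome_altered(split_seg))
})

test_that("terciles partition the cohort with stable tie-breaking", {
  b <- data.frame(sample = c("S1", "S2", "S3"), fga = c(0.1, 0.2, 0.3))
  t3 <- assign_terciles(b)
  expect_equal(as.character(t3$aneuploidy_tercile), c("low", "mid", "high"))

  b9 <- data.frame(sample = sprintf("S%d", 1:9), fga = seq(0.1, 0.9, by = 0.1))
  t9 <- assign_terciles(b9)
  expect_equal(as.vector(table(t9$aneuploidy_tercile)), c(3L, 3L, 3L))
  expect_equal(as.character(t9$aneuploidy_tercile[t9$fga > 0.6]),
               rep("high", 3))

  # degenerate: all equal fga -> sizes as equal as possible, by sample order
  b4 <- data.frame(sample = c("S1", "S2", "S3", "S4"), fga = rep(0.2, 4))
  t4 <- assign_terciles(b4)
  expect_equal(as.vector(table(t4$aneuploidy_tercile)), c(2L, 1L, 1L))
  expect_equal(as.character(t4$aneuploidy_tercile), c("low", "low", "mid", "high"))

  expect_error(assign_terciles(b[1:2, ]), "at least 3")
})

test_that("cohort-wide calling agrees with the per-sample operations", {
  sim <- simulate_cohort(cohort_sim_config(n_samples = 12, n_genes = 20,
                                           rng_seed = 3))
  cor <- correct_segments(sim$seg, sim$purity)
  calls <- cohort_cna_calls(cor, genes = sim$genes, arms = sim$arms)
  for (sid in unique(cor$sample)[1:4]) {
    s <- cor[cor$sample == sid, ]
    for (i in sample(nrow(sim$arms), 6)) {
      ref <- call_arm_cna(s, sim$arms[i, ])
      got <- calls$arm_calls[calls$arm_calls$sample == sid &
                               calls$arm_calls$target == sim$arms$name[i], ]
      expect_equal(got$state, ref$state)
      expect_equal(got$support_fraction, ref$support_fraction)
    }
    for (i in seq_len(nrow(sim$genes))) {
      ref <- call_gene_cna(s, sim$genes[i, ])
      got <- calls$gene_calls[calls$gene_calls$sample == sid &
                                calls$gene_calls$target == sim$genes$name[i], ]
      expect_equal(got$state, ref$state)
      expect_equal(got$mean_corrected, ref$mean_corrected)
    }
    expect_equal(calls$burdens$fga[calls$burdens$sample == sid],
                 fraction_genome_altered(s))
  }
})

test_that("samples without purity estimates are excluded with a message", {
  seg <- make_segments(c("S1", "S2"), "1", c(0, 0), c(100, 100), c(0, 0))
  purity <- data.frame(sample = "S1", purity = 0.8)
  expect_message(out <- correct_segments(seg, purity), "S2")
  expect_equal(unique(out$sample), "S1")
})
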