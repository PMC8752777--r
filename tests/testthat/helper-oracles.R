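# Independent oracles used across the suite. Each is deliberately written
# as a direct transcription of the definition (scalar loops, enumeration,
# brute force) and shares no code with the package implementation.

# Running-sum enrichment score by direct iteration over the list.
oracle_es <- function(scores_desc, hit, weight = 1) {
  n <- length(scores_desc)
  nh <- sum(hit)
  nr <- sum(abs(scores_desc[hit])^weight)
  run <- 0
  hi <- lo <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (nr > 0) abs(scores_desc[i])^weight / nr else 1 / nh
    } else {
      run <- run - 1 / (n - nh)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  # same tie rule as the implementation: exact ties go negative
  if (hi + lo > 1e-12) hi else lo
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
oracle_hypergeom_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  lesion1 <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% lesion1))
  mean(hits >= k)
}

# Arm call by per-base majority on tiny arms (exhaustive base loop).
oracle_arm_call <- function(segments, arm_start, arm_end, min_frac = 0.75) {
  thr <- c(loss = log2(2 / 3), gain = log2(4 / 3))
  states <- character(arm_end - arm_start)
  states[] <- "none"
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    bases <- seq(max(s$start, arm_start), min(s$end, arm_end) - 1)
    bases <- bases[bases >= arm_start & bases < arm_end]
    st <- if (s$corrected_mean <= thr["loss"]) "loss"
          else if (s$corrected_mean >= thr["gain"]) "gain" else "neutral"
    states[bases - arm_start + 1] <- st
  }
  f_loss <- mean(states == "loss")
  f_gain <- mean(states == "gain")
  if (f_loss >= min_frac) "loss" else if (f_gain >= min_frac) "gain" else "neutral"
}

# Full unanchored global affine-gap alignment via Biostrings (independent
# dynamic-programming route; same scoring convention: a gap of length L
# costs gap_open + L * gap_extend).
oracle_global_score <- function(read, ref, match = 2, mismatch = -2,
                                gap_open = 4, gap_extend = 0.5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = read, subject = ref, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE))
}

# Scalar reference implementation of the C-Norm loop (same RNG protocol:
# set.seed at start, one sample() call per iteration over the max-score
# pool), with frequencies, labels and scores recomputed by explicit loops.
oracle_cnorm_trace <- function(carriers, group, defining, seed,
                               margin = 0.05, tol = 0.05, cap_frac = 0.5) {
  group <- as.factor(group)
  lv <- levels(group)
  n0 <- c(sum(group == lv[1]), sum(group == lv[2]))
  cap <- floor(cap_frac * n0)
  removed <- c(0L, 0L)
  alive <- rep(TRUE, nrow(carriers))
  names(alive) <- rownames(carriers)
  events <- setdiff(colnames(carriers), defining)
  trace <- character()
  set.seed(seed)
  repeat {
    fa <- fb <- numeric(length(events))
    for (j in seq_along(events)) {
      ina <- alive & group == lv[1]
      inb <- alive & group == lv[2]
      fa[j] <- sum(carriers[ina, events[j]]) / sum(ina)
      fb[j] <- sum(carriers[inb, events[j]]) / sum(inb)
    }
    if (max(abs(fa - fb)) <= tol) break
    lab <- ifelse(fa - fb > margin, "A", ifelse(fb - fa > margin, "B", "bal"))
    sc <- integer(nrow(carriers))
    for (i in which(alive)) {
      own <- if (group[i] == lv[1]) "A" else "B"
      sc[i] <- sum(carriers[i, events[lab == own]])
    }
    gi <- ifelse(group == lv[1], 1L, 2L)
    sc[removed[gi] >= cap[gi]] <- 0L
    if (max(sc) == 0L) break
    pool <- rownames(carriers)[alive & sc == max(sc)]
    pick <- if (length(pool) == 1) pool else sample(pool, 1)
    alive[pick] <- FALSE
    gp <- if (group[match(pick, rownames(carriers))] == lv[1]) 1L else 2L
    removed[gp] <- removed[gp] + 1L
    trace <- c(trace, pick)
  }
  trace
}

# Tiny deterministic segment-table builder for unit tests.
make_segments <- function(sample, chrom, start, end, c_values) {
  n <- length(start)
  data.frame(sample = rep_len(sample, n), chrom = rep_len(as.character(chrom), n),
             start = as.integer(start), end = as.integer(end),
             num_probes = rep_len(10L, n), seg_mean = c_values,
             purity = rep_len(1, n), corrected_mean = c_values,
             floored = rep_len(FALSE, n), stringsAsFactors = FALSE)
}
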