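#' C-Norm configuration
#'
#' Parameters of the iterative cohort covariate-normalization algorithm.
#'
#' @param enrichment_margin Frequency difference above which a covariate CNA
#'   counts as enriched in one group (strict ">"); default 0.05.
#' @param convergence_tolerance Maximum absolute frequency difference, over
#'   all non-defining CNAs, at which normalization is declared achieved;
#'   default 0.05 (set equal to the enrichment margin).
#' @param max_removed_fraction Cap on the fraction of either group's initial
#'   membership that may be masked; default 0.5 ("no more than 50% of samples
#'   in either group").
#' @param batch_size Samples removed per iteration; default 1.
#' @param rng_seed Integer seed for the removal draws.
#' @param defining_cna Name of the arm event that defines the group contrast
#'   (e.g. `"8p_loss"`); excluded from normalization.
#' @return A list of class `cnorm_config`.
#' @export
cnorm_config <- function(enrichment_margin = 0.05,
                         convergence_tolerance = 0.05,
                         max_removed_fraction = 0.5,
                         batch_size = 1L,
                         rng_seed = 1L,
                         defining_cna = "8p_loss") {
  stopifnot(enrichment_margin > 0, enrichment_margin <= 1,
            convergence_tolerance >= 0,
            max_removed_fraction > 0, max_removed_fraction <= 0.5,
            batch_size >= 1)
  structure(list(enrichment_margin = enrichment_margin,
                 convergence_tolerance = convergence_tolerance,
                 max_removed_fraction = max_removed_fraction,
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed),
                 defining_cna = defining_cna),
            class = "cnorm_config")
}

.check_groups <- function(carriers, group) {
  if (is.null(rownames(carriers))) {
    stop("carrier matrix must have sample ids as rownames", call. = FALSE)
  }
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required", call. = FALSE)
  if (length(group) != nrow(carriers)) {
    stop("group assignment length must match the carrier matrix", call. = FALSE)
  }
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  group
}

#' Per-CNA per-group carrier frequencies
#'
#' @param carriers Logical sample-by-event matrix ([arm_event_matrix()]).
#' @param group Two-level factor of group membership, aligned with rows.
#' @return Matrix with one row per event and columns `freq_A`, `freq_B`
#'   (A = first factor level).
#' @export
cna_frequencies <- function(carriers, group) {
  group <- .check_groups(carriers, group)
  a <- levels(group)[1]
  fa <- colMeans(carriers[group == a, , drop = FALSE])
  fb <- colMeans(carriers[group != a, , drop = FALSE])
  cbind(freq_A = fa, freq_B = fb)
}

#' Categorize covariate CNAs by group enrichment
#'
#' An event is enriched in a group when its frequency there exceeds the other
#' group's by strictly more than `margin` (the "> 5%" rule; a difference of
#' exactly the margin is balanced).
#'
#' @param freq_table Output of [cna_frequencies()].
#' @param margin Enrichment margin; default 0.05.
#' @return Character vector over events: `"enriched_in_A"`,
#'   `"enriched_in_B"`, or `"balanced"`.
#' @export
categorize_enrichment <- function(freq_table, margin = 0.05) {
  d <- freq_table[, "freq_A"] - freq_table[, "freq_B"]
  out <- ifelse(d > margin, "enriched_in_A",
                ifelse(-d > margin, "enriched_in_B", "balanced"))
  stats::setNames(out, rownames(freq_table))
}

#' Per-sample overrepresentation scores
#'
#' A sample's score is the number of CNAs enriched in its *own* group that it
#' carries; events enriched in the other group do not count, nor does the
#' defining CNA.
#'
#' @param carriers Logical sample-by-event matrix.
#' @param group Two-level factor aligned with rows.
#' @param labels Enrichment labels from [categorize_enrichment()].
#' @return Named integer vector of scores.
#' @export
score_samples <- function(carriers, group, labels) {
  group <- .check_groups(carriers, group)
  a <- levels(group)[1]
  ev_a <- names(labels)[labels == "enriched_in_A"]
  ev_b <- names(labels)[labels == "enriched_in_B"]
  score <- integer(nrow(carriers))
  in_a <- group == a
  if (length(ev_a) > 0) {
    score[in_a] <- rowSums(carriers[in_a, ev_a, drop = FALSE])
  }
  if (length(ev_b) > 0) {
    score[!in_a] <- rowSums(carriers[!in_a, ev_b, drop = FALSE])
  }
  stats::setNames(as.integer(score), rownames(carriers))
}

#' Run C-Norm: iterative cohort CNA covariate normalization
#'
#' Equalizes the frequencies of all non-defining arm-level CNA events between
#' a group of interest and its complement by iteratively masking
#' covariate-enriched samples. Each iteration: (1) recompute per-group event
#' frequencies on the retained samples and label enrichment; (2) stop with
#' `achieved = TRUE` when the maximum absolute non-defining frequency
#' difference is at or below the convergence tolerance; (3) otherwise score
#' every retained sample by the number of own-group-enriched events it
#' carries, pool the samples attaining the current maximum positive score
#' across both groups, and remove `batch_size` of them uniformly at random
#' with the seeded generator — never letting either group's removed count
#' exceed `max_removed_fraction` of its initial size; (4) if no removal is
#' possible (all scores zero or both caps reached), stop with
#' `achieved = FALSE`. The returned retained sets correspond to the point of
#' best concordance along the trace, so the reported maximum frequency
#' difference never exceeds its initial value. Group labels are fixed
#' throughout; only membership masks change, so the defining CNA's group
#' contrast is preserved by construction.
#'
#' @param carriers Logical sample-by-event matrix ([arm_event_matrix()]).
#' @param group Two-level factor aligned with rows; the first level is the
#'   group of interest.
#' @param config A [cnorm_config()].
#' @return A list of class `cnorm_result`: `retained` (character vector of
#'   sample ids), `retained_by_group`, `removal_trace` (data.frame iteration
#'   / group / sample), `final_max_diff`, `initial_max_diff`, `achieved`,
#'   `iterations`, `config`.
#' @export
run_cnorm <- function(carriers, group, config = cnorm_config()) {
  group <- .check_groups(carriers, group)
  if (!config$defining_cna %in% colnames(carriers)) {
    stop(sprintf("defining CNA '%s' absent from the call table",
                 config$defining_cna), call. = FALSE)
  }
  non_defining <- setdiff(colnames(carriers), config$defining_cna)
  lv <- levels(group)
  n0 <- table(group)
  cap <- floor(config$max_removed_fraction * as.numeric(n0))
  names(cap) <- lv

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)

  retained <- rep(TRUE, nrow(carriers))
  names(retained) <- rownames(carriers)
  removed_n <- stats::setNames(c(0L, 0L), lv)
  trace <- list()
  iter <- 0L
  achieved <- FALSE
  max_diff_path <- numeric()
  removals_at_eval <- integer()

  max_diff_now <- function(keep) {
    fr <- cna_frequencies(carriers[keep, , drop = FALSE], group[keep])
    max(abs(fr[non_defining, "freq_A"] - fr[non_defining, "freq_B"]))
  }

  repeat {
    keep <- which(retained)
    fr <- cna_frequencies(carriers[keep, , drop = FALSE], group[keep])
    md <- max(abs(fr[non_defining, "freq_A"] - fr[non_defining, "freq_B"]))
    max_diff_path <- c(max_diff_path, md)
    removals_at_eval <- c(removals_at_eval, length(trace))
    if (md <= config$convergence_tolerance) {
      achieved <- TRUE
      break
    }
    labels <- categorize_enrichment(fr[non_defining, , drop = FALSE],
                                    config$enrichment_margin)
    sc <- score_samples(carriers[keep, non_defining, drop = FALSE],
                        group[keep], labels)
    eligible <- removed_n[as.character(group[keep])] < cap[as.character(group[keep])]
    sc[!eligible] <- 0L
    if (max(sc) == 0L) break
    pool <- names(sc)[sc == max(sc)]
    take <- min(config$batch_size, length(pool))
    chosen <- if (length(pool) == 1) pool else sample(pool, take)
    iter <- iter + 1L
    for (s in chosen) {
      g <- as.character(group[match(s, rownames(carriers))])
      if (removed_n[g] >= cap[g]) next  # batch may straddle a cap
      retained[s] <- FALSE
      removed_n[g] <- removed_n[g] + 1L
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = iter, group = g, sample = s, stringsAsFactors = FALSE)
    }
  }

  trace_df <- if (length(trace) > 0) do.call(rbind, trace) else
    data.frame(iteration = integer(), group = character(),
               sample = character(), stringsAsFactors = FALSE)

  # Report the best-concordance point along the trace: replay removals up to
  # the prefix with the minimum max frequency difference.
  best_k <- removals_at_eval[[which.min(max_diff_path)]]
  n_removals <- nrow(trace_df)
  if (best_k < n_removals && !achieved) {
    retained[] <- TRUE
    if (best_k > 0) retained[trace_df$sample[seq_len(best_k)]] <- FALSE
  }
  keep <- which(retained)
  final_md <- max_diff_now(keep)

  structure(list(
    retained = rownames(carriers)[keep],
    retained_by_group = split(rownames(carriers)[keep], group[keep]),
    removal_trace = trace_df,
    initial_max_diff = max_diff_path[[1]],
    final_max_diff = final_md,
    achieved = achieved,
    iterations = iter,
    max_diff_path = max_diff_path,
    config = config
  ), class = "cnorm_result")
}

#' @export
print.cnorm_result <- function(x, ...) {
  cat(sprintf("C-Norm result: %d samples retained (%d removed), %s\n",
              length(x$retained), nrow(x$removal_trace),
              if (x$achieved) "converged" else "best achievable"))
  cat(sprintf("  max non-defining frequency difference: %.4f -> %.4f (tol %.3f)\n",
              x$initial_max_diff, x$final_max_diff,
              x$config$convergence_tolerance))
  invisible(x)
}

#' Group-versus-signature association on the C-Norm retained cohort
#'
#' For each gene-set signature score, compares the two groups on the retained
#' samples with a rank-based two-group test (Wilcoxon rank-sum) and adjusts
#' across gene sets with Benjamini-Hochberg FDR.
#'
#' @param scores Numeric matrix of per-sample signature scores, samples in
#'   rows (ids as rownames), gene sets in columns ([signature_score()]).
#' @param group Two-level factor aligned with `rownames(scores)`.
#' @param result Optional `cnorm_result`; when supplied, only retained
#'   samples enter the test. When NULL, the naive (un-normalized) contrast is
#'   computed.
#' @return data.frame with columns `geneset`, `statistic` (rank-sum W),
#'   `delta` (mean score difference, group A minus B), `p_value`, `fdr`.
#' @export
association_after_cnorm <- function(scores, group, result = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required", call. = FALSE)
  if (is.null(rownames(scores))) {
    stop("scores must have sample ids as rownames", call. = FALSE)
  }
  keep <- rownames(scores)
  if (!is.null(result)) keep <- intersect(keep, result$retained)
  g <- group[match(keep, rownames(scores))]
  if (min(table(g)) < 3) {
    stop("retained group has fewer than 3 samples; refusing the contrast",
         call. = FALSE)
  }
  s <- scores[keep, , drop = FALSE]
  a <- levels(g)[1]
  res <- lapply(colnames(s), function(set) {
    x <- s[g == a, set]
    y <- s[g != a, set]
    w <- stats::wilcox.test(x, y, exact = FALSE)
    data.frame(geneset = set, statistic = unname(w$statistic),
               delta = mean(x) - mean(y), p_value = w$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
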