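#' TP53 loss-of-function status per sample
#'
#' A sample is TP53-LOF when it carries a TP53 variant whose classification
#' is in the non-synonymous vocabulary, or a TP53 copy-number loss call
#' ("mutation or deletion").
#'
#' @param maf MAF-lite data.frame ([read_maf_lite()]).
#' @param gene_calls Gene-level CNA calls containing TP53 rows (long
#'   data.frame with `sample`, `target`, `state`), or NULL to use mutations
#'   only.
#' @param samples Character vector of cohort sample ids the flags are
#'   reported for.
#' @param nonsyn Classifications counted as loss-of-function; defaults to
#'   [maf_variant_vocabulary]`(nonsynonymous = TRUE)`.
#' @return Named logical vector over `samples`.
#' @export
tp53_lof_status <- function(maf, gene_calls = NULL, samples,
                            nonsyn = maf_variant_vocabulary(nonsynonymous = TRUE)) {
  mut <- maf$sample[maf$gene == "TP53" & maf$variant_classification %in% nonsyn]
  del <- character()
  if (!is.null(gene_calls)) {
    del <- gene_calls$sample[gene_calls$target == "TP53" &
                               gene_calls$state == "loss"]
  }
  stats::setNames(samples %in% c(mut, del), samples)
}

.check_overlap_table <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop("overlap table entries must be nonnegative integers", call. = FALSE)
  }
  if (K > N || n > N) stop("lesion counts cannot exceed cohort size", call. = FALSE)
  if (k > min(K, n)) stop("overlap k cannot exceed min(K, n)", call. = FALSE)
  if (k < K + n - N) stop("overlap k below the feasible minimum K + n - N", call. = FALSE)
  invisible(vals)
}

#' Hypergeometric enrichment of lesion co-occurrence
#'
#' Exact upper-tail hypergeometric probability P(X >= k) of observing at
#' least `k` doubly-lesioned samples when `K` of `N` cohort samples carry
#' lesion 1 and `n` carry lesion 2, under independent assortment.
#'
#' @param N Cohort size.
#' @param K Samples with lesion 1.
#' @param n Samples with lesion 2.
#' @param k Samples with both.
#' @param lower If `TRUE`, return the lower tail P(X <= k) instead
#'   (depletion; reported explicitly rather than by doubling).
#' @return The tail probability.
#' @export
hypergeom_enrichment <- function(N, K, n, k, lower = FALSE) {
  .check_overlap_table(N, K, n, k)
  if (lower) {
    stats::phyper(k, K, N - K, n)
  } else {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
}

#' Pairwise arm-event co-association with an anchor event
#'
#' For every arm event other than the anchor, tabulates co-occurrence with
#' the anchor across the cohort and reports both hypergeometric tails
#' (enrichment and depletion), each with Benjamini-Hochberg FDR across
#' events. The anchor is excluded from its own table.
#'
#' @param carriers Logical sample-by-event matrix ([arm_event_matrix()]).
#' @param anchor_event Column name of the anchor (e.g. `"8p_loss"`).
#' @return data.frame sorted by enrichment p: `event`, `N`, `K`, `n`, `k`,
#'   `p_enrich`, `p_deplete`, `fdr_enrich`, `fdr_deplete`.
#' @export
pairwise_arm_coassociation <- function(carriers, anchor_event) {
  if (!anchor_event %in% colnames(carriers)) {
    stop(sprintf("anchor event '%s' absent from the carrier matrix",
                 anchor_event), call. = FALSE)
  }
  others <- setdiff(colnames(carriers), anchor_event)
  N <- nrow(carriers)
  K <- sum(carriers[, anchor_event])
  rows <- lapply(others, function(ev) {
    n <- sum(carriers[, ev])
    k <- sum(carriers[, anchor_event] & carriers[, ev])
    data.frame(event = ev, N = N, K = K, n = n, k = k,
               p_enrich = hypergeom_enrichment(N, K, n, k),
               p_deplete = hypergeom_enrichment(N, K, n, k, lower = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_enrich <- stats::p.adjust(out$p_enrich, method = "BH")
  out$fdr_deplete <- stats::p.adjust(out$p_deplete, method = "BH")
  out[order(out$p_enrich, out$event), , drop = FALSE]
}
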