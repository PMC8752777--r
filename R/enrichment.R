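#' Construct a ranked gene list
#'
#' Orders genes by signed score, descending; ties are broken by gene symbol
#' (stable, documented — upstream FDR-ranked lists can carry ties). Genes
#' must be unique and scores finite.
#'
#' @param genes Character vector of gene symbols.
#' @param scores Numeric vector of signed ranking scores.
#' @return data.frame of class `ranked_list` with columns `gene`, `score`,
#'   sorted descending.
#' @export
ranked_list <- function(genes, scores) {
  if (length(genes) != length(scores)) {
    stop("genes and scores must have equal length", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("ranked list genes must be unique", call. = FALSE)
  if (any(!is.finite(scores))) stop("ranking scores must be finite", call. = FALSE)
  o <- order(-scores, genes)
  structure(data.frame(gene = genes[o], score = scores[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Weighted running-sum enrichment score
#'
#' The weighted Kolmogorov-Smirnov-like statistic of preranked gene-set
#' enrichment ("weighted mode"): walking down the ranked list, a gene-set hit
#' at position i increments the running sum by
#' \eqn{|s_i|^w / \sum_{hits} |s|^w} and a miss decrements it by
#' \eqn{1/(N - N_{hit})}. The enrichment score ES is the signed extremum of
#' the running sum (maximal deviation from zero); when the positive and
#' negative deviations tie (within 1e-12, absorbing float accumulation
#' error), the negative extremum is reported. Should all hit scores be zero
#' (degenerate weighting), hits fall back to equal increments.
#'
#' @param ranked A [ranked_list()].
#' @param geneset Character vector of member gene symbols.
#' @param weight_exponent Weight w on |score|; default 1.
#' @return List with `es` and the `running_sum` profile (length N).
#' @export
enrichment_score <- function(ranked, geneset, weight_exponent = 1) {
  n <- nrow(ranked)
  hit <- ranked$gene %in% geneset
  n_hit <- sum(hit)
  if (n_hit == 0) stop("gene set has empty intersection with the ranked list",
                       call. = FALSE)
  if (n_hit == n) stop("gene set equals the ranked universe; miss decrement undefined",
                       call. = FALSE)
  w <- abs(ranked$score)^weight_exponent
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / n_hit, n)
  step <- ifelse(hit, inc, -1 / (n - n_hit))
  rs <- cumsum(step)
  list(es = .signed_extremum(rs), running_sum = rs)
}

# Signed extremum with a deterministic tie rule (ties go negative).
.signed_extremum <- function(rs) {
  max_p <- max(rs)
  min_p <- min(rs)
  if (max_p + min_p > 1e-12) max_p else min_p
}

# ES for many same-size random gene sets, by position sampling. Same
# statistic as enrichment_score(); vectorized over permutations.
.null_es <- function(scores_desc, set_size, n_perm) {
  n <- length(scores_desc)
  w <- abs(scores_desc)
  vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(n, set_size)
    hit <- logical(n)
    hit[pos] <- TRUE
    nr <- sum(w[hit])
    inc <- if (nr > 0) w / nr else rep(1 / set_size, n)
    step <- ifelse(hit, inc, -1 / (n - set_size))
    .signed_extremum(cumsum(step))
  }, numeric(1))
}

#' Permutation significance for preranked enrichment
#'
#' Builds a gene-permutation null (random same-size gene sets drawn from the
#' ranked universe — the preranked convention, since sample permutation needs
#' raw expression), then reports for each set: ES, NES (ES divided by the
#' mean |null ES| of matching sign), a one-sided nominal p on the matching
#' sign, and FDR q by the standard NES-ratio method with monotone
#' enforcement in |NES|. Null distributions are generated per distinct set
#' size from a seed derived from `seed` and the size, so identical sets give
#' identical results regardless of input order.
#'
#' @param ranked A [ranked_list()].
#' @param genesets Named list of character vectors.
#' @param n_perm Number of permutations per set size; at least 100.
#' @param seed Integer RNG seed.
#' @param weight_exponent Weight on |score|; default 1.
#' @return data.frame: `geneset`, `size`, `es`, `nes`, `p_value`, `fdr`.
#' @export
permutation_significance <- function(ranked, genesets, n_perm = 1000,
                                     seed = 1L, weight_exponent = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  obs <- vapply(genesets, function(gs) {
    enrichment_score(ranked, gs, weight_exponent)$es
  }, numeric(1))
  sizes <- vapply(genesets, function(gs) sum(ranked$gene %in% gs), integer(1))

  scores_desc <- if (weight_exponent == 1) ranked$score else
    sign(ranked$score) * abs(ranked$score)^weight_exponent
  nulls <- list()
  for (k in unique(sizes)) {
    set.seed((as.integer(seed) + 7919L * (k %% 1000L)) %% .Machine$integer.max)
    nulls[[as.character(k)]] <- .null_es(scores_desc, k, n_perm)
  }

  # Nominal p: fraction of same-sign null ES at least as extreme (the
  # preranked tool's convention; 0 when no permutation reaches the observed).
  stat_one <- function(es, null) {
    if (es >= 0) {
      pos <- null[null >= 0]
      p <- if (length(pos) > 0) mean(pos >= es) else 0
      nes <- if (length(pos) > 0 && mean(pos) > 0) es / mean(pos) else NA_real_
    } else {
      neg <- null[null < 0]
      p <- if (length(neg) > 0) mean(neg <= es) else 0
      nes <- if (length(neg) > 0) es / abs(mean(neg)) else NA_real_
    }
    c(p = p, nes = nes)
  }
  st <- t(vapply(seq_along(obs), function(i) {
    stat_one(obs[[i]], nulls[[as.character(sizes[[i]])]])
  }, c(p = 0, nes = 0)))

  # FDR: ratio of null tail fraction to observed tail fraction on NES of the
  # matching sign, capped at 1, made monotone nonincreasing in |NES|.
  null_nes <- unlist(lapply(names(nulls), function(k) {
    null <- nulls[[k]]
    pos <- null[null >= 0]; neg <- null[null < 0]
    c(if (length(pos) > 0 && mean(pos) > 0) pos / mean(pos) else numeric(),
      if (length(neg) > 0) neg / abs(mean(neg)) else numeric())
  }), use.names = FALSE)
  nes <- st[, "nes"]
  fdr <- vapply(seq_along(nes), function(i) {
    v <- nes[[i]]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= v)
      den <- mean(nes[nes >= 0 & is.finite(nes)] >= v)
    } else {
      num <- mean(null_nes[null_nes < 0] <= v)
      den <- mean(nes[nes < 0 & is.finite(nes)] <= v)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  o <- order(-abs(nes))
  fdr[o] <- cummax(replace(fdr[o], is.na(fdr[o]), 0)) # monotone in |NES|
  fdr[!is.finite(nes)] <- NA_real_

  data.frame(geneset = names(genesets), size = sizes, es = unname(obs),
             nes = unname(nes), p_value = unname(st[, "p"]),
             fdr = unname(fdr), stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample gene-set signature score
#'
#' Mean of z-scored member-gene expression per sample: each member gene's
#' log-scale expression is standardized across the cohort, then averaged
#' within the set. Used as the per-sample immune-abundance proxy.
#'
#' @param expr Numeric matrix of log-scale expression, genes in rows
#'   (symbols as rownames), samples in columns.
#' @param geneset Character vector of member genes; at least 2 must be
#'   present in `expr`.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, geneset) {
  members <- intersect(rownames(expr), geneset)
  if (length(members) < 2) {
    stop("fewer than 2 signature genes present in the expression matrix",
         call. = FALSE)
  }
  sub <- expr[members, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  sdv[sdv == 0] <- 1  # constant gene contributes 0, not NaN
  z <- (sub - mu) / sdv
  colMeans(z)
}

#' Signature scores for a gene-set collection
#'
#' @param expr Log-scale expression matrix (genes x samples).
#' @param genesets Named list of gene sets.
#' @return Matrix of scores, samples in rows, gene sets in columns.
#' @export
signature_score_matrix <- function(expr, genesets) {
  out <- vapply(genesets, function(gs) signature_score(expr, gs),
                numeric(ncol(expr)))
  rownames(out) <- colnames(expr)
  out
}
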