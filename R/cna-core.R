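#' Deep-loss sentinel for the purity correction
#'
#' When the argument of the purity-correction logarithm is nonpositive
#' (observed ratio at or below the normal-contamination floor), the corrected
#' ratio is undefined; it is floored at this documented sentinel so the value
#' remains usable for loss calls without infinities.
#'
#' @return The sentinel corrected log2 ratio, -8.
#' @export
deep_loss_sentinel <- function() -8

#' Purity-correct a log2 copy-number ratio
#'
#' For an observed log2 copy ratio x from a tumor sample that is a mixture of
#' malignant cells (fraction p, the tumor purity) and copy-neutral normal
#' cells, the tumor-intrinsic log2 ratio is
#' \deqn{c = \log_2\left(\frac{2^x - (1 - p)}{p}\right).}
#' When \eqn{2^x \le 1 - p} the argument is nonpositive (a loss deeper than
#' purity can explain, or noise); the result is floored at
#' [deep_loss_sentinel()] and flagged.
#'
#' @param x Observed log2 copy ratio(s); finite.
#' @param p Tumor purity in (0, 1]; scalar or vector recycled against `x`.
#' @return Numeric vector of corrected ratios c, with attribute `floored`
#'   (logical vector) marking sentinel values.
#' @export
purity_correct <- function(x, p) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("purity p must be in (0, 1]", call. = FALSE)
  }
  arg <- (2^x - (1 - p)) / p
  floored <- arg <= 0
  c_out <- ifelse(floored, deep_loss_sentinel(), log2(pmax(arg, .Machine$double.xmin)))
  attr(c_out, "floored") <- floored
  c_out
}

#' Loss and gain thresholds on a triploid baseline
#'
#' Calling thresholds in purity-corrected log2 ratio units for the loss or
#' gain of at least one copy in a triploid tumor background, i.e. a 33% copy
#' decrease or increase: loss when c <= log2(2/3), gain when c >= log2(4/3).
#' Both boundaries are inclusive ("at least one copy").
#'
#' @return Named numeric vector `c(loss = log2(2/3), gain = log2(4/3))`.
#' @export
loss_gain_thresholds <- function() {
  c(loss = log2(2 / 3), gain = log2(4 / 3))
}

.cna_state <- function(c_value) {
  thr <- loss_gain_thresholds()
  ifelse(c_value <= thr[["loss"]], "loss",
         ifelse(c_value >= thr[["gain"]], "gain", "neutral"))
}

#' Attach purity-corrected means to a segment table
#'
#' Joins segments with per-sample purity and adds `corrected_mean` (and a
#' `floored` flag). Samples with no purity estimate are excluded from the
#' output with a message, mirroring restriction of purity-corrected analyses
#' to samples with an available purity estimate.
#'
#' @param seg Segment data.frame from [read_seg()].
#' @param purity Purity data.frame from [read_purity()].
#' @return The segment table with added columns `purity`, `corrected_mean`,
#'   `floored`, restricted to samples present in `purity`.
#' @export
correct_segments <- function(seg, purity) {
  validate_segments(seg)
  dropped <- setdiff(unique(seg$sample), purity$sample)
  if (length(dropped) > 0) {
    message(sprintf("correct_segments: excluding %d sample(s) without purity estimates: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    seg <- seg[!seg$sample %in% dropped, , drop = FALSE]
  }
  p <- purity$purity[match(seg$sample, purity$sample)]
  cc <- purity_correct(seg$seg_mean, p)
  seg$purity <- p
  seg$corrected_mean <- as.numeric(cc)
  seg$floored <- attr(cc, "floored")
  seg
}

# Length of overlap between [s1,e1) and [s2,e2), vectorized.
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Call a gene-level CNA for one sample
#'
#' The gene-level corrected ratio is the length-weighted mean of
#' `corrected_mean` over the segments overlapping the gene; the state follows
#' [loss_gain_thresholds()]. The support fraction is the fraction of the gene
#' covered by segments whose own state matches the call. A gene with no
#' overlapping segment is called neutral with support 0 and `uncovered = TRUE`.
#'
#' @param segments Corrected segments of a single sample
#'   (see [correct_segments()]).
#' @param gene A one-row data.frame or list with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`.
#' @return A one-row data.frame: `sample`, `target`, `state`,
#'   `support_fraction`, `mean_corrected`, `uncovered`.
#' @export
call_gene_cna <- function(segments, gene) {
  if (length(unique(segments$sample)) > 1) {
    stop("call_gene_cna expects segments from a single sample", call. = FALSE)
  }
  gchrom <- normalize_chrom(gene$chrom)
  gname <- if (!is.null(gene$name)) gene$name else sprintf("%s:%d-%d", gchrom, gene$start, gene$end)
  sid <- if (nrow(segments) > 0) segments$sample[[1]] else NA_character_
  hit <- segments$chrom == gchrom &
    .overlap_len(segments$start, segments$end, gene$start, gene$end) > 0
  hit_seg <- segments[hit, , drop = FALSE]
  if (nrow(hit_seg) == 0) {
    return(data.frame(sample = sid, target = gname, state = "neutral",
                      support_fraction = 0, mean_corrected = NA_real_,
                      uncovered = TRUE, stringsAsFactors = FALSE))
  }
  w <- .overlap_len(hit_seg$start, hit_seg$end, gene$start, gene$end)
  cbar <- sum(w * hit_seg$corrected_mean) / sum(w)
  state <- .cna_state(cbar)
  consistent <- .cna_state(hit_seg$corrected_mean) == state
  support <- sum(w[consistent]) / (gene$end - gene$start)
  data.frame(sample = hit_seg$sample[[1]], target = gname, state = state,
             support_fraction = support, mean_corrected = cbar,
             uncovered = FALSE, stringsAsFactors = FALSE)
}

#' Call an arm-level CNA for one sample
#'
#' An arm is called lost (gained) when segments at or beyond the loss (gain)
#' threshold cover at least `min_arm_fraction` of the arm — by default 75% of
#' the arm affected by the gain or loss of at least one copy in a triploid
#' background. Otherwise the arm is neutral. The two states cannot both reach
#' the cutoff since a segment is never simultaneously loss and gain.
#'
#' @param segments Corrected segments of a single sample.
#' @param arm One-row data.frame or list with `chrom`, `start`, `end`, `name`.
#' @param min_arm_fraction Minimum fraction of the arm affected; default 0.75.
#' @return One-row data.frame: `sample`, `target`, `state`,
#'   `support_fraction` (support of the called state; for neutral, the larger
#'   of the two directional supports).
#' @export
call_arm_cna <- function(segments, arm, min_arm_fraction = 0.75) {
  if (length(unique(segments$sample)) > 1) {
    stop("call_arm_cna expects segments from a single sample", call. = FALSE)
  }
  arm_len <- arm$end - arm$start
  if (is.null(arm_len) || arm_len <= 0) {
    stop("arm interval must have positive length", call. = FALSE)
  }
  achrom <- normalize_chrom(arm$chrom)
  sid <- if (nrow(segments) > 0) segments$sample[[1]] else NA_character_
  on_arm <- segments[segments$chrom == achrom, , drop = FALSE]
  w <- .overlap_len(on_arm$start, on_arm$end, arm$start, arm$end)
  st <- .cna_state(on_arm$corrected_mean)
  support_loss <- sum(w[st == "loss"]) / arm_len
  support_gain <- sum(w[st == "gain"]) / arm_len
  if (support_loss >= min_arm_fraction) {
    state <- "loss"; support <- support_loss
  } else if (support_gain >= min_arm_fraction) {
    state <- "gain"; support <- support_gain
  } else {
    state <- "neutral"; support <- max(support_loss, support_gain)
  }
  data.frame(sample = sid, target = arm$name, state = state,
             support_fraction = support, stringsAsFactors = FALSE)
}

#' Fraction of the genome altered
#'
#' The summed length of all copy-number-altered segments (corrected ratio at
#' or beyond the loss or gain threshold) divided by the total length surveyed
#' (the summed length of all segments).
#'
#' @param segments Corrected segments of a single sample; must be non-empty.
#' @return Scalar fga in \[0, 1\].
#' @export
fraction_genome_altered <- function(segments) {
  if (nrow(segments) == 0) {
    stop("fraction_genome_altered: empty segment list", call. = FALSE)
  }
  len <- segments$end - segments$start
  altered <- .cna_state(segments$corrected_mean) != "neutral"
  sum(len[altered]) / sum(len)
}

#' Assign aneuploidy terciles from fraction genome altered
#'
#' Samples are partitioned into three groups ("low", "mid", "high") by the
#' empirical terciles of their fga distribution. Ties are broken by stable
#' sample-id order and partition sizes are kept as equal as possible, with any
#' remainder going to the lower terciles.
#'
#' @param burdens data.frame with columns `sample`, `fga`; at least 3 rows.
#' @return The input with an added `aneuploidy_tercile` factor column.
#' @export
assign_terciles <- function(burdens) {
  n <- nrow(burdens)
  if (n < 3) stop("assign_terciles requires at least 3 samples", call. = FALSE)
  o <- order(burdens$fga, burdens$sample)
  sizes <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lab <- rep(c("low", "mid", "high"), times = sizes)
  burdens$aneuploidy_tercile <- factor(NA_character_,
                                       levels = c("low", "mid", "high"))
  burdens$aneuploidy_tercile[o] <- lab
  burdens
}

#' Cohort-wide CNA calls, burdens, and terciles
#'
#' Runs [call_gene_cna()] and [call_arm_cna()] for every sample against gene
#' and arm annotations, plus [fraction_genome_altered()] and
#' [assign_terciles()] per sample.
#'
#' @param seg Corrected segment table ([correct_segments()]).
#' @param genes BED-like data.frame of genes (may be NULL).
#' @param arms BED-like data.frame of chromosome arms.
#' @param min_arm_fraction Minimum fraction of an arm affected for an
#'   arm-level call; default 0.75.
#' @return List with `gene_calls`, `arm_calls` (long data.frames) and
#'   `burdens` (with `aneuploidy_tercile`).
#' @export
cohort_cna_calls <- function(seg, genes = NULL, arms,
                             min_arm_fraction = 0.75) {
  samples <- sort(unique(seg$sample))
  seg_state <- .cna_state(seg$corrected_mean)

  # Arm calls, vectorized over the cohort: per arm, length-weighted support
  # of each state accumulated per sample (matches call_arm_cna row by row).
  arm_calls <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    arm <- arms[i, ]
    achrom <- normalize_chrom(arm$chrom)
    sel <- seg$chrom == achrom
    w <- .overlap_len(seg$start[sel], seg$end[sel], arm$start, arm$end)
    sid <- factor(seg$sample[sel], levels = samples)
    sup_l <- tapply(w * (seg_state[sel] == "loss"), sid, sum, default = 0)
    sup_g <- tapply(w * (seg_state[sel] == "gain"), sid, sum, default = 0)
    arm_len <- arm$end - arm$start
    sup_l <- sup_l / arm_len; sup_g <- sup_g / arm_len
    state <- ifelse(sup_l >= min_arm_fraction, "loss",
                    ifelse(sup_g >= min_arm_fraction, "gain", "neutral"))
    data.frame(sample = samples, target = arm$name, state = state,
               support_fraction = ifelse(state == "loss", sup_l,
                                         ifelse(state == "gain", sup_g,
                                                pmax(sup_l, sup_g))),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  gene_calls <- NULL
  if (!is.null(genes) && nrow(genes) > 0) {
    gene_calls <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      gene <- genes[i, ]
      gchrom <- normalize_chrom(gene$chrom)
      sel <- seg$chrom == gchrom &
        .overlap_len(seg$start, seg$end, gene$start, gene$end) > 0
      w <- .overlap_len(seg$start[sel], seg$end[sel], gene$start, gene$end)
      sid <- factor(seg$sample[sel], levels = samples)
      cbar <- tapply(w * seg$corrected_mean[sel], sid, sum, default = NA) /
        tapply(w, sid, sum, default = NA)
      state <- ifelse(is.na(cbar), "neutral", .cna_state(cbar))
      consistent <- seg_state[sel] == state[as.integer(sid)]
      support <- tapply(w * consistent, sid, sum, default = 0) /
        (gene$end - gene$start)
      data.frame(sample = samples, target = gene$name, state = state,
                 support_fraction = as.numeric(support),
                 mean_corrected = as.numeric(cbar),
                 uncovered = is.na(cbar),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }

  len <- seg$end - seg$start
  sidf <- factor(seg$sample, levels = samples)
  fga <- tapply(len * (seg_state != "neutral"), sidf, sum) /
    tapply(len, sidf, sum)
  burdens <- data.frame(sample = samples, fga = as.numeric(fga),
                        stringsAsFactors = FALSE)
  if (nrow(burdens) >= 3) burdens <- assign_terciles(burdens)
  list(gene_calls = gene_calls, arm_calls = arm_calls, burdens = burdens)
}

#' Expand arm calls into a sample-by-event carrier matrix
#'
#' Each arm yields two events, `<arm>_loss` and `<arm>_gain`; a sample
#' carries an event when its arm state matches. This is the CohortTable
#' representation consumed by C-Norm and the co-occurrence tests.
#'
#' @param arm_calls Long data.frame from [cohort_cna_calls()].
#' @return Logical matrix, samples in rows, arm events in columns.
#' @export
arm_event_matrix <- function(arm_calls) {
  samples <- sort(unique(arm_calls$sample))
  arms <- unique(arm_calls$target)
  events <- c(paste0(arms, "_loss"), paste0(arms, "_gain"))
  m <- matrix(FALSE, nrow = length(samples), ncol = length(events),
              dimnames = list(samples, events))
  i <- match(arm_calls$sample, samples)
  hit <- arm_calls$state != "neutral"
  ev <- paste0(arm_calls$target, "_", arm_calls$state)[hit]
  m[cbind(i[hit], match(ev, events))] <- TRUE
  m
}
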