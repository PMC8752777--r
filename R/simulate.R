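# Approximate human autosome arm lengths (Mb) used by the cohort simulator.
# Acrocentric p arms are kept short but present so arm annotations always
# carry both arms of every chromosome.
.default_arm_table <- function() {
  chrlen <- c(249, 243, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
              114, 107, 102, 90, 83, 80, 59, 64, 47, 51)
  pfrac <- rep(0.45, 22)
  pfrac[c(13, 14, 15, 21, 22)] <- 0.12
  pfrac[8] <- 0.31
  pfrac[17] <- 0.30
  rows <- lapply(1:22, function(i) {
    plen <- round(chrlen[i] * pfrac[i] * 1e6)
    qlen <- chrlen[i] * 1e6 - plen
    data.frame(chrom = as.character(i),
               start = c(0L, plen),
               end = c(plen, plen + qlen),
               name = paste0(i, c("p", "q")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.default_gene_table <- function() {
  data.frame(chrom = c("8", "17"),
             start = c(11600000L, 7500000L),
             end = c(11700000L, 7600000L),
             name = c("GATA4", "TP53"),
             stringsAsFactors = FALSE)
}

.default_signatures <- function(n_per_set = 30) {
  sets <- c("CD8_T", "NK", "Macrophage")
  out <- lapply(seq_along(sets), function(i) {
    sprintf("IMM%d_%03d", i, seq_len(n_per_set))
  })
  stats::setNames(out, sets)
}

#' Configuration for the synthetic tumor-cohort generator
#'
#' Defaults encode the statistical structure the cohort analyses assume:
#' purity mixing of a clonal tumor copy state with normal cells, arm-level
#' CNA landscapes with -8p coupled to +8q, GATA4 focal status following the
#' 8p arm, TP53 loss-of-function enriched in GATA4-lost samples, and
#' immune-signature expression scaling with a latent infiltration level.
#'
#' @param n_samples Cohort size; default 400.
#' @param purity_shape1,purity_shape2 Beta parameters of the tumor-purity
#'   distribution; default Beta(5, 2).
#' @param purity_fixed When non-NULL, every sample gets this exact purity
#'   (e.g. 1 for pure tumors) instead of a Beta draw.
#' @param ploidy Baseline tumor ploidy; default 3 (the triploid calling
#'   background), so one-copy arm losses sit at the calling boundary by
#'   construction.
#' @param arm_loss_prob,arm_gain_prob Baseline per-arm event probabilities;
#'   defaults 0.12 each.
#' @param arm8p_loss_prob,arm8q_gain_prob Marginal probabilities of the -8p
#'   and +8q events; defaults 0.35 and 0.30.
#' @param coupling_odds Odds multiplier applied to +8q given -8p; default 4.
#' @param focal_gata4_prob Probability of a focal-only GATA4 deletion on a
#'   neutral 8p arm; default 0.03.
#' @param tp53_base_prob Baseline TP53 non-synonymous mutation probability;
#'   default 0.25.
#' @param tp53_coupling_odds Odds multiplier on TP53 mutation given GATA4
#'   loss; default 2.5.
#' @param gata4_effect Latent-infiltration shift (SD units) attributable to
#'   GATA4 loss; default 1.
#' @param covariate_effect Infiltration shift attributable to
#'   `covariate_event`; default 0.
#' @param covariate_event Arm event carrying the covariate effect; default
#'   `"8q_gain"`.
#' @param n_genes Number of background genes in the expression matrix;
#'   default 2000 (signature genes are added on top).
#' @param dispersion Negative-binomial dispersion of counts; default 0.2.
#' @param seg_noise_sd Gaussian noise added to emitted segment means;
#'   default 0 (boundary behavior stays exact).
#' @param boundary_epsilon Epsilon subtracted from one-copy-loss (and added
#'   to one-copy-gain) true ratios so calling boundaries do not flap under
#'   floating point; default 1e-6.
#' @param signatures Named list of signature gene sets; default three
#'   30-gene immune sets.
#' @param rng_seed Integer seed; recorded in all outputs.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 400,
                              purity_shape1 = 5, purity_shape2 = 2,
                              purity_fixed = NULL,
                              ploidy = 3,
                              arm_loss_prob = 0.12, arm_gain_prob = 0.12,
                              arm8p_loss_prob = 0.35, arm8q_gain_prob = 0.30,
                              coupling_odds = 4,
                              focal_gata4_prob = 0.03,
                              tp53_base_prob = 0.25,
                              tp53_coupling_odds = 2.5,
                              gata4_effect = 1,
                              covariate_effect = 0,
                              covariate_event = "8q_gain",
                              n_genes = 2000,
                              dispersion = 0.2,
                              seg_noise_sd = 0,
                              boundary_epsilon = 1e-6,
                              signatures = .default_signatures(),
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(arm_loss_prob, arm_gain_prob, arm8p_loss_prob, arm8q_gain_prob,
             focal_gata4_prob, tp53_base_prob)
  if (any(probs < 0) || any(probs > 1) || arm_loss_prob + arm_gain_prob > 1) {
    stop("event probabilities must lie in [0, 1] (and loss + gain <= 1)",
         call. = FALSE)
  }
  if (coupling_odds <= 0 || tp53_coupling_odds <= 0) {
    stop("coupling odds multipliers must be positive", call. = FALSE)
  }
  structure(cfg, class = "cohort_sim_config")
}

.odds_boost <- function(p, odds_mult) {
  o <- odds_mult * p / (1 - p)
  o / (1 + o)
}

#' Simulate a tumor cohort with known ground truth
#'
#' For each sample: draws arm-level CNA events (with the -8p/+8q odds
#' coupling), derives integer copy states on the ploidy baseline, computes
#' the true tumor-intrinsic ratio `c = log2(copies / ploidy)`, and emits the
#' observed segment mean `x = log2(p * 2^c + (1 - p))` under the sample's
#' purity. GATA4 focal status follows the 8p arm (plus an optional
#' focal-only deletion); TP53 loss-of-function is drawn with odds coupling
#' to GATA4 loss; a latent infiltration level
#' `z = N(0,1) + gata4_effect * [GATA4 lost] + covariate_effect * [covariate]`
#' scales signature-gene expression means by `exp(0.5 z)`; counts are
#' negative-binomial and also returned log-CPM-normalized.
#'
#' @param config A [cohort_sim_config()].
#' @param out_dir Optional directory; when given, SEG / purity / MAF-lite /
#'   expression / annotation files and a truth JSON are written there.
#' @return List: `seg` (internal 0-based convention, validated), `purity`,
#'   `maf`, `expression` (log2 CPM matrix, genes x samples), `counts`,
#'   `arms`, `genes`, `signatures`, and `truth` (per-sample data.frame plus
#'   the seed).
#' @export
simulate_cohort <- function(config = cohort_sim_config(), out_dir = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)

  arms <- .default_arm_table()
  genes <- .default_gene_table()
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  purity <- if (!is.null(config$purity_fixed)) {
    rep(config$purity_fixed, n)
  } else {
    pmin(pmax(stats::rbeta(n, config$purity_shape1, config$purity_shape2),
              0.1), 1)
  }

  ev_loss <- matrix(FALSE, n, nrow(arms), dimnames = list(sample_ids, arms$name))
  ev_gain <- matrix(FALSE, n, nrow(arms), dimnames = list(sample_ids, arms$name))
  for (j in seq_len(nrow(arms))) {
    arm <- arms$name[[j]]
    pl <- config$arm_loss_prob
    pg <- config$arm_gain_prob
    if (arm == "8p") { pl <- config$arm8p_loss_prob }
    if (arm == "8q") { pg <- config$arm8q_gain_prob }
    u <- stats::runif(n)
    ev_loss[, j] <- u < pl
    ev_gain[, j] <- u >= pl & u < pl + pg
  }
  # -8p -> +8q odds coupling: redraw +8q for 8p-lost samples at boosted odds.
  boosted <- .odds_boost(config$arm8q_gain_prob, config$coupling_odds)
  redraw <- ev_loss[, "8p"]
  ev_gain[redraw, "8q"] <- stats::runif(sum(redraw)) < boosted
  ev_loss[ev_gain[, "8q"], "8q"] <- FALSE

  copies <- matrix(config$ploidy, n, nrow(arms),
                   dimnames = list(sample_ids, arms$name))
  copies[ev_loss] <- config$ploidy - 1
  copies[ev_gain] <- config$ploidy + 1
  true_c <- log2(copies / config$ploidy)
  eps <- config$boundary_epsilon
  true_c[ev_loss] <- true_c[ev_loss] - eps
  true_c[ev_gain] <- true_c[ev_gain] + eps

  focal_gata4 <- !ev_loss[, "8p"] & stats::runif(n) < config$focal_gata4_prob
  gata4_lost <- ev_loss[, "8p"] | focal_gata4

  # Segments: one per arm; 8p is split around GATA4 for focal-only samples.
  gata4_iv <- genes[genes$name == "GATA4", ]
  arm8p <- arms[arms$name == "8p", ]
  seg_rows <- vector("list", n)
  for (i in seq_len(n)) {
    df <- data.frame(sample = sample_ids[[i]], chrom = arms$chrom,
                     start = arms$start, end = arms$end,
                     num_probes = pmax(10L, as.integer((arms$end - arms$start) / 1e5)),
                     seg_mean = true_c[i, ], stringsAsFactors = FALSE)
    if (focal_gata4[[i]]) {
      focal_c <- log2((config$ploidy - 1) / config$ploidy) - eps
      j <- which(df$chrom == "8" & df$start == arm8p$start)
      before <- df[j, ]; mid <- df[j, ]; after <- df[j, ]
      before$end <- gata4_iv$start
      mid$start <- gata4_iv$start; mid$end <- gata4_iv$end
      mid$seg_mean <- focal_c
      after$start <- gata4_iv$end
      df <- rbind(df[-j, ], before, mid, after)
    }
    seg_rows[[i]] <- df
  }
  seg <- do.call(rbind, seg_rows)
  rownames(seg) <- NULL
  # Mix with normal cells at the sample's purity to get the observed ratio.
  p_per_row <- purity[match(seg$sample, sample_ids)]
  seg$seg_mean <- log2(p_per_row * 2^seg$seg_mean + (1 - p_per_row))
  if (config$seg_noise_sd > 0) {
    seg$seg_mean <- seg$seg_mean + stats::rnorm(nrow(seg), 0, config$seg_noise_sd)
  }
  validate_segments(seg)

  # TP53 loss of function: mutation with odds coupling to GATA4 loss,
  # or deletion through 17p arm loss.
  p_mut <- ifelse(gata4_lost,
                  .odds_boost(config$tp53_base_prob, config$tp53_coupling_odds),
                  config$tp53_base_prob)
  tp53_mut <- stats::runif(n) < p_mut
  tp53_del <- ev_loss[, "17p"]
  tp53_lof <- tp53_mut | tp53_del
  nonsyn <- maf_variant_vocabulary(nonsynonymous = TRUE)
  maf_rows <- list()
  for (i in which(tp53_mut)) {
    maf_rows[[length(maf_rows) + 1L]] <- data.frame(
      sample = sample_ids[[i]], gene = "TP53",
      variant_classification = sample(nonsyn, 1), stringsAsFactors = FALSE)
  }
  silent <- stats::runif(n) < 0.05
  for (i in which(silent)) {
    maf_rows[[length(maf_rows) + 1L]] <- data.frame(
      sample = sample_ids[[i]], gene = "TP53",
      variant_classification = "Silent", stringsAsFactors = FALSE)
  }
  maf <- if (length(maf_rows) > 0) do.call(rbind, maf_rows) else
    data.frame(sample = character(), gene = character(),
               variant_classification = character(), stringsAsFactors = FALSE)

  # Latent infiltration and expression.
  covariate <- if (grepl("_gain$", config$covariate_event)) {
    ev_gain[, sub("_gain$", "", config$covariate_event)]
  } else {
    ev_loss[, sub("_loss$", "", config$covariate_event)]
  }
  z <- stats::rnorm(n) + config$gata4_effect * gata4_lost +
    config$covariate_effect * covariate
  sig_genes <- unlist(config$signatures, use.names = FALSE)
  bg_genes <- sprintf("BG%04d", seq_len(config$n_genes))
  all_genes <- c(sig_genes, bg_genes)
  base_mu <- stats::rlnorm(length(all_genes), meanlog = 4, sdlog = 1)
  scale <- matrix(1, length(all_genes), n)
  scale[seq_along(sig_genes), ] <- matrix(rep(exp(0.5 * z), each = length(sig_genes)),
                                          nrow = length(sig_genes))
  mu <- base_mu * scale
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow = length(all_genes),
                   dimnames = list(all_genes, sample_ids))
  libsize <- colSums(counts)
  expression <- log2(t(t(counts) / libsize) * 1e6 + 1)

  truth <- data.frame(sample = sample_ids, purity = purity,
                      gata4_lost = gata4_lost, focal_gata4 = focal_gata4,
                      tp53_mut = tp53_mut, tp53_del = tp53_del,
                      tp53_lof = tp53_lof, infiltration = z,
                      stringsAsFactors = FALSE)
  out <- list(seg = seg, purity = data.frame(sample = sample_ids,
                                             purity = purity,
                                             stringsAsFactors = FALSE),
              maf = maf, expression = expression, counts = counts,
              arms = arms, genes = genes, signatures = config$signatures,
              truth = list(samples = truth,
                           arm_loss = ev_loss, arm_gain = ev_gain,
                           true_c = true_c, rng_seed = config$rng_seed))
  if (!is.null(out_dir)) .write_cohort_files(out, out_dir)
  out
}

.write_cohort_files <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg_disk <- data.frame(Sample = sim$seg$sample,
                         Chromosome = sim$seg$chrom,
                         Start = sim$seg$start + 1L,   # 1-based inclusive on disk
                         End = sim$seg$end,
                         Num_Probes = sim$seg$num_probes,
                         Segment_Mean = sim$seg$seg_mean)
  utils::write.table(seg_disk, file.path(out_dir, "cohort.seg"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_result_tsv(sim$purity, file.path(out_dir, "purity.tsv"))
  maf_disk <- data.frame(Tumor_Sample_Barcode = sim$maf$sample,
                         Hugo_Symbol = sim$maf$gene,
                         Variant_Classification = sim$maf$variant_classification)
  utils::write.table(maf_disk, file.path(out_dir, "mutations.maf.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$arms, file.path(out_dir, "arms.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$genes, file.path(out_dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  expr <- data.frame(gene = rownames(sim$expression), sim$expression,
                     check.names = FALSE)
  utils::write.table(expr, file.path(out_dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(sim$signatures), function(nm) {
    paste(c(nm, "synthetic immune signature", sim$signatures[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(out_dir, "signatures.gmt"))
  write_result_json(list(samples = sim$truth$samples,
                         rng_seed = sim$truth$rng_seed),
                    file.path(out_dir, "truth.json"))
  invisible(out_dir)
}

#' Configuration for the synthetic amplicon-read generator
#'
#' @param reference_length Amplicon reference length in bp; default 240.
#' @param cut_site 0-based position of the nuclease cut; default 120.
#' @param editing_fraction Fraction of pairs carrying an indel; default 0.5.
#' @param indel_geom_prob Geometric parameter of the indel size distribution
#'   (size = 1 + Geom); default 0.3.
#' @param position_jitter Maximum +/- jitter of the indel around the cut
#'   site in bp; default 2.
#' @param deletion_prob Probability an indel is a deletion (vs insertion);
#'   default 0.6.
#' @param sub_error_rate Per-base substitution sequencing error rate;
#'   default 0.003.
#' @param read_length Read length; default 150 (paired 150-300 bp amplicon
#'   regime).
#' @param insert_mean,insert_sd Fragment (insert) size distribution;
#'   defaults: the full amplicon, sd 0. Inserts shorter than twice the read
#'   length give overlapping mates, exercising pair concordance.
#' @param n_pairs Number of read pairs; default 2000.
#' @param guide_length,pam_length sgRNA and PAM lengths defining the
#'   summarization window (guide ends 3 bp 5' of the cut; PAM 3' of the
#'   guide); defaults 20 and 3.
#' @param rng_seed Integer seed.
#' @return List of class `amplicon_sim_config`.
#' @export
amplicon_sim_config <- function(reference_length = 240,
                                cut_site = 120,
                                editing_fraction = 0.5,
                                indel_geom_prob = 0.3,
                                position_jitter = 2,
                                deletion_prob = 0.6,
                                sub_error_rate = 0.003,
                                read_length = 150,
                                insert_mean = NULL,
                                insert_sd = 0,
                                n_pairs = 2000,
                                guide_length = 20,
                                pam_length = 3,
                                rng_seed = 1L) {
  stopifnot(editing_fraction >= 0, editing_fraction <= 1, read_length >= 30,
            reference_length >= 3 * 30, cut_site > 30,
            cut_site < reference_length - 30)
  if (is.null(insert_mean)) insert_mean <- reference_length
  structure(as.list(environment()), class = "amplicon_sim_config")
}

#' sgRNA + PAM window implied by an amplicon simulation config
#'
#' The guide's 3' end sits 3 bp 5' of the cut site and the PAM lies
#' immediately 3' of the guide, so the window is
#' `[cut_site + 3 - guide_length, cut_site + 3 + pam_length)`, 0-based
#' half-open.
#'
#' @param config An [amplicon_sim_config()].
#' @return Integer vector `c(start, end)`.
#' @export
sgrna_window <- function(config) {
  guide_end <- config$cut_site + 3L
  c(guide_end - config$guide_length, guide_end + config$pam_length)
}

.apply_event <- function(ref, kind, pos, size, seq) {
  if (kind == "deletion") {
    paste0(substr(ref, 1, pos), substr(ref, pos + size + 1, nchar(ref)))
  } else {
    paste0(substr(ref, 1, pos), seq, substr(ref, pos + 1, nchar(ref)))
  }
}

.add_sub_errors <- function(seq, rate) {
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate)
  if (length(hits) == 0) return(seq)
  ch <- strsplit(seq, NULL)[[1]]
  for (i in hits) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate an edited amplicon sequencing library
#'
#' Generates a random reference, then per pair: with probability
#' `editing_fraction` introduces a single indel near the cut site (geometric
#' size, jittered position), fragments the (possibly edited) amplicon, and
#' emits overlapping paired-end reads with substitution errors. Ground truth
#' records each pair's edit status and its left-aligned canonical event.
#'
#' @param config An [amplicon_sim_config()].
#' @param out_dir Optional directory for FASTA / paired FASTQ / truth JSON.
#' @return List: `reference`, `reads` (data.frame `id`, `seq1`, `seq2`),
#'   `window` ([sgrna_window()]), `truth` (per-pair data.frame: `edited`,
#'   `kind`, `pos`, `size`), `rng_seed`.
#' @export
simulate_amplicon <- function(config = amplicon_sim_config(), out_dir = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)

  reference <- paste(sample(c("A", "C", "G", "T"), config$reference_length,
                            replace = TRUE), collapse = "")
  n <- config$n_pairs
  truth <- data.frame(id = sprintf("p%05d", seq_len(n)),
                      edited = logical(n), kind = NA_character_,
                      pos = NA_integer_, size = NA_integer_,
                      stringsAsFactors = FALSE)
  seq1 <- character(n); seq2 <- character(n)
  for (i in seq_len(n)) {
    mol <- reference
    if (stats::runif(1) < config$editing_fraction) {
      size <- 1L + stats::rgeom(1, config$indel_geom_prob)
      jitter <- sample(-config$position_jitter:config$position_jitter, 1)
      if (stats::runif(1) < config$deletion_prob) {
        kind <- "deletion"
        pos <- config$cut_site - size %/% 2L + jitter
        seqi <- ""
      } else {
        kind <- "insertion"
        pos <- config$cut_site + jitter
        seqi <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                      collapse = "")
      }
      canon <- .left_align_event(kind, pos, size, seqi, reference)
      truth$edited[[i]] <- TRUE
      truth$kind[[i]] <- canon$kind
      truth$pos[[i]] <- canon$pos
      truth$size[[i]] <- canon$size
      mol <- .apply_event(reference, kind, pos, size, seqi)
    }
    mlen <- nchar(mol)
    flen <- round(stats::rnorm(1, config$insert_mean, config$insert_sd))
    flen <- max(min(flen, mlen), min(config$read_length, mlen))
    fstart <- if (mlen > flen) sample.int(mlen - flen + 1L, 1) else 1L
    frag <- substr(mol, fstart, fstart + flen - 1L)
    r1 <- substr(frag, 1, min(config$read_length, flen))
    r2 <- .revcomp(substr(frag, max(1, flen - config$read_length + 1L), flen))
    seq1[[i]] <- .add_sub_errors(r1, config$sub_error_rate)
    seq2[[i]] <- .add_sub_errors(r2, config$sub_error_rate)
  }
  reads <- data.frame(id = truth$id, seq1 = seq1, seq2 = seq2,
                      stringsAsFactors = FALSE)
  out <- list(reference = reference, reads = reads,
              window = sgrna_window(config), truth = truth,
              rng_seed = config$rng_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(c(">amplicon", reference), file.path(out_dir, "reference.fa"))
    qual <- function(s) strrep("I", nchar(s))
    writeLines(as.vector(rbind(paste0("@", reads$id, "/1"), reads$seq1,
                               "+", vapply(reads$seq1, qual, ""))),
               file.path(out_dir, "reads_R1.fastq"))
    writeLines(as.vector(rbind(paste0("@", reads$id, "/2"), reads$seq2,
                               "+", vapply(reads$seq2, qual, ""))),
               file.path(out_dir, "reads_R2.fastq"))
    write_result_json(list(truth = truth, rng_seed = config$rng_seed),
                      file.path(out_dir, "truth.json"))
  }
  out
}
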