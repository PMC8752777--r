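.config_from <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  config
}

.file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.make_manifest <- function(config, seed, inputs, outputs, timings) {
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  on.exit(unlink(cfg_file))
  list(tool = "cnakit",
       version = as.character(utils::packageVersion("cnakit")),
       config_hash = unname(tools::md5sum(cfg_file)),
       seed = seed,
       input_checksums = .file_checksums(inputs),
       stage_timings_sec = timings,
       output_inventory = .file_checksums(outputs))
}

# Derive per-stage RNG seeds from one master seed (documented stream split;
# kept below 2^31).
.stage_seed <- function(master, stage_index) {
  (as.integer(master) * 37L + 1009L * as.integer(stage_index)) %% 2147480000L
}

#' Run the cohort CNA workflow
#'
#' End-to-end ordering: input acquisition (synthetic simulation by default,
#' or SEG / purity / MAF / annotation files) -> purity correction -> gene and
#' arm CNA calls, fraction genome altered and terciles -> optional
#' low-aneuploidy restriction -> group definition by GATA4 status -> C-Norm
#' -> signature association before and after C-Norm -> TP53 co-occurrence
#' and arm co-association. All randomness derives from `config$seed` by a
#' fixed stream split, so reruns with an identical config are identical.
#'
#' @param config List (or YAML path) with optional entries: `mode`
#'   ("synthetic", the default, or "files"), `seed`, `sim` (overrides for
#'   [cohort_sim_config()]), `seg`/`purity`/`maf`/`arms`/`genes`/`gmt` file
#'   paths for file mode, `defining_cna` (default "8p_loss"),
#'   `low_aneuploidy_only` (default FALSE), `anchor_event` (default the
#'   defining CNA).
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest; files are written under `out_dir`.
#' @export
run_cohort_workflow <- function(config = list(), out_dir) {
  config <- .config_from(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  defining <- if (!is.null(config$defining_cna)) config$defining_cna else "8p_loss"
  anchor <- if (!is.null(config$anchor_event)) config$anchor_event else defining
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  inputs <- character()
  if (identical(config$mode, "files")) {
    for (f in c("seg", "purity", "arms")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop(sprintf("input reading stage: missing %s file", f), call. = FALSE)
      }
    }
    seg <- read_seg(config$seg)
    purity <- read_purity(config$purity)
    arms <- read_bed_annotation(config$arms, arms = TRUE)
    genes <- if (!is.null(config$genes)) read_bed_annotation(config$genes) else .default_gene_table()
    maf <- if (!is.null(config$maf)) read_maf_lite(config$maf) else NULL
    signatures <- if (!is.null(config$gmt)) read_gmt(config$gmt) else .default_signatures()
    expression <- if (!is.null(config$expression)) {
      m <- utils::read.delim(config$expression, check.names = FALSE)
      as.matrix(data.frame(m[, -1], row.names = m[[1]], check.names = FALSE))
    } else NULL
    inputs <- unlist(config[c("seg", "purity", "maf", "arms", "genes",
                              "gmt", "expression")], use.names = FALSE)
  } else {
    sim_args <- if (!is.null(config$sim)) config$sim else list()
    sim_args$rng_seed <- .stage_seed(seed, 1L)
    sim <- do.call(cohort_sim_config, sim_args)
    data <- simulate_cohort(sim)
    seg <- data$seg; purity <- data$purity; maf <- data$maf
    arms <- data$arms; genes <- data$genes
    signatures <- data$signatures; expression <- data$expression
    write_result_json(list(rng_seed = sim$rng_seed,
                           samples = data$truth$samples),
                      file.path(out_dir, "truth.json"))
  }
  timings$input <- lap(t0)

  t0 <- tic()
  corrected <- correct_segments(seg, purity)
  calls <- cohort_cna_calls(corrected, genes = genes, arms = arms)
  timings$cna_calls <- lap(t0)

  burdens <- calls$burdens
  if (isTRUE(config$low_aneuploidy_only)) {
    keep <- burdens$sample[burdens$aneuploidy_tercile == "low"]
    calls$arm_calls <- calls$arm_calls[calls$arm_calls$sample %in% keep, ]
    calls$gene_calls <- calls$gene_calls[calls$gene_calls$sample %in% keep, ]
    if (!is.null(expression)) {
      expression <- expression[, colnames(expression) %in% keep, drop = FALSE]
    }
  }

  t0 <- tic()
  carriers <- arm_event_matrix(calls$arm_calls)
  gata4 <- calls$gene_calls[calls$gene_calls$target == "GATA4", ]
  group <- factor(ifelse(gata4$state[match(rownames(carriers), gata4$sample)] == "loss",
                         "GATA4_loss", "GATA4_wt"),
                  levels = c("GATA4_loss", "GATA4_wt"))
  cn <- run_cnorm(carriers, group,
                  cnorm_config(rng_seed = .stage_seed(seed, 2L),
                               defining_cna = defining))
  timings$cnorm <- lap(t0)

  t0 <- tic()
  assoc_naive <- assoc_cnorm <- NULL
  if (!is.null(expression)) {
    scores <- signature_score_matrix(expression, signatures)
    scores <- scores[rownames(scores) %in% rownames(carriers), , drop = FALSE]
    g2 <- group[match(rownames(scores), rownames(carriers))]
    if (min(table(g2)) >= 3) {
      assoc_naive <- association_after_cnorm(scores, g2, result = NULL)
      assoc_cnorm <- tryCatch(association_after_cnorm(scores, g2, result = cn),
                              error = function(e) {
                                message("association stage: ", conditionMessage(e))
                                NULL
                              })
    } else {
      message("association stage: a group has fewer than 3 scored samples; skipping the contrast")
    }
  }
  timings$association <- lap(t0)

  t0 <- tic()
  cooccur_tp53 <- NULL
  if (!is.null(maf)) {
    samples <- rownames(carriers)
    tp53 <- tp53_lof_status(maf, calls$gene_calls, samples)
    g_loss <- group == "GATA4_loss"
    cooccur_tp53 <- list(N = length(samples), K = sum(g_loss),
                         n = sum(tp53), k = sum(g_loss & tp53))
    cooccur_tp53$p_enrich <- hypergeom_enrichment(cooccur_tp53$N, cooccur_tp53$K,
                                                  cooccur_tp53$n, cooccur_tp53$k)
  }
  coassoc <- pairwise_arm_coassociation(carriers, anchor)
  timings$cooccurrence <- lap(t0)

  out_files <- c(arm_calls = "arm_calls.tsv", gene_calls = "gene_calls.tsv",
                 burdens = "burdens.tsv", retained = "cnorm_retained.tsv",
                 trace = "cnorm_trace.tsv", coassoc = "arm_coassociation.tsv")
  write_result_tsv(calls$arm_calls, file.path(out_dir, out_files["arm_calls"]))
  write_result_tsv(calls$gene_calls, file.path(out_dir, out_files["gene_calls"]))
  write_result_tsv(burdens, file.path(out_dir, out_files["burdens"]))
  write_result_tsv(data.frame(sample = cn$retained),
                   file.path(out_dir, out_files["retained"]))
  write_result_tsv(cn$removal_trace, file.path(out_dir, out_files["trace"]))
  write_result_tsv(coassoc, file.path(out_dir, out_files["coassoc"]))
  if (!is.null(assoc_naive)) {
    write_result_tsv(assoc_naive, file.path(out_dir, "association_naive.tsv"))
  }
  if (!is.null(assoc_cnorm)) {
    write_result_tsv(assoc_cnorm, file.path(out_dir, "association_cnorm.tsv"))
  }
  cnorm_report <- list(achieved = cn$achieved,
                       initial_max_diff = cn$initial_max_diff,
                       final_max_diff = cn$final_max_diff,
                       n_removed = nrow(cn$removal_trace),
                       rng_seed = cn$config$rng_seed)
  write_result_json(cnorm_report, file.path(out_dir, "cnorm_report.json"))
  if (!is.null(cooccur_tp53)) {
    write_result_json(cooccur_tp53, file.path(out_dir, "cooccurrence_tp53.json"))
  }
  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- .make_manifest(config, seed, inputs, outputs, timings)
  write_result_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(calls = calls, cnorm = cn, association_naive = assoc_naive,
                 association_cnorm = assoc_cnorm, cooccurrence_tp53 = cooccur_tp53,
                 coassociation = coassoc, manifest = manifest))
}

#' Run the amplicon indel-quantification workflow
#'
#' Simulates (default) or reads one or more paired-end amplicon libraries,
#' runs the anchor-and-extend caller on each, and optionally pools the
#' libraries of one biological group by summing their window tallies and
#' per-event counts.
#'
#' @param config List (or YAML path): `seed`; either `sim` (overrides for
#'   [amplicon_sim_config()]) or `libraries` (list of lists with `r1`, `r2`,
#'   `reference`, `window`); `pool` (default TRUE) to aggregate libraries.
#' @param out_dir Output directory.
#' @return Invisibly, a list with per-library results, the pooled summary
#'   (if pooling), and the manifest.
#' @export
run_amplicon_workflow <- function(config = list(), out_dir) {
  config <- .config_from(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  inputs <- character()
  t0 <- Sys.time()
  libs <- list()
  if (!is.null(config$libraries)) {
    for (i in seq_along(config$libraries)) {
      lb <- config$libraries[[i]]
      reads <- read_fastq_pairs(lb$r1, lb$r2)
      libs[[i]] <- list(reads = reads, reference = lb$reference,
                        window = as.integer(lb$window))
      inputs <- c(inputs, lb$r1, lb$r2,
                  if (is.character(lb$reference)) lb$reference)
    }
  } else {
    sim_args <- if (!is.null(config$sim)) config$sim else list()
    sim_args$rng_seed <- .stage_seed(seed, 1L)
    sim <- do.call(amplicon_sim_config, sim_args)
    data <- simulate_amplicon(sim)
    libs[[1]] <- list(reads = data$reads, reference = data$reference,
                      window = data$window)
    write_result_json(list(rng_seed = data$rng_seed, truth = data$truth),
                      file.path(out_dir, "truth.json"))
  }
  timings$input <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- Sys.time()
  results <- lapply(libs, function(lb) {
    run_amplicon_pipeline(lb$reads, lb$reference, lb$window)
  })
  timings$alignment <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  pooled <- NULL
  if (!isFALSE(config$pool) && length(results) >= 1) {
    n_wt <- sum(vapply(results, function(r) r$summary$n_wildtype, numeric(1)))
    n_ed <- sum(vapply(results, function(r) r$summary$n_edited, numeric(1)))
    ev <- do.call(rbind, lapply(results, function(r) r$events))
    if (nrow(ev) > 0) {
      agg <- stats::aggregate(supporting_pairs ~ kind + pos + size, ev, sum)
      ev <- agg[order(-agg$supporting_pairs, agg$pos), ]
    }
    pooled <- list(n_wildtype = n_wt, n_edited = n_ed,
                   fraction_edited = if (n_wt + n_ed > 0) n_ed / (n_wt + n_ed) else NA_real_,
                   event_table = ev)
  }

  for (i in seq_along(results)) {
    r <- results[[i]]
    write_result_tsv(r$events, file.path(out_dir, sprintf("events_lib%d.tsv", i)))
    write_result_json(list(n_wildtype = r$summary$n_wildtype,
                           n_edited = r$summary$n_edited,
                           n_excluded_overlap = r$summary$n_excluded_overlap,
                           fraction_edited = r$summary$fraction_edited,
                           discarded = as.list(r$discarded),
                           n_pairs = r$n_pairs),
                      file.path(out_dir, sprintf("summary_lib%d.json", i)))
  }
  if (!is.null(pooled)) {
    write_result_tsv(pooled$event_table, file.path(out_dir, "events_pooled.tsv"))
    write_result_json(pooled[c("n_wildtype", "n_edited", "fraction_edited")],
                      file.path(out_dir, "summary_pooled.json"))
  }
  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- .make_manifest(config, seed, inputs, outputs, timings)
  write_result_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(libraries = results, pooled = pooled, manifest = manifest))
}
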