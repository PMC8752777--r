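# A fixed 80 bp reference used across the alignment tests (no repeats at the
# ends; a tandem repeat is placed internally for the multi-hit lookup test).
ref80 <- paste0("ACGTACGGTTCAGCTAAGGCTTACCGGATCAAGCTTGGCA",
                "TCGATCGATGGCCATTCAGGACCTGAATCGTACGGTCCAA")

test_that("exact-match index finds unique, absent and repeated words", {
  idx <- build_index(ref80)
  expect_equal(index_lookup(idx, substr(ref80, 11, 20)), 11L)
  expect_equal(index_lookup(idx, "TTTTTTTTTT"), integer(0))
  # tandem repeat: TCGATCGAT contains TCGAT twice (overlapping matches)
  hits <- index_lookup(idx, "TCGAT")
  naive <- which(vapply(seq_len(nchar(ref80) - 4),
                        function(i) substr(ref80, i, i + 4) == "TCGAT",
                        logical(1)))
  expect_equal(hits, as.integer(naive))
  expect_true(length(hits) >= 2)
  # N never matches
  idxN <- build_index(paste0(ref80, "NNNNNNNNNN"))
  expect_equal(index_lookup(idxN, "NNNNN"), integer(0))
  expect_error(build_index("ACGT"), "at least 30")
})

test_that("read ends anchor with sliding-window soft-clips up to 10 bp", {
  idx <- build_index(ref80)
  read <- substr(ref80, 16, 55)
  anc <- anchor_read(read, idx)
  expect_equal(anc$left_pos, 16L)
  expect_equal(anc$right_pos, 46L)
  expect_equal(anc$left_clip, 0L)
  expect_equal(anc$right_clip, 0L)

  # last 4 bases corrupted: right anchor found at clip offset 4
  bad_tail <- paste0(substr(read, 1, 36), "AAAA")
  bad_tail <- sub("AAAA$", "GGGG", bad_tail)  # ensure mismatch with reference
  anc2 <- anchor_read(bad_tail, idx)
  expect_equal(anc2$right_clip, 4L)
  expect_equal(anc2$right_pos, 42L)

  # unanchorable read: terminal words match nowhere within the clip limit
  junk <- strrep("AT", 20)
  expect_null(anchor_read(junk, idx))
})

test_that("inter-anchor alignment reproduces engineered indels", {
  idx <- build_index(ref80)
  read <- substr(ref80, 6, 70)
  anc <- anchor_read(read, idx)
  aln <- align_between_anchors(read, anc, idx)
  expect_equal(nrow(aln$events), 0)
  expect_equal(aln$n_mismatch, 0)
  expect_false(aln$rejected)
  expect_equal(aln$ref_start, 5L)
  expect_equal(aln$ref_end, 70L)

  # 3 bp deletion at reference offset 40 (0-based)
  del_read <- paste0(substr(ref80, 6, 40), substr(ref80, 44, 70))
  a2 <- align_read(del_read, idx)
  expect_equal(a2$events$kind, "deletion")
  expect_equal(a2$events$size, 3L)
  canon <- normalize_events(data.frame(kind = "deletion", pos = 40L,
                                       size = 3L, seq = "",
                                       stringsAsFactors = FALSE), ref80)
  expect_equal(a2$events$pos, canon$pos)

  # 4 bp insertion at the same junction
  ins_read <- paste0(substr(ref80, 6, 40), "TTTT", substr(ref80, 41, 70))
  a3 <- align_read(ins_read, idx)
  expect_equal(a3$events$kind, "insertion")
  expect_equal(a3$events$size, 4L)
})

test_that("reads with more than four mismatches are rejected", {
  idx <- build_index(ref80)
  read <- substr(ref80, 6, 70)
  flip <- function(s, at) {
    for (i in at) {
      old <- substr(s, i, i)
      substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  # 5 scattered substitutions strictly between the anchors -> rejected
  r5 <- flip(read, c(15, 20, 25, 30, 35))
  a5 <- align_read(r5, idx)
  expect_true(a5$rejected)
  expect_equal(a5$n_mismatch, 5L)
  # 4 substitutions pass ("up to four mismatches")
  r4 <- flip(read, c(15, 20, 25, 30))
  expect_false(align_read(r4, idx)$rejected)
})

test_that("anchored alignment equals the full dynamic-programming oracle", {
  set.seed(52)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  idx <- build_index(base)
  for (i in 1:20) {
    start <- sample(1:40, 1)
    len <- sample(80:150, 1)
    read <- substr(base, start, min(200, start + len))
    # random internal indel, clear of the 10 bp terminal anchors
    mid <- nchar(read) %/% 2
    if (i %% 2 == 0) {
      read <- paste0(substr(read, 1, mid), substr(read, mid + 4, nchar(read)))
    } else {
      read <- paste0(substr(read, 1, mid), "ACGTA", substr(read, mid + 1, nchar(read)))
    }
    aln <- align_read(read, idx)
    span_ref <- substr(base, aln$ref_start + 1, aln$ref_end)
    expect_equal(aln$score, oracle_global_score(read, span_ref),
                 label = sprintf("case %d", i))
  }
})

test_that("indels left-align to their leftmost equivalent position", {
  # deletion inside a homopolymer run: AAAA at offsets 10..13 (0-based)
  ref <- paste0("CGTACGGTTC", "AAAA", "GCTTACCGGATCAAGCTTGGCATCGATCGG")
  ev <- normalize_events(data.frame(kind = "deletion", pos = 12L, size = 1L,
                                    seq = "", stringsAsFactors = FALSE), ref)
  expect_equal(ev$pos, 10L)
  ev2 <- normalize_events(data.frame(kind = "insertion", pos = 13L, size = 2L,
                                     seq = "AA", stringsAsFactors = FALSE), ref)
  expect_equal(ev2$pos, 10L)
})

test_that("pair concordance enforces agreement inside the mate overlap", {
  mk <- function(start, end, strand, events = NULL) {
    ev <- if (is.null(events)) {
      data.frame(kind = character(), pos = integer(), size = integer(),
                 seq = character(), stringsAsFactors = FALSE)
    } else events
    structure(list(ref_start = start, ref_end = end, strand = strand,
                   events = ev, score = 0, n_mismatch = 0, rejected = FALSE),
              class = "amplicon_alignment")
  }
  del55 <- data.frame(kind = "deletion", pos = 55L, size = 3L, seq = "",
                      stringsAsFactors = FALSE)
  # both mates report the deletion inside their overlap -> retained
  pc <- pair_concordance(mk(0, 80, "+", del55), mk(30, 110, "-", del55))
  expect_true(pc$proper)
  expect_equal(nrow(pc$events), 1)
  # one mate wild-type across the event -> discarded
  pc2 <- pair_concordance(mk(0, 80, "+", del55), mk(30, 110, "-"))
  expect_true(pc2$proper)
  expect_equal(nrow(pc2$events), 0)
  # event outside the overlap: single-mate support suffices
  del10 <- data.frame(kind = "deletion", pos = 10L, size = 2L, seq = "",
                      stringsAsFactors = FALSE)
  pc3 <- pair_concordance(mk(0, 80, "+", del10), mk(60, 140, "-"))
  expect_true(pc3$proper)
  expect_equal(pc3$events$pos, 10L)
  # same-strand mates are improper
  expect_false(pair_concordance(mk(0, 80, "+"), mk(30, 110, "+"))$proper)
})

test_that("window summarization needs 20 bp overlap and tallies pairs", {
  win <- c(100L, 123L)
  mkpair <- function(span, events = NULL) {
    ev <- if (is.null(events)) {
      data.frame(kind = character(), pos = integer(), size = integer(),
                 seq = character(), stringsAsFactors = FALSE)
    } else events
    list(proper = TRUE, events = ev, span = span)
  }
  del <- data.frame(kind = "deletion", pos = 110L, size = 2L, seq = "",
                    stringsAsFactors = FALSE)
  pairs <- list(
    mkpair(c(0L, 112L), del),        # 12 bp overlap -> excluded
    mkpair(c(0L, 200L)),             # contributing, wild-type
    mkpair(c(0L, 200L), del)         # contributing, edited
  )
  s <- summarize_window(pairs, win)
  expect_equal(s$n_excluded_overlap, 1L)
  expect_equal(s$n_wildtype, 1L)
  expect_equal(s$n_edited, 1L)
  expect_equal(s$fraction_edited, 0.5)
  expect_equal(s$event_table$supporting_pairs, 1L)
  expect_error(summarize_window(pairs, NULL), "window")
})

test_that("pipeline conserves pairs across outcome classes", {
  sim <- simulate_amplicon(amplicon_sim_config(n_pairs = 150, rng_seed = 31))
  res <- run_amplicon_pipeline(sim$reads, sim$reference, sim$window)
  contributing <- res$summary$n_wildtype + res$summary$n_edited
  expect_equal(contributing + res$summary$n_excluded_overlap +
                 sum(res$discarded), res$n_pairs)
  # deterministic: same inputs, same outputs
  res2 <- run_amplicon_pipeline(sim$reads, sim$reference, sim$window)
  expect_identical(res$summary$fraction_edited, res2$summary$fraction_edited)
  expect_identical(res$events, res2$events)
})

test_that("event coordinates shift exactly with extra reference padding", {
  sim <- simulate_amplicon(amplicon_sim_config(n_pairs = 60, rng_seed = 77,
                                               sub_error_rate = 0))
  res <- run_amplicon_pipeline(sim$reads, sim$reference, sim$window)
  pad <- 25L
  padded <- paste0(strrep("T", pad), sim$reference, strrep("C", pad))
  res_p <- run_amplicon_pipeline(sim$reads, padded, sim$window + pad)
  expect_equal(res$summary$fraction_edited, res_p$summary$fraction_edited)
  o1 <- res$events[order(res$events$pos, res$events$kind, res$events$size), ]
  o2 <- res_p$events[order(res_p$events$pos, res_p$events$kind, res_p$events$size), ]
  expect_equal(o2$pos, o1$pos + pad)
  expect_equal(o2$size, o1$size)
  expect_equal(o2$supporting_pairs, o1$supporting_pairs)
})

test_that("an empty library yields an empty summary", {
  reads <- data.frame(id = character(), seq1 = character(),
                      seq2 = character(), stringsAsFactors = FALSE)
  res <- run_amplicon_pipeline(reads, ref80, c(30L, 53L))
  expect_equal(res$summary$n_edited + res$summary$n_wildtype, 0)
  expect_true(is.na(res$summary$fraction_edited))
  expect_equal(nrow(res$events), 0)
})
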