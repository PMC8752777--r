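#' Alignment scoring parameters for the amplicon aligner
#'
#' Defaults chosen so that short and long indels score above the rejection
#' floor while substitution-heavy reads are removed by the explicit mismatch
#' cap (applied as a post-filter, separate from the score).
#'
#' @param match Match score; default +2.
#' @param mismatch Mismatch score; default -2.
#' @param gap_open Gap-opening penalty (positive); a gap of length L costs
#'   `gap_open + L * gap_extend`; default 4.
#' @param gap_extend Per-base gap extension penalty (positive); default 0.5.
#' @return Named list of scoring parameters.
#' @export
amplicon_scoring <- function(match = 2, mismatch = -2,
                             gap_open = 4, gap_extend = 0.5) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Build an exact-match index over an amplicon reference
#'
#' Indexes every 10-mer of the reference for O(1) exact-match lookup — the
#' anchoring primitive of the aligner. `N` bases never match: 10-mers
#' containing `N` are not indexed and queries containing `N` return no hits.
#'
#' @param reference Reference sequence (A/C/G/T/N), at least 30 bp; typically
#'   the target locus supplemented with 10 bp genomic flanks.
#' @param k Anchor word size; default 10.
#' @return An object of class `amplicon_index`.
#' @export
build_index <- function(reference, k = 10L) {
  reference <- toupper(reference)
  if (nchar(reference) < 30) {
    stop("reference must be at least 30 bp", call. = FALSE)
  }
  if (grepl("[^ACGTN]", reference)) {
    stop("reference may contain only A, C, G, T, N", call. = FALSE)
  }
  L <- nchar(reference)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(reference, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  idx <- split(starts[ok], kmers[ok])
  structure(list(sequence = reference, k = as.integer(k), index = idx),
            class = "amplicon_index")
}

#' Exact-match lookup in an amplicon index
#'
#' Returns all (possibly overlapping) start positions of `query` in the
#' reference, 1-based, sorted. Queries of at least `k` bases use the k-mer
#' index and verify the extension; shorter queries are scanned directly.
#'
#' @param index An [build_index()] object.
#' @param query Query sequence, at least 1 bp.
#' @return Sorted integer vector of 1-based match positions.
#' @export
index_lookup <- function(index, query) {
  query <- toupper(query)
  qn <- nchar(query)
  if (qn < 1) stop("query must be at least 1 bp", call. = FALSE)
  if (grepl("N", query, fixed = TRUE)) return(integer(0))
  L <- nchar(index$sequence)
  if (qn >= index$k) {
    cand <- index$index[[substr(query, 1, index$k)]]
    if (is.null(cand)) return(integer(0))
    cand <- cand[cand + qn - 1L <= L]
    hits <- cand[substring(index$sequence, cand, cand + qn - 1L) == query]
  } else {
    starts <- seq_len(L - qn + 1L)
    hits <- starts[substring(index$sequence, starts, starts + qn - 1L) == query]
  }
  sort(as.integer(hits))
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, NULL)[[1]]), collapse = ""))
}

#' Anchor a read's ends in the reference
#'
#' Each read end is anchored by exact `k`-mer lookup of its terminal segment,
#' sliding inwards one base at a time up to the soft-clip limit until an
#' exact match is found. Among the candidate left/right placements, the
#' consistently ordered pair spanning the maximal reference distance is
#' selected. Returns `NULL` when either end finds no anchor within the clip
#' limit, or when no consistent pair exists (ambiguous placement).
#'
#' @param read Read sequence, at least 30 bp.
#' @param index An [build_index()] object.
#' @param max_clip Maximal soft-clip per end; default 10.
#' @return List `left_pos`, `right_pos` (1-based reference starts of the two
#'   anchor words), `left_clip`, `right_clip`; or `NULL`.
#' @export
anchor_read <- function(read, index, max_clip = 10L) {
  k <- index$k
  L <- nchar(read)
  if (L < 30) stop("read must be at least 30 bp", call. = FALSE)
  left_pos <- integer(0); left_clip <- NA_integer_
  for (off in 0:max_clip) {
    hits <- index_lookup(index, substr(read, 1L + off, k + off))
    if (length(hits) > 0) { left_pos <- hits; left_clip <- off; break }
  }
  if (length(left_pos) == 0) return(NULL)
  right_pos <- integer(0); right_clip <- NA_integer_
  for (off in 0:max_clip) {
    hits <- index_lookup(index, substr(read, L - k + 1L - off, L - off))
    if (length(hits) > 0) { right_pos <- hits; right_clip <- off; break }
  }
  if (length(right_pos) == 0) return(NULL)
  combos <- expand.grid(lp = left_pos, rp = right_pos)
  combos <- combos[combos$rp >= combos$lp + k, , drop = FALSE]
  if (nrow(combos) == 0) return(NULL)
  best <- combos[which.max(combos$rp - combos$lp), , drop = FALSE]
  list(left_pos = best$lp[[1]], right_pos = best$rp[[1]],
       left_clip = left_clip, right_clip = right_clip)
}

# Parse "10M3D2M" into data.frame(len, op).
.parse_cigar <- function(cigar) {
  if (!nzchar(cigar)) {
    return(data.frame(len = integer(), op = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("\\d+[MID]", cigar)[[1]]
  tok <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  data.frame(len = as.integer(sub("[MID]", "", tok)),
             op = sub("\\d+", "", tok), stringsAsFactors = FALSE)
}

# Left-align an indel against the reference (leftmost equivalent position),
# making mate-concordance comparison well-defined in repeat context.
# Positions are 0-based; a deletion occupies [pos, pos + size); an insertion
# of `seq` sits at the junction before reference offset pos.
.left_align_event <- function(kind, pos, size, seq, reference) {
  ref <- strsplit(reference, NULL)[[1]]
  if (kind == "deletion") {
    while (pos > 0 && ref[pos] == ref[pos + size]) pos <- pos - 1L
  } else {
    s <- strsplit(seq, NULL)[[1]]
    while (pos > 0 && ref[pos] == s[length(s)]) {
      s <- c(s[length(s)], s[-length(s)])
      pos <- pos - 1L
    }
    seq <- paste(s, collapse = "")
  }
  list(kind = kind, pos = as.integer(pos), size = as.integer(size), seq = seq)
}

#' Left-align (normalize) a table of indel events
#'
#' @param events data.frame with `kind`, `pos` (0-based), `size`, `seq`.
#' @param reference Reference sequence.
#' @return The events with canonical leftmost positions.
#' @export
normalize_events <- function(events, reference) {
  if (nrow(events) == 0) return(events)
  for (i in seq_len(nrow(events))) {
    e <- .left_align_event(events$kind[[i]], events$pos[[i]],
                           events$size[[i]], events$seq[[i]], reference)
    events$pos[[i]] <- e$pos
    events$seq[[i]] <- e$seq
  }
  events
}

#' Align the inter-anchor segment of a read
#'
#' Performs optimal affine-gap dynamic-programming alignment between the
#' read sequence inside its two anchors and the reference spanning the
#' maximally distanced anchor placements, then reassembles the full
#' alignment (anchors are exact matches by construction). Alignments with
#' more than `max_mismatch` mismatches are rejected; soft-clipped bases are
#' excluded from mismatch counting.
#'
#' @param read Read sequence (orientation already resolved).
#' @param anchors Anchor pair from [anchor_read()].
#' @param index An [build_index()] object.
#' @param scoring [amplicon_scoring()] parameters.
#' @param max_mismatch Mismatch cap; default 4 ("up to four mismatches").
#' @return List of class `amplicon_alignment`: `ref_start`, `ref_end`
#'   (0-based half-open span on the reference), `cigar`, `score`,
#'   `n_mismatch`, `events` (left-aligned indel data.frame), `rejected`.
#' @export
align_between_anchors <- function(read, anchors, index,
                                  scoring = amplicon_scoring(),
                                  max_mismatch = 4L) {
  k <- index$k
  L <- nchar(read)
  ref <- index$sequence
  lp <- anchors$left_pos; rp <- anchors$right_pos
  lc <- anchors$left_clip; rc <- anchors$right_clip
  inner_read <- substr(read, lc + k + 1L, L - rc - k)
  inner_ref <- substr(ref, lp + k, rp - 1L)
  dp <- .affine_align_cpp(inner_read, inner_ref, scoring$match,
                          scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend)
  score <- dp$score + 2 * k * scoring$match
  cigar <- paste0(k, "M", dp$cigar, k, "M")

  # Walk the CIGAR to collect indel events (0-based reference coordinates).
  ops <- .parse_cigar(cigar)
  rpos <- lp - 1L            # 0-based reference cursor
  qpos <- lc                 # 0-based read cursor past the left clip
  ev <- list()
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[[i]]; op <- ops$op[[i]]
    if (op == "M") {
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "deletion", pos = rpos, size = len, seq = "",
        stringsAsFactors = FALSE)
      rpos <- rpos + len
    } else {
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "insertion", pos = rpos, size = len,
        seq = substr(read, qpos + 1L, qpos + len), stringsAsFactors = FALSE)
      qpos <- qpos + len
    }
  }
  events <- if (length(ev) > 0) do.call(rbind, ev) else
    data.frame(kind = character(), pos = integer(), size = integer(),
               seq = character(), stringsAsFactors = FALSE)
  events <- normalize_events(events, ref)
  structure(list(ref_start = lp - 1L, ref_end = rp + k - 1L,
                 cigar = cigar, score = score,
                 n_mismatch = dp$n_mismatch, events = events,
                 rejected = dp$n_mismatch > max_mismatch),
            class = "amplicon_alignment")
}

#' Anchor and align one read in both orientations
#'
#' Tries the read as given and reverse-complemented; when both orientations
#' anchor, the higher-scoring alignment wins. Returns `NULL` when neither
#' orientation anchors.
#'
#' @inheritParams align_between_anchors
#' @return An `amplicon_alignment` with an added `strand` ("+" or "-"), or
#'   `NULL`.
#' @export
align_read <- function(read, index, scoring = amplicon_scoring(),
                       max_mismatch = 4L) {
  out <- NULL
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") read else .revcomp(read)
    anc <- anchor_read(seq, index)
    if (is.null(anc)) next
    aln <- align_between_anchors(seq, anc, index, scoring, max_mismatch)
    aln$strand <- strand
    if (is.null(out) || aln$score > out$score) out <- aln
  }
  out
}

.event_interval <- function(events) {
  # Interval footprint used for overlap logic: deletions span their deleted
  # bases; an insertion spans the two reference bases flanking its junction.
  s <- ifelse(events$kind == "deletion", events$pos, events$pos - 1L)
  e <- ifelse(events$kind == "deletion", events$pos + events$size,
              events$pos + 1L)
  cbind(start = pmax(s, 0L), end = e)
}

#' Reconcile the indel events of a read pair
#'
#' Requires proper orientation (mates on opposite strands, forward mate
#' upstream). An event whose footprint lies inside the mates' reference
#' overlap is retained only when both mates report it identically (kind,
#' position, size); an event outside the overlap is retained on the support
#' of its covering mate alone.
#'
#' @param aln1,aln2 `amplicon_alignment` objects for the two mates.
#' @return List: `proper` (logical), `events` (reconciled data.frame),
#'   `span` (0-based half-open union of the mate spans), or `proper = FALSE`.
#' @export
pair_concordance <- function(aln1, aln2) {
  improper <- list(proper = FALSE, events = NULL, span = NULL)
  if (is.null(aln1) || is.null(aln2)) return(improper)
  if (aln1$strand == aln2$strand) return(improper)
  fwd <- if (aln1$strand == "+") aln1 else aln2
  rev <- if (aln1$strand == "+") aln2 else aln1
  if (fwd$ref_start > rev$ref_start || fwd$ref_end > rev$ref_end) {
    return(improper)
  }
  ov_start <- max(aln1$ref_start, aln2$ref_start)
  ov_end <- min(aln1$ref_end, aln2$ref_end)
  key <- function(ev) paste(ev$kind, ev$pos, ev$size, sep = ":")
  all_ev <- unique(rbind(aln1$events, aln2$events))
  if (nrow(all_ev) == 0) {
    return(list(proper = TRUE, events = all_ev,
                span = c(min(aln1$ref_start, aln2$ref_start),
                         max(aln1$ref_end, aln2$ref_end))))
  }
  iv <- .event_interval(all_ev)
  in_overlap <- ov_start < ov_end & iv[, "start"] < ov_end & iv[, "end"] > ov_start
  k1 <- key(aln1$events); k2 <- key(aln2$events); ka <- key(all_ev)
  keep <- ifelse(in_overlap, ka %in% k1 & ka %in% k2, ka %in% c(k1, k2))
  list(proper = TRUE, events = all_ev[keep, , drop = FALSE],
       span = c(min(aln1$ref_start, aln2$ref_start),
                max(aln1$ref_end, aln2$ref_end)))
}

#' Summarize editing within the sgRNA + PAM window
#'
#' Only read pairs whose aligned span overlaps the window by at least
#' `min_overlap` bases contribute. A contributing pair is "edited" when it
#' carries at least one retained indel whose footprint intersects the
#' window, otherwise it counts as wild-type.
#'
#' @param pairs List of reconciled pairs from [pair_concordance()] (proper
#'   pairs only).
#' @param window Integer vector `c(start, end)`, 0-based half-open, covering
#'   the sgRNA sequence and PAM site.
#' @param min_overlap Minimum alignment-window overlap in bp; default 20.
#' @return List of class `edit_summary`: `n_wildtype`, `n_edited`,
#'   `n_excluded_overlap`, `fraction_edited`, `event_table` (per-event
#'   supporting pair counts over contributing pairs).
#' @export
summarize_window <- function(pairs, window, min_overlap = 20L) {
  if (is.null(window) || length(window) != 2 || window[[2]] <= window[[1]]) {
    stop("a valid sgRNA+PAM window is required", call. = FALSE)
  }
  n_wt <- 0L; n_ed <- 0L; n_ex <- 0L
  tally <- list()
  for (p in pairs) {
    ov <- min(p$span[[2]], window[[2]]) - max(p$span[[1]], window[[1]])
    if (ov < min_overlap) { n_ex <- n_ex + 1L; next }
    ev <- p$events
    hit <- FALSE
    if (!is.null(ev) && nrow(ev) > 0) {
      iv <- .event_interval(ev)
      in_win <- iv[, "start"] < window[[2]] & iv[, "end"] > window[[1]]
      if (any(in_win)) {
        hit <- TRUE
        for (i in which(in_win)) {
          k <- paste(ev$kind[[i]], ev$pos[[i]], ev$size[[i]], sep = ":")
          tally[[k]] <- if (is.null(tally[[k]])) {
            list(kind = ev$kind[[i]], pos = ev$pos[[i]], size = ev$size[[i]],
                 n = 1L)
          } else {
            utils::modifyList(tally[[k]], list(n = tally[[k]]$n + 1L))
          }
        }
      }
    }
    if (hit) n_ed <- n_ed + 1L else n_wt <- n_wt + 1L
  }
  event_table <- if (length(tally) > 0) {
    df <- do.call(rbind, lapply(tally, function(t) {
      data.frame(kind = t$kind, pos = t$pos, size = t$size,
                 supporting_pairs = t$n, stringsAsFactors = FALSE)
    }))
    rownames(df) <- NULL
    df[order(-df$supporting_pairs, df$pos), , drop = FALSE]
  } else {
    data.frame(kind = character(), pos = integer(), size = integer(),
               supporting_pairs = integer(), stringsAsFactors = FALSE)
  }
  denom <- n_wt + n_ed
  structure(list(n_wildtype = n_wt, n_edited = n_ed,
                 n_excluded_overlap = n_ex,
                 fraction_edited = if (denom > 0) n_ed / denom else NA_real_,
                 event_table = event_table),
            class = "edit_summary")
}

#' @export
print.edit_summary <- function(x, ...) {
  cat(sprintf("Edit summary: %d edited / %d contributing pairs (%.1f%%); %d excluded by window overlap\n",
              x$n_edited, x$n_edited + x$n_wildtype,
              100 * x$fraction_edited, x$n_excluded_overlap))
  invisible(x)
}

#' Run the full amplicon indel-quantification pipeline
#'
#' Anchors and aligns every mate of every pair in both orientations, applies
#' the mismatch cap, enforces paired-read concordance, and summarizes
#' editing within the sgRNA + PAM window. Deterministic: identical inputs
#' give identical outputs.
#'
#' @param reads data.frame with columns `id`, `seq1`, `seq2`
#'   ([read_fastq_pairs()]), or `r1_path`/`r2_path` FASTQ paths via the
#'   `...`-free convenience arguments below.
#' @param reference Reference sequence, or a path to a FASTA file.
#' @param window sgRNA + PAM window, `c(start, end)` 0-based half-open.
#' @param scoring [amplicon_scoring()] parameters.
#' @param max_mismatch Per-read mismatch cap; default 4.
#' @param min_overlap Window-overlap requirement in bp; default 20.
#' @return List of class `amplicon_result`: `summary` ([summarize_window()]
#'   output), `events` (per-event table), `discarded` (named counts by
#'   reason: `no_anchor`, `too_many_mismatches`, `improper_orientation`),
#'   `n_pairs`.
#' @export
run_amplicon_pipeline <- function(reads, reference, window,
                                  scoring = amplicon_scoring(),
                                  max_mismatch = 4L, min_overlap = 20L) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- unname(read_fasta(reference)[[1]])
  }
  index <- build_index(reference)
  discarded <- c(no_anchor = 0L, too_many_mismatches = 0L,
                 improper_orientation = 0L)
  good_pairs <- list()
  for (i in seq_len(nrow(reads))) {
    a1 <- align_read(reads$seq1[[i]], index, scoring, max_mismatch)
    a2 <- align_read(reads$seq2[[i]], index, scoring, max_mismatch)
    if (is.null(a1) || is.null(a2)) {
      discarded[["no_anchor"]] <- discarded[["no_anchor"]] + 1L
      next
    }
    if (a1$rejected || a2$rejected) {
      discarded[["too_many_mismatches"]] <- discarded[["too_many_mismatches"]] + 1L
      next
    }
    pc <- pair_concordance(a1, a2)
    if (!pc$proper) {
      discarded[["improper_orientation"]] <- discarded[["improper_orientation"]] + 1L
      next
    }
    good_pairs[[length(good_pairs) + 1L]] <- pc
  }
  summary <- summarize_window(good_pairs, window, min_overlap)
  structure(list(summary = summary, events = summary$event_table,
                 discarded = discarded, n_pairs = nrow(reads)),
            class = "amplicon_result")
}
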