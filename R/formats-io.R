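#' @useDynLib cnakit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Chromosome names are canonicalized by stripping any leading "chr"/"Chr",
# so "chr8" and "8" compare equal everywhere downstream.
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  if (any(!nzchar(chrom) | is.na(chrom))) {
    stop("chromosome names must be non-empty", call. = FALSE)
  }
  sub("^[Cc][Hh][Rr]", "", chrom)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a SEG file of segmented copy-number ratios
#'
#' Reads a tab-delimited SEG file with header columns `Sample`, `Chromosome`,
#' `Start`, `End`, `Num_Probes`, `Segment_Mean`. On-disk coordinates are
#' 1-based inclusive; they are converted once, here, to the package-internal
#' 0-based half-open convention. Segments belonging to one sample must not
#' overlap; overlapping input is an error rather than being silently merged.
#'
#' @param path Path to a tab-delimited SEG file.
#' @return A data.frame with columns `sample`, `chrom` (canonicalized, no
#'   "chr" prefix), `start`, `end` (0-based half-open), `num_probes`,
#'   `seg_mean` (log2 copy ratio, the observed quantity x).
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("Sample", "Chromosome", "Start", "End",
                         "Num_Probes", "Segment_Mean"), "SEG file")
  if (nrow(df) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      num_probes = integer(), seg_mean = numeric(),
                      stringsAsFactors = FALSE))
  }
  seg_mean <- suppressWarnings(as.numeric(df$Segment_Mean))
  bad <- which(!is.finite(seg_mean))
  if (length(bad) > 0) {
    stop(sprintf("SEG file: non-numeric or non-finite Segment_Mean at data line(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    sample = as.character(df$Sample),
    chrom = normalize_chrom(df$Chromosome),
    start = as.integer(df$Start) - 1L,
    end = as.integer(df$End),
    num_probes = as.integer(df$Num_Probes),
    seg_mean = seg_mean,
    stringsAsFactors = FALSE
  )
  validate_segments(out)
  out
}

#' Validate a segment table
#'
#' Checks interval invariants (start >= 0, end > start, num_probes >= 0) and
#' that segments within one sample do not overlap.
#'
#' @param seg A segment data.frame as returned by [read_seg()].
#' @return The input, invisibly, if valid.
#' @export
validate_segments <- function(seg) {
  .require_columns(seg, c("sample", "chrom", "start", "end", "seg_mean"),
                   "segment table")
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(seg$start < 0) || any(seg$end <= seg$start)) {
    stop("segment table: intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(seg$num_probes) && any(seg$num_probes < 0, na.rm = TRUE)) {
    stop("segment table: num_probes must be nonnegative", call. = FALSE)
  }
  if (any(!is.finite(seg$seg_mean))) {
    stop("segment table: seg_mean must be finite", call. = FALSE)
  }
  key <- split(seq_len(nrow(seg)), paste(seg$sample, seg$chrom, sep = "\r"))
  for (idx in key) {
    if (length(idx) < 2) next
    o <- idx[order(seg$start[idx])]
    if (any(seg$start[o][-1] < seg$end[o][-length(o)])) {
      stop(sprintf("segment table: overlapping segments for sample '%s' on chromosome %s",
                   seg$sample[o][1], seg$chrom[o][1]), call. = FALSE)
    }
  }
  invisible(seg)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of unique gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d: expected at least 3 tab-separated fields", i),
           call. = FALSE)
    }
    name <- fields[[1]]
    members <- fields[-c(1, 2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicate members dropped", name),
              call. = FALSE)
      members <- unique(members)
    }
    if (length(members) < 1) {
      stop(sprintf("GMT set '%s': empty member list", name), call. = FALSE)
    }
    if (name %in% names(sets)) {
      stop(sprintf("GMT: set name '%s' appears more than once (ambiguous collection)",
                   name), call. = FALSE)
    }
    sets[[name]] <- members
  }
  sets
}

#' Controlled vocabulary of MAF variant classifications
#'
#' @param nonsynonymous If `TRUE`, return only the classifications counted as
#'   protein-altering (used for TP53 loss-of-function calls).
#' @return Character vector of classification tokens.
#' @export
maf_variant_vocabulary <- function(nonsynonymous = FALSE) {
  nonsyn <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
              "Frame_Shift_Del", "Splice_Site", "Nonstop_Mutation",
              "Translation_Start_Site", "In_Frame_Ins", "In_Frame_Del")
  if (nonsynonymous) return(nonsyn)
  c(nonsyn, "Silent", "3'UTR", "5'UTR", "Intron", "IGR", "RNA",
    "3'Flank", "5'Flank")
}

#' Read a MAF-lite mutation table
#'
#' Expects tab-delimited columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`; classifications must come from
#' [maf_variant_vocabulary()].
#'
#' @param path Path to a MAF-lite TSV.
#' @return A data.frame with columns `sample`, `gene`, `variant_classification`.
#' @export
read_maf_lite <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("Tumor_Sample_Barcode", "Hugo_Symbol",
                         "Variant_Classification"), "MAF-lite file")
  vc <- as.character(df$Variant_Classification)
  unknown <- setdiff(unique(vc), maf_variant_vocabulary())
  if (length(unknown) > 0) {
    stop(sprintf("MAF-lite: unknown Variant_Classification token(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  data.frame(sample = as.character(df$Tumor_Sample_Barcode),
             gene = as.character(df$Hugo_Symbol),
             variant_classification = vc,
             stringsAsFactors = FALSE)
}

#' Read per-sample tumor purity estimates
#'
#' @param path Path to a tab-delimited file with columns `sample`, `purity`.
#' @return A data.frame with columns `sample`, `purity`; purity in (0, 1],
#'   one row per sample.
#' @export
read_purity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("sample", "purity"), "purity file")
  p <- suppressWarnings(as.numeric(df$purity))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("purity file: purity values must be finite and in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df$sample)) {
    stop("purity file: more than one record for a sample", call. = FALSE)
  }
  data.frame(sample = as.character(df$sample), purity = p,
             stringsAsFactors = FALSE)
}

#' Read a BED-like annotation of genes or chromosome arms
#'
#' BED convention on disk: 0-based half-open, columns `chrom`, `start`,
#' `end`, `name` (no header). With `arms = TRUE` the names must follow the
#' `<chrom>p` / `<chrom>q` pattern and every chromosome present must carry
#' both of its arms, so arm-level calling is never silently one-sided.
#'
#' @param path Path to a 4-column BED-like TSV.
#' @param arms If `TRUE`, validate the file as a chromosome-arm annotation.
#' @return A data.frame with columns `chrom` (canonicalized), `start`, `end`,
#'   `name`.
#' @export
read_bed_annotation <- function(path, arms = FALSE) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) {
    stop("BED annotation: expected 4 columns (chrom, start, end, name)",
         call. = FALSE)
  }
  out <- data.frame(chrom = normalize_chrom(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    name = as.character(df[[4]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$end <= out$start)) {
    stop("BED annotation: intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (anyDuplicated(out$name)) {
    stop("BED annotation: duplicate feature names", call. = FALSE)
  }
  if (arms) {
    arm_letter <- sub("^.*(p|q)$", "\\1", out$name)
    arm_chrom <- sub("(p|q)$", "", out$name)
    if (any(!arm_letter %in% c("p", "q")) || any(!nzchar(arm_chrom))) {
      stop("arm annotation: names must look like '8p' / '8q'", call. = FALSE)
    }
    for (ch in unique(arm_chrom)) {
      have <- sort(arm_letter[arm_chrom == ch])
      if (!identical(have, c("p", "q"))) {
        stop(sprintf("arm annotation: chromosome %s is missing arm %s",
                     ch, setdiff(c("p", "q"), have)), call. = FALSE)
      }
    }
  }
  out
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

.strip_mate_suffix <- function(ids) {
  ids <- sub("\\s.*$", "", ids)       # modern convention: "id 1:N:0:..."
  sub("/[12]$", "", ids)              # classic convention: "id/1", "id/2"
}

#' Read paired-end FASTQ files
#'
#' Mates are matched by read identifier after stripping `/1`, `/2` or
#' whitespace-delimited mate descriptors. Any orphan identifier is an error.
#'
#' @param r1_path,r2_path Paths to the forward and reverse FASTQ files.
#' @return A data.frame with columns `id`, `seq1`, `seq2` (uppercase).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  id1 <- .strip_mate_suffix(names(r1))
  id2 <- .strip_mate_suffix(names(r2))
  orphans <- c(setdiff(id1, id2), setdiff(id2, id1))
  if (length(orphans) > 0) {
    stop(sprintf("unmatched read pair id(s): %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(id1) || anyDuplicated(id2)) {
    stop("duplicate read identifiers within a FASTQ file", call. = FALSE)
  }
  m <- match(id1, id2)
  data.frame(id = id1,
             seq1 = toupper(as.character(r1)),
             seq2 = toupper(as.character(r2))[m],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write and read result tables
#'
#' `write_result_tsv()` / `read_result_tsv()` round-trip any result
#' data.frame (values identical within printed precision);
#' `write_result_json()` writes a list as JSON with unboxed scalars.
#'
#' @param x A data.frame (TSV) or list (JSON).
#' @param path Output path.
#' @return `path`, invisibly; `read_result_tsv()` returns a data.frame.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_result_tsv
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
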