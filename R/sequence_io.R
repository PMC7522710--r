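#' Read a FASTA file of reference sequences
#'
#' @param path FASTA file.
#' @return named character vector (one element per record, order preserved);
#'   empty vector for an empty file.
#' @export
read_fasta <- function(path) {
  if (file.exists(path) && file.size(path) == 0) return(setNames(character(0), character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reference sequences to FASTA
#'
#' @param refs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(unname(refs))
  names(x) <- names(refs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

# structural FASTQ validation producing line-numbered errors
.validate_fastq_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record starting at line ",
         (n %/% 4L) * 4L + 1L)
  for (i in seq_len(n %/% 4L)) {
    b <- (i - 1L) * 4L
    if (!startsWith(lines[b + 1L], "@"))
      stop("malformed FASTQ '", path, "': expected '@' header at line ", b + 1L)
    if (!startsWith(lines[b + 3L], "+"))
      stop("malformed FASTQ '", path, "': expected '+' separator at line ", b + 3L)
    if (nchar(lines[b + 2L]) != nchar(lines[b + 4L]))
      stop("malformed FASTQ '", path, "': sequence/quality length mismatch ",
           "for record at line ", b + 1L)
  }
  invisible(lines)
}

#' Read a FASTQ file of small-RNA reads
#'
#' Phred+33 qualities. Malformed records raise an error naming the offending
#' line; an empty file yields an empty collection.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  empty <- data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  if (file.exists(path) && file.size(path) == 0) return(empty)
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path,
      quality.scoring = "phred")),  # benign metadata-column warnings
    error = function(e) {
      .validate_fastq_lines(path)  # produce a line-numbered error if malformed
      stop(e)
    })
  .validate_fastq_lines(path)
  if (length(x) == 0L) return(empty)
  data.frame(read_id = unname(sub("\\s.*$", "", names(x))),
             seq = unname(as.character(x)),
             qual = unname(as.character(Biostrings::quality(x))),
             stringsAsFactors = FALSE)
}

#' Write small-RNA reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `seq`, `qual` (qual may be
#'   missing, in which case constant Phred 40 is written).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(qual))
  names(x) <- reads$read_id
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

# decode Phred+33 quality string to integer scores
phred_scores <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

#' Trim 3' adapters and filter reads by quality and size
#'
#' Locates the leftmost occurrence of the adapter at the read 3' end,
#' allowing at most 10\% mismatches over the overlapping bases (minimum
#' overlap 3 nt, so a terminal 3-nt overlap must match exactly), and
#' truncates the read there. Reads are then discarded when (in this order
#' of precedence) no adapter was found (`require_adapter = TRUE`), the mean
#' Phred score of the trimmed insert is not above `min_phred`, or the
#' trimmed length falls outside `size_window`.
#'
#' @param reads data.frame with `read_id`, `seq`, and optionally `qual`.
#' @param adapter 3' adapter sequence (DNA string); must be non-empty.
#' @param min_phred mean-Phred threshold (strictly greater-than).
#' @param size_window inclusive insert length window (nt).
#' @param max_error_rate adapter mismatch tolerance per overlap base.
#' @param min_overlap minimum adapter overlap (nt).
#' @param require_adapter discard reads without an adapter hit (the standard
#'   small-RNA library rule); set FALSE for already-trimmed input.
#' @return list with `kept` (trimmed reads data.frame) and `stats` (named
#'   integer vector: input, kept, no_adapter, low_quality, too_short,
#'   too_long).
#' @export
trim_and_filter <- function(reads, adapter, min_phred = 20,
                            size_window = c(19L, 33L),
                            max_error_rate = 0.1, min_overlap = 3L,
                            require_adapter = TRUE) {
  if (missing(adapter) || is.null(adapter) || !nzchar(adapter))
    stop("a non-empty adapter sequence is required")
  adapter <- toupper(adapter)
  araw <- charToRaw(adapter)
  la <- length(araw)
  n <- nrow(reads)
  has_qual <- !is.null(reads$qual)

  keep <- logical(n)
  out_seq <- character(n)
  out_qual <- character(n)
  reason <- character(n)

  for (r in seq_len(n)) {
    sq <- reads$seq[r]
    rraw <- charToRaw(sq)
    len <- length(rraw)
    cut <- NA_integer_  # first adapter base position in the read
    if (len >= min_overlap) {
      for (t in seq_len(len - min_overlap + 1L)) {
        ov <- min(len - t + 1L, la)
        mm <- sum(rraw[t:(t + ov - 1L)] != araw[seq_len(ov)])
        if (mm <= floor(max_error_rate * ov)) { cut <- t; break }
      }
    }
    if (is.na(cut)) {
      if (require_adapter) { reason[r] <- "no_adapter"; next }
      ins_len <- len
    } else {
      ins_len <- cut - 1L
    }
    ins <- substr(sq, 1L, ins_len)
    q <- if (has_qual) substr(reads$qual[r], 1L, ins_len) else strrep("I", ins_len)
    mq <- if (ins_len > 0L) mean(phred_scores(q)) else 0
    if (!(mq > min_phred)) { reason[r] <- "low_quality"; next }
    if (ins_len < size_window[1]) { reason[r] <- "too_short"; next }
    if (ins_len > size_window[2]) { reason[r] <- "too_long"; next }
    keep[r] <- TRUE
    out_seq[r] <- ins
    out_qual[r] <- q
  }

  kept <- data.frame(read_id = reads$read_id[keep], seq = out_seq[keep],
                     qual = out_qual[keep], stringsAsFactors = FALSE)
  stats <- c(input = n, kept = sum(keep),
             no_adapter = sum(reason == "no_adapter"),
             low_quality = sum(reason == "low_quality"),
             too_short = sum(reason == "too_short"),
             too_long = sum(reason == "too_long"))
  list(kept = kept, stats = stats)
}

#' Write alignments in a minimal SAM dialect
#'
#' Emits @HD/@SQ header lines and one record per alignment with FLAG 0/16,
#' 1-based POS, ungapped CIGAR, and the NM:i mismatch tag. SEQ/QUAL are
#' stored in reference-forward orientation (reverse-complemented for minus
#' strand alignments), following the SAM convention.
#'
#' @param alignments alignment data.frame (see [align_reads()]).
#' @param reads data.frame with `read_id`, `seq`, optionally `qual`; used to
#'   fill SEQ/QUAL.
#' @param refs named character vector of reference sequences (for @SQ).
#' @param path output file.
#' @export
write_sam <- function(alignments, reads, refs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(refs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs)[i], nchar(refs[[i]])), con)
  }
  if (nrow(alignments) == 0L) return(invisible(path))
  idx <- match(alignments$read_id, reads$read_id)
  sq <- reads$seq[idx]
  ql <- if (!is.null(reads$qual)) reads$qual[idx] else strrep("I", nchar(sq))
  neg <- alignments$strand == "-"
  if (any(neg)) {
    sq[neg] <- dna_revcomp(sq[neg])
    ql[neg] <- vapply(ql[neg], function(q)
      paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""), character(1))
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                 alignments$read_id, ifelse(neg, 16L, 0L), alignments$ref_id,
                 alignments$pos, alignments$read_len, sq, ql,
                 alignments$mismatches)
  writeLines(rec, con)
  invisible(path)
}
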