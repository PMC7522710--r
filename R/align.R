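#' Build a k-mer index of a reference sequence
#'
#' Maps every k-mer of the reference (+ strand) to its 1-based start
#' positions; k-mers containing N are skipped. The index is the seeding
#' structure of the small-read aligner.
#'
#' @param ref named character vector of length 1 (or list with `id`/`seq`).
#' @param k seed length; must satisfy `1 <= k <= nchar(ref)`.
#' @return a `kmer_index` object (list: ref_id, ref_len, k, env, refraw).
#' @export
build_index <- function(ref, k = 12L) {
  r <- as_refseq(ref)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  L <- nchar(r$seq)
  if (k > L) stop("seed length k (", k, ") exceeds reference length (", L, ")")
  starts <- seq_len(L - k + 1L)
  kmers <- substring(r$seq, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  env <- list2env(split(starts[keep], kmers[keep]), hash = TRUE)
  structure(list(ref_id = r$id, ref_len = L, k = k, env = env,
                 refraw = charToRaw(r$seq)),
            class = "kmer_index")
}

#' Look up the positions of a k-mer in an index
#'
#' @param index a [build_index()] object.
#' @param kmer a string of length `index$k`.
#' @return integer vector of 1-based positions (empty when absent).
#' @export
index_lookup <- function(index, kmer) {
  hits <- get0(kmer, envir = index$env, ifnotfound = NULL)
  if (is.null(hits)) integer(0) else hits
}

# candidate placements of `target` (already oriented) against the index,
# from its first and last k-mer seeds
.seed_candidates <- function(target, index) {
  k <- index$k
  len <- nchar(target)
  o2 <- len - k + 1L
  p1 <- index_lookup(index, substr(target, 1L, k))
  p2 <- index_lookup(index, substr(target, o2, len))
  cand <- unique(c(p1, p2 - o2 + 1L))
  cand[cand >= 1L & cand + len - 1L <= index$ref_len]
}

.verify_candidates <- function(target, cand, index, max_mismatch) {
  if (length(cand) == 0L) return(list(pos = integer(0), mm = integer(0)))
  traw <- charToRaw(target)
  len <- length(traw)
  mm <- vapply(cand, function(p)
    sum(index$refraw[p:(p + len - 1L)] != traw), integer(1))
  ok <- mm <= max_mismatch
  list(pos = cand[ok], mm = mm[ok])
}

#' Align one small read to an indexed reference
#'
#' Seed-and-verify ungapped alignment on both strands with an exact
#' mismatch-stratum contract: if any 0-mismatch placement exists only
#' 0-mismatch placements are reported; otherwise (with `max_mismatch = 1`)
#' all 1-mismatch placements. Multi-mappers are reported in full and
#' down-weighted by `1/n_best`. Seeds are the first and last k-mer of the
#' read (and of its reverse complement); by the pigeonhole principle this
#' finds every placement with at most one mismatch whenever
#' `k <= floor(readlen/2)`.
#'
#' @param read a single read: data.frame row or list with `read_id`, `seq`.
#' @param index a [build_index()] object.
#' @param max_mismatch 0 or 1.
#' @return alignment data.frame (possibly empty): read_id, ref_id, pos,
#'   strand, mismatches, n_best, weight, read_len, five_prime. `pos` is the
#'   1-based leftmost footprint coordinate; `five_prime` is the reference
#'   coordinate of the read's 5' base (`pos` on +, `pos + readlen - 1` on -).
#'   Ties are ordered by (pos, strand) with + before -.
#' @export
align_read <- function(read, index, max_mismatch = 0L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  seq <- toupper(read$seq)
  if (nchar(seq) < index$k)
    stop("read shorter than seed length k = ", index$k)
  .align_seq(read$read_id, seq, dna_revcomp(seq), index, as.integer(max_mismatch))
}

.align_seq_core <- function(fwd, rev, index, max_mismatch) {
  vf <- .verify_candidates(fwd, .seed_candidates(fwd, index), index, max_mismatch)
  vr <- .verify_candidates(rev, .seed_candidates(rev, index), index, max_mismatch)
  pos <- c(vf$pos, vr$pos)
  if (length(pos) == 0L) return(NULL)
  mm <- c(vf$mm, vr$mm)
  strand <- rep(c("+", "-"), c(length(vf$pos), length(vr$pos)))
  if (any(mm == 0L)) {  # best stratum only
    keep <- mm == 0L
    pos <- pos[keep]; mm <- mm[keep]; strand <- strand[keep]
  }
  o <- order(pos, strand)  # "+" < "-" in ASCII
  list(pos = pos[o], mm = mm[o], strand = strand[o])
}

.align_seq <- function(read_id, fwd, rev, index, max_mismatch) {
  core <- .align_seq_core(fwd, rev, index, max_mismatch)
  if (is.null(core)) return(empty_alignments())
  len <- nchar(fwd)
  n <- length(core$pos)
  data.frame(read_id = read_id, ref_id = index$ref_id, pos = core$pos,
             strand = core$strand, mismatches = core$mm, n_best = n,
             weight = 1 / n, read_len = len,
             five_prime = ifelse(core$strand == "+", core$pos,
                                 core$pos + len - 1L),
             stringsAsFactors = FALSE)
}

#' Align a library of small reads to a reference
#'
#' Convenience driver over [align_read()]: builds the index once and aligns
#' every read. The default seed length 9 guarantees the pigeonhole
#' completeness condition (`k <= floor(readlen/2)`) for every read of at
#' least 18 nt, i.e. the whole 19--33 nt library window, at 1 mismatch.
#'
#' @param reads data.frame with `read_id`, `seq`.
#' @param ref named character vector of length 1.
#' @param max_mismatch 0 or 1 (mismatch stratum contract as in
#'   [align_read()]).
#' @param k seed length for [build_index()].
#' @return alignment data.frame over all mapped reads; unmapped reads are
#'   simply absent.
#' @export
align_reads <- function(reads, ref, max_mismatch = 0L, k = 9L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  index <- build_index(ref, k)
  n <- nrow(reads)
  if (n == 0L) return(empty_alignments())
  seqs <- toupper(reads$seq)
  revs <- dna_revcomp(seqs)
  lens <- nchar(seqs)
  mmx <- as.integer(max_mismatch)
  acc_id <- vector("list", n); acc_pos <- vector("list", n)
  acc_mm <- vector("list", n); acc_strand <- vector("list", n)
  acc_n <- vector("list", n); acc_len <- vector("list", n)
  for (r in seq_len(n)) {
    if (lens[r] < k) next
    core <- .align_seq_core(seqs[r], revs[r], index, mmx)
    if (is.null(core)) next
    nb <- length(core$pos)
    acc_id[[r]] <- rep.int(reads$read_id[r], nb)
    acc_pos[[r]] <- core$pos
    acc_mm[[r]] <- core$mm
    acc_strand[[r]] <- core$strand
    acc_n[[r]] <- rep.int(nb, nb)
    acc_len[[r]] <- rep.int(lens[r], nb)
  }
  pos <- unlist(acc_pos, use.names = FALSE)
  if (length(pos) == 0L) return(empty_alignments())
  strand <- unlist(acc_strand, use.names = FALSE)
  read_len <- unlist(acc_len, use.names = FALSE)
  n_best <- unlist(acc_n, use.names = FALSE)
  data.frame(read_id = unlist(acc_id, use.names = FALSE),
             ref_id = index$ref_id, pos = pos, strand = strand,
             mismatches = unlist(acc_mm, use.names = FALSE),
             n_best = n_best, weight = 1 / n_best, read_len = read_len,
             five_prime = ifelse(strand == "+", pos, pos + read_len - 1L),
             stringsAsFactors = FALSE)
}
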