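# Independent oracles used to cross-check the package's own implementations.
# These deliberately take a different route (Biostrings exhaustive scan,
# brute-force double loops) from the code they verify.

# Exhaustive-scan alignment oracle: every offset on both strands via
# Biostrings::matchPattern, then the same best-stratum rule.
oracle_align_read <- function(read_id, seq, ref, max_mismatch) {
  refseq <- Biostrings::DNAString(unname(ref[[1]]))
  ref_id <- names(ref)
  len <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    target <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    m <- Biostrings::matchPattern(target, refseq, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    if (length(m) == 0L) next
    starts <- Biostrings::start(m)
    mm <- vapply(starts, function(p) {
      sum(charToRaw(as.character(Biostrings::subseq(refseq, p, p + len - 1L))) !=
            charToRaw(target))
    }, integer(1))
    hits[[strand]] <- data.frame(pos = starts, strand = strand, mm = mm)
  }
  h <- do.call(rbind, hits)
  if (is.null(h) || nrow(h) == 0L) return(NULL)
  h <- h[h$mm <= max_mismatch, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  if (any(h$mm == 0L)) h <- h[h$mm == 0L, , drop = FALSE]
  h <- h[order(h$pos, h$strand), , drop = FALSE]
  n <- nrow(h)
  data.frame(read_id = read_id, ref_id = ref_id, pos = h$pos,
             strand = h$strand, mismatches = h$mm, n_best = n, weight = 1 / n,
             read_len = len,
             five_prime = ifelse(h$strand == "+", h$pos, h$pos + len - 1L),
             stringsAsFactors = FALSE)
}

# Brute-force overlap pair counts: double loop over all (+,-) alignment
# pairs, counting weight products at each 5'-overlap distance.
brute_overlap_counts <- function(alignments, size_class = c(26L, 30L),
                                 region = NULL, Dmax = 30L) {
  a <- alignments[alignments$read_len >= size_class[1] &
                    alignments$read_len <= size_class[2], , drop = FALSE]
  plus <- a[a$strand == "+", , drop = FALSE]
  if (!is.null(region)) {
    plus <- plus[plus$five_prime >= region[1] & plus$five_prime <= region[2], ,
                 drop = FALSE]
  }
  minus <- a[a$strand == "-", , drop = FALSE]
  cd <- numeric(Dmax)
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      d <- minus$five_prime[j] - plus$five_prime[i] + 1L
      if (d >= 1L && d <= Dmax)
        cd[d] <- cd[d] + plus$weight[i] * minus$weight[j]
    }
  }
  cd
}

# random read set drawn from a reference with planted mutations, for
# aligner-oracle comparisons
draw_oracle_reads <- function(ref, n, mutate_frac = 0.3, len_range = c(19L, 33L)) {
  seq <- unname(ref[[1]])
  L <- nchar(seq)
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), integer(1))
  reads <- substring(seq, starts, starts + lens - 1L)
  flip <- runif(n) < 0.5
  reads[flip] <- evepirna::dna_revcomp(reads[flip])
  nmut <- sample(0:2, n, replace = TRUE,
                 prob = c(1 - mutate_frac, mutate_frac * 0.7, mutate_frac * 0.3))
  for (r in which(nmut > 0)) {
    ch <- strsplit(reads[r], "", fixed = TRUE)[[1]]
    at <- sample.int(length(ch), nmut[r])
    for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    reads[r] <- paste(ch, collapse = "")
  }
  data.frame(read_id = sprintf("r%05d", seq_len(n)), seq = reads,
             stringsAsFactors = FALSE)
}

# small standard simulated dataset shared across tests (cheap: ~3 kb virus)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- evepirna::simulation_config(
        seed = 77, virus_length = 3000L, host_flank_length = 800L,
        fragment_length_range = c(200L, 600L),
        n_sirna = 600L, n_primary = 900L, n_secondary = 700L)
      cache <<- evepirna::simulate_dataset(cfg)
    }
    cache
  }
})
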