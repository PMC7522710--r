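mk_aln <- function(five_prime, strand, weight = 1, read_len = 28L) {
  n <- length(five_prime)
  strand <- rep_len(strand, n)
  weight <- rep_len(weight, n)
  pos <- ifelse(strand == "+", five_prime, five_prime - read_len + 1L)
  data.frame(read_id = sprintf("a%04d", seq_len(n)), ref_id = "virus",
             pos = as.integer(pos), strand = strand, mismatches = 0L,
             n_best = 1L, weight = weight, read_len = as.integer(read_len),
             five_prime = as.integer(five_prime), stringsAsFactors = FALSE)
}

test_that("information content spans its limits", {
  # identical reads: 2 bits at every covered position
  aln <- mk_aln(rep(100L, 20), "+")
  reads <- data.frame(read_id = aln$read_id,
                      seq = strrep("TACGTACGTACGTACGTACGTACGTACG", 1),
                      stringsAsFactors = FALSE)
  reads$seq <- substr(reads$seq, 1, 28)
  pr <- nucleotide_profile(aln, reads)
  expect_equal(pr$information, rep(2, 20), tolerance = 1e-12)
  expect_true(all(abs(rowSums(pr$freq) - 1) < 1e-12))

  # uniform random reads: information tends to zero
  set.seed(61)
  n <- 4000L
  aln2 <- mk_aln(rep(100L, n), "+")
  reads2 <- data.frame(read_id = aln2$read_id,
                       seq = vapply(seq_len(n), function(i) random_dna(28),
                                    character(1)),
                       stringsAsFactors = FALSE)
  pr2 <- nucleotide_profile(aln2, reads2)
  expect_lt(max(pr2$information), 0.01)
})

test_that("1U bias of simulated primaries recovers the enforcement rate", {
  sim <- small_sim()  # u1_enforcement = 0.9
  prim_ids <- sim$labels$read_id[sim$labels$class == "primary_pirna"]
  reads <- sim$reads[sim$reads$read_id %in% prim_ids, ]
  aln <- align_reads(reads, sim$host_contig, max_mismatch = 1)
  pr <- nucleotide_profile(aln, reads, orientation = "sense",
                           region = c(sim$eve_start, sim$eve_end))
  b <- bias_fractions(pr)
  expect_lt(abs(b$u1 - 0.9), 3 * sqrt(0.9 * 0.1 / pr$n_reads) + 0.005)
})

test_that("bias fractions read off the logo matrix and reject empty input", {
  aln <- mk_aln(rep(50L, 5), "+", read_len = 26L)
  reads <- data.frame(read_id = aln$read_id,
                      seq = paste0("T", strrep("A", 25)),
                      stringsAsFactors = FALSE)
  b <- bias_fractions(nucleotide_profile(aln, reads))
  expect_equal(b$u1, 1)
  expect_equal(b$a10, 1)
  empty <- nucleotide_profile(empty_alignments(), reads)
  expect_equal(empty$n_reads, 0)
  expect_error(bias_fractions(empty), "n_reads = 0")
})

test_that("overlap spectrum matches its closed form on a single pair", {
  aln <- rbind(mk_aln(1L, "+", weight = 2), mk_aln(10L, "-", weight = 3))
  os <- overlap_spectrum(aln, Dmax = 30L)
  expect_equal(os$count[10], 6)
  expect_equal(sum(os$count[-10]), 0)
  expect_equal(os$prob[10], 1)
  expect_equal(os$z[10], sqrt(29), tolerance = 1e-12)
  expect_equal(attr(os, "ping_pong_z"), sqrt(29), tolerance = 1e-12)

  # no opposite strand: all zero, z undefined
  os0 <- overlap_spectrum(mk_aln(1L, "+"), Dmax = 30L)
  expect_true(all(os0$count == 0))
  expect_true(all(is.na(os0$z)))
  expect_true(is.na(attr(os0, "ping_pong_z")))
})

test_that("pair counts equal the brute-force double loop", {
  set.seed(62)
  n <- 800L
  aln <- mk_aln(sample.int(500L, n, replace = TRUE),
                sample(c("+", "-"), n, replace = TRUE),
                weight = sample(c(1, 0.5, 0.25), n, replace = TRUE),
                read_len = sample(26:30, n, replace = TRUE))
  os <- overlap_spectrum(aln, Dmax = 30L)
  expect_equal(os$count, brute_overlap_counts(aln, Dmax = 30L))

  # with a region restriction attributed by the + read's 5' position
  region <- c(101L, 300L)
  osr <- overlap_spectrum(aln, region = region, Dmax = 30L)
  expect_equal(osr$count, brute_overlap_counts(aln, region = region, Dmax = 30L))
})

test_that("region partition is additive and z is affine-invariant", {
  set.seed(63)
  n <- 600L
  aln <- mk_aln(sample.int(400L, n, replace = TRUE),
                sample(c("+", "-"), n, replace = TRUE))
  whole <- overlap_spectrum(aln, region = c(1L, 400L))
  parts <- lapply(list(c(1L, 150L), c(151L, 280L), c(281L, 400L)),
                  function(r) overlap_spectrum(aln, region = r)$count)
  expect_equal(Reduce(`+`, parts), whole$count)

  # z computed on probabilities equals z computed on counts
  p <- whole$prob
  zp <- (p - mean(p)) / sqrt(mean((p - mean(p))^2))
  expect_equal(zp, whole$z, tolerance = 1e-9)
})

test_that("EVE alignments re-expressed in virus coordinates flip correctly", {
  # hand-built 20-nt fragment: contig [101,120] <-> virus [501,520], flipped
  frag <- data.frame(contig_start = 101L, contig_end = 120L,
                     virus_start = 501L, virus_end = 520L,
                     orientation = "-", stringsAsFactors = FALSE)
  a <- data.frame(read_id = c("left", "right"), ref_id = "host",
                  pos = c(101L, 101L), strand = c("+", "-"),
                  mismatches = 0L, n_best = 1L, weight = 1,
                  read_len = c(20L, 20L), five_prime = c(101L, 120L),
                  stringsAsFactors = FALSE)
  conv <- orient_relative_to_virus(a, frag)
  # full-length read on a flipped fragment maps to the whole virus interval
  expect_equal(conv$pos, c(501L, 501L))
  expect_identical(conv$strand, c("-", "+"))
  expect_equal(conv$five_prime, c(520L, 501L))

  # off-by-one audit at both ends with a 5-nt read
  a2 <- data.frame(read_id = c("s", "e"), ref_id = "host",
                   pos = c(101L, 116L), strand = "+", mismatches = 0L,
                   n_best = 1L, weight = 1, read_len = 5L,
                   five_prime = c(101L, 116L), stringsAsFactors = FALSE)
  conv2 <- orient_relative_to_virus(a2, frag)
  expect_equal(conv2$pos, c(516L, 501L))
  expect_equal(conv2$five_prime, c(520L, 505L))

  # alignments outside all fragments are dropped and counted
  a3 <- rbind(a2, transform(a2[1, ], read_id = "out", pos = 90L,
                            five_prime = 90L))
  conv3 <- orient_relative_to_virus(a3, frag)
  expect_equal(nrow(conv3), 2L)
  expect_equal(attr(conv3, "n_dropped"), 1L)
  expect_error(orient_relative_to_virus(a2, frag[0, ]), "empty")
})

test_that("simulated primaries from flipped fragments read as antisense", {
  sim <- small_sim()
  prim <- sim$labels[sim$labels$class == "primary_pirna" &
                       !is.na(sim$labels$virus_strand), ]
  reads <- sim$reads[sim$reads$read_id %in% prim$read_id, ]
  ca <- align_reads(reads, sim$host_contig, max_mismatch = 1)
  conv <- orient_relative_to_virus(ca, sim$fragments)
  flipped <- sim$fragments$fragment[sim$fragments$orientation == "-"]
  from_flipped <- prim$read_id[prim$virus_strand == "-"]
  got <- conv$strand[conv$read_id %in% from_flipped]
  expect_gte(mean(got == "-"), 0.99)
})
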