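test_that("an exact embedded substring yields one full-identity HSP", {
  set.seed(31)
  virus <- c(virus = random_dna(4000))
  seg <- substr(virus[[1]], 1001, 1500)
  contig <- c(host = paste0(random_dna(600), seg, random_dna(600)))
  h <- find_hsps(contig, virus)
  expect_equal(nrow(h), 1L)
  expect_identical(h$orientation, "+")
  # the HSP covers the planted interval; X-drop extension may absorb a few
  # chance-matching flank columns beyond it
  expect_lte(h$contig_start, 601); expect_gte(h$contig_start, 596)
  expect_gte(h$contig_end, 1100); expect_lte(h$contig_end, 1105)
  expect_equal(h$virus_end - h$virus_start, h$contig_end - h$contig_start)
  expect_gte(100 * h$matches / h$aligned_columns, 99.5)

  # reverse-complemented insertion: orientation flips, virus interval fixed
  contig_rc <- c(host = paste0(random_dna(600), dna_revcomp(seg),
                               random_dna(600)))
  hr <- find_hsps(contig_rc, virus)
  expect_equal(nrow(hr), 1L)
  expect_identical(hr$orientation, "-")
  expect_lte(hr$virus_start, 1001); expect_gte(hr$virus_start, 996)
  expect_gte(hr$virus_end, 1500); expect_lte(hr$virus_end, 1505)
  expect_lte(hr$contig_start, 601)
  expect_gte(hr$contig_end, 1100)
})

test_that("chaining merges same-diagonal HSPs and respects orientation", {
  set.seed(32)
  virus <- c(virus = random_dna(3000))
  # one 500-nt segment with a 10-nt corrupted stretch in the middle: two
  # HSPs on one diagonal, 10 apart, must chain into a single fragment
  seg <- substr(virus[[1]], 1001, 1500)
  ch <- strsplit(seg, "")[[1]]
  for (i in 241:250) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  contig <- c(host = paste0(random_dna(500), paste(ch, collapse = ""),
                            random_dna(500)))
  h <- find_hsps(contig, virus, xdrop = 12)
  expect_gte(nrow(h), 2L)
  fr <- chain_into_fragments(h, max_gap = 50, contig = contig, virus = virus)
  expect_equal(nrow(fr), 1L)
  expect_lte(fr$contig_start, 501); expect_gte(fr$contig_start, 496)
  expect_gte(fr$contig_end, 1000); expect_lte(fr$contig_end, 1005)
  expect_equal(fr$virus_end - fr$virus_start, fr$contig_end - fr$contig_start)
  # mismatch columns inside the merged fragment are exactly the 10 planted
  expect_equal(round(fr$length * (1 - fr$percent_identity / 100)), 10)

  # opposite orientations are never merged, however close
  h2 <- data.frame(contig_start = c(100L, 360L), contig_end = c(349L, 609L),
                   virus_start = c(500L, 760L), virus_end = c(749L, 1009L),
                   orientation = c("+", "-"), matches = c(250L, 250L),
                   aligned_columns = c(250L, 250L), score = c(250L, 250L),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(chain_into_fragments(h2, max_gap = 50)), 2L)
})

test_that("reported fragment identity is reproducible from the sequences", {
  sim <- small_sim()
  fr <- discover_eve(sim$host_contig, sim$virus)
  for (i in seq_len(nrow(fr))) {
    expect_equal(fragment_identity(fr[i, ], sim$host_contig, sim$virus),
                 fr$percent_identity[i])
  }
})

test_that("planted fragments are recovered with orientation and boundaries", {
  n_ok <- 0L; n_frag <- 0L
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, virus_length = 5000L,
                             host_flank_length = 1000L,
                             fragment_length_range = c(250L, 700L),
                             divergence = 0.05,
                             n_sirna = 0L, n_primary = 0L, n_secondary = 0L)
    v <- make_virus_genome(cfg)
    p <- plant_eve(v, cfg)
    fr <- discover_eve(p$host_contig, v)
    truth <- p$fragments
    expect_equal(nrow(fr), nrow(truth))
    for (i in seq_len(nrow(truth))) {
      n_frag <- n_frag + 1L
      j <- which.min(abs(fr$contig_start - truth$contig_start[i]))
      hit <- fr$orientation[j] == truth$orientation[i] &&
        abs(fr$contig_start[j] - truth$contig_start[i]) <= 11 &&
        abs(fr$contig_end[j] - truth$contig_end[i]) <= 11
      if (hit) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_frag, 0.95)
})

test_that("scanning the reverse-complemented contig mirrors the fragments", {
  sim <- small_sim()
  fr <- discover_eve(sim$host_contig, sim$virus)
  Lc <- nchar(sim$host_contig[[1]])
  rc <- c(host_rc = dna_revcomp(sim$host_contig[[1]]))
  fr_rc <- discover_eve(rc, sim$virus)
  expect_equal(nrow(fr_rc), nrow(fr))
  mirrored <- fr_rc[order(Lc - fr_rc$contig_end + 1L), ]
  expect_equal(Lc - mirrored$contig_end + 1L, fr$contig_start)
  expect_equal(Lc - mirrored$contig_start + 1L, fr$contig_end)
  expect_identical(mirrored$orientation,
                   ifelse(fr$orientation == "+", "-", "+"))
  expect_equal(mirrored$virus_start, fr$virus_start)
  expect_equal(mirrored$virus_end, fr$virus_end)
  expect_equal(mirrored$percent_identity, fr$percent_identity)
})

test_that("identity report pools fragments length-weighted and writes BED", {
  sim <- small_sim()
  fr <- discover_eve(sim$host_contig, sim$virus)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  rep <- fragment_identity_report(fr, sim$host_contig, sim$virus,
                                  tsv = tsv, bed = bed)
  w <- rep$fragments$length
  expect_equal(rep$overall_identity,
               sum(rep$fragments$percent_identity * w) / sum(w))
  bed_df <- read.table(bed, sep = "\t")
  expect_equal(nrow(bed_df), nrow(fr))
  expect_equal(bed_df$V2, fr$contig_start - 1L)  # 0-based half-open
  expect_equal(bed_df$V3, fr$contig_end)
  expect_error(fragment_identity_report(fr[0, ], sim$host_contig, sim$virus),
               "no fragments")
})
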