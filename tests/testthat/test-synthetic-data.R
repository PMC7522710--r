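test_that("virus genome generator honours length, composition, determinism", {
  cfg <- simulation_config(seed = 1, virus_length = 100L, n_sirna = 0L,
                           n_primary = 0L, n_secondary = 0L)
  v <- make_virus_genome(cfg)
  expect_equal(nchar(v[[1]]), 100L)
  expect_identical(v, make_virus_genome(cfg))

  gc_only <- simulation_config(seed = 3, virus_length = 500L, gc_content = 1)
  expect_match(make_virus_genome(gc_only)[[1]], "^[GC]+$")
  at_only <- simulation_config(seed = 3, virus_length = 500L, gc_content = 0)
  expect_match(make_virus_genome(at_only)[[1]], "^[AT]+$")
})

test_that("planted fragments respect orientation, identity and bounds", {
  cfg0 <- simulation_config(seed = 11, virus_length = 5000L, divergence = 0,
                            fragment_length_range = c(300L, 800L),
                            host_flank_length = 1000L)
  v <- make_virus_genome(cfg0)
  p0 <- plant_eve(v, cfg0)
  expect_equal(nrow(p0$fragments), 4L)
  expect_true(all(p0$fragments$percent_identity == 100))
  expect_identical(p0$fragments$orientation, c("+", "-", "-", "+"))

  # fragment intervals non-overlapping on the virus and inside bounds
  fr <- p0$fragments[order(p0$fragments$virus_start), ]
  expect_true(all(fr$virus_start >= 1 & fr$virus_end <= 5000))
  expect_true(all(fr$virus_start[-1] > fr$virus_end[-nrow(fr)]))

  # orientation contract at divergence 0: planted sequence equals the
  # (reverse-complemented) viral segment exactly
  for (i in seq_len(nrow(p0$fragments))) {
    f <- p0$fragments[i, ]
    planted <- substr(p0$host_contig[[1]], f$contig_start, f$contig_end)
    seg <- substr(v[[1]], f$virus_start, f$virus_end)
    if (f$orientation == "-") seg <- dna_revcomp(seg)
    expect_identical(planted, seg)
  }

  # realized identity under divergence matches a direct recount, and sits
  # within binomial noise of 1 - divergence
  cfg4 <- simulation_config(seed = 12, virus_length = 8000L, divergence = 0.04,
                            fragment_length_range = c(1000L, 1000L),
                            host_flank_length = 1000L)
  v4 <- make_virus_genome(cfg4)
  p4 <- plant_eve(v4, cfg4)
  for (i in seq_len(nrow(p4$fragments))) {
    f <- p4$fragments[i, ]
    expect_equal(fragment_identity(f, p4$host_contig, v4), f$percent_identity)
    tol <- 3 * sqrt(0.04 * 0.96 / f$length) * 100
    expect_lt(abs(f$percent_identity - 96), tol + 1e-9)
  }
})

test_that("infeasible fragment placement fails explicitly", {
  cfg <- simulation_config(seed = 5, virus_length = 900L,
                           fragment_length_range = c(400L, 500L),
                           n_fragments = 4L)
  v <- make_virus_genome(cfg)
  expect_error(plant_eve(v, cfg), "non-overlapping fragments")
})

test_that("error-free reads are exact template substrings", {
  cfg <- simulation_config(seed = 21, virus_length = 3000L,
                           host_flank_length = 600L,
                           fragment_length_range = c(200L, 500L),
                           n_sirna = 400L, n_primary = 300L,
                           n_secondary = 200L, error_rate = 0,
                           divergence = 0, u1_enforcement = 1)
  sim <- simulate_dataset(cfg)
  lab <- sim$labels
  vseq <- sim$virus[[1]]
  cseq <- sim$host_contig[[1]]

  for (i in seq_len(nrow(sim$reads))) {
    rd <- sim$reads$seq[i]
    l <- lab[i, ]
    tpl <- if (l$template == "virus") vseq else cseq
    expect_identical(rd, if (l$true_strand == "+") {
      substr(tpl, l$true_5p, l$true_5p + nchar(rd) - 1L)
    } else {
      dna_revcomp(substr(tpl, l$true_5p - nchar(rd) + 1L, l$true_5p))
    })
  }

  # forced biases: all primaries start with T(U); complementarity forces A
  # at position 10 of every secondary
  prim <- sim$reads$seq[lab$class == "primary_pirna"]
  expect_true(all(substr(prim, 1, 1) == "T"))
  sec <- sim$reads$seq[lab$class == "secondary_pirna"]
  expect_true(all(substr(sec, 10, 10) == "A"))
})

test_that("secondary 10A fraction tracks divergence via planted substitutions", {
  cfg <- simulation_config(seed = 22, virus_length = 6000L,
                           host_flank_length = 800L,
                           n_sirna = 0L, n_primary = 3000L,
                           n_secondary = 3000L, error_rate = 0,
                           divergence = 0.04, u1_enforcement = 1)
  sim <- simulate_dataset(cfg)
  sec <- sim$reads$seq[sim$labels$class == "secondary_pirna"]
  a10 <- mean(substr(sec, 10, 10) == "A")
  expect_lt(abs(a10 - 0.96), 3 * sqrt(0.96 * 0.04 / length(sec)) + 0.01)
})

test_that("read accounting and labels are conserved", {
  sim <- small_sim()
  cfg <- sim$config
  requested <- cfg$n_sirna + cfg$n_primary + cfg$n_secondary
  expect_equal(nrow(sim$reads) + sim$n_rejected, requested)
  expect_equal(nrow(sim$labels), nrow(sim$reads))
  expect_identical(sim$labels$read_id, sim$reads$read_id)
  expect_false(any(duplicated(sim$labels$read_id)))
  # every fragment lies inside both coordinate systems
  expect_true(all(sim$fragments$contig_start >= 1 &
                    sim$fragments$contig_end <= nchar(sim$host_contig[[1]])))
  expect_true(all(sim$fragments$virus_start >= 1 &
                    sim$fragments$virus_end <= nchar(sim$virus[[1]])))
})

test_that("size selection rejects out-of-window reads and reports them", {
  cfg <- simulation_config(seed = 31, virus_length = 2000L,
                           host_flank_length = 500L,
                           fragment_length_range = c(200L, 400L),
                           n_sirna = 300L, n_primary = 100L, n_secondary = 0L,
                           sirna_length = 21L, size_selection = c(26L, 30L))
  sim <- simulate_dataset(cfg)
  expect_equal(sim$n_rejected, 300L)  # all 21-nt siRNAs fall outside 26-30
  expect_true(all(sim$labels$class == "primary_pirna"))
})

test_that("secondaries without eligible primaries fail explicitly", {
  cfg <- simulation_config(seed = 41, virus_length = 2000L,
                           host_flank_length = 500L,
                           fragment_length_range = c(200L, 300L),
                           n_sirna = 0L, n_primary = 0L, n_secondary = 10L)
  v <- make_virus_genome(cfg)
  p <- plant_eve(v, cfg)
  expect_error(simulate_reads(c(list(virus = v), p), cfg),
               "secondary piRNAs requested")
})
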