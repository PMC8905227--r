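test_that("genome generation is deterministic and honors planted counts", {
  cfg <- small_config(seed = 7)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$assembled, sim2$assembled)

  tr <- sim1$truth
  expect_equal(sum(tr$true_class_code == "u" &
                     tr$kind %in% c("lnc", paste0("decoy_", c("short",
                       "near_gene", "coding", "low_fpkm", "no_est")))),
               cfg$n_lnc_u + 5 * cfg$n_decoys_per_rule)
  expect_equal(sum(tr$kind == "lnc" & tr$true_class_code == "u"),
               cfg$n_lnc_u)
  expect_equal(sum(tr$true_class_code == "i"), cfg$n_lnc_i)
  expect_equal(sum(tr$true_class_code == "x"), cfg$n_lnc_x)
  expect_equal(sum(!is.na(tr$syntenic_truth) & tr$syntenic_truth),
               2 * cfg$n_homolog_pairs)
  expect_false(anyDuplicated(tr$feature_id) > 0)

  # written files are byte-identical across seeded runs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(sim1, dir = d1)
  write_simulation(sim2, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generated files round-trip through the package readers", {
  cfg <- small_config(seed = 7)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, dir = d)
  genome <- read_fasta(file.path(d, "genome.fa"))
  expect_identical(genome, sim$genome)
  asm <- read_gtf(file.path(d, "assembled.gtf"))
  orig <- sim$assembled[order(sim$assembled$transcript_id,
                              sim$assembled$start), ]
  expect_equal(asm$start, orig$start)
  expect_equal(asm$end, orig$end)
  expect_equal(asm$chrom, orig$chrom)
  # spliced sequences recovered from genome + exons match the stored ones
  for (id in sample(unique(asm$transcript_id), 10)) {
    expect_identical(
      spliced_sequence(genome, asm[asm$transcript_id == id, ]),
      unname(sim$transcript_seqs[[id]]), label = id)
  }
})

test_that("undersized chromosomes raise a sizing error naming the constraint", {
  expect_error(simulate_genome(small_config(chromosome_length = 30000L)),
               "chromosome_length")
})

test_that("count generation plants the requested fold changes", {
  fx <- shared_sim()
  cnt <- fx$cnt
  tr <- cnt$truth
  expect_identical(rownames(cnt$expr$values), tr$feature_id)
  expect_equal(ncol(cnt$expr$values), nrow(fx$cfg$design))
  # determinism
  cnt2 <- simulate_counts(fx$sim, fx$cfg)
  expect_identical(cnt$expr$values, cnt2$expr$values)
  # low-expression decoys are all zero (degenerate rows survive I/O)
  zero_ids <- tr$feature_id[tr$kind == "decoy_low_fpkm"]
  expect_true(all(cnt$expr$values[zero_ids, ] == 0))
  # empirical log2FC of planted-DE features ~ planted magnitude
  de <- tr$true_de & tr$kind == "lnc"
  m <- cnt$expr$values
  infested <- fx$cfg$design$timepoint_h > 0
  est <- log2(rowMeans(m[de, infested, drop = FALSE]) /
                rowMeans(m[de, !infested, drop = FALSE]))
  expect_lt(abs(mean(abs(est)) - fx$cfg$de_log2fc), 0.2)
})

test_that("dispersion zero with no planted effect gives Poisson-level equality", {
  cfg <- small_config(seed = 11, dispersion = 0, de_fraction = 0,
                      n_homolog_pairs = 0L, n_shuffled_pairs = 0L)
  sim <- simulate_genome(cfg)
  cnt <- simulate_counts(sim, cfg)
  m <- cnt$expr$values
  tr <- cnt$truth
  expect_true(all(tr$true_log2fc == 0))
  infested <- cfg$design$timepoint_h > 0
  keep <- rowMeans(m) > 20
  g1 <- rowMeans(m[keep, infested, drop = FALSE])
  g0 <- rowMeans(m[keep, !infested, drop = FALSE])
  # sample-size factors differ between groups, so compare after
  # normalizing by total signal; differences stay within sampling error
  ratio <- (g1 / mean(g1)) / (g0 / mean(g0))
  expect_lt(median(abs(log2(ratio))), 0.25)
})

test_that("empty design is rejected", {
  fx <- shared_sim()
  cfg <- fx$cfg
  cfg$design <- cfg$design[0, ]
  expect_error(simulate_counts(fx$sim, cfg), "empty design")
})

test_that("amplicon generator realizes outcome proportions exactly", {
  fix <- fixture_amplicon()
  mix <- data.frame(type = c("WT", "deletion"), length = c(0, 5),
                    proportion = c(0.5, 0.5))
  out <- simulate_amplicons(fix$amplicon, fix$guide, mix, 100, seed = 3,
                            read_error_rate = 0)
  expect_equal(sum(out$truth$outcome == "deletion"), 50)
  expect_equal(sum(out$truth$outcome == "WT"), 50)
  ref_len <- nchar(fix$amplicon)
  expect_true(all(nchar(out$reads[out$truth$outcome == "deletion"]) ==
                    ref_len - 5))
  expect_true(all(out$reads[out$truth$outcome == "WT"] == fix$amplicon))
  # determinism, including error injection
  a <- simulate_amplicons(fix$amplicon, fix$guide, mix, 60, seed = 9,
                          read_error_rate = 0.01)
  b <- simulate_amplicons(fix$amplicon, fix$guide, mix, 60, seed = 9,
                          read_error_rate = 0.01)
  expect_identical(a$reads, b$reads)
  # FASTQ round trip
  d <- withr::local_tempdir()
  write_fastq(a$reads, file.path(d, "reads.fastq"))
  back <- read_fastq(file.path(d, "reads.fastq"))
  expect_identical(unname(back), unname(a$reads))
})

test_that("amplicon generator rejects absent or ambiguous guides", {
  fix <- fixture_amplicon()
  mix <- data.frame(type = "WT", length = 0, proportion = 1)
  expect_error(simulate_amplicons(fix$amplicon, "AAAAAAAAAAAAAAAAAAAA",
                                  mix, 10), "exactly once")
  double <- paste0(fix$amplicon, fix$amplicon)
  expect_error(simulate_amplicons(double, fix$guide, mix, 10),
               "exactly once")
})
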