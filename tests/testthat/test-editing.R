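test_that("guide sites are located with the canonical cut coordinate", {
  guide <- "GACTGACTGACTGACTGACT"
  x <- strrep("C", 50)  # C-only flanks cannot spawn spurious guide matches
  y <- strrep("A", 60)
  amp <- paste0(x, guide, "AGG", y)
  site <- locate_guide(amp, guide)
  expect_equal(site$strand, "+")
  expect_equal(site$pam_start, 70L)   # 0-based PAM start
  expect_equal(site$cut_pos, 67L)     # cut between 0-based bases 66/67
  expect_equal(site$pam, "AGG")

  expect_error(locate_guide(amp, "AAAAAAAAAAAAAAAAAAAA"), "exactly once")
  expect_error(locate_guide(paste0(amp, guide, "TGG"), guide),
               "exactly once")
  expect_error(locate_guide(amp, "ACGT"), "20 nt")
})

test_that("reverse-strand sites mirror under reverse complement", {
  fix <- fixture_amplicon()
  site <- locate_guide(fix$amplicon, fix$guide)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fix$amplicon)))
  site_rc <- locate_guide(rc, fix$guide)
  expect_equal(site_rc$strand, "-")
  # between-base coordinates mirror: cut + cut' = amplicon length
  expect_equal(site$cut_pos + site_rc$cut_pos, nchar(fix$amplicon))
})

test_that("constructed edits are classified with their exact lengths", {
  fix <- fixture_amplicon()
  amp <- fix$amplicon
  site <- locate_guide(amp, fix$guide)
  cut <- site$cut_pos
  # reference read -> WT
  wt <- classify_reads(c(r1 = amp), amp, site)
  expect_equal(wt$outcome, "WT")
  # 5 bp removed at the cut -> deletion of length 5
  del5 <- paste0(substr(amp, 1, cut - 2), substr(amp, cut + 4, nchar(amp)))
  rd <- classify_reads(c(r1 = del5), amp, site)
  expect_equal(rd$outcome, "deletion")
  expect_equal(rd$length, 5L)
  # 1 bp inserted at the cut -> insertion of length 1
  ins1 <- paste0(substr(amp, 1, cut), "T", substr(amp, cut + 1, nchar(amp)))
  ri <- classify_reads(c(r1 = ins1), amp, site)
  expect_equal(ri$outcome, "insertion")
  expect_equal(ri$length, 1L)
  # two substitutions at the cut -> substitution; one -> WT
  sub2 <- amp
  for (pos in c(cut, cut + 1)) {
    old <- substr(sub2, pos, pos)
    substr(sub2, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(classify_reads(c(r1 = sub2), amp, site)$outcome,
               "substitution")
  sub1 <- amp
  substr(sub1, cut, cut) <- setdiff(c("A", "C", "G", "T"),
                                    substr(amp, cut, cut))[1]
  expect_equal(classify_reads(c(r1 = sub1), amp, site)$outcome, "WT")
  # deletion far outside the window is ignored
  far <- paste0(substr(amp, 1, 10), substr(amp, 16, nchar(amp)))
  expect_equal(classify_reads(c(r1 = far), amp, site)$outcome, "WT")
  # garbage read -> unaligned
  bad <- random_seq(nchar(amp))
  expect_equal(classify_reads(c(r1 = bad), amp, site)$outcome, "unaligned")
})

test_that("planted outcome mixes are recovered exactly on error-free reads", {
  fix <- fixture_amplicon()
  site <- locate_guide(fix$amplicon, fix$guide)
  mix <- data.frame(type = c("deletion", "deletion", "deletion", "insertion",
                             "substitution", "WT"),
                    length = c(1, 7, 20, 3, 0, 0),
                    proportion = c(0.2, 0.1, 0.1, 0.2, 0.1, 0.3))
  out <- simulate_amplicons(fix$amplicon, fix$guide, mix, 200, seed = 21,
                            read_error_rate = 0)
  calls <- classify_reads(out$reads, fix$amplicon, site)
  merged <- merge(calls, out$truth, by = "read_id",
                  suffixes = c("_call", "_truth"))
  # per-read recall/precision = 1 for all outcome classes
  expect_equal(merged$outcome_call, merged$outcome_truth)
  expect_equal(merged$length_call[merged$outcome_truth == "deletion"],
               merged$length_truth[merged$outcome_truth == "deletion"])
  s <- summarize_editing(calls)
  expect_equal(s$efficiency, 100 * 0.7)
  # deletion-length histogram equals the planted spectrum
  expect_equal(unname(s$deletion_length_histogram[c("1", "7", "20")]),
               c(40L, 20L, 20L))
  # efficiency invariant to read duplication
  dup <- classify_reads(setNames(c(out$reads, out$reads),
                                 paste0("d", seq_len(2 * length(out$reads)))),
                        fix$amplicon, site)
  expect_equal(summarize_editing(dup)$efficiency, s$efficiency)
})

test_that("efficiency stays within one point under 0.1% base error", {
  fix <- fixture_amplicon()
  site <- locate_guide(fix$amplicon, fix$guide)
  mix <- data.frame(type = c("deletion", "WT"), length = c(5, 0),
                    proportion = c(0.6, 0.4))
  out <- simulate_amplicons(fix$amplicon, fix$guide, mix, 500, seed = 8,
                            read_error_rate = 0.001)
  calls <- classify_reads(out$reads, fix$amplicon, site)
  s <- summarize_editing(calls)
  expect_lt(abs(s$efficiency - 60), 1)
})

test_that("summaries enforce coverage rules", {
  fix <- fixture_amplicon()
  site <- locate_guide(fix$amplicon, fix$guide)
  calls <- classify_reads(setNames(rep(fix$amplicon, 10), paste0("r", 1:10)),
                          fix$amplicon, site)
  s <- summarize_editing(calls, min_reads = 50)
  expect_equal(s$efficiency, 0)
  expect_true(s$low_coverage)
  all_un <- data.frame(read_id = "r", outcome = "unaligned", length = 0L,
                       offset_from_cut = NA, n_mismatch_window = NA,
                       score = -1)
  expect_error(summarize_editing(all_un), "zero aligned")
})
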