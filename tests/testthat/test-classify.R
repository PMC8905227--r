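# toy reference: two genes on chr A01
toy_reference <- function() {
  data.frame(
    transcript_id = c("g1.1", "g1.1", "g2.1"),
    gene_id = c("g1", "g1", "g2"),
    chrom = "A01", strand = c("+", "+", "-"),
    start = c(1000L, 2000L, 5000L),
    end = c(1500L, 2500L, 6000L), stringsAsFactors = FALSE)
}

test_that("class codes follow the positional rules", {
  ref <- toy_reference()
  asm <- data.frame(
    transcript_id = c("t_same", "t_anti", "t_intron", "t_u", "t_span"),
    gene_id = c("t_same", "t_anti", "t_intron", "t_u", "t_span"),
    chrom = "A01",
    strand = c("+", "-", "+", "+", "."),
    start = c(1000L, 1100L, 1600L, 3100L, 900L),
    end = c(1500L, 1400L, 1900L, 3500L, 1600L), stringsAsFactors = FALSE)
  res <- assign_class_codes(asm, ref)
  codes <- setNames(res$class_code, res$transcript_id)
  expect_equal(unname(codes["t_same"]), "overlapping_other")
  expect_equal(unname(codes["t_anti"]), "x")
  expect_equal(unname(codes["t_intron"]), "i")
  expect_equal(unname(codes["t_u"]), "u")
  # unknown-strand exonic overlap cannot claim antisense
  expect_equal(unname(codes["t_span"]), "overlapping_other")
  # intronic transcript: distance 0, nearest gene g1
  expect_equal(res$distance_to_nearest_gene[res$transcript_id == "t_intron"],
               0L)
  expect_equal(res$nearest_gene_id[res$transcript_id == "t_intron"], "g1")
  # every transcript gets exactly one code (partition property)
  expect_true(all(!is.na(res$class_code)))
  expect_equal(nrow(res), length(unique(asm$transcript_id)))
})

test_that("distance to nearest gene matches a brute-force scan", {
  ref <- toy_reference()
  # nearest gene (g2, ends at 6000 exclusive) is 600 bp away
  asm <- data.frame(transcript_id = "t", gene_id = "t", chrom = "A01",
                    strand = "+", start = 6600L, end = 7000L,
                    stringsAsFactors = FALSE)
  res <- assign_class_codes(asm, ref)
  expect_equal(res$class_code, "u")
  expect_equal(res$distance_to_nearest_gene, 600L)
  expect_equal(res$nearest_gene_id, "g2")

  # randomized transcripts vs O(n*m) brute force
  set.seed(21)
  genes <- data.frame(start = sort(sample(seq(1000, 90000, by = 100), 15)))
  genes$end <- genes$start + sample(500:2000, 15, replace = TRUE)
  genes$gene_id <- sprintf("g%02d", seq_len(15))
  ref2 <- data.frame(transcript_id = paste0(genes$gene_id, ".1"),
                     gene_id = genes$gene_id, chrom = "A01", strand = "+",
                     start = genes$start, end = genes$end,
                     stringsAsFactors = FALSE)
  for (i in 1:25) {
    s <- sample(1:100000, 1)
    asm_i <- data.frame(transcript_id = "t", gene_id = "t", chrom = "A01",
                        strand = "+", start = s, end = s + 300L,
                        stringsAsFactors = FALSE)
    res_i <- assign_class_codes(asm_i, ref2)
    brute <- min(pmax(0L, pmax(genes$start - (s + 300L), s - genes$end)))
    expect_equal(res_i$distance_to_nearest_gene, brute)
  }
})

test_that("unknown chromosomes yield per-record errors, not a failure", {
  ref <- toy_reference()
  asm <- data.frame(transcript_id = c("ok", "bad"), gene_id = c("ok", "bad"),
                    chrom = c("A01", "Z99"), strand = "+",
                    start = c(3000L, 100L), end = c(3400L, 500L),
                    stringsAsFactors = FALSE)
  res <- assign_class_codes(asm, ref)
  expect_equal(res$class_code[res$transcript_id == "ok"], "u")
  expect_true(is.na(res$class_code[res$transcript_id == "bad"]))
  expect_match(res$note[res$transcript_id == "bad"], "unknown chromosome")
})

test_that("filter cascade matches brute-force predicate evaluation", {
  ref <- toy_reference()
  # ten transcripts with per-rule decoys
  mk <- function(id, start, len) {
    data.frame(transcript_id = id, gene_id = id, chrom = "A01",
               strand = "+", start = start, end = start + len,
               stringsAsFactors = FALSE)
  }
  asm <- rbind(mk("pass1", 10000L, 400L), mk("pass2", 20000L, 250L),
               mk("short1", 30000L, 150L), mk("near1", 6100L, 300L),
               mk("low1", 40000L, 400L), mk("noest1", 50000L, 400L),
               mk("code1", 1000L, 500L), mk("pass3", 60000L, 800L),
               mk("short2", 70000L, 120L), mk("low2", 80000L, 300L))
  assigned <- assign_class_codes(asm, ref)
  samples <- paste0("s", 1:3)
  fp <- matrix(5, nrow = 10, ncol = 3,
               dimnames = list(unique(asm$transcript_id), samples))
  fp["low1", ] <- c(0.1, 0.2, 0.5)   # never exceeds 0.5 strictly
  fp["low2", ] <- 0
  est <- data.frame(chrom = "A01",
                    start = c(10000L, 20000L, 30000L, 6100L, 40000L,
                              1000L, 60000L, 70000L, 80000L),
                    end = c(10100L, 20100L, 30100L, 6200L, 40100L,
                            1100L, 60100L, 70100L, 80100L))
  params <- filter_params()
  res <- filter_candidates(assigned, asm, fp, params, est)
  # independent predicate evaluation
  spans <- split(asm, asm$transcript_id)
  expected <- sort(Filter(function(id) {
    tr <- spans[[id]]
    code_ok <- assigned$class_code[assigned$transcript_id == id] == "u"
    len_ok <- sum(tr$end - tr$start) >= 200
    fpkm_ok <- max(fp[id, ]) > 0.5
    d <- assigned$distance_to_nearest_gene[assigned$transcript_id == id]
    dist_ok <- !is.na(d) && d > 500
    est_ok <- any(est$start < tr$end[1] & tr$start[1] < est$end)
    code_ok && len_ok && fpkm_ok && dist_ok && est_ok
  }, names(spans)))
  expect_identical(res$candidates, expected)
  # first-fail attribution in cascade order
  led <- setNames(res$ledger$rule_failed, res$ledger$transcript_id)
  expect_equal(unname(led["short1"]), "length")
  expect_equal(unname(led["near1"]), "distance")
  expect_equal(unname(led["low1"]), "fpkm")
  expect_equal(unname(led["noest1"]), "est")
  expect_equal(unname(led["code1"]), "code")  # overlaps gene -> not "u"
  # FPKM needs only one sample strictly above threshold
  fp["low1", ] <- c(0.4, 0.4, 0.6)
  res2 <- filter_candidates(assigned, asm, fp, params, est)
  expect_true(!"fpkm" %in%
                res2$ledger$rule_failed[res2$ledger$transcript_id == "low1"])
})

test_that("tightening any threshold never adds survivors", {
  fx <- shared_sim()
  sim <- fx$sim
  assigned <- assign_class_codes(sim$assembled, sim$reference)
  fpkm <- counts_to_fpkm(fx$cnt$expr)
  asm_ids <- unique(sim$assembled$transcript_id)
  fp <- fpkm$values[asm_ids, , drop = FALSE]
  base <- filter_candidates(assigned, sim$assembled, fp, filter_params(),
                            sim$est)$candidates
  tighter <- list(filter_params(min_length = 400L),
                  filter_params(min_fpkm = 5),
                  filter_params(min_gene_distance = 2000L))
  for (p in tighter) {
    cand <- filter_candidates(assigned, sim$assembled, fp, p,
                              sim$est)$candidates
    expect_true(all(cand %in% base))
  }
})

test_that("missing expression rows are reported by id", {
  ref <- toy_reference()
  asm <- data.frame(transcript_id = "t1", gene_id = "t1", chrom = "A01",
                    strand = "+", start = 3000L, end = 3400L,
                    stringsAsFactors = FALSE)
  assigned <- assign_class_codes(asm, ref)
  fp <- matrix(1, 1, 2, dimnames = list("other", c("s1", "s2")))
  expect_error(filter_candidates(assigned, asm, fp, filter_params(),
                                 data.frame(chrom = "A01", start = 1L,
                                            end = 2L)),
               "t1")
})

test_that("feature summaries and Wilcoxon comparisons are correct", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  # Wilcoxon equals exact enumeration on a no-ties case
  p_pkg <- suppressWarnings(wilcox.test(c(1, 2, 3), c(4, 5, 6),
                                        correct = FALSE)$p.value)
  expect_equal(p_pkg, oracle_wilcox_exact(c(1, 2, 3), c(4, 5, 6)))

  fx <- shared_sim()
  sim <- fx$sim
  tr <- fx$cnt$truth
  lnc <- tr$feature_id[tr$kind == "lnc" & tr$true_class_code == "u"]
  mrna <- names(sim$mrna_seqs)
  groups <- setNames(c(rep("lncRNA", length(lnc)), rep("mRNA", length(mrna))),
                     c(lnc, mrna))
  exons <- rbind(sim$assembled, sim$reference)
  seqs <- c(sim$transcript_seqs, sim$mrna_seqs)
  fpkm <- counts_to_fpkm(fx$cnt$expr)
  s <- summarize_features(exons, seqs, fpkm$values, groups)
  expect_equal(nrow(s$features), length(groups))
  cmp <- s$comparisons
  gc_row <- cmp[cmp$metric == "gc_content" & cmp$group1 == "lncRNA", ]
  # planted GC divergence (lncRNA ~0.36 < mRNA ~0.44) is detected
  expect_lt(gc_row$median1, gc_row$median2)
  expect_lt(gc_row$p_value, 0.01)
  # identical groups give p = 1 (tie-handled, no continuity correction)
  x <- s$features$gc_content[s$features$group == "lncRNA"][1:5]
  expect_equal(suppressWarnings(wilcox.test(x, x, correct = FALSE)$p.value),
               1)
})
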