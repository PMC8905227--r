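test_that("duplicated sequence sets pair every feature with its copy", {
  set.seed(12)
  at <- setNames(replicate(6, random_seq(150)), paste0("a", 1:6))
  dt <- setNames(at, paste0("d", 1:6))
  pairs <- reciprocal_best_pairs(at, dt)
  expect_equal(nrow(pairs), 6)
  expect_equal(sub("a", "", pairs$at_id), sub("d", "", pairs$dt_id))
  expect_true(all(pairs$identity == 1))
  expect_true(all(pairs$coverage == 1))
  # empty inputs
  expect_equal(nrow(reciprocal_best_pairs(at, character(0))), 0)
  expect_equal(nrow(reciprocal_best_pairs(character(0), dt)), 0)
})

test_that("RBH equals an all-vs-all Smith-Waterman oracle on a toy set", {
  set.seed(77)
  n <- 20
  base <- replicate(n, random_seq(70))
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), k)
    v[pos] <- vapply(v[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(v, collapse = "")
  }
  at <- setNames(base, sprintf("a%02d", 1:n))
  dt <- setNames(vapply(base, mutate, character(1), k = 3),
                 sprintf("d%02d", 1:n))
  got <- reciprocal_best_pairs(at, dt, min_identity = 0.8,
                               min_coverage = 0.7)
  # oracle: full DP score matrix, reciprocal best, same thresholds
  sc <- matrix(NA_real_, n, n, dimnames = list(names(at), names(dt)))
  for (i in names(at)) {
    for (j in names(dt)) sc[i, j] <- oracle_sw_nt(at[[i]], dt[[j]])
  }
  best_d <- colnames(sc)[apply(sc, 1, which.max)]
  best_a <- rownames(sc)[apply(sc, 2, which.max)]
  names(best_d) <- rownames(sc); names(best_a) <- colnames(sc)
  oracle_pairs <- sort(unlist(lapply(rownames(sc), function(a) {
    d <- best_d[[a]]
    if (best_a[[d]] == a) paste(a, d) else NULL
  })))
  # package pairs passed thresholds, so they must be a subset of the
  # oracle's reciprocal-best set with identical scores
  expect_true(all(paste(got$at_id, got$dt_id) %in% oracle_pairs))
  for (i in seq_len(nrow(got))) {
    expect_equal(got$score[i], sc[got$at_id[i], got$dt_id[i]])
  }
  # with mild mutation every pair should be recovered
  expect_equal(nrow(got), n)
})

test_that("output is invariant under swapping the subgenome arguments", {
  set.seed(13)
  at <- setNames(replicate(4, random_seq(100)), paste0("a", 1:4))
  dt <- setNames(lapply(at, function(s) s), paste0("d", 1:4))
  dt <- unlist(dt)
  p1 <- reciprocal_best_pairs(at, dt)
  p2 <- reciprocal_best_pairs(dt, at)
  expect_equal(p1$at_id, sub("d", "a", p2$dt_id))
  expect_equal(p1$dt_id, sub("a", "d", p2$at_id))
  expect_equal(p1$score, p2$score)
})

test_that("synteny filter accepts planted blocks and rejects shuffled ones", {
  fx <- shared_sim()
  sim <- fx$sim
  tr <- sim$truth
  lnc <- tr$feature_id[tr$kind == "lnc" & tr$true_class_code == "u"]
  at_ids <- lnc[tr$subgenome[match(lnc, tr$feature_id)] == "At"]
  dt_ids <- lnc[tr$subgenome[match(lnc, tr$feature_id)] == "Dt"]
  pairs <- reciprocal_best_pairs(sim$transcript_seqs[at_ids],
                                 sim$transcript_seqs[dt_ids])
  truth_pairs <- tr[!is.na(tr$pair_id) & grepl("_at$", tr$feature_id), ]
  expect_setequal(pairs$at_id, truth_pairs$feature_id)
  ao <- sim$gene_order[substr(sim$gene_order$chrom, 1, 1) == "A", ]
  do_ <- sim$gene_order[substr(sim$gene_order$chrom, 1, 1) == "D", ]
  flagged <- synteny_filter(pairs, ao, do_)
  want <- tr$syntenic_truth[match(flagged$at_id, tr$feature_id)]
  expect_equal(flagged$syntenic, want)
  # flank_k = 0 makes the criterion vacuous
  vac <- synteny_filter(pairs, ao, do_, flank_k = 0L)
  expect_true(all(vac$syntenic))
  # missing member -> non-syntenic with warning
  expect_warning(
    miss <- synteny_filter(data.frame(at_id = "ghost", dt_id = "ghost2"),
                           ao, do_),
    "missing")
  expect_false(miss$syntenic)
})

test_that("pair expression bias reports medians and a signed-rank test", {
  pairs <- data.frame(at_id = paste0("a", 1:8), dt_id = paste0("d", 1:8))
  mk_de <- function(at_vals, dt_vals) {
    data.frame(feature_id = c(paste0("a", 1:8), paste0("d", 1:8)),
               log2_fold_change = c(at_vals, dt_vals),
               stringsAsFactors = FALSE)
  }
  # identical values: p = 1, zero median difference
  b <- pair_expression_bias(pairs, mk_de(1:8 / 4, 1:8 / 4))
  expect_equal(b$p_value, 1)
  expect_equal(b$median_diff, 0)
  # constant Dt shift of -2 is detected
  at_vals <- c(-0.5, 0.2, 0.1, -0.3, 0.4, -0.1, 0.3, 0)
  b2 <- pair_expression_bias(pairs, mk_de(at_vals, at_vals - 2))
  expect_equal(b2$median_diff, -2)
  expect_lt(b2$p_value, 0.01)
  # exact signed-rank reference: distinct all-negative differences give
  # the extreme two-sided exact p = 2 / 2^n
  b2b <- pair_expression_bias(pairs,
                              mk_de(at_vals, at_vals - 2 - (1:8) / 50))
  expect_equal(b2b$p_value, 2 / 2^8)
  # single pair: test skipped with a notice
  expect_message(
    b3 <- pair_expression_bias(pairs[1, ], mk_de(rep(1, 8), rep(0.5, 8))),
    "skipped")
  expect_true(is.na(b3$p_value))
  # no complete pairs -> error
  expect_error(pair_expression_bias(pairs,
                                    data.frame(feature_id = "z",
                                               log2_fold_change = 1)),
               "no pair")
})
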