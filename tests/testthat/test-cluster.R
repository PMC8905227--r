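test_that("k-means recovers a planted partition and degenerate cases", {
  set.seed(41)
  up <- t(sapply(1:10, function(i) c(0, 0, 0) + c(0, 3, 3) + rnorm(3, 0, .2)))
  down <- t(sapply(1:10, function(i) c(3, 0, 0) + rnorm(3, 0, .2)))
  m <- rbind(up, down)
  rownames(m) <- c(paste0("up", 1:10), paste0("dn", 1:10))
  colnames(m) <- paste0("s", 1:3)
  res <- kmeans_profiles(m, k = 2, seed = 3)
  cl <- setNames(res$assignments$cluster, res$assignments$feature_id)
  # exact recovery up to label permutation
  expect_equal(length(unique(cl[paste0("up", 1:10)])), 1)
  expect_equal(length(unique(cl[paste0("dn", 1:10)])), 1)
  expect_false(cl[["up1"]] == cl[["dn1"]])
  # determinism under fixed seed
  res2 <- kmeans_profiles(m, k = 2, seed = 3)
  expect_identical(res$assignments, res2$assignments)
  # k = n features: singleton clusters, zero inertia
  res3 <- kmeans_profiles(m[1:5, ], k = 5, seed = 1)
  expect_equal(res3$inertia, 0, tolerance = 1e-12)
  expect_equal(sort(unique(res3$assignments$cluster)), 1:5)
  expect_error(kmeans_profiles(m, k = 100), "exceeds")
  # constant rows are excluded with a notice
  m2 <- rbind(m, const = c(1, 1, 1))
  expect_message(res4 <- kmeans_profiles(m2, k = 2, seed = 3), "constant")
  expect_false("const" %in% res4$assignments$feature_id)
  # z-scored profiles have mean 0, sd 1
  expect_true(all(abs(rowMeans(res$profiles)) < 1e-12))
  expect_true(all(abs(apply(res$profiles, 1, sd) - 1) < 1e-12))
})

test_that("Fisher enrichment equals the hypergeometric tail sum", {
  # the spec'd worked example: a=5, b=15, c=10, d=70
  universe <- paste0("g", 1:100)
  fset <- universe[1:20]
  annotated <- c(universe[1:5], universe[21:30])
  ann <- data.frame(feature_id = annotated, term_id = "T1")
  res <- fisher_enrichment(fset, universe, ann, min_term_size = 1)
  expect_equal(res$a, 5)
  expect_equal(res$b, 15)
  expect_equal(res$c, 10)
  expect_equal(res$d, 70)
  expect_equal(res$p_value, oracle_fisher_p(5, 15, 10, 70))

  # random tables with N <= 200
  set.seed(52)
  for (i in 1:200) {
    N <- sample(20:200, 1)
    uni <- paste0("u", seq_len(N))
    k <- sample(2:(N - 1), 1)
    s <- sample(1:(N - 1), 1)
    term_genes <- sample(uni, k)
    fs <- sample(uni, s)
    a <- length(intersect(fs, term_genes))
    r <- fisher_enrichment(fs, uni,
                           data.frame(feature_id = term_genes,
                                      term_id = "T"),
                           min_term_size = 1)
    expect_equal(r$p_value,
                 oracle_fisher_p(a, s - a, k - a, N - s - (k - a)),
                 tolerance = 1e-12, label = paste("table", i))
  }
})

test_that("degenerate enrichment cases give p = 1", {
  universe <- paste0("g", 1:50)
  ann_all <- data.frame(feature_id = universe, term_id = "T")
  r <- fisher_enrichment(universe[1:10], universe, ann_all,
                         min_term_size = 1)
  expect_equal(r$p_value, 1)
  # feature_set = universe
  ann <- data.frame(feature_id = universe[1:20], term_id = "T")
  r2 <- fisher_enrichment(universe, universe, ann, min_term_size = 1)
  expect_equal(r2$p_value, 1)
  expect_error(fisher_enrichment("a", character(0),
                                 data.frame(feature_id = "a",
                                            term_id = "T")),
               "empty universe")
  expect_error(fisher_enrichment("zz", universe, ann), "subset")
})

test_that("BH FDR is monotone and bounded by p", {
  set.seed(61)
  universe <- paste0("g", 1:80)
  ann <- data.frame(
    feature_id = sample(universe, 200, replace = TRUE),
    term_id = sample(paste0("T", 1:12), 200, replace = TRUE))
  ann <- unique(ann)
  r <- fisher_enrichment(sample(universe, 25), universe, ann)
  expect_true(all(r$fdr >= r$p_value - 1e-12))
  expect_true(all(r$fdr <= 1))
  expect_true(all(diff(r$fdr) >= -1e-12))  # sorted by p => fdr monotone
  expect_equal(r$fdr, p.adjust(r$p_value, "BH"))
})

test_that("function transfer associates co-clustered terms, never more", {
  # planted cluster 1: all PCGs carry T_planted; cluster 2: no signal
  assignments <- data.frame(
    feature_id = c(paste0("p", 1:10), "lnc1", paste0("q", 1:10), "lnc2"),
    cluster = c(rep(1L, 11), rep(2L, 11)))
  kind <- setNames(c(rep("PCG", 10), "lncRNA", rep("PCG", 10), "lncRNA"),
                   assignments$feature_id)
  ann <- data.frame(feature_id = paste0("p", 1:10), term_id = "T_planted")
  tf <- transfer_function(assignments, kind, ann, alpha = 0.01,
                          min_term_size = 2)
  expect_equal(tf$associations$lncRNA_id, "lnc1")
  expect_equal(tf$associations$term_id, "T_planted")
  expect_equal(tf$associations$evidence, "associated")
  # lncRNA in a cluster with no significant term -> no association
  expect_false("lnc2" %in% tf$associations$lncRNA_id)
  # reproducible
  tf2 <- transfer_function(assignments, kind, ann, alpha = 0.01,
                           min_term_size = 2)
  expect_identical(tf$associations, tf2$associations)
})

test_that("planted generator profile groups are recovered by k-means", {
  fx <- shared_sim()
  tr <- fx$cnt$truth
  m <- fx$cnt$expr$values
  # induced (cluster 2) vs repressed (cluster 3) planted profiles
  ids <- tr$feature_id[tr$cluster %in% c(2L, 3L) &
                         rowMeans(m[tr$feature_id, ]) > 5]
  res <- kmeans_profiles(m[ids, ], k = 2, seed = 11)
  cl <- setNames(res$assignments$cluster, res$assignments$feature_id)
  truth_cl <- setNames(tr$cluster, tr$feature_id)[names(cl)]
  tab <- table(truth_cl, cl)
  # agreement up to label permutation
  agree <- sum(apply(tab, 1, max)) / length(cl)
  expect_gte(agree, 0.95)
})
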