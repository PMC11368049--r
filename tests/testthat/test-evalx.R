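test_that("top decile takes exactly ceil(N/10) with positional tie-breaks", {
  ds100 <- synth_library(100, noise_sd = 0.2, seed = 6)
  expect_length(top_decile(ds100)$ids, 10)
  expect_length(top_decile(ds100[1:95, , drop = FALSE])$ids, 10)
  # ties at the threshold resolve to earliest position
  tied <- compound_dataset(TINY_SMILES[1:10],
                           c(9, rep(5, 8), 5))
  hs <- top_decile(tied)
  expect_identical(hs$ids, "cmpd_1")
  tied2 <- compound_dataset(TINY_SMILES[1:11], c(9, rep(5, 10)))
  expect_identical(top_decile(tied2)$ids, c("cmpd_1", "cmpd_2"))
  expect_error(top_decile(tied[1:9, , drop = FALSE]), "at least 10")
})

test_that("top decile agrees with a full-sort brute force", {
  ds <- synth_library(100, noise_sd = 0.2, seed = 6)
  for (n in c(10, 37, 64, 100)) {
    sub <- ds[seq_len(n), , drop = FALSE]
    brute <- sub$id[order(-sub$potency)][seq_len(ceiling(0.1 * n))]
    expect_setequal(top_decile(sub)$ids, brute)
  }
})

test_that("retrieval curves are monotone, bounded and correctly seeded", {
  ds <- synth_library(60)
  hits <- top_decile(ds)
  pol <- oracle_policy("activedelta", ds, iterations = 20, seeds = 14)
  traj <- run_active_learning(pol, ds)
  rc <- retrieval_curve(traj, hits)
  expect_length(rc, 21)
  expect_true(all(diff(rc) >= 0))
  expect_true(all(rc >= 0 & rc <= 1))
  h0 <- sum(attr(traj, "cold_start")$id %in% hits$ids)
  expect_equal(unname(rc[1]), h0 / length(hits$ids))
})

test_that("scaffold diversity counts unique frameworks", {
  analogs <- compound_dataset(
    c("Cc1ccccc1", "CCc1ccccc1", "OCc1ccccc1"), c(1, 2, 3))
  expect_equal(scaffold_diversity(analogs)$count, 1)
  # manual enumeration: 3 benzene analogs share one framework; the two
  # phenylpiperidines differ (4-phenyl vs N-phenyl attachment); plus
  # biphenyl, thiophene-cyclohexane and one acyclic -> 6 scaffold classes
  eight <- compound_dataset(
    c("Cc1ccccc1", "CCc1ccccc1", "OCc1ccccc1",
      "CN1CCC(CC1)c1ccccc1", "C1CCN(CC1)c1ccccc1",
      "c1ccc(-c2ccccc2)cc1", "CC1CCC(c2cccs2)CC1", "CCO"),
    potency = 8:1)
  expect_equal(scaffold_diversity(eight)$count, 6)
  # restricted to hits: selected == all hits gives fraction 1
  ds <- synth_library(60)
  hits <- top_decile(ds)
  res <- scaffold_diversity(hits$records, hits)
  expect_equal(res$fraction, 1.0)
  expect_equal(res$count,
               scaffold_diversity(hits$records)$count)
  # diversity of a growing selection never decreases
  sel <- ds[order(ds$potency, decreasing = TRUE), , drop = FALSE]
  counts <- vapply(c(5, 15, 30, 60), function(k) {
    scaffold_diversity(sel[seq_len(k), , drop = FALSE])$count
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("similarity windows equal a brute-force recomputation", {
  ds <- synth_library(60)
  pol <- policy_config("random", iterations = 10, seeds = 77)
  traj <- run_active_learning(pol, ds)
  tab <- similarity_windows(traj, windows = list(`1-5` = 1:5, `6-10` = 6:10),
                            kinds = c("morgan_r2_2048", "maccs"))
  expect_equal(nrow(tab), 4)
  cs <- attr(traj, "cold_start")
  for (r in seq_len(nrow(tab))) {
    win <- if (tab$window[r] == "1-5") 1:5 else 6:10
    vals <- vapply(win, function(t) {
      ref_smiles <- c(cs$smiles, traj$smiles[seq_len(t - 1)])
      fps <- lapply(ref_smiles, fingerprint, kind = tab$kind[r])
      q <- fingerprint(traj$smiles[t], kind = tab$kind[r])
      max(vapply(fps, tanimoto, numeric(1), a = q))
    }, numeric(1))
    expect_equal(tab$mean_similarity[r], mean(vals))
  }
  # acquiring exact duplicates of training molecules pins the mean at 1
  dup_traj <- structure(
    data.frame(iteration = 1:3, id = paste0("d", 1:3),
               smiles = rep(cs$smiles[1], 3), potency = 1:3,
               score = NA, anchor_id = NA, train_size = 3:5),
    cold_start = cs, class = c("al_trajectory", "data.frame"))
  out <- similarity_windows(dup_traj, windows = list(all = 1:3),
                            kinds = "morgan_r2_2048")
  expect_equal(out$mean_similarity, 1.0)
  expect_error(similarity_windows(traj, windows = list(w = 1:45)), "window")
})

test_that("chemical-space embedding is 2-D, seeded, and locality-preserving", {
  ds <- synth_library(60)
  # duplicate one molecule to check near-coincidence
  dup <- rbind(as.data.frame(ds),
               data.frame(id = "dup_1", smiles = ds$smiles[5],
                          potency = ds$potency[5]))
  dup <- compound_dataset(dup$smiles, dup$potency, id = dup$id,
                          canonicalize = FALSE)
  emb <- embed_chemical_space(dup, seed = 4, max_iter = 250)
  expect_equal(dim(emb), c(61, 2))
  emb2 <- embed_chemical_space(dup, seed = 4, max_iter = 250)
  expect_identical(unclass(emb), unclass(emb2))
  # the duplicated molecule embeds next to its twin: mutual nearest neighbors
  D <- as.matrix(stats::dist(unclass(emb))) + diag(Inf, nrow(emb))
  nn <- rownames(D)[apply(D, 1, which.min)]
  expect_equal(nn[rownames(emb) == "dup_1"], ds$id[5])
  expect_equal(nn[rownames(emb) == ds$id[5]], "dup_1")
  expect_warning(embed_chemical_space(ds[1:20, , drop = FALSE], seed = 1,
                                      max_iter = 50), "PCA")
})

test_that("jump/stay counts transitions and conserves their total", {
  traj <- structure(
    data.frame(iteration = 1:5, id = paste0("m", 1:5), smiles = "",
               potency = 0, score = 0, anchor_id = NA, train_size = 3:7),
    class = c("al_trajectory", "data.frame"))
  labels <- stats::setNames(c(1, 1, 2, 2, 3), paste0("m", 1:5))
  js <- jump_stay(labels, traj)
  expect_equal(js$jumps, 2)
  expect_equal(js$stays, 2)
  same <- stats::setNames(rep(1, 5), paste0("m", 1:5))
  expect_equal(jump_stay(same, traj), list(jumps = 0, stays = 4L))
  # conservation under arbitrary labelings
  set.seed(10)
  for (k in 1:20) {
    lab <- stats::setNames(sample(1:3, 5, replace = TRUE), paste0("m", 1:5))
    js_k <- jump_stay(lab, traj)
    expect_equal(js_k$jumps + js_k$stays, 4)
  }
  # two equiprobable clusters: jumps and stays balance in the long run
  long <- structure(
    data.frame(iteration = 1:2000, id = paste0("x", 1:2000), smiles = "",
               potency = 0, score = 0, anchor_id = NA, train_size = 1:2000),
    class = c("al_trajectory", "data.frame"))
  set.seed(3)
  lab2 <- stats::setNames(sample(1:2, 2000, replace = TRUE),
                          paste0("x", 1:2000))
  js2 <- jump_stay(lab2, long)
  expect_lt(abs(js2$jumps - js2$stays) / 1999, 0.07)  # ~3 binomial SEs
  expect_error(jump_stay(labels[1:3], traj), "unlabeled")
})

test_that("strategy comparison matches exact signed-rank enumeration", {
  # identical vectors: degenerate, p = 1
  res <- compare_strategies(c(1, 2, 3), c(1, 2, 3))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_difference, 0)
  # hand-computed n = 6 statistic: d = (1,-2,3,4,-1,5) ->
  # ranks of |d| = (1.5, 3, 4, 5, 1.5, 6), V = 1.5+4+5+6 = 16.5
  a <- c(2, 1, 5, 9, 0, 12); b <- c(1, 3, 2, 5, 1, 7)
  res6 <- compare_strategies(a, b)
  expect_equal(unname(res6$statistic), 16.5)
  # uniform dominance, n = 20, distinct magnitudes: two-sided p equals the
  # exact all-positive tail 2/2^20
  set.seed(8)
  b20 <- rnorm(20)
  a20 <- b20 + seq(0.1, 2, length.out = 20)
  res20 <- compare_strategies(a20, b20)
  expect_equal(res20$p_value, 2 / 2^20, tolerance = 1e-12)
  # exact enumeration oracle for assorted small cases
  set.seed(21)
  for (n in c(5, 8, 10, 12)) {
    x <- round(rnorm(n), 3); y <- round(rnorm(n), 3)
    d <- x - y
    if (any(d == 0) || any(duplicated(abs(d)))) next
    expect_equal(compare_strategies(x, y)$p_value, signed_rank_exact_p(d),
                 tolerance = 1e-12, label = paste("n =", n))
  }
  # summary statistics of the paired differences
  expect_equal(res6$mean_difference, mean(a - b))
  expect_equal(res6$se_difference, sd(a - b) / sqrt(6))
  expect_error(compare_strategies(1:3, 1:4), "equal length")
})
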