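# Group statistics: t-tests, Spearman correlation, cluster permutation test.

test_that("pooled t-test matches stats::t.test and handles degeneracies", {
  set.seed(61)
  for (rep in 1:5) {
    a <- rnorm(8, 1); b <- rnorm(12)
    got <- unpaired_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  same <- c(1, 2, 3)
  eq <- unpaired_t(same, same)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  const <- unpaired_t(c(2, 2), c(1, 1))
  expect_true(is.infinite(const$t) && const$t > 0)
  expect_error(unpaired_t(1, same), "n >= 2")
})

test_that("summary-statistic t-test scales and degenerates correctly", {
  expect_equal(t_from_summary(5, 1, 10, 5, 2, 10)$t, 0)
  t1 <- t_from_summary(6, 1, 10, 5, 1, 10)
  t2 <- t_from_summary(6, 2, 10, 5, 2, 10)
  expect_equal(t2$t, t1$t / 2, tolerance = 1e-12)
  expect_error(t_from_summary(1, 0, 5, 2, 1, 5), "positive")
})

test_that("Spearman correlation uses average ranks and the t approximation", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  set.seed(62)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_corr(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  # ties via average ranks
  xt <- c(1, 1, 2, 3, 3, 4); yt <- c(2, 1, 2, 3, 4, 4)
  expect_equal(spearman_corr(xt, yt)$rho, cor(rank(xt), rank(yt)))
  expect_true(is.na(spearman_corr(rep(1, 5), 1:5)$rho))
  expect_error(spearman_corr(1:3, 1:3), "n >= 4")
})

test_that("cluster means reduce topographies per subject", {
  topo <- matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(cluster_mean(topo, "b"), topo[, "b"])
  expect_equal(cluster_mean(topo, c("a", "c")), rowMeans(topo[, c(1, 3)]))
  expect_equal(unname(cluster_mean(cbind(a = c(1, 1), b = c(3, 3)),
                                   c("a", "b"))), c(2, 2))
  expect_error(cluster_mean(topo, character()), "empty")
  expect_error(cluster_mean(topo, "zz"), "not in")
})

test_that("cluster permutation test: null behavior, reproducibility,
           observed map equals per-channel t-tests", {
  mon <- make_montage(16)
  adj <- build_adjacency(mon)
  set.seed(63)
  A <- matrix(rnorm(8 * 16), 8, 16, dimnames = list(NULL, mon$labels))
  # duplicated groups: t identically 0, no clusters
  r0 <- snpm_cluster_test(A, A, adj, n_perm = 256, seed = 1)
  expect_equal(nrow(r0), 0)
  expect_true(all(abs(attr(r0, "t_map")) < 1e-10))

  B <- matrix(rnorm(8 * 16), 8, 16, dimnames = list(NULL, mon$labels))
  r1 <- snpm_cluster_test(A, B, adj, n_perm = 512, seed = 7)
  r2 <- snpm_cluster_test(A, B, adj, n_perm = 512, seed = 7)
  expect_identical(r1, r2)

  tm <- attr(r1, "t_map")
  for (ch in c(1, 9, 16))
    expect_equal(unname(tm[ch]), unpaired_t(A[, ch], B[, ch])$t,
                 tolerance = 1e-10)
  expect_true(all(r1$p > 0 & r1$p <= 1))
})

test_that("supra-threshold components agree with igraph", {
  skip_if_not_installed("igraph")
  mon <- make_montage(32)
  adj <- build_adjacency(mon)
  nb <- somnotype:::adjacency_list(adj)
  g <- igraph::graph_from_edgelist(adj$edges, directed = FALSE)
  set.seed(64)
  for (rep in 1:10) {
    tv <- rnorm(32, sd = 2)
    chan <- which(abs(tv) > 2)
    if (!length(chan)) next
    comps <- somnotype:::supra_components(chan, sign(tv[chan]), nb)
    # igraph reference: subgraph on same-sign supra channels
    ref <- 0L
    for (s in c(-1, 1)) {
      sub <- chan[sign(tv[chan]) == s]
      if (!length(sub)) next
      sg <- igraph::induced_subgraph(g, sub)
      ref <- ref + igraph::components(sg)$no
    }
    expect_equal(length(comps), ref)
  }
})

test_that("a spatially coherent shift is detected as a cluster", {
  # +3 SD shift on 10 adjacent channels, 16 vs 16 subjects
  mon <- make_montage(64)
  adj <- build_adjacency(mon)
  nb <- somnotype:::adjacency_list(adj)
  seedch <- 5L
  shift_set <- seedch
  while (length(shift_set) < 10) {
    shift_set <- unique(c(shift_set, unlist(nb[shift_set])))
  }
  shift_set <- shift_set[1:10]
  hits <- 0L
  for (rep in 1:20) {
    set.seed(700 + rep)
    A <- matrix(rnorm(16 * 64), 16, 64, dimnames = list(NULL, mon$labels))
    B <- matrix(rnorm(16 * 64), 16, 64, dimnames = list(NULL, mon$labels))
    A[, shift_set] <- A[, shift_set] + 3
    ct <- snpm_cluster_test(A, B, adj, t_thresh = critical_t(0.05, 30),
                            n_perm = 512, seed = rep)
    sig <- ct[ct$p < 0.05, , drop = FALSE]
    if (nrow(sig)) {
      got <- unlist(strsplit(sig$channels[1], ";"))
      if (sum(mon$labels[shift_set] %in% got) >= 8) hits <- hits + 1L
    }
  }
  expect_gte(hits, 16)   # >= 80% of replicates
})

test_that("exact enumeration covers all relabelings for tiny designs", {
  mon <- make_montage(8)
  adj <- build_adjacency(mon)
  set.seed(65)
  A <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(NULL, mon$labels))
  B <- matrix(rnorm(4 * 8) + 2, 4, 8, dimnames = list(NULL, mon$labels))
  r <- snpm_cluster_test(A, B, adj, n_perm = 100, exact = TRUE, seed = 1)
  expect_equal(length(attr(r, "null_max")), choose(8, 4))
  if (nrow(r)) expect_gte(min(r$p), 1 / choose(8, 4))
})
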