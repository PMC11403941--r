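test_that("compute_differential returns means, one-sample t p-values and BH FDR", {
  ratios <- data.frame(
    gene = rep(c("g1", "g2"), each = 3),
    treatment = "T1",
    log_ratio = c(1.0, 1.1, 0.9, 0, 0, 0))
  expect_warning(tab <- compute_differential(ratios), "zero replicate")
  g1 <- tab[tab$gene == "g1", ]
  g2 <- tab[tab$gene == "g2", ]
  expect_equal(g1$log2fc, 1.0)
  expect_equal(g2$log2fc, 0)
  expect_equal(g2$p_raw, 1)
  expect_equal(g1$p_raw,
               t.test(c(1.0, 1.1, 0.9))$p.value)
  expect_true(all(tab$p_fdr >= tab$p_raw))

  expect_error(compute_differential(data.frame(gene = "g", treatment = "T1",
                                               log_ratio = 0.5)),
               "2 replicates")
})

test_that("type-I error of the replicate t-test is nominal on a null table", {
  set.seed(91)
  n_genes <- 2000L
  ratios <- data.frame(
    gene = rep(sprintf("g%04d", 1:n_genes), each = 4),
    treatment = "T1",
    log_ratio = rnorm(4 * n_genes, 0, 0.3))
  tab <- compute_differential(ratios)
  frac <- mean(tab$p_raw < 0.05)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("select_degs applies the fold and FDR thresholds with correct boundaries", {
  tab <- data.frame(
    gene = c("up", "down", "weakp", "weakfc"),
    treatment = "T1",
    log2fc = c(1.5, -1.5, 1.5, 0.9),
    p_raw = 0.001,
    p_fdr = c(0.01, 0.01, 0.06, 0.01))
  part <- select_degs(tab)
  expect_equal(part$treatments$T1$up, "up")
  expect_equal(part$treatments$T1$down, "down")
  expect_equal(length(deg_genes(part)), 2L)
  expect_equal(intersect(part$treatments$T1$up, part$treatments$T1$down),
               character(0))
})

test_that("venn_partition counts every gene in exactly one region", {
  v <- venn_partition(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(unname(v[c("A", "B", "A&B")]), c(1L, 1L, 1L))

  sets4 <- list(W = paste0("w", 1:2), X = paste0("x", 1:3),
                Y = paste0("y", 1:4), Z = paste0("z", 1:5))
  v4 <- venn_partition(sets4)
  expect_equal(unname(v4[c("W", "X", "Y", "Z")]), c(2L, 3L, 4L, 5L))
  expect_equal(sum(v4), 14L)
  expect_true(all(v4[!names(v4) %in% c("W", "X", "Y", "Z")] == 0L))

  # conservation + bitmask oracle on random sets
  set.seed(17)
  for (rep in 1:5) {
    genes <- sprintf("g%03d", 1:100)
    sets <- lapply(1:4, function(i) sample(genes, sample(10:60, 1)))
    names(sets) <- paste0("S", 1:4)
    v <- venn_partition(sets)
    expect_equal(sum(v), length(unique(unlist(sets))))
    # oracle: per-gene membership bitmask tally
    univ <- unique(unlist(sets))
    mask <- sapply(univ, function(g)
      sum(2^(0:3) * vapply(sets, function(s) g %in% s, logical(1))))
    oracle <- table(factor(mask, levels = 1:15))
    expect_equal(unname(as.integer(oracle)), unname(as.integer(v)))
  }
  expect_error(venn_partition(rep(list(letters), 5)), "1 to 4")
})

test_that("fc_histogram bins absolute fold changes left-closed", {
  tab <- data.frame(gene = "g1", treatment = "T1", log2fc = 2,
                    p_raw = 1e-5, p_fdr = 1e-4)
  part <- select_degs(tab)
  h <- fc_histogram(part, tab)
  expect_equal(unname(h["T1", ]), c(0, 1, 0, 0))  # fold 4 in [3,5)

  folds <- c(2.2, 2.8, 3.5, 4.5, 6, 7, 8, 9.5, 10.5, 12)
  tab10 <- data.frame(gene = sprintf("g%02d", 1:10), treatment = "T1",
                      log2fc = log2(folds), p_raw = 1e-6, p_fdr = 1e-5)
  h10 <- fc_histogram(select_degs(tab10), tab10)
  # hand tally: [2,3): 2, [3,5): 2, [5,10): 4, [10,Inf): 2
  expect_equal(unname(h10["T1", ]), c(2, 2, 4, 2) / 10)
  expect_equal(sum(h10["T1", ]), 1)

  empty <- select_degs(data.frame(gene = "g", treatment = "T1", log2fc = 0,
                                  p_raw = 1, p_fdr = 1))
  expect_warning(h0 <- fc_histogram(empty, tab), "all-zero")
  expect_equal(sum(h0), 0)
  expect_error(fc_histogram(part, tab, bin_edges = c(3, 2)), "increasing")
})

test_that("uncentered correlation matches its definition", {
  expect_equal(uncentered_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(uncentered_correlation(c(1, 0), c(0, 1)), 0)
  expect_equal(uncentered_correlation(c(1, 2), c(2, 4)), 1)
  expect_error(uncentered_correlation(c(0, 0), c(1, 2)), "zero vector")
  expect_error(uncentered_correlation(1:3, 1:2), "equal length")
})

test_that("average-linkage clustering equals the naive O(n^3) oracle", {
  # two identical rows merge at height 0; proportional rows merge first
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-3, 1, 2))
  hc <- hcluster_average(m)
  expect_equal(hc$height[1], 0)
  m2 <- rbind(r1 = c(1, 2, 1), r2 = c(2, 4, 2), r3 = c(-1, 5, -2))
  hc2 <- hcluster_average(m2)
  expect_equal(sort(abs(hc2$merge[1, ])), c(1, 2))

  set.seed(23)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(n * 5), nrow = n)
    hc <- hcluster_average(m)
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      d[i, j] <- 1 - uncentered_correlation(m[i, ], m[j, ])
    }
    expect_equal(hc$height, oracle_average_linkage_heights(d),
                 tolerance = 1e-9)
    expect_false(is.unsorted(hc$height))
  }
  expect_error(hcluster_average(rbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("delta-delta-Ct fold changes follow 2^(-ddCt) with averaged normalizers", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddct_fold_change(17, 20, 20, 20), 8)  # ddCt = -3
  # two normalizers averaged: Ct_n = 21
  fold <- ddct_fold_change(19, c(20, 22), 22, c(20, 22))
  expect_equal(fold, 2^(-((19 - 21) - (22 - 21))))
  expect_equal(fold, 8)
})

test_that("ora computes hypergeometric enrichment with BH adjustment", {
  universe <- sprintf("u%02d", 1:20)
  ann <- list(hit = universe[1:5], other = universe[6:12])
  res <- ora(query = universe[1:5], universe = universe, annotation = ann)
  expect_equal(res$p[res$term == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_true(res$enriched[res$term == "hit"])
  expect_gte(res$p[res$term == "other"], 0.99)

  expect_error(ora(c("u01", "zz"), universe, ann), "zz")

  # BH on (0.01, 0.02, 0.03) -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("crossref_targets intersects and sorts by evidence", {
  targets <- data.frame(gene = c("Tpcn1", "Hopx"), evidence = c(18L, 3L))
  res <- crossref_targets(c("Tpcn1", "Hopx", "X"), targets)
  expect_equal(res$gene, c("Tpcn1", "Hopx", "X"))
  expect_equal(res$in_targets, c(TRUE, TRUE, FALSE))
  expect_equal(res$evidence, c(18L, 3L, 0L))
  expect_equal(nrow(crossref_targets(character(), targets)), 0L)

  set.seed(31)
  deg <- sample(letters, 10)
  tg <- data.frame(gene = sample(letters, 12), evidence = sample(1:20, 12))
  res2 <- crossref_targets(deg, tg)
  expect_equal(sort(res2$gene[res2$in_targets]),
               sort(intersect(deg, tg$gene)))
})
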