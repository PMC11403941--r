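make_set <- function(pwm, n, planted, length = 300L) {
  cons <- consensus(pwm, 1)
  prom <- simulate_promoters(n_promoters = n, length = length, lambda = 0)
  p <- prom$promoters
  for (i in seq_len(min(planted, n))) {
    s <- p$seq[i]
    p$seq[i] <- paste0(substr(s, 1, 99), cons,
                       substr(s, 100 + nchar(cons), length))
  }
  p
}

test_that("promoter_coverage reports coverage fraction and pooled density", {
  set.seed(41)
  pwm <- sharp_pwm(L = 10)
  p <- make_set(pwm, n = 10, planted = 9)
  cov <- promoter_coverage(p, pwm, mss_cutoff = 0.99, css_cutoff = 0.99)
  expect_equal(cov$coverage_fraction, 0.9)
  expect_equal(cov$n_promoters_with_site, 9L)
  expect_equal(cov$per_kb, site_density(cov$hits, cov$total_bp))
  expect_equal(cov$total_bp, sum(nchar(p$seq)))
  expect_error(promoter_coverage(p[0, ], pwm), "empty")
})

test_that("an exact-match cutoff finds nothing in unplanted background", {
  set.seed(43)
  pwm <- sharp_pwm(L = 12)
  p <- make_set(pwm, n = 10, planted = 0)
  cov <- promoter_coverage(p, pwm, mss_cutoff = 1, css_cutoff = 1)
  expect_equal(cov$n_sites, 0L)
  expect_equal(cov$coverage_fraction, 0)
})

test_that("conditional binomial enrichment reproduces the exact tail sum", {
  fake_stats <- function(n_sites, total_bp, n_prom = 10L) {
    structure(list(n_sites = n_sites, total_bp = total_bp,
                   per_kb = 1000 * n_sites / total_bp,
                   n_promoters = n_prom, n_promoters_with_site = n_prom,
                   coverage_fraction = 1,
                   hits = NULL,
                   per_promoter = data.frame(
                     id = sprintf("p%d", 1:n_prom),
                     length = rep(total_bp / n_prom, n_prom),
                     n_sites = c(rep(n_sites %/% n_prom +
                                       n_sites %% n_prom, 1),
                                 rep(n_sites %/% n_prom, n_prom - 1)))),
              class = "density_stats")
  }
  fg <- fake_stats(10L, 2000L)
  bg <- fake_stats(5L, 2000L)
  res <- density_enrichment(fg, bg, method = "binomial_conditional",
                            alternative = "greater")
  expect_equal(res$p_value, 4944 / 32768, tolerance = 1e-12)

  # null case: equal densities and exposures give an unremarkable p
  eq <- density_enrichment(fake_stats(5L, 2000L), fake_stats(5L, 2000L),
                           method = "binomial_conditional")
  expect_gte(eq$p_value, 0.5)

  # no sites at all: p = 1 with a warning
  expect_warning(z <- density_enrichment(fake_stats(0L, 2000L),
                                         fake_stats(0L, 2000L),
                                         method = "binomial_conditional"),
                 "zero total")
  expect_equal(z$p_value, 1)

  # swapping fg and bg flips enrichment to depletion
  swapped <- density_enrichment(bg, fg, method = "binomial_conditional",
                                alternative = "greater")
  expect_gte(res$p_value + swapped$p_value, 1)

  pois <- density_enrichment(fg, bg, method = "poisson_rate")
  expect_equal(pois$p_value,
               poisson.test(c(10L, 5L), c(2000L, 2000L),
                            alternative = "greater")$p.value)
})

test_that("permutation p agrees with the binomial p within Monte-Carlo error", {
  set.seed(47)
  pwm <- sharp_pwm(L = 10)
  fg <- promoter_coverage(make_set(pwm, 15, planted = 12), pwm, 0.99, 0.99)
  bg <- promoter_coverage(make_set(pwm, 15, planted = 3), pwm, 0.99, 0.99)
  p_bin <- density_enrichment(fg, bg, "binomial_conditional")$p_value
  p_perm <- density_enrichment(fg, bg, "permutation", n_perm = 4000L)$p_value
  expect_lt(abs(p_perm - p_bin), 0.05)
})

test_that("permutation p-values are valid under the null", {
  set.seed(53)
  pwm <- sharp_pwm(L = 8)
  reps <- 60L
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    fg <- promoter_coverage(make_set(pwm, 8, planted = 4), pwm, 0.99, 0.99)
    bg <- promoter_coverage(make_set(pwm, 8, planted = 4), pwm, 0.99, 0.99)
    pvals[r] <- density_enrichment(fg, bg, "permutation",
                                   n_perm = 200L)$p_value
  }
  alpha <- 0.1
  slack <- 3 * sqrt(alpha * (1 - alpha) / reps)
  expect_lte(mean(pvals <= alpha), alpha + slack)
})

test_that("anchor windows flank the hit and clip at promoter ends", {
  prom <- data.frame(id = "p1", seq = rand_seq(3000))
  hits <- data.frame(promoter_id = "p1", offset = c(500L, 10L),
                     strand = c("+", "-"), mss = 1, css = 1,
                     site_seq = "x")
  expect_message(
    w <- anchor_windows(hits, prom, pwm_length = 12L, flank = 100L),
    "clipping")
  expect_equal(w$start[1], 400L)
  expect_equal(w$end[1], 612L)
  expect_equal(nchar(w$seq[1]), 212L)
  expect_equal(w$seq[1], substring(prom$seq, 401, 612))
  expect_equal(w$start[2], 0L)
  expect_equal(w$end[2], 122L)

  bad <- data.frame(promoter_id = "nope", offset = 1L, strand = "+",
                    mss = 1, css = 1, site_seq = "x")
  expect_error(anchor_windows(bad, prom, 12L), "unknown promoter")
})

test_that("module_discovery ranks a fully separating secondary motif first", {
  set.seed(59)
  sec <- sharp_pwm(L = 8, name = "M2")
  decoy <- sharp_pwm(L = 8, name = "decoy")
  cons <- consensus(sec, 1)
  pos <- data.frame(seq = vapply(1:5, function(i)
    paste0(rand_seq(60), cons, rand_seq(60)), ""))
  con <- data.frame(seq = vapply(1:5, function(i) rand_seq(128), ""))
  res <- module_discovery(pos, con, list(sec, decoy), anchor_name = "Abl1",
                          mss_cutoff = 0.99, css_cutoff = 0.99)
  expect_equal(res$secondary[1], "M2")
  expect_equal(res$p[1], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res[res$secondary == "M2", c("a", "b", "c", "d")],
               data.frame(a = 5L, b = 0L, c = 0L, d = 5L),
               ignore_attr = TRUE)

  # a motif present everywhere conveys no module
  allhit <- data.frame(seq = vapply(1:4, function(i)
    paste0(rand_seq(10), cons, rand_seq(10)), ""))
  res2 <- module_discovery(allhit, allhit, list(sec), anchor_name = "Abl1",
                           mss_cutoff = 0.99, css_cutoff = 0.99)
  expect_equal(res2$p, 1)

  expect_warning(
    res3 <- module_discovery(pos, con, list(sec, decoy),
                             anchor_name = "decoy",
                             mss_cutoff = 0.99, css_cutoff = 0.99),
    "anchor")
  expect_false("decoy" %in% res3$secondary)
  expect_error(module_discovery(pos[1, , drop = FALSE], con, list(sec)),
               "at least 2")
})

test_that("profile-1 and profile-2 designs coincide when the contrast sets do", {
  set.seed(61)
  sec <- sharp_pwm(L = 8, name = "M2")
  dec <- sharp_pwm(L = 8, name = "M3")
  cons <- consensus(sec, 1)
  pos <- data.frame(seq = vapply(1:6, function(i)
    paste0(rand_seq(50), if (i <= 4) cons else rand_seq(8), rand_seq(50)),
    ""))
  contrast <- data.frame(seq = vapply(1:6, function(i) rand_seq(108), ""))
  r1 <- module_discovery(pos, contrast, list(sec, dec), "Abl1", 0.99, 0.99)
  r2 <- module_discovery(pos, contrast, list(sec, dec), "Abl1", 0.99, 0.99)
  expect_identical(r1, r2)
})

test_that("planted composite modules are recovered as the top-ranked secondary", {
  set.seed(67)
  planted <- sharp_pwm(L = 9, name = "planted")
  decoys <- lapply(1:3, function(i) sharp_pwm(L = 9, name = paste0("d", i)))
  cons <- consensus(planted, 1)
  wins <- 0L
  reps <- 25L
  for (r in seq_len(reps)) {
    pos <- data.frame(seq = vapply(1:8, function(i)
      paste0(rand_seq(55), cons, rand_seq(55)), ""))
    con <- data.frame(seq = vapply(1:8, function(i) rand_seq(119), ""))
    res <- module_discovery(pos, con, c(list(planted), decoys), "Abl1",
                            0.99, 0.99)
    if (res$secondary[1] == "planted") wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.95)
})
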