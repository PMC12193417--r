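# Trait summary statistics, level binning, Shannon diversity, Ward
# clustering and dendrogram cutting.

test_that("summarize_trait uses the sample (n-1) SD and CV = 100 s/mean", {
  s <- summarize_trait(c(1, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$s, sqrt(2))
  expect_equal(s$cv, 100 * sqrt(2) / 2)
  expect_equal(s$range, s$max - s$min)

  const <- summarize_trait(c(5, 5, 5))
  expect_equal(const$s, 0)
  expect_equal(const$cv, 0)
  expect_error(summarize_trait(5), ">= 2")
})

test_that("level binning follows the half-open 0.5-sd grid around the mean", {
  # mean 10, sd 2: inner edges 6,7,...,14
  expect_equal(assign_levels(5, 10, 2), 1L)       # below mean - 2 sd
  expect_equal(assign_levels(14.1, 10, 2), 10L)   # at/above mean + 2 sd
  expect_equal(assign_levels(14, 10, 2), 10L)     # boundary closed below
  expect_equal(assign_levels(10, 10, 2), 6L)
  expect_equal(assign_levels(6, 10, 2), 2L)       # lower edge belongs upward
  expect_equal(assign_levels(5.999, 10, 2), 1L)
  expect_error(assign_levels(1, 10, 0), "sd must be > 0")
})

test_that("shannon_index attains its extremes and validates input", {
  expect_equal(shannon_index(rep(0.1, 10)), log(10))
  expect_equal(shannon_index(c(1, rep(0, 9))), 0)
  expect_error(shannon_index(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_index(c(1.5, -0.5)), "negative")
})

test_that("uniform level distribution is the unique Shannon maximum", {
  set.seed(42)
  for (i in 1:50) {
    p <- stats::runif(10)
    p <- p / sum(p)
    h <- shannon_index(p)
    expect_lte(h, log(10) + 1e-12)
    if (max(abs(p - 0.1)) > 1e-3) expect_lt(h, log(10))
  }
})

test_that("diversity_table matches an independent histogram-based oracle", {
  set.seed(11)
  n <- 1000
  v <- stats::rnorm(n, 50, 5)
  tab <- tibble::tibble(population_id = as.character(seq_len(n)),
                        !!!stats::setNames(as.list(rep(1, 8))[1:8],
                                           paste0("M", c(1:6, 8, 9))),
                        M7 = 0.5)
  tab$M1 <- v
  div <- diversity_table(tab, traits = "M1")
  # oracle: direct histogram over the ten explicit bin edges
  m <- mean(v); s <- stats::sd(v)
  edges <- c(-Inf, m - 2 * s + 0.5 * s * (0:8), Inf)
  counts <- table(cut(v, edges, right = FALSE))
  h_oracle <- shannon_index(as.numeric(counts) / n)
  expect_lt(abs(div$summary$h - h_oracle), 0.1)
  expect_equal(div$summary$h, h_oracle)  # identical binning, in fact
  # frequencies sum to one, every population has exactly one level
  expect_equal(sum(div$frequencies$p), 1, tolerance = 1e-12)
  expect_equal(nrow(div$levels), n)
})

test_that("two distinct populations split level mass into 0/0.5 frequencies", {
  tab <- tibble::tibble(population_id = c("a", "b"), M1 = c(10, 20),
                        M2 = c(1, 2), M3 = c(5, 6), M4 = c(2, 3),
                        M5 = c(0, 1), M6 = c(0.3, 0.4), M7 = c(0.4, 0.5),
                        M8 = c(0.3, 0.5), M9 = c(50, 90))
  div <- diversity_table(tab)
  expect_true(all(div$frequencies$p %in% c(0, 0.5)))
})

test_that("H' and CV are invariant to population relabeling and level permutation", {
  set.seed(5)
  tab <- simulate_study(paper_like_config(seed = 3))$traits
  div1 <- diversity_table(tab)
  shuf <- tab[sample.int(nrow(tab)), ]
  div2 <- diversity_table(shuf)
  expect_equal(div1$summary$cv, div2$summary$cv)
  expect_equal(div1$summary$h, div2$summary$h)
  # level permutation: H' depends only on the multiset of frequencies
  p <- div1$frequencies$p[div1$frequencies$trait == "M1"]
  expect_equal(shannon_index(p), shannon_index(sample(p)))
})

test_that("standardize_traits yields exact z-scores, idempotently", {
  tab <- tibble::tibble(population_id = c("a", "b", "c"), M1 = c(1, 2, 3),
                        M2 = c(1, 5, 9), M3 = c(5, 6, 8), M4 = c(2, 3, 4),
                        M5 = c(0, 1, 2), M6 = c(0.3, 0.4, 0.5),
                        M7 = c(0.4, 0.5, 0.6), M8 = c(0.3, 0.5, 0.6),
                        M9 = c(50, 90, 100))
  z <- standardize_traits(tab)
  expect_equal(z$M1, c(-1, 0, 1))
  for (tr in paste0("M", 1:9)) {
    expect_lt(abs(mean(z[[tr]])), 1e-9)
    expect_equal(stats::sd(z[[tr]]), 1)
  }
  z2 <- standardize_traits(z)
  expect_equal(as.matrix(z2[-1]), as.matrix(z[-1]), tolerance = 1e-9)
  const <- dplyr::mutate(tab, M3 = 1)
  expect_error(standardize_traits(const), "M3")
})

test_that("ward clustering merges duplicates at zero and nearest points first", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  d <- ward_cluster(m)
  expect_equal(min(d$heights), 0)

  # 3 points on a line at 0, 1, 10: first merge joins {0, 1}
  m2 <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("x", "y", "z"), NULL))
  d2 <- ward_cluster(m2)
  first <- d2$hclust$merge[1, ]
  expect_setequal(first, c(-1, -2))
  expect_equal(d2$heights[1], 1)  # squared-distance Ward cost of {0},{1}
})

test_that("two well-separated blobs are recovered by a mid-height cut", {
  set.seed(99)
  blob <- rbind(matrix(stats::rnorm(10, 0, 1), 5, 2),
                matrix(stats::rnorm(10, 10, 1), 5, 2))
  rownames(blob) <- sprintf("s%d", 1:10)
  d <- ward_cluster(blob)
  cl <- cut_dendrogram(d, max(d$heights) / 2)
  expect_equal(max(cl$cluster), 2)
  expect_equal(cl$cluster, rep(c(1L, 2L), each = 5), ignore_attr = TRUE)
})

test_that("cut_dendrogram honors strict-below semantics and monotonicity", {
  set.seed(2)
  m <- matrix(stats::rnorm(16), 8, 2, dimnames = list(letters[1:8], NULL))
  m[2, ] <- m[1, ]  # exact duplicate pair
  d <- ward_cluster(m)
  at0 <- cut_dendrogram(d, 0)
  expect_equal(max(at0$cluster), 8)  # zero-height merges are NOT below 0
  top <- cut_dendrogram(d, max(d$heights) + 1)
  expect_equal(max(top$cluster), 1)
  ks <- vapply(seq(0, max(d$heights) + 1, length.out = 25),
               function(t) max(cut_dendrogram(d, t)$cluster), integer(1))
  expect_true(all(diff(ks) <= 0))
  # labels numbered by first appearance in row order
  expect_equal(at0$cluster, 1:8, ignore_attr = TRUE)
})

test_that("ward merge heights are non-decreasing; rescaling tops out at 25", {
  set.seed(8)
  m <- matrix(stats::rnorm(30), 10, 3, dimnames = list(letters[1:10], NULL))
  d <- ward_cluster(m)
  expect_true(all(diff(d$heights) >= -1e-9))
  r <- ward_cluster(m, rescale = TRUE)
  expect_equal(max(r$heights), 25)
  expect_equal(r$heights / 25, d$heights / max(d$heights))
})

test_that("cluster_profiles recovers per-group means", {
  # one cluster: profile equals the global means
  tab <- simulate_study(paper_like_config(seed = 4))$traits
  all1 <- cut_dendrogram(ward_cluster(standardize_traits(tab)), 1e9)
  prof <- cluster_profiles(all1, tab)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$M9, mean(tab$M9))

  # synthetic 2-group fixture: M9 means 40 vs 90 recovered within 2 SE
  set.seed(77)
  n <- 40
  t2 <- tibble::tibble(population_id = sprintf("p%02d", 1:n),
                       M1 = stats::rnorm(n, 30, 2), M2 = 1, M3 = 9, M4 = 3,
                       M5 = 0.1, M6 = 0.3, M7 = 0.4, M8 = 0.4,
                       M9 = stats::rnorm(n, rep(c(40, 90), each = n / 2), 5))
  truth <- rep(1:2, each = n / 2)
  asg <- structure(tibble::tibble(sample_id = t2$population_id,
                                  cluster = truth),
                   class = c("cluster_assignment", class(tibble::tibble())))
  prof2 <- cluster_profiles(asg, t2, traits = "M9")
  se <- 5 / sqrt(n / 2)
  expect_lt(abs(prof2$M9[1] - 40), 2 * se)
  expect_lt(abs(prof2$M9[2] - 90), 2 * se)
  # singleton clusters reproduce their row exactly
  one <- structure(tibble::tibble(sample_id = t2$population_id,
                                  cluster = seq_len(n)),
                   class = c("cluster_assignment", class(tibble::tibble())))
  p1 <- cluster_profiles(one, t2, traits = "M9")
  expect_equal(p1$M9, t2$M9)
})

test_that("ward dendrogram equals the naive Lance-Williams recurrence for n <= 8", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:8, 1)
    m <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(sprintf("s%d", 1:n), NULL))
    d <- ward_cluster(m)
    oracle <- naive_sahn(as.matrix(stats::dist(m))^2, "ward")
    expect_equal(d$heights, oracle$heights, tolerance = 1e-9)
    for (k in 2:(n - 1)) {
      mine <- stats::cutree(d$hclust, k = k)
      theirs <- oracle$partitions[[n - k]]
      expect_true(same_partition(mine, theirs))
    }
  }
})
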