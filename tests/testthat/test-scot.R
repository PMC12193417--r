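# Dominant-marker band analysis: polymorphism, PIC, simple matching, UPGMA.

test_that("polymorphic loci are columns with both states; rates in percent", {
  x <- rbind(c(1, 1, 0, 1),
             c(1, 0, 1, 1),
             c(1, 1, 0, 1))
  m <- band_fixture(x, primers = c("P1", "P1", "P2", "P2"))
  out <- polymorphic_loci(m)
  expect_equal(out$loci$polymorphic, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$rate, 50)
  expect_equal(out$by_primer$rate, c(50, 50))
  # invariance to sample and locus order
  perm <- band_fixture(x[c(3, 1, 2), c(2, 4, 1, 3)],
                       primers = c("P1", "P2", "P1", "P2"))
  expect_equal(polymorphic_loci(perm)$rate, 50)
})

test_that("pic formula for a dominant biallelic locus", {
  expect_equal(pic_locus(0.5), 0.5)
  expect_equal(pic_locus(1), 0)
  expect_equal(pic_locus(0), 0)
  expect_equal(pic_locus(0.69), 1 - 0.69^2 - 0.31^2)
  expect_equal(pic_locus(0.69), 0.4278)
  # symmetry and maximum at 1/2
  p <- seq(0, 1, by = 0.01)
  expect_equal(pic_locus(p), pic_locus(1 - p))
  expect_true(all(pic_locus(p) <= 0.5 + 1e-12))
  expect_error(pic_locus(1.2), "\\[0, 1\\]")
})

test_that("primer summary aggregates per primer with Mean/Total rows", {
  x <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(1, 1, 0, 0), c(0, 1, 1, 0))
  m <- band_fixture(x, primers = c("P1", "P1", "P2", "P2"))
  s <- primer_summary(m)
  p1 <- s[s$primer == "P1", ]
  expect_equal(p1$n_bands, 2)
  expect_equal(p1$n_polymorphic, 1)
  expect_equal(p1$mean_freq, mean(c(0.5, 1)))
  expect_equal(p1$pic, pic_locus(0.5))  # polymorphic loci only by default
  sm_all <- primer_summary(m, pic_include_monomorphic = TRUE)
  expect_equal(sm_all$pic[sm_all$primer == "P1"], mean(pic_locus(c(0.5, 1))))
  expect_equal(s$n_polymorphic[s$primer == "Total"], 2)
  # a single-primer matrix with all loci at p = 0.5 has PIC 0.5
  y <- rbind(c(1, 1), c(0, 0))
  expect_equal(primer_summary(band_fixture(y))$pic[1], 0.5)
})

test_that("polymorphism aggregates reproduce counts-based headline figures", {
  counts <- tibble::tibble(primer = c("A", "B"), n_polymorphic = c(3, 5),
                           n_bands = c(4, 5), pic = c(0.2, 0.4))
  agg <- polymorphism_aggregates(counts)
  expect_equal(agg$total_polymorphic, 8)
  expect_equal(agg$overall_rate, 100 * 8 / 9)
  expect_equal(agg$best_primer, "B")
  expect_equal(agg$best_primer_rate, 100)
  expect_equal(agg$max_pic, 0.4)
})

test_that("simple matching counts shared absences and presences", {
  x <- rbind(c(1, 0, 1, 1, 0),
             c(1, 0, 0, 1, 1),
             c(0, 1, 0, 0, 1))
  m <- band_fixture(x)
  s <- sm_similarity(m)
  expect_equal(s[1, 2], 3 / 5)
  expect_equal(s[1, 3], 0)      # complementary rows
  expect_equal(diag(s), stats::setNames(rep(1, 3), rownames(s)))
  expect_equal(s, t(s))
  # invariant under global 0/1 relabeling
  flip <- band_fixture(1 - x)
  expect_equal(unname(sm_similarity(flip)), unname(s))
})

test_that("1 - SM is a metric: triangle inequality on random matrices", {
  set.seed(14)
  for (i in 1:10) {
    x <- matrix(stats::rbinom(8 * 20, 1, 0.5), 8, 20)
    d <- 1 - sm_similarity(band_fixture(x))
    for (a in 1:8) for (b in 1:8) for (c in 1:8) {
      expect_lte(d[a, b], d[a, c] + d[c, b] + 1e-12)
    }
  }
})

test_that("UPGMA dendrogram is ultrametric with non-decreasing heights", {
  set.seed(15)
  x <- matrix(stats::rbinom(10 * 30, 1, 0.5), 10, 30)
  res <- scot_cluster(sm_similarity(band_fixture(x)), threshold = 0.5)
  expect_true(all(diff(res$dendrogram$heights) >= -1e-9))
  cop <- stats::cophenetic(res$dendrogram$hclust)
  cm <- as.matrix(cop)
  for (a in 1:10) for (b in 1:10) for (c in 1:10) {
    expect_lte(cm[a, b], max(cm[a, c], cm[c, b]) + 1e-9)
  }
})

test_that("UPGMA equals the naive Lance-Williams recurrence for n <= 8", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:8, 1)
    x <- matrix(stats::rbinom(n * 25, 1, 0.5), n, 25)
    s <- sm_similarity(band_fixture(x))
    res <- scot_cluster(s, threshold = 0.5)
    oracle <- naive_sahn(1 - s, "average")
    expect_equal(res$dendrogram$heights, oracle$heights, tolerance = 1e-9)
  }
})

test_that("planted band groups are recovered by the documented cut", {
  set.seed(16)
  n_loci <- 30
  profA <- stats::rbinom(n_loci, 1, 0.5)
  profB <- profA
  flipidx <- sample(n_loci, 12)  # 40% of loci differ between groups
  profB[flipidx] <- 1 - profB[flipidx]
  rows <- rbind(
    t(replicate(6, (profA + stats::rbinom(n_loci, 1, 0.02)) %% 2)),
    t(replicate(6, (profB + stats::rbinom(n_loci, 1, 0.02)) %% 2)))
  res <- scot_cluster(sm_similarity(band_fixture(rows)), threshold = 0.3)
  expect_equal(max(res$assignment$cluster), 2)
  expect_equal(res$assignment$cluster, rep(c(1L, 2L), each = 6),
               ignore_attr = TRUE)

  # duplicates merge at height zero; threshold 1 gives a single cluster
  dup <- band_fixture(rbind(profA, profA, profB))
  res2 <- scot_cluster(sm_similarity(dup), threshold = 1)
  expect_equal(min(res2$dendrogram$heights), 0)
  expect_equal(max(res2$assignment$cluster), 1)
})
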