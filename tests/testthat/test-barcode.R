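# Variable sites, haplotype grouping, K2P distances and locus concatenation.

test_that("variable sites and haplotypes on tiny alignments", {
  inv <- aln_fixture(a = "AAAA", b = "AAAA", c = "AAAA", locus = "trnL-F")
  prof <- variable_sites(inv)
  expect_equal(nrow(prof$sites), 0)
  expect_equal(max(prof$haplotypes$haplotype), 1)

  one <- aln_fixture(a = "AAA", b = "AAA", c = "AAC")
  prof1 <- variable_sites(one)
  expect_equal(prof1$sites$position, 3)
  expect_equal(max(prof1$haplotypes$haplotype), 2)
  expect_equal(prof1$haplotypes$haplotype, c(1L, 1L, 2L))
})

test_that("gaps, N and ambiguity codes are excluded from site comparison", {
  # site 1: A vs gap vs N -> only one unambiguous state, not variable
  # site 2: A vs R (ambiguity) vs A -> not variable; site 3: A/C -> variable
  aln <- aln_fixture(a = "AAA", b = "-RC", c = "NAC", d = "AAA")
  prof <- variable_sites(aln)
  expect_equal(prof$sites$position, 3)
})

test_that("reference coordinates map through ungapped reference positions", {
  aln <- aln_fixture(REF = "A-CGT", s1 = "AACGT", s2 = "AACGA",
                     reference_id = "REF")
  prof <- variable_sites(aln)
  expect_equal(prof$sites$position, 5)
  expect_equal(prof$sites$ref_position, 4)  # gap at alignment column 2
})

test_that("planted haplotypes are recovered exactly from the generator", {
  st <- simulate_study(paper_like_config(seed = 13))
  its <- variable_sites(st$alignments$ITS)
  expect_setequal(its$sites$position, st$planted_sites$ITS)
  expect_equal(max(its$haplotypes$haplotype), 5)
  agree <- pair_agreement_oracle(st$truth$group,
                                 its$haplotypes$haplotype[match(st$truth$population_id,
                                                                its$haplotypes$sample_id)])
  expect_equal(agree, 1)
})

test_that("k2p distance matches the closed form on counted substitutions", {
  same <- k2p_distance("ACGT", "ACGT")
  expect_equal(same$distance, 0)
  expect_false(same$saturated)

  # 100 sites, exactly one transition
  a <- strrep("ACGT", 25)
  b <- paste0("GCGT", strrep("ACGT", 24))
  k <- k2p_distance(a, b)
  expect_equal(k$P, 0.01)
  expect_equal(k$Q, 0)
  expect_equal(k$distance, -0.5 * log(0.98), tolerance = 1e-12)

  # saturated: all transversions
  sat <- k2p_distance("AT", "TA")
  expect_true(sat$saturated)
  expect_true(is.na(sat$distance))

  # pairwise deletion of gaps/ambiguity
  pd <- k2p_distance("A-CGN", "AACGT")
  expect_equal(pd$sites, 3)
  expect_error(k2p_distance("---", "AAA"), "no comparable sites")
  expect_error(k2p_distance("AC", "ACG"), "length")
})

test_that("k2p properties: Q=0 reduction, bound below by p-distance, symmetry", {
  set.seed(31)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    bch <- strsplit(a, "")[[1]]
    nmut <- sample(1:20, 1)
    idx <- sample(200, nmut)
    bch[idx] <- vapply(bch[idx], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    b <- paste(bch, collapse = "")
    k <- k2p_distance(a, b)
    if (!k$saturated) {
      pdist <- (k$P + k$Q)
      expect_gte(k$distance, pdist - 1e-12)
      if (k$Q == 0) expect_equal(k$distance, -0.5 * log(1 - 2 * k$P))
    }
    expect_equal(k2p_distance(b, a)$distance, k$distance)
  }
})

test_that("k2p matrix is symmetric with zero diagonal and flags saturation", {
  aln <- aln_fixture(a = "ACGTACGTAC", b = "ACGTACGTAT", c = "GCGTACGTAC")
  d <- k2p_matrix(aln)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(attr(d, "metric"), "K2P")
  expect_false(any(attr(d, "saturated")))

  sat <- k2p_matrix(aln_fixture(a = "AT", b = "TA", c = "AT"))
  expect_true(attr(sat, "saturated")["a", "b"])
  expect_true(is.na(sat["a", "b"]))
})

test_that("concatenation sums lengths, records boundaries, requires shared samples", {
  its <- aln_fixture(s1 = strrep("A", 588), s2 = strrep("C", 588), locus = "ITS")
  psb <- aln_fixture(s1 = strrep("G", 337), s2 = strrep("T", 337), locus = "psbA")
  comb <- concatenate_barcodes(list(its, psb))
  expect_equal(comb$length, 925)
  expect_equal(comb$locus, "ITS+psbA")
  b <- attr(comb, "boundaries")
  expect_equal(b$start, c(1, 589))
  expect_equal(b$end, c(588, 925))

  expect_equal(concatenate_barcodes(list(its))$sequences, its$sequences)

  other <- aln_fixture(s1 = "AA", s3 = "CC", locus = "psbA")
  expect_error(concatenate_barcodes(list(its, other)), "sample set mismatch")
})

test_that("crossed haplotypes combine into the planted number of classes", {
  st <- simulate_study(paper_like_config(seed = 17))
  comb <- concatenate_barcodes(st$alignments[c("ITS", "psbA")])
  asg <- barcode_cluster(comb)
  expect_equal(max(asg$cluster), 7)
  # refinement: combined partition refines each single-locus partition
  its <- barcode_cluster(st$alignments$ITS)
  psb <- barcode_cluster(st$alignments$psbA)
  ord <- st$truth$population_id
  cc <- asg$cluster[match(ord, asg$sample_id)]
  expect_true(is_refinement_oracle(cc, its$cluster[match(ord, its$sample_id)]))
  expect_true(is_refinement_oracle(cc, psb$cluster[match(ord, psb$sample_id)]))
})

test_that("barcode_cluster covers the degenerate and saturated-free cases", {
  inv <- aln_fixture(a = strrep("ACGT", 10), b = strrep("ACGT", 10),
                     c = strrep("ACGT", 10), locus = "trnL-F")
  asg <- barcode_cluster(inv)
  expect_equal(max(asg$cluster), 1)
  expect_s3_class(attr(asg, "tree"), "phylo")

  uniq <- aln_fixture(a = "AAAA", b = "AACA", c = "ACAA", d = "CAAA")
  expect_equal(max(barcode_cluster(uniq)$cluster), 4)
})
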