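geno_freqs <- c(0.005, 0.272, 0.088, 0.095, 0.038, 0.502)

test_that("allele frequencies follow from the six genotype classes", {
  af <- genotype_to_allele_frequencies(geno_freqs)
  expect_equal(unname(af["green"]), 0.0715)
  expect_equal(unname(af["striped"]), 0.5705)
  expect_equal(unname(af["melanic"]), 0.3580)
  expect_equal(sum(af), 1)
  # named input in any order gives the same answer
  named <- stats::setNames(geno_freqs, genotype_cluster_levels())
  expect_equal(genotype_to_allele_frequencies(rev(named)), af)
})

test_that("genotype frequency inputs are validated", {
  expect_error(genotype_to_allele_frequencies(geno_freqs[1:5]), "six")
  expect_error(genotype_to_allele_frequencies(geno_freqs * 2), "sum to 1")
  expect_error(genotype_to_allele_frequencies(c(-0.01, 0.31, 0.088, 0.095,
                                                0.015, 0.502)),
               "non-negative")
  wrong <- stats::setNames(geno_freqs, c(genotype_cluster_levels()[-1], "x/y"))
  expect_error(genotype_to_allele_frequencies(wrong), "exactly the six")
})

test_that("the Monte-Carlo heterozygote-excess test converges to the exact tail", {
  out <- het_excess_test(57, 602, 0.0815, reps = 2e5, seed = 1)
  expect_equal(out$p_exact,
               stats::pbinom(56, 602, 0.0815, lower.tail = FALSE))
  expect_lt(abs(out$p_mc - out$p_exact), 0.005)
  expect_equal(out$expected_count, 602 * 0.0815)
})

test_that("het_excess_test tie handling and corrections behave", {
  geq <- het_excess_test(57, 602, 0.0815, reps = 5000, seed = 2)
  gt <- het_excess_test(57, 602, 0.0815, reps = 5000, seed = 2, ties = "gt")
  expect_lte(gt$p_mc, geq$p_mc)
  raw <- het_excess_test(57, 602, 0.0815, reps = 5000, seed = 2,
                         add_one = FALSE)
  expect_equal(geq$p_mc, (raw$p_mc * 5000 + 1) / 5001)
  expect_identical(geq, het_excess_test(57, 602, 0.0815, reps = 5000,
                                        seed = 2))
  expect_error(het_excess_test(700, 602, 0.0815))
  expect_error(het_excess_test(57, 602, 0.0815, reps = 0), ">= 1")
})

test_that("het_excess_from_genotypes wires the arithmetic together", {
  out <- het_excess_from_genotypes(geno_freqs, n = 602, reps = 1000, seed = 1)
  af <- attr(out, "allele_freqs")
  expect_equal(unname(af["green"]), 0.0715)
  expect_equal(out$expected_het_freq, 2 * 0.0715 * 0.5705)
  # default observed count is the green/striped class count
  expect_equal(out$observed, round(602 * 0.095))
})

test_that("PCA + k-means recovers well-separated genotype clusters", {
  gs <- sim_genotypes(300, rep(1 / 6, 6), n_snps = 200, seed = 42)
  asg <- assign_clusters(gs$snps, seed = 7)
  expect_equal(nrow(asg$assignments), 300)
  expect_setequal(asg$assignments$individual, gs$individuals$individual)
  ari <- mclust::adjustedRandIndex(asg$assignments$cluster,
                                   gs$individuals$genotype_cluster)
  expect_gte(ari, 0.95)
  expect_identical(assign_clusters(gs$snps, seed = 7)$assignments,
                   asg$assignments)
})

test_that("assign_clusters rejects degenerate input", {
  expect_error(assign_clusters(matrix(0, 4, 10)), "at least k")
  expect_error(assign_clusters(matrix(0, 20, 10)), "distinct points")
})

test_that("designate_genotypes relabels clusters without changing frequencies", {
  gs <- sim_genotypes(120, rep(1 / 6, 6), n_snps = 100, seed = 5)
  asg <- assign_clusters(gs$snps, seed = 5)
  # majority phenotype per cluster plays the role of the external designation
  truth <- gs$individuals$genotype_cluster
  des <- tibble::tibble(
    cluster = sort(unique(asg$assignments$cluster)),
    genotype = vapply(sort(unique(asg$assignments$cluster)), function(k) {
      names(which.max(table(truth[asg$assignments$cluster == k])))
    }, character(1))
  )
  lab <- designate_genotypes(asg, des)
  expect_true("genotype" %in% names(lab))
  expect_equal(nrow(lab), 120)
  expect_error(designate_genotypes(asg, tibble::tibble(cluster = 1,
                                                       genotype = "odd")),
               "unknown genotype")
})
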