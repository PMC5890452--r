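test_that("the same seed reproduces the cohort exactly", {
  cfg <- sim_config(n_taxa = 10, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                    n_true_sites = 200, n_error_only_sites = 20,
                    n_paralog_sites = 10, n_translocated_sites = 5,
                    seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$anchor$geno, b$anchor$geno)
  expect_identical(a$depths$chr1$depth, b$depths$chr1$depth)
  # and a different seed gives a different cohort
  cfg2 <- sim_config(n_taxa = 10, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                     n_true_sites = 200, n_error_only_sites = 20,
                     n_paralog_sites = 10, n_translocated_sites = 5,
                     seed = 124)
  expect_false(identical(simulate_cohort(cfg2)$depths$chr1$depth,
                         a$depths$chr1$depth))
})

test_that("the config validates counts, rates and the mandatory seed", {
  expect_error(sim_config(n_taxa = 10), "seed")
  expect_error(sim_config(seq_error_rate = 1.5, seed = 1))
  expect_error(sim_config(n_true_sites = -1, seed = 1))
  expect_error(sim_config(anchor_density = 2, seed = 1), "anchor_density")
})

test_that("noiseless cohorts genotype back to the planted truth", {
  cfg <- sim_config(n_taxa = 15, n_founders = 3,
                    chrom_lengths = c(chr1 = 2e6), n_true_sites = 300,
                    coverage_mean = 10, seq_error_rate = 0,
                    het_residual_rate = 0, seed = 31)
  co <- simulate_cohort(cfg)
  d <- co$depths$chr1
  g <- co$truth$geno
  for (i in seq_along(d$positions)) {
    dep <- matrix(d$depth[i, , ], ncol = 6)
    called <- apply(dep, 1, call_genotype)
    covered <- rowSums(dep) > 0
    expect_identical(called[covered], g[i, covered])
  }
})

test_that("taxa sharing a founder mosaic are at IBS distance zero", {
  cfg <- sim_config(n_taxa = 8, n_founders = 2, founder_block_bp = 1e12,
                    founder_assignment = "balanced",
                    chrom_lengths = c(chr1 = 2e6), n_true_sites = 500,
                    seq_error_rate = 0, het_residual_rate = 0, seed = 32)
  co <- simulate_cohort(cfg)
  f <- co$truth$founder[1, ]
  same <- which(f == f[1])
  g <- co$truth$geno
  expect_equal(ibs_distance(g[, same[1]], g[, same[2]],
                            min_comparable = 100), 0)
  diff <- which(f != f[1])[1]
  expect_gt(ibs_distance(g[, same[1]], g[, diff], min_comparable = 100), 0.02)
})

test_that("error-only sites carry minor depth matching the error model", {
  cfg <- sim_config(n_taxa = 30, chrom_lengths = c(chr1 = 5e6),
                    n_true_sites = 0, n_error_only_sites = 1000,
                    coverage_mean = 6, seq_error_rate = 0.01,
                    het_residual_rate = 0, seed = 33)
  co <- simulate_cohort(cfg)
  d <- co$depths$chr1
  ref_idx <- d$ref
  nonref <- vapply(seq_along(d$positions), function(i) {
    sum(d$depth[i, , -ref_idx[i]])
  }, 0)
  # expected non-reference depth per site: n_taxa * coverage * error rate
  expected <- 30 * 6 * 0.01
  expect_equal(mean(nonref), expected, tolerance = 0.1)
  # per specific allele: a fifth of the error mass
  one_allele <- vapply(seq_along(d$positions), function(i) {
    a <- setdiff(1:6, ref_idx[i])[1]
    sum(d$depth[i, , a])
  }, 0)
  expect_equal(mean(one_allele), expected / 5, tolerance = 0.25)
})

test_that("planted MAFs follow the configured distribution", {
  cfg <- sim_config(n_taxa = 40, chrom_lengths = c(chr1 = 5e7),
                    n_true_sites = 5000,
                    maf_distribution = function(n) runif(n, 0.05, 0.5),
                    seed = 34)
  co <- simulate_cohort(cfg)
  maf <- co$truth$sites$maf[co$truth$sites$label == "true"]
  ks <- suppressWarnings(ks.test(maf, "punif", 0.05, 0.5))
  expect_gt(ks$p.value, 0.001)
})

test_that("paralog sites emit systematic heterozygosity in carrier taxa", {
  cfg <- sim_config(n_taxa = 30, n_founders = 3,
                    chrom_lengths = c(chr1 = 2e6), n_true_sites = 50,
                    n_paralog_sites = 50, coverage_mean = 10,
                    seq_error_rate = 0, paralog_freq = 0.5, seed = 35)
  co <- simulate_cohort(cfg)
  d <- co$depths$chr1
  par_rows <- which(co$truth$sites$label == "paralog")
  key <- match(co$truth$sites$pos[par_rows], d$positions)
  het_frac <- vapply(seq_along(par_rows), function(j) {
    dep <- matrix(d$depth[key[j], , ], ncol = 6)
    called <- apply(dep, 1, call_genotype)
    mean(geno_is_het(called), na.rm = TRUE)
  }, 0)
  # with carrier founder frequency 0.5, a large het fraction is systematic
  expect_gt(mean(het_frac), 0.2)
  # truth keeps the primary locus monomorphic reference
  expect_true(all(co$truth$geno[par_rows, ] ==
                    geno_code(co$truth$sites$ref[par_rows],
                              co$truth$sites$ref[par_rows])))
})

test_that("translocated sites copy a distant donor's carrier pattern", {
  cfg <- sim_config(n_taxa = 30, n_founders = 3,
                    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                    n_true_sites = 2000, n_translocated_sites = 20,
                    founder_block_bp = 1e6, seed = 36)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  idx <- which(tr$sites$label == "translocated")
  for (s in idx) {
    d <- tr$sites$donor[s]
    expect_false(is.na(d))
    # donors are distant: other chromosome or beyond three block lengths
    expect_true(tr$sites$chrom[d] != tr$sites$chrom[s] ||
                  abs(tr$sites$pos[d] - tr$sites$pos[s]) > 3e6)
    carrier_here <- geno_carries(tr$geno[s, ], tr$sites$alt[s])
    carrier_donor <- geno_carries(tr$geno[d, ], tr$sites$alt[d])
    expect_identical(carrier_here, carrier_donor)
  }
})

test_that("anchor sites are high-MAF true SNPs away from indels", {
  cfg <- sim_config(n_taxa = 25, chrom_lengths = c(chr1 = 5e6),
                    n_true_sites = 2000, n_error_only_sites = 100,
                    indel_fraction = 0.2, seed = 37)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  ai <- tr$anchor_idx
  expect_true(all(tr$sites$label[ai] == "true"))
  expect_true(all(tr$sites$alt[ai] <= 4))
  expect_true(all(tr$sites$realized_maf[ai] >= 0.05))
  indel_pos <- tr$sites$pos[!is.na(tr$sites$alt) & tr$sites$alt >= 5]
  for (p in tr$sites$pos[ai]) {
    expect_gt(min(abs(indel_pos - p)), 5)
  }
})
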