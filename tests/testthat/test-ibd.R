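test_that("IBS distance handles identity, thresholds and comparability", {
  aa <- geno_code(1, 1); cc <- geno_code(2, 2); ac <- geno_code(1, 2)
  g <- rep(aa, 300)
  expect_equal(ibs_distance(g, g), 0)
  expect_true(is.na(ibs_distance(rep(aa, 150), rep(aa, 150))))
  # 200 comparable, 4 fully discordant homozygote pairs -> 0.02
  gi <- rep(aa, 200); gj <- rep(aa, 200); gj[1:4] <- cc
  expect_equal(ibs_distance(gi, gj), 0.02)
  # het vs hom sharing one allele counts 0.5
  expect_equal(ibs_distance(rep(ac, 200), rep(aa, 200)), 0.5)
  expect_error(ibs_distance(rep(aa, 10), rep(aa, 9)), "length")
})

test_that("IBD pairs respect the 0.02 boundary exactly", {
  aa <- geno_code(1, 1); cc <- geno_code(2, 2)
  ns <- 500
  g1 <- rep(aa, ns)
  g2 <- g1; g2[1:10] <- cc        # distance 10/500 = 0.02
  g3 <- g1; g3[1:11] <- cc        # distance 0.022
  anchor <- anchor_map(
    data.frame(chrom = "chr1", pos = seq_len(ns) * 1000L,
               ref = 1L, alt = 2L),
    cbind(g1, g2, g3), c("a", "b", "c"))
  ibd <- find_ibd_pairs(anchor, window_sites = ns, threshold = 0.02,
                        min_comparable = 200)
  pr <- ibd$pairs[[1]]
  keys <- paste(pr$taxon_a, pr$taxon_b)
  expect_true("1 2" %in% keys)     # d = 0.02 included
  expect_false("1 3" %in% keys)    # d = 0.021.. excluded
})

test_that("windows partition anchor sites with remainder merged", {
  aa <- geno_code(1, 1)
  ns <- 4500
  anchor <- anchor_map(
    data.frame(chrom = "chr1", pos = seq_len(ns) * 100L, ref = 1L, alt = 2L),
    matrix(aa, ns, 2), c("a", "b"))
  ibd <- find_ibd_pairs(anchor, window_sites = 2000)
  expect_identical(nrow(ibd$windows), 2L)     # 2000 + 2500 (merged tail)
  expect_identical(ibd$windows$end_pos[2], 4500L * 100L)
  # positions outside the anchored span map to the nearest window
  expect_identical(ibd_window_of(ibd, "chr1", 1), 1L)
  expect_identical(ibd_window_of(ibd, "chr1", 1e9), 2L)
  expect_true(is.na(ibd_window_of(ibd, "chrX", 5)))
})

test_that("clone cohorts yield exactly the planted IBD pairs", {
  cfg <- sim_config(n_taxa = 12, n_founders = 3,
                    chrom_lengths = c(chr1 = 5e6), n_true_sites = 6000,
                    coverage_mean = 8, seq_error_rate = 0,
                    het_residual_rate = 0, founder_block_bp = 1e12,
                    founder_assignment = "balanced", anchor_density = 0.8,
                    seed = 14)
  co <- simulate_cohort(cfg)
  ibd <- find_ibd_pairs(co$anchor)
  tp <- truth_ibd_pairs(co)
  expect_identical(length(tp), nrow(ibd$windows))
  for (w in seq_along(tp)) {
    found <- paste(ibd$pairs[[w]]$taxon_a, ibd$pairs[[w]]$taxon_b)
    planted <- paste(tp[[w]][, 1], tp[[w]][, 2])
    expect_setequal(found, planted)
  }
})

test_that("IBD filter reproduces the canonical confirmation cases", {
  aa <- geno_code(1, 1); cc <- geno_code(2, 2); ac <- geno_code(1, 2)
  pairs10 <- data.frame(taxon_a = 1:10, taxon_b = 11:20, distance = 0)
  ibd <- make_ibd(pairs10)
  # 6 concordant major-hom pairs + 4 concordant minor-hom pairs: both
  # alleles at infinite ratio -> confirmed
  g <- c(rep(aa, 6), rep(cc, 4), rep(aa, 6), rep(cc, 4))
  expect_identical(ibd_filter(g, ibd, "chr1", 1000)$status, "confirmed")
  # minor allele 2 matches vs 2 mismatches (ratio 1): only the major
  # allele reaches ratio 2 -> fail
  g <- c(rep(aa, 6), rep(cc, 4), rep(aa, 8), rep(cc, 2))
  r <- ibd_filter(g, ibd, "chr1", 1000)
  expect_identical(unname(r$match[2]), 2L)
  expect_identical(unname(r$mismatch[2]), 2L)
  expect_identical(r$status, "fail")
  # minor allele only outside the IBD taxa -> weak pass, IBD1
  g <- c(rep(aa, 20), rep(cc, 3))
  ibd_small <- make_ibd(pairs10)
  expect_identical(ibd_filter(g, ibd_small, "chr1", 1000)$status, "ibd1")
  # a heterozygote carries both of its alleles
  g <- c(ac, rep(aa, 9), rep(aa, 10))
  r <- ibd_filter(g, make_ibd(pairs10), "chr1", 1000)
  expect_identical(unname(r$match[1]), 10L)
  expect_identical(unname(r$mismatch[2]), 1L)
})

test_that("IBD filter agrees with the brute-force oracle on random sites", {
  set.seed(44)
  nt <- 12
  for (i in 1:1000) {
    np <- sample(0:8, 1)
    pairs <- if (np == 0) {
      data.frame(taxon_a = integer(0), taxon_b = integer(0),
                 distance = numeric(0))
    } else {
      sel <- replicate(np, sample.int(nt, 2))
      data.frame(taxon_a = pmin(sel[1, ], sel[2, ]),
                 taxon_b = pmax(sel[1, ], sel[2, ]), distance = 0)
    }
    g <- sample(c(NA_integer_, geno_code(1, 1), geno_code(2, 2),
                  geno_code(1, 2), geno_code(3, 3), geno_code(2, 3)),
                nt, replace = TRUE)
    got <- ibd_filter(g, make_ibd(pairs), "chr1", 500)$status
    expect_identical(got, oracle_ibd_filter(g, pairs))
  }
})

test_that("noisy cohorts: error sites fail IBD, real variants survive", {
  cfg <- sim_config(n_taxa = 60, n_founders = 4,
                    chrom_lengths = c(chr1 = 1e7), n_true_sites = 1500,
                    n_error_only_sites = 150, coverage_mean = 4,
                    seq_error_rate = 0.005, het_residual_rate = 0.01,
                    founder_block_bp = 1e12,
                    founder_assignment = "balanced",
                    anchor_density = 0.8, seed = 15)
  co <- simulate_cohort(cfg)
  ibd <- find_ibd_pairs(co$anchor)
  key <- paste(co$truth$sites$chrom, co$truth$sites$pos)
  stat <- character(0); lab <- character(0); maf <- numeric(0)
  d <- co$depths$chr1
  for (i in seq_along(d$positions)) {
    st <- discover_site(matrix(d$depth[i, , ], ncol = 6),
                        HAP_ALLELES[d$ref[i]], chrom = d$chrom,
                        pos = d$positions[i])
    if (is.null(st)) next
    k <- match(paste("chr1", d$positions[i]), key)
    stat <- c(stat, ibd_filter(st$geno, ibd, st$chrom, st$pos)$status)
    lab <- c(lab, co$truth$sites$label[k])
    maf <- c(maf, co$truth$sites$realized_maf[k])
  }
  err <- stat[lab == "error_only"]
  tru <- stat[lab == "true" & maf >= 0.05]
  expect_gt(length(err), 50)
  expect_gte(mean(err == "fail"), 0.9)
  expect_gte(mean(tru %in% c("confirmed", "ibd1")), 0.95)
})
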