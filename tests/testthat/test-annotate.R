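test_that("inbreeding coefficient matches hand-evaluated cases", {
  aa <- geno_code(1, 1); ac <- geno_code(1, 2)
  # 4 sites, p = (0.5, 0.25, 0.1, 0.0), genotypes hom,hom,het,hom:
  # E = 0.5 + 0.625 + 0.82 + 1.0 = 2.945, O = 3, N = 4
  f <- inbreeding_coefficient(c(aa, aa, ac, aa), c(0.5, 0.25, 0.1, 0))
  expect_equal(f, (3 - 2.945) / (4 - 2.945), tolerance = 1e-12)
  # all homozygous: F = 1 regardless of E (E < N)
  expect_equal(inbreeding_coefficient(rep(aa, 5), rep(0.3, 5)), 1)
  # O = E gives F = 0
  f0 <- inbreeding_coefficient(c(aa, ac), c(0.5, 0.5))  # O=1, E=1, N=2
  expect_equal(f0, 0)
  expect_error(inbreeding_coefficient(rep(NA_integer_, 3), rep(0.1, 3)),
               "no genotyped sites")
})

test_that("inbreeding coefficients equal the brute-force oracle", {
  set.seed(81)
  for (i in 1:1000) {
    ns <- sample(3:12, 1); nt <- sample(2:6, 1)
    g <- matrix(sample(c(NA_integer_, geno_code(1, 1), geno_code(2, 2),
                         geno_code(1, 2)), ns * nt, replace = TRUE), ns, nt)
    if (any(colSums(!is.na(g)) == 0)) next
    maf <- apply(g, 1, function(row) {
      ok <- !is.na(row)
      if (!any(ok)) return(0)
      cnt <- c(sum(row[ok] == geno_code(1, 1)) * 2 +
                 sum(row[ok] == geno_code(1, 2)),
               sum(row[ok] == geno_code(2, 2)) * 2 +
                 sum(row[ok] == geno_code(1, 2)))
      min(cnt) / sum(cnt)
    })
    got <- inbreeding_coefficients(g)
    want <- vapply(seq_len(nt), function(t) oracle_inbreeding(g[, t], maf), 0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("F is near zero under Hardy-Weinberg and 1 under full inbreeding", {
  set.seed(82)
  ns <- 400; nt <- 150
  p <- runif(ns, 0.1, 0.5)
  g <- matrix(NA_integer_, ns, nt)
  for (s in seq_len(ns)) {
    n_minor <- rbinom(nt, 2, p[s])
    g[s, ] <- ifelse(n_minor == 2, geno_code(2, 2),
                     ifelse(n_minor == 1, geno_code(1, 2), geno_code(1, 1)))
  }
  f <- inbreeding_coefficients(g)
  expect_lt(abs(mean(f)), 3 * sd(f) / sqrt(nt))
  # fully homozygous limit
  g_hom <- matrix(ifelse(runif(ns * nt) < 0.3, geno_code(2, 2),
                         geno_code(1, 1)), ns, nt)
  expect_equal(unname(inbreeding_coefficients(g_hom)), rep(1, nt))
})

test_that("high-coverage subset and FH follow the strict >50% rule", {
  aa <- geno_code(1, 1); ac <- geno_code(1, 2)
  # 4 taxa x 10 sites on the designated chromosome; taxon 3 exactly 50%
  g <- matrix(aa, 10, 4)
  g[1:6, 2] <- NA       # 40% nonmissing -> out
  g[1:5, 3] <- NA       # exactly 50% -> out (strict)
  g[1, 4] <- NA         # 90% -> in
  sub <- highcov_taxa(g, rep("chr1", 10), "chr1")
  expect_identical(sub, c(1L, 4L))
  # FH: heterozygotes / nonmissing within the subset
  site <- c(ac, aa, ac, aa)
  expect_equal(fraction_het_highcov(site, sub), 0.5)
  expect_equal(fraction_het_highcov(c(aa, ac, ac, aa), sub), 0)
  expect_true(is.na(fraction_het_highcov(site, integer(0))))
})

test_that("site annotations compute the documented statistics and flags", {
  aa <- geno_code(1, 1); ab <- geno_code(1, 2); bb <- geno_code(2, 2)
  nt <- 100
  sites <- data.frame(chrom = "chr1", pos = c(1000L, 5000L, 5003L, 5010L),
                      ref = 1L, alt1 = c(2L, 2L, 5L, 2L), alt2 = NA_integer_)
  g <- rbind(c(rep(aa, 90), rep(bb, 10)),
             c(rep(aa, 90), rep(ab, 5), rep(bb, 5)),
             rep(aa, 100),
             rep(c(aa, bb), 50))
  g[3, 1:20] <- geno_code(1, 5)
  ann <- annotate_sites(sites, g, fh_chrom = "chr1")
  # GN = (90, 0, 10): HT 0, EF 0
  expect_identical(ann$GN[1], "90,0,10")
  expect_identical(ann$HT[1], 0L)
  expect_equal(ann$EF[1], 0)
  expect_equal(ann$MAF[1], 0.1)
  # het frequency 0.05, presence 1, MAF 0.075 -> EF = 0.05/0.075
  expect_equal(ann$EF[2], 0.05 / ((100 / nt) * ann$MAF[2]))
  # DUP iff het frequency > 3%
  expect_true(ann$DUP[2])
  expect_false(ann$DUP[1])
  # NI5: the indel site itself and the SNP 3 bp away, not the SNP 7 bp away
  expect_true(ann$NI5[3])
  expect_true(ann$NI5[2])      # 3 bp from the indel at 5003
  expect_false(ann$NI5[4])     # 7 bp away
  expect_false(ann$NI5[1])
  # consistency: NZ = sum(GN), HT = het classes in GN
  gn <- lapply(strsplit(ann$GN, ","), as.integer)
  expect_identical(ann$NZ, vapply(gn, sum, 0L))
  expect_identical(ann$HT, vapply(gn, function(x) x[2], 0L))
})

test_that("EF is missing, not zero, in degenerate cases", {
  aa <- geno_code(1, 1)
  sites <- data.frame(chrom = "chr1", pos = 1L, ref = 1L, alt1 = 2L,
                      alt2 = NA_integer_)
  ann <- annotate_sites(sites, matrix(rep(aa, 10), 1), fh_chrom = NULL)
  expect_true(is.na(ann$EF[1]))          # MAF = 0
})

test_that("multiallelic sites emit six genotype classes in VCF order", {
  g <- c(geno_code(1, 1), geno_code(1, 2), geno_code(1, 3), geno_code(2, 2),
         geno_code(2, 3), geno_code(3, 3), geno_code(1, 1))
  sites <- data.frame(chrom = "chr1", pos = 100L, ref = 1L, alt1 = 2L,
                      alt2 = 3L)
  ann <- annotate_sites(sites, matrix(g, 1), fh_chrom = NULL)
  expect_identical(ann$GN[1], "2,1,1,1,1,1")
  expect_identical(ann$HT[1], 3L)
})

test_that("VCF round-trips sites, genotypes and annotations", {
  set.seed(83)
  cfg <- sim_config(n_taxa = 15, n_founders = 3,
                    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                    n_true_sites = 100, coverage_mean = 8,
                    indel_fraction = 0.1, founder_assignment = "balanced",
                    seed = 29)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  keep <- which(tr$sites$realized_maf > 0)
  sites <- data.frame(chrom = tr$sites$chrom[keep], pos = tr$sites$pos[keep],
                      ref = tr$sites$ref[keep], alt1 = tr$sites$alt[keep],
                      alt2 = NA_integer_)
  g <- tr$geno[keep, , drop = FALSE]
  g[sample(length(g), 50)] <- NA_integer_
  ann <- annotate_sites(sites, g, pv = runif(length(keep)) * 1e-3,
                        fh_chrom = "chr1")
  path <- file.path(withr::local_tempdir(), "x.vcf")
  write_vcf(path, sites, g, ann, tr$taxa)
  v <- read_vcf(path)
  expect_identical(v$sites$chrom, sites$chrom)
  expect_identical(v$sites$pos, sites$pos)
  expect_identical(v$sites$ref, sites$ref)
  expect_identical(v$sites$alt1, sites$alt1)
  expect_identical(unname(v$geno), unname(g))
  expect_identical(v$taxa, tr$taxa)
  expect_identical(v$ann$HT, ann$HT)
  expect_identical(v$ann$NZ, ann$NZ)
  expect_equal(v$ann$MAF, ann$MAF, tolerance = 1e-3)
  expect_equal(v$ann$PV, ann$PV, tolerance = 1e-3)
  expect_identical(v$ann$GN, ann$GN)
  expect_identical(v$ann$NI5, ann$NI5)
  expect_identical(v$ann$FH2, ann$FH2)
  # writing the re-read data reproduces the file byte for byte
  path2 <- file.path(withr::local_tempdir(), "y.vcf")
  write_vcf(path2, v$sites, v$geno, ann, v$taxa)
  expect_identical(readLines(path2), readLines(path))
})

test_that("an empty site set produces a valid header-only VCF", {
  sites <- data.frame(chrom = character(0), pos = integer(0),
                      ref = integer(0), alt1 = integer(0), alt2 = integer(0))
  ann <- annotate_sites(sites, matrix(NA_integer_, 0, 3), fh_chrom = NULL)
  path <- file.path(withr::local_tempdir(), "empty.vcf")
  write_vcf(path, sites, matrix(NA_integer_, 0, 3), ann, c("a", "b", "c"))
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "#CHROM")))
  expect_identical(sum(!startsWith(lines, "#")), 0L)
})
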