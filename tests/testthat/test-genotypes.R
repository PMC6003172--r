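toy_geno <- function() {
  dos <- matrix(c(0, 1, 2, 1,
                  2, NA, 0, 1,
                  2, 2, 2, 2), nrow = 4,
                dimnames = list(paste0("a", 1:4), c("s1", "s2", "s3")))
  map <- tibble::tibble(snp_id = c("s1", "s2", "s3"), chr = 1L,
                        pos = c(100L, 200L, 300L))
  genotypes(dos, map)
}

test_that("genotype round trip through the CSV dialect is lossless", {
  g <- toy_geno()
  gf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, gf, mf)
  g2 <- read_genotypes(gf, mf, format = "csv")
  expect_equal(g2$dosage, g$dosage)
  expect_equal(g2$map, g$map)
})

test_that("out-of-order maps are re-sorted and bad symbols are named", {
  dos <- matrix(c(0, 1, 2, 0), 2, 2,
                dimnames = list(c("a1", "a2"), c("s1", "s2")))
  map <- tibble::tibble(snp_id = c("s1", "s2"), chr = 1L,
                        pos = c(500L, 100L))
  g <- genotypes(dos, map)
  expect_equal(g$map$snp_id, c("s2", "s1"))
  expect_equal(colnames(g$dosage), c("s2", "s1"))
  expect_true(attr(g, "reordered"))

  gf <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,s1,s2", "a1,0,1", "a2,7,2"), gf)
  readr::write_csv(map, mf)
  expect_error(read_genotypes(gf, mf, format = "csv"), "dosage symbol '7'")
})

test_that("allele frequencies ignore missing calls and flag empty SNPs", {
  g <- toy_geno()
  expect_equal(unname(allele_freq(g)), c(0.5, 0.5, 1.0))
  bad <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(allele_freq(bad), "no non-missing")
})

test_that("HWE chi-square matches the goodness-of-fit oracle", {
  perfect <- matrix(rep(c(0, 1, 1, 2), times = c(25, 25, 25, 25)), ncol = 1,
                    dimnames = list(NULL, "s"))
  expect_equal(unname(hwe_chi2(perfect)), 0)
  allhet <- matrix(rep(1, 100), ncol = 1, dimnames = list(NULL, "s"))
  expect_equal(unname(hwe_chi2(allhet)), 100)  # sum((obs-exp)^2/exp), exp (25,50,25)
  mono <- matrix(rep(2, 10), ncol = 1, dimnames = list(NULL, "s"))
  expect_equal(unname(hwe_chi2(mono)), 0)
})

test_that("QC removes exactly the independently recomputed sets, in order", {
  g <- qc_fixture()
  qc <- qc_genotypes(g, hwe_max = 8)
  oracle <- qc_oracle(g, hwe_max = 8)
  rep <- qc$report
  expect_identical(sort(attr(rep, "removed_snps")$snp_call_rate),
                   sort(oracle$snp_call_rate))
  expect_identical(sort(attr(rep, "removed_snps")$maf), sort(oracle$maf))
  expect_identical(sort(attr(rep, "removed_snps")$hwe), sort(oracle$hwe))
  expect_identical(sort(attr(rep, "removed_animals")), sort(oracle$animal))
  expect_identical(sort(colnames(qc$genotypes$dosage)),
                   sort(oracle$surviving_snps))
  expect_identical(sort(rownames(qc$genotypes$dosage)),
                   sort(oracle$surviving_animals))
  # removed + surviving = input, per filter
  inp <- attr(rep, "input")
  expect_equal(rep$removed + rep$surviving,
               c(inp["snps"], rep$surviving[1], rep$surviving[2],
                 inp["animals"]), ignore_attr = TRUE)
  # idempotence on this fixture
  qc2 <- qc_genotypes(qc$genotypes, hwe_max = 8)
  expect_equal(sum(qc2$report$removed), 0)
  # JSON serialisation round-trips the counts
  js <- jsonlite::fromJSON(qc_report_json(rep))
  expect_equal(js$filters$removed, rep$removed)
})

test_that("QC thresholds sit exactly at the published boundaries", {
  # chi2 = 24 kept, chi2 > 24 removed: build a 600-animal SNP with
  # continuously tunable het deficit
  make_snp <- function(n, nhet) {
    nhom <- (n - nhet) / 2
    matrix(rep(c(0, 1, 2), times = c(nhom, nhet, nhom)), ncol = 1,
           dimnames = list(NULL, "s"))
  }
  n <- 600
  chi_at <- function(nhet) unname(hwe_chi2(make_snp(n, nhet)))
  # find het counts bracketing the 24 boundary
  hets <- seq(180, 300, by = 2)
  chis <- vapply(hets, chi_at, numeric(1))
  keep <- hets[max(which(chis > 24))]     # largest deficit above 24
  expect_gt(chi_at(keep), 24)
  ok <- hets[min(which(chis <= 24))]
  expect_lte(chi_at(ok), 24)

  base <- matrix(rep(c(0, 1, 2), times = c(150, 300, 150)), ncol = 1)
  dos <- cbind(make_snp(n, keep), make_snp(n, ok), base)
  colnames(dos) <- c("fail", "kept", "filler")
  rownames(dos) <- paste0("a", seq_len(n))
  map <- tibble::tibble(snp_id = colnames(dos), chr = 1L, pos = 1:3 * 100L)
  qc <- qc_genotypes(genotypes(dos, map))
  expect_identical(attr(qc$report, "removed_snps")$hwe, "fail")

  # MAF 0.005 removed, 0.05 kept (paper threshold 1%)
  dos2 <- cbind(c(rep(0, 995), rep(1, 10), rep(0, 0)),
                c(rep(0, 905), rep(1, 100)))[1:1000, ]
  dos2 <- cbind(dos2, rep(c(0, 1, 2), length.out = 1000))
  colnames(dos2) <- c("rare", "common", "filler")
  rownames(dos2) <- paste0("b", 1:1000)
  map2 <- tibble::tibble(snp_id = colnames(dos2), chr = 1L,
                         pos = 1:3 * 100L)
  qc2 <- qc_genotypes(genotypes(dos2, map2), hwe_max = Inf)
  expect_identical(attr(qc2$report, "removed_snps")$maf, "rare")
})

test_that("per-group QC requires a SNP to pass in every group", {
  set.seed(4)
  dos <- matrix(rbinom(40 * 6, 2, 0.5), 40, 6,
                dimnames = list(paste0("a", 1:40), paste0("s", 1:6)))
  dos[1:20, 1] <- 0  # monomorphic in group 1 only
  map <- tibble::tibble(snp_id = paste0("s", 1:6), chr = 1L,
                        pos = 1:6 * 100L)
  grp <- rep(c("g1", "g2"), each = 20)
  qc <- qc_genotypes(genotypes(dos, map), group = grp, hwe_max = Inf)
  expect_true("s1" %in% attr(qc$report, "removed_snps")$maf)
})

test_that("centering imputes missing to the column mean exactly", {
  g <- toy_geno()
  p <- allele_freq(g)
  M <- center_genotypes(g, p)
  expect_equal(M["a3", "s1"], 2 - 2 * 0.5)
  expect_equal(M["a2", "s2"], 0)  # missing -> 2p -> 0 after centering
  full <- matrix(c(0, 1, 2, 1), 4, 1, dimnames = list(paste0("x", 1:4), "s"))
  expect_lt(max(abs(colMeans(center_genotypes(full)))), 1e-12)
})

test_that("G construction follows the blended weighted formula", {
  M <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
  p <- 0.5
  G1 <- build_g(M, p, blend = 1)
  expect_equal(unname(G1), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)
  a22 <- diag(2); dimnames(a22) <- list(c("a", "b"), c("a", "b"))
  G2 <- build_g(M, p, a22 = a22, blend = 0.95)
  expect_equal(unname(diag(G2)), c(1.95, 1.95))
  # unit weights reproduce the unweighted G bit for bit
  set.seed(2)
  Mm <- matrix(rnorm(50), 10, 5,
               dimnames = list(paste0("a", 1:10), paste0("s", 1:5)))
  pp <- runif(5, 0.2, 0.8)
  aa <- diag(10); dimnames(aa) <- list(rownames(Mm), rownames(Mm))
  expect_identical(unclass(build_g(Mm, pp, aa))[, ],
                   unclass(build_g(Mm, pp, aa, weights = rep(1, 5)))[, ])
  expect_error(build_g(Mm, rep(0, 5), aa), "monomorphic")
})

test_that("blending bounds the smallest eigenvalue of G away from zero", {
  sim <- small_sim(seed = 21)
  ids <- rownames(sim$data$geno$dosage)
  a22 <- a_submatrix(sim$data$ped, ids)
  p <- allele_freq(sim$data$geno)
  M <- center_genotypes(sim$data$geno, p)
  for (blend in c(0.5, 0.95)) {
    G <- build_g(M, p, a22 = a22, blend = blend)
    lmin_g <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    lmin_a <- min(eigen(a22, symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(lmin_g, (1 - blend) * lmin_a - 1e-10)
    expect_gt(lmin_g, 0)
  }
})

test_that("gene-SNP association chi-square matches contingency oracles", {
  # SNP perfectly determined by a 3-genotype gene class, n = 30 balanced
  cls <- rep(c("AA", "AE", "EE"), each = 10)
  dos <- matrix(rep(c(0, 1, 2), each = 10), ncol = 1,
                dimnames = list(paste0("a", 1:30), "s1"))
  gene <- tibble::tibble(animal = paste0("a", 1:30),
                         allele1 = substr(cls, 1, 1),
                         allele2 = substr(cls, 2, 2))
  map <- tibble::tibble(snp_id = "s1", chr = 1L, pos = 100L)
  out <- gene_snp_chi2(gene, genotypes(dos, map))
  expect_equal(out$chi2, 60)  # n * (min(r,c) - 1) for a perfect diagonal

  # exactly proportional counts -> independence -> 0
  dos2 <- matrix(rep(rep(c(0, 1), each = 5), 3), ncol = 1,
                 dimnames = list(paste0("a", 1:30), "s1"))
  out2 <- gene_snp_chi2(gene, genotypes(dos2, map))
  expect_equal(out2$chi2, 0)

  # missing SNP calls are excluded from the table
  dos3 <- dos
  dos3[1, 1] <- NA
  out3 <- gene_snp_chi2(gene, genotypes(dos3, map))
  tab <- table(cls[-1], dos[-1, 1])
  expect_equal(out3$chi2,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)))

  # degenerate margins are NA
  dos4 <- matrix(rep(2, 30), ncol = 1,
                 dimnames = list(paste0("a", 1:30), "s1"))
  expect_true(is.na(gene_snp_chi2(gene, genotypes(dos4, map))$chi2))
})

test_that("allele frequencies are invariant to animal permutation", {
  sim <- small_sim(seed = 22)
  g <- sim$data$geno
  perm <- sample(nrow(g$dosage))
  g2 <- genotypes(g$dosage[perm, ], g$map)
  expect_equal(allele_freq(g), allele_freq(g2))
})
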