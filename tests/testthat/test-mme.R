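test_that("design matrices carry the set-to-zero constraint and incidences", {
  ped <- as_pedigree(tibble::tibble(animal = c("a", "b"),
                                    sire = NA_character_,
                                    dam = NA_character_))
  ph <- tibble::tibble(animal = c("a", "a", "a", "b"),
                       herd = c("h1", "h1", "h2", "h2"),
                       y = c(1, 2, 3, 4))
  spec <- model_spec("y", fixed = "herd")
  d <- build_design(ph, spec, ped)
  # intercept + one retained level for a 2-level factor
  expect_equal(ncol(d$X), 2)
  expect_equal(d$constrained$level, "h1")
  expect_equal(Matrix::colSums(d$W)[["a"]], 3)
  expect_true(all(Matrix::rowSums(d$Z) == 1))
  expect_error(build_design(tibble::tibble(animal = "zz", herd = "h", y = 1),
                            spec, ped), "absent from pedigree")
})

test_that("single-record shrinkage follows the closed-form 2x2 equations", {
  ped <- as_pedigree(tibble::tibble(animal = "a", sire = NA_character_,
                                    dam = NA_character_))
  y <- 3.7
  ph <- tibble::tibble(animal = "a", y = y)
  spec <- model_spec("y", fixed = character(0), permanent_env = FALSE)
  vc <- variance_components(h2 = 0.4, repeatability = 0.4 + 1e-9,
                            phenotypic_var = 2)
  fit <- solve_mme(build_design(ph, spec, ped), a_inverse(ped), vc)
  lam <- vc$s2_e / vc$s2_u
  # [1 1; 1 1+lam] [mu; u] = [y; y]  =>  u = 0, mu = y is NOT the solution
  # because the system is singular-free: solve directly as the oracle
  C <- matrix(c(1, 1, 1, 1 + lam), 2)
  sol <- solve(C, c(y, y))
  expect_equal(fit$beta$estimate[1], sol[1], tolerance = 1e-10)
  expect_equal(fit$u$gebv, sol[2], tolerance = 1e-10)
})

test_that("normal-equation residuals meet the convergence definition", {
  sim <- small_sim(seed = 31)
  fit <- run_evaluation(sim$data, default_spec(), default_vc(),
                        mode = "pblup")
  expect_lt(fit$diagnostics$residual_norm, 1e-10)
})

test_that("direct and PCG solvers agree", {
  ped <- random_pedigree(50, seed = 9)
  set.seed(9)
  recorded <- sample(ped$animal, 30)
  ph <- tibble::tibble(animal = rep(recorded, each = 2),
                       herd = sample(c("h1", "h2", "h3"), 60, replace = TRUE),
                       y = rnorm(60, 10))
  spec <- model_spec("y", fixed = "herd")
  vc <- variance_components(phenotypic_var = 4)
  d <- build_design(ph, spec, ped)
  ainv <- a_inverse(ped)
  f1 <- solve_mme(d, ainv, vc, method = "direct")
  f2 <- solve_mme(d, ainv, vc, method = "pcg", tol = 1e-12)
  expect_lt(max(abs(f1$u$gebv - f2$u$gebv)), 1e-8)
  expect_lt(max(abs(f1$beta$estimate - f2$beta$estimate)), 1e-8)
  expect_gt(f2$diagnostics$iterations, 0)
})

test_that("adding a constant to y moves only the intercept", {
  sim <- small_sim(seed = 32)
  spec <- default_spec(); vc <- default_vc()
  d1 <- build_design(sim$data$phenotypes, spec, sim$data$ped)
  f1 <- solve_mme(d1, a_inverse(sim$data$ped), vc)
  ph2 <- dplyr::mutate(sim$data$phenotypes, protein = protein + 5)
  d2 <- build_design(ph2, spec, sim$data$ped)
  f2 <- solve_mme(d2, a_inverse(sim$data$ped), vc)
  expect_lt(max(abs(f1$u$gebv - f2$u$gebv)), 1e-7)
  ic <- which(f1$beta$term == "(Intercept)")
  expect_equal(f2$beta$estimate[ic] - f1$beta$estimate[ic], 5,
               tolerance = 1e-7)
})

test_that("H-inverse reduces to A-inverse and G-inverse in the limits", {
  sim <- small_sim(seed = 33)
  ped <- sim$data$ped
  ids <- rownames(sim$data$geno$dosage)
  a22 <- a_submatrix(ped, ids)
  ainv <- a_inverse(ped)
  h1 <- build_h_inverse(ainv, a22, a22)  # G = A22
  expect_lt(max(abs(h1 - ainv)), 1e-8)

  # all animals genotyped: H^-1 = G^-1
  Afull <- a_submatrix(ped, ped$animal)
  p <- allele_freq(sim$geno_all)
  M <- center_genotypes(sim$geno_all, p)
  G <- build_g(M, p, a22 = Afull, blend = 0.95)
  h2 <- build_h_inverse(ainv, Afull, G)
  expect_lt(max(abs(as.matrix(h2) - solve(G))), 1e-6)
})

test_that("inverse of H-inverse equals the four-block H formula", {
  sim <- small_sim(seed = 34, years = 3, n_founder_males = 5,
                   n_founder_females = 12, n_dams = 8)
  ped <- sim$data$ped
  ids <- rownames(sim$data$geno$dosage)
  a22 <- a_submatrix(ped, ids)
  p <- allele_freq(sim$data$geno)
  M <- center_genotypes(sim$data$geno, p)
  G <- build_g(M, p, a22 = a22, blend = 0.95)
  hinv <- build_h_inverse(a_inverse(ped), a22, G)
  H_impl <- solve(as.matrix(hinv))
  A <- pairwise_a(ped)
  gi <- match(ids, ped$animal)
  ui <- setdiff(seq_len(nrow(ped)), gi)
  A22i <- solve(A[gi, gi])
  H <- matrix(0, nrow(ped), nrow(ped))
  H[ui, ui] <- A[ui, ui] +
    A[ui, gi] %*% A22i %*% (G - A[gi, gi]) %*% A22i %*% A[gi, ui]
  H[ui, gi] <- A[ui, gi] %*% A22i %*% G
  H[gi, ui] <- t(H[ui, gi])
  H[gi, gi] <- G
  expect_lt(max(abs(H - H_impl)), 1e-8)
})

test_that("singular G is rejected with advice to blend", {
  sim <- small_sim(seed = 35)
  ids <- rownames(sim$data$geno$dosage)
  a22 <- a_submatrix(sim$data$ped, ids)
  p <- allele_freq(sim$data$geno)
  M <- center_genotypes(sim$data$geno, p)
  # rank-1 unblended G is exactly singular
  G <- tcrossprod(M[, 1, drop = FALSE])
  dimnames(G) <- list(ids, ids)
  expect_error(build_h_inverse(a_inverse(sim$data$ped), a22, G),
               "blend")
})

test_that("ssGBLUP reductions: G = A22 and no genotypes give pedigree BLUP", {
  sim <- small_sim(seed = 36)
  spec <- default_spec(); vc <- default_vc()
  fp <- run_evaluation(sim$data, spec, vc, mode = "pblup")
  ids <- rownames(sim$data$geno$dosage)
  a22 <- a_submatrix(sim$data$ped, ids)
  fs <- run_evaluation(sim$data, spec, vc, mode = "ssgblup", G = a22)
  expect_lt(max(abs(fp$u$gebv - fs$u$gebv)), 1e-8)

  nogeno <- ss_data(sim$data$ped, sim$data$phenotypes)
  f0 <- run_evaluation(nogeno, spec, vc, mode = "ssgblup")
  expect_equal(f0$u$gebv, fp$u$gebv, tolerance = 1e-12)
})

test_that("all-genotyped ssGBLUP matches a dense GBLUP oracle", {
  sim <- small_sim(seed = 37, years = 3, n_founder_males = 5,
                   n_founder_females = 12, n_dams = 8)
  ped <- sim$data$ped
  Afull <- a_submatrix(ped, ped$animal)
  p <- allele_freq(sim$geno_all)
  M <- center_genotypes(sim$geno_all, p)
  G <- build_g(M, p, a22 = Afull, blend = 0.95)
  spec <- model_spec("protein", fixed = "herd_year")
  vc <- default_vc()
  data_all <- ss_data(ped, sim$data$phenotypes, geno = sim$geno_all)
  fit <- run_evaluation(data_all, spec, vc, mode = "ssgblup", G = G)

  ph <- sim$data$phenotypes
  hy <- factor(ph$herd_year)
  X <- cbind(1, stats::model.matrix(~hy)[, -1, drop = FALSE])
  oracle <- dense_animal_model(ph$protein, match(ph$animal, ped$animal),
                               nrow(ped), G, vc, X = X)
  expect_lt(max(abs(fit$u$gebv - oracle$u)), 1e-7)
})

test_that("parent GEBV tracks progeny means as daughters accumulate", {
  # a sire with many phenotyped daughters converges toward the
  # progeny-mean expectation: check the correlation between sire GEBV and
  # daughter-mean adjusted phenotype is high for well-recorded sires
  sim <- small_sim(seed = 38)
  fit <- run_evaluation(sim$data, default_spec(), default_vc(),
                        mode = "pblup")
  ped <- sim$data$ped
  ph <- sim$data$phenotypes
  u <- setNames(fit$u$gebv, fit$u$animal)
  kids <- ped[!is.na(ped$sire) & ped$animal %in% ph$animal, ]
  # fixed-effect-adjusted daughter means
  adj <- fit$y - fit$fitted_fixed
  dmean <- tapply(adj, fit$record_animal, mean)
  prog <- tapply(dmean[kids$animal], kids$sire, mean)
  prog <- prog[!is.na(prog)]
  nprog <- table(kids$sire)[names(prog)]
  well <- names(prog)[nprog >= 8]
  expect_gt(cor(u[well], prog[well]), 0.5)
})
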