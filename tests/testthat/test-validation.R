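make_val_fixture <- function() {
  # 2 validation sires with daughters, 1 training sire, explicit records
  ped <- as_pedigree(tibble::tibble(
    animal = c("old", "v1", "v2", "damA", "damB", "g1", "g2", "g3"),
    sire = c(NA, NA, NA, NA, NA, "v1", "v1", "v2"),
    dam = c(NA, NA, NA, NA, NA, "damA", "damB", "damA"),
    birth_year = c(1995L, 2008L, 2009L, 2000L, 2000L, 2010L, 2010L, 2011L),
    sex = c("M", "M", "M", "F", "F", "F", "F", "F"),
    breed = "B"))
  dos <- matrix(rep(c(0, 1, 2), 3), 3, 3, byrow = TRUE,
                dimnames = list(c("old", "v1", "v2"), paste0("s", 1:3)))
  geno <- genotypes(dos, tibble::tibble(snp_id = paste0("s", 1:3), chr = 1L,
                                        pos = 1:3 * 100L))
  ph <- tibble::tibble(
    animal = c("damA", "damB", "g1", "g1", "g2", "g3"),
    herd = "h1",
    y = c(30, 31, 29, 30, 33, 28))
  list(data = ss_data(ped, ph, geno = geno))
}

test_that("validation split reserves daughters of validation sires", {
  fx <- make_val_fixture()
  vs <- split_validation(fx$data, c(1993, 2007), c(2008, 2012))
  expect_setequal(vs$sires$sire, c("v1", "v2"))
  # all records of daughters removed from training, including multi-record g1
  expect_false(any(vs$train_phenotypes$animal %in% c("g1", "g2", "g3")))
  expect_true(all(c("damA", "damB") %in% vs$train_phenotypes$animal))
  # boundary year is inclusive: sire born 2008 is a validation candidate
  expect_true("v1" %in% vs$sires$sire)
  # ungenotyped sires are not candidates
  ped2 <- fx$data$ped
  geno2 <- genotypes(fx$data$geno$dosage["old", , drop = FALSE],
                     fx$data$geno$map)
  d2 <- ss_data(ped2, fx$data$phenotypes, geno = geno2)
  expect_error(split_validation(d2, c(1993, 2007), c(2008, 2012)),
               "no validation sires")
  expect_error(split_validation(fx$data, c(1993, 2008), c(2008, 2012)),
               "overlap")
})

test_that("DYD follows the weighted corrected-daughter formula", {
  # hand-built fit: zero fixed effects, zero pe, chosen dam solutions
  fit <- structure(list(
    beta = tibble::tibble(term = character(0), level = character(0),
                          estimate = numeric(0), constrained = logical(0)),
    u = tibble::tibble(animal = c("s1", "d1", "d2", "k1", "k2"),
                       gebv = c(0, 0, 0.5, 0, 0)),
    pe = tibble::tibble(animal = character(0), pe = numeric(0)),
    fitted_fixed = rep(0, 4),
    record_animal = c("k1", "k2", "k2", "k2"),
    y = c(1.0, 3.0, 3.0, 3.0),
    diagnostics = list(), vc = NULL), class = "ss_fit")
  design <- structure(list(
    daughters = tibble::tibble(animal = c("k1", "k2"),
                               sire = c("s1", "s1"),
                               dam = c(NA_character_, NA_character_))),
    class = "ss_validation")
  dyd <- compute_dyd(fit, design)
  # YD k1 = 1 (1 record), YD k2 = 3 (3 records); DYD = 2*(1*1+3*3)/4 = 5
  expect_equal(dyd$dyd, 5.0)
  expect_equal(dyd$edc, 4)

  # one daughter, YD = 1, dam at 0 -> DYD = 2
  fit1 <- fit
  fit1$record_animal <- "k1"; fit1$y <- 1.0; fit1$fitted_fixed <- 0
  design1 <- structure(list(daughters = tibble::tibble(
    animal = "k1", sire = "s1", dam = NA_character_)),
    class = "ss_validation")
  expect_equal(compute_dyd(fit1, design1)$dyd, 2.0)

  # known dam merit is subtracted
  design2 <- structure(list(daughters = tibble::tibble(
    animal = c("k1", "k2"), sire = c("s1", "s1"), dam = c("d2", NA))),
    class = "ss_validation")
  dyd2 <- compute_dyd(fit, design2)
  expect_equal(dyd2$dyd, (1 * (2 * 1 - 0.5) + 3 * (2 * 3)) / 4)
})

test_that("accuracy is the Pearson correlation with affine invariance", {
  g <- tibble::tibble(animal = paste0("s", 1:5),
                      gebv = c(1, 2, 3, 4, 5))
  dyd <- tibble::tibble(sire = paste0("s", 1:5),
                        dyd = c(2.1, 2.9, 4.2, 3.8, 5.5))
  r_hand <- cor(g$gebv, dyd$dyd)
  expect_equal(prediction_accuracy(g, dyd), r_hand)
  expect_equal(prediction_accuracy(
    dplyr::mutate(g, gebv = 3 * gebv + 7), dyd), r_hand)
  expect_equal(prediction_accuracy(
    dplyr::mutate(g, gebv = dyd$dyd), dyd), 1)
  expect_equal(prediction_accuracy(
    dplyr::mutate(g, gebv = -dyd$dyd), dyd), -1)
  expect_error(prediction_accuracy(g[1:2, ], dyd), "at least 3")
  expect_error(prediction_accuracy(
    dplyr::mutate(g, gebv = 1), dyd), "zero variance")
})

test_that("Williams' t matches an independently coded closed form", {
  expect_equal(hotelling_williams(0.7, 0.7, 0.5, 50)$statistic, 0)
  expect_equal(hotelling_williams(0.7, 0.7, 0.5, 50)$p.value, 1)
  r12 <- 0.8; r13 <- 0.7; r23 <- 0.9; n <- 100
  got <- hotelling_williams(r12, r13, r23, n)
  # independent evaluation, coded from the published formula layout
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  detR <- det(R)
  rb <- mean(c(r12, r13))
  t_oracle <- (r12 - r13) * sqrt(((n - 1) * (1 + r23)) /
    (2 * detR * (n - 1) / (n - 3) + rb^2 * (1 - r23)^3))
  expect_equal(got$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(got$p.value, 2 * pt(-abs(t_oracle), n - 3))
  expect_equal(got$parameter, n - 3)
  expect_error(hotelling_williams(1, 0.5, 0.5, 10), "inside")
  expect_error(hotelling_williams(0.5, 0.5, 0.5, 3))
})

test_that("DYD without dam information reduces to twice the weighted mean", {
  sim <- small_sim(seed = 71)
  # forget all dams so their merit cannot enter
  ped_nodam <- dplyr::mutate(sim$data$ped, dam = NA_character_)
  data2 <- ss_data(as_pedigree(ped_nodam), sim$data$phenotypes,
                   geno = sim$data$geno)
  fit <- run_evaluation(data2, default_spec(), default_vc(), mode = "pblup")
  vs <- split_validation(data2, c(0, 3), c(4, 6))
  dyd <- compute_dyd(fit, vs)
  # recompute by hand from the fit components
  rec_an <- fit$record_animal
  yd <- fit$y - fit$fitted_fixed -
    ifelse(rec_an %in% fit$pe$animal,
           setNames(fit$pe$pe, fit$pe$animal)[rec_an], 0)
  for (i in seq_len(min(3, nrow(dyd)))) {
    dd <- vs$daughters$animal[vs$daughters$sire == dyd$sire[i]]
    rows <- rec_an %in% dd
    ydm <- tapply(yd[rows], rec_an[rows], mean)
    w <- table(rec_an[rows])[names(ydm)]
    expect_equal(dyd$dyd[i], sum(w * 2 * ydm) / sum(w), tolerance = 1e-10)
  }
})

test_that("DYD outperforms parent average for well-recorded sires", {
  # pooled over replicates: sires with >= 20 recorded daughters
  pool <- NULL
  for (s in 101:106) {
    sim <- small_sim(seed = s, years = 8, n_sires = 2, n_dams = 60)
    fit <- run_evaluation(sim$data, default_spec(), default_vc(),
                          mode = "pblup")
    vs <- split_validation(sim$data, c(0, 4), c(5, 8))
    dyd <- compute_dyd(fit, vs)
    dyd <- dyd[dyd$n_daughters >= 20, ]
    truth <- setNames(sim$truth$u, sim$truth$animal)
    ped <- sim$data$ped
    pa <- vapply(dyd$sire, function(x) {
      i <- match(x, ped$animal)
      mean(c(truth[ped$sire[i]], truth[ped$dam[i]]), na.rm = TRUE)
    }, numeric(1))
    pa[is.na(pa)] <- 0
    pool <- rbind(pool, cbind(dyd$dyd, pa, truth[dyd$sire]))
  }
  expect_gt(nrow(pool), 20)
  expect_gt(cor(pool[, 1], pool[, 3]), cor(pool[, 2], pool[, 3]))
})
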