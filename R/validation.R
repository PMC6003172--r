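#' Split data into training records and a validation design
#'
#' Mirrors the sire-validation protocol of national dairy evaluations:
#' genotyped sires born in the training year range form the reference
#' population; genotyped sires born in the validation range are the
#' candidates, and all records of their daughters are removed from the
#' training data (a daughter with records in both periods loses all of
#' them). Year ranges are inclusive on both ends.
#'
#' @param data An [ss_data()] bundle (pedigree needs `birth_year` and `sex`).
#' @param train_years Length-2 inclusive birth-year range for training sires.
#' @param valid_years Length-2 inclusive birth-year range for validation
#'   sires (disjoint from `train_years`).
#' @return A list of class `ss_validation`: `train_phenotypes`, `sires`
#'   (tibble of validation sires with daughter counts), `daughters` (tibble
#'   sire/daughter pairs), and the year ranges.
#' @export
split_validation <- function(data, train_years, valid_years) {
  stopifnot(inherits(data, "ss_data"), length(train_years) == 2,
            length(valid_years) == 2)
  if (max(train_years) >= min(valid_years) &&
      max(valid_years) >= min(train_years)) {
    stop("training and validation year ranges overlap")
  }
  ped <- data$ped
  if (is.null(data$geno)) stop("validation candidates must be genotyped")
  genotyped <- rownames(data$geno$dosage)
  cand <- ped$animal[!is.na(ped$birth_year) &
                       ped$birth_year >= valid_years[1] &
                       ped$birth_year <= valid_years[2] &
                       ped$animal %in% genotyped &
                       (is.na(ped$sex) | ped$sex == "M")]
  ph <- data$phenotypes
  an_col <- ph$animal
  recorded <- unique(as.character(an_col))
  dtr <- ped[!is.na(ped$sire) & ped$sire %in% cand &
               ped$animal %in% recorded, c("animal", "sire", "dam")]
  sires <- dplyr::count(dtr, .data$sire, name = "n_daughters")
  cand <- sires$sire
  if (length(cand) == 0) {
    stop("no validation sires with phenotyped daughters in ",
         valid_years[1], "-", valid_years[2])
  }
  train <- ph[!(as.character(an_col) %in% dtr$animal), , drop = FALSE]
  structure(list(train_phenotypes = train,
                 sires = sires,
                 daughters = tibble::as_tibble(dtr),
                 train_years = train_years, valid_years = valid_years),
            class = "ss_validation")
}

#' Daughter yield deviations for validation sires
#'
#' For each daughter d of a validation sire, the yield deviation is the mean
#' over her records of (y - fitted fixed effects - her permanent-environment
#' solution); the sire's DYD is the weighted mean of (2 * YD_d - u_dam(d))
#' with effective daughter contributions (EDC) as weights. EDC is taken as
#' the daughter's record count; an unknown dam contributes u = 0. The fixed
#' and dam solutions come from a full-data pedigree-BLUP fit, matching the
#' convention that DYD derive from the official (pedigree-based) evaluation.
#'
#' @param fit_full An `ss_fit` from the full-data pedigree-BLUP run.
#' @param design An `ss_validation` from [split_validation()].
#' @param edc Optional named vector of user-supplied EDC per daughter id,
#'   overriding record counts.
#' @return A tibble of class `ss_dyd`: `sire`, `dyd`, `edc` (summed),
#'   `n_daughters`.
#' @export
compute_dyd <- function(fit_full, design, edc = NULL) {
  stopifnot(inherits(fit_full, "ss_fit"), inherits(design, "ss_validation"))
  rec_an <- fit_full$record_animal
  yd_rec <- fit_full$y - fit_full$fitted_fixed
  pe <- stats::setNames(fit_full$pe$pe, fit_full$pe$animal)
  if (length(pe) > 0) {
    yd_rec <- yd_rec - ifelse(rec_an %in% names(pe), pe[rec_an], 0)
  }
  uhat <- stats::setNames(fit_full$u$gebv, fit_full$u$animal)

  out <- purrr::map_dfr(split(design$daughters, design$daughters$sire),
                        function(dd) {
    rows <- rec_an %in% dd$animal
    if (!any(rows)) return(NULL)
    yd <- tapply(yd_rec[rows], rec_an[rows], mean)
    daughters <- names(yd)
    w <- if (is.null(edc)) {
      as.numeric(table(rec_an[rows])[daughters])
    } else {
      as.numeric(edc[daughters])
    }
    dam <- dd$dam[match(daughters, dd$animal)]
    udam <- ifelse(is.na(dam), 0, unname(uhat[dam]))
    udam[is.na(udam)] <- 0
    tibble::tibble(sire = dd$sire[1],
                   dyd = sum(w * (2 * yd - udam)) / sum(w),
                   edc = sum(w), n_daughters = length(daughters))
  })
  class(out) <- c("ss_dyd", class(out))
  out
}

#' Validation accuracy: Pearson correlation of GEBV with DYD
#'
#' @param gebv Tibble with columns `animal` and `gebv` (e.g. `fit$u`), or a
#'   named numeric vector.
#' @param dyd An `ss_dyd` tibble (or tibble with `sire` and `dyd`).
#' @return The sample Pearson correlation over the intersecting sires.
#' @export
prediction_accuracy <- function(gebv, dyd) {
  g <- if (is.data.frame(gebv)) stats::setNames(gebv$gebv, gebv$animal)
       else gebv
  common <- intersect(names(g), dyd$sire)
  if (length(common) < 3) stop("need at least 3 overlapping sires")
  x <- g[common]
  y <- dyd$dyd[match(common, dyd$sire)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in GEBV or DYD; correlation undefined")
  }
  stats::cor(x, y)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Williams' t test of H0: rho12 = rho13 for correlations sharing the
#' variable 1 (here: two methods' GEBV correlated with the same DYD), given
#' the correlation r23 between the two competing vectors. Uses the standard
#' determinant form with n - 3 degrees of freedom.
#'
#' @param r12,r13 The two dependent correlations being compared.
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (>= 4).
#' @return A tibble with `estimate` (r12 - r13), `statistic`, `p.value`,
#'   `parameter` (df).
#' @export
hotelling_williams <- function(r12, r13, r23, n) {
  stopifnot(n >= 4)
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)")
  }
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3
  tstat <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  tibble::tibble(estimate = r12 - r13, statistic = tstat, p.value = p,
                 parameter = n - 3)
}
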