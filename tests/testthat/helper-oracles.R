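# Independent oracles, deliberately written differently from the package:
# pairwise-recursive A, dense mixed-model solves, tiny fixture builders.

# additive relationship by the pairwise recursion a(i,j), memoised
pairwise_a <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  memo <- matrix(NA_real_, n, n)
  a <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == j) {
      1 + 0.5 * a(ifelse(is.na(si[i]), 0, si[i]),
                  ifelse(is.na(di[i]), 0, di[i]))
    } else if (i < j) {
      0.5 * (a(i, ifelse(is.na(si[j]), 0, si[j])) +
               a(i, ifelse(is.na(di[j]), 0, di[j])))
    } else {
      a(j, i)
    }
    memo[i, j] <<- v
    memo[j, i] <<- v
    v
  }
  out <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) out[i, j] <- out[j, i] <- a(i, j)
  out
}

# random valid pedigree: founders then offspring with parents drawn from
# earlier animals of the right sex
random_pedigree <- function(n, n_founders = 8, seed = 1) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  animal <- sprintf("x%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    if (length(males) > 0 && stats::runif(1) < 0.9) {
      sire[i] <- animal[sample(males, 1)]
    }
    if (length(females) > 0 && stats::runif(1) < 0.9) {
      dam[i] <- animal[sample(females, 1)]
    }
  }
  as_pedigree(tibble::tibble(animal = animal, sire = sire, dam = dam,
                             birth_year = seq_len(n), sex = sex,
                             breed = "B"))
}

# dense mixed-model oracle: solves the animal-model equations built from
# scratch with base linear algebra and an explicit relationship matrix K
dense_animal_model <- function(y, animal_idx, n_animals, K, vc,
                               X = matrix(1, length(y), 1), pe = TRUE) {
  nrec <- length(y)
  Z <- matrix(0, nrec, n_animals)
  Z[cbind(seq_len(nrec), animal_idx)] <- 1
  lam_u <- vc$s2_e / vc$s2_u
  blocks <- list(X, Z)
  if (pe) {
    ids <- sort(unique(animal_idx))
    W <- matrix(0, nrec, length(ids))
    W[cbind(seq_len(nrec), match(animal_idx, ids))] <- 1
    blocks <- c(blocks, list(W))
  }
  Tm <- do.call(cbind, blocks)
  C <- crossprod(Tm)
  iu <- ncol(X) + seq_len(n_animals)
  C[iu, iu] <- C[iu, iu] + lam_u * solve(K)
  if (pe) {
    ip <- ncol(X) + n_animals + seq_len(ncol(blocks[[3]]))
    diag(C)[ip] <- diag(C)[ip] + vc$s2_e / vc$s2_p
  }
  sol <- solve(C, crossprod(Tm, y))
  list(beta = sol[seq_len(ncol(X))], u = sol[iu])
}

# small simulated population shared across engine tests
small_sim <- function(seed = 5, ...) {
  args <- list(seed = seed, years = 6, n_founder_males = 12,
               n_founder_females = 45, n_sires = 5, n_dams = 25,
               n_chr = 3, snps_per_chr = 60)
  args <- utils::modifyList(args, list(...))
  sim_population(do.call(sim_config, args))
}

default_spec <- function() model_spec("protein", fixed = c("herd_year", "parity"))
default_vc <- function() variance_components(phenotypic_var = 9)

# crafted QC fixture: 10 animals x 20 SNPs with known violations; used with
# hwe_max = 8 (the largest attainable 1-df statistic at n = 10 is 10, from a
# SNP with no heterozygotes or all heterozygotes)
qc_fixture <- function() {
  n <- 10
  snps <- sprintf("q%02d", 1:20)
  set.seed(99)
  dos <- matrix(rbinom(n * 20, 2, 0.5), n, 20,
                dimnames = list(paste0("an", 1:n), snps))
  dos[1:4, 1] <- NA       # q01: call rate 0.6 < 0.95
  dos[, 2] <- 2           # q02: monomorphic, MAF 0 < 0.01
  dos[, 3] <- 1           # q03: all heterozygous, HWE chi2 = 10 > 8
  dos[, 4] <- rep(c(0, 2), 5)  # q04: no heterozygotes, chi2 = 10 > 8
  dos[10, c(6, 7, 8)] <- NA    # an10: animal call rate < 0.99
  map <- tibble::tibble(snp_id = snps, chr = rep(1:2, each = 10),
                        pos = rep(seq(1e6, 1e7, length.out = 10), 2))
  genotypes(dos, map)
}

# independent QC oracle: recompute the per-filter removal sets with plain
# column statistics in the package's fixed filter order
qc_oracle <- function(g, maf = 0.01, snp_call_rate = 0.95, hwe_max = 8,
                      animal_call_rate = 0.99) {
  d <- g$dosage
  cr <- colMeans(!is.na(d))
  rm1 <- colnames(d)[cr < snp_call_rate]
  d <- d[, setdiff(colnames(d), rm1), drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  rm2 <- colnames(d)[pmin(p, 1 - p) < maf]
  d <- d[, setdiff(colnames(d), rm2), drop = FALSE]
  chi <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[!is.na(d[, j]), j]
    nn <- length(x)
    pj <- mean(x) / 2
    ex <- nn * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    ob <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    sum(((ob - ex)^2 / ex)[ex > 0])
  }, numeric(1))
  rm3 <- colnames(d)[chi > hwe_max]
  d <- d[, setdiff(colnames(d), rm3), drop = FALSE]
  acr <- rowMeans(!is.na(d))
  rm4 <- rownames(d)[acr < animal_call_rate]
  list(snp_call_rate = rm1, maf = rm2, hwe = rm3, animal = rm4,
       surviving_snps = colnames(d), surviving_animals = setdiff(rownames(d), rm4))
}
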