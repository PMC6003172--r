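#' Configuration for the population simulator
#'
#' Collects everything the forward-in-time simulator needs: pedigree
#' structure (two breeds with overlapping generations, sires genotyped /
#' daughters phenotyped), genome (SNP map, chromosome lengths, linkage-
#' disequilibrium parameter of the founder copying chain), the multi-allelic
#' major locus (breed-specific allele frequencies, effect pattern and target
#' fraction of genetic variance) and the phenotype model (heritability,
#' repeatability, per-breed coefficient of variation, herd-year and parity
#' structure).
#'
#' @param seed Integer seed driving all randomness.
#' @param breeds Breed labels.
#' @param n_founder_males,n_founder_females Founders per breed.
#' @param years Breeding years after the founder year.
#' @param n_sires,n_dams Sires and dams selected per breed and year.
#' @param sire_max_age,dam_max_age Oldest age (years) at which males and
#'   females are candidates for mating; young-sire sampling mirrors a
#'   progeny-testing scheme.
#' @param p_female Probability an offspring is female.
#' @param n_chr,snps_per_chr,chr_length_m,chr_length_bp Genome layout
#'   (per-chromosome SNP count, genetic length in Morgans, physical length).
#' @param ld_rho Copying probability of the founder-haplotype chain
#'   (adjacent-marker dependence; 0 = linkage equilibrium).
#' @param major_chr,major_pos_bp Location of the major locus.
#' @param major_freqs Matrix (breeds x 6 alleles A,B,C,E,F,O) of allele
#'   frequencies; rows sum to 1.
#' @param major_effects Named base pattern of allele effects (rescaled to
#'   hit `major_var_frac`).
#' @param major_var_frac Target fraction of additive genetic variance
#'   explained by the major locus (default 0.40, the middle of the 38-43%
#'   range reported for the casein locus).
#' @param exclude_fo_oo Forbid the FO and OO genotypes (resampled/flipped at
#'   transmission), mirroring genotypes never observed in the population.
#' @param h2 Heritability (default 0.5).
#' @param repeatability Repeatability of lactation records (default 0.6).
#' @param cv Named per-breed coefficient of variation of the phenotype.
#' @param sigma_p Total phenotypic standard deviation (u + pe + e scale;
#'   trait units g/kg).
#' @param herd_year_sd Standard deviation of herd-year effects relative to
#'   `sigma_p`.
#' @param n_herds Herds per breed.
#' @param max_parity Maximum lactation number.
#' @param genotype_female_frac Fraction of females SNP-genotyped (all males
#'   are); casein genotyping additionally covers `casein_female_frac` of
#'   females.
#' @param casein_female_frac See above.
#' @param n_causal_frac Fraction of SNPs that carry polygenic effects.
#' @param assoc_snps,assoc_decay Number of flanking SNPs whose founder
#'   haplotype determines the casein allele, and the geometric decay of
#'   their influence with distance; together they set how many local SNPs
#'   tag the locus (the chip region around a real casein cluster is dense
#'   and in strong LD with it).
#' @return A list of class `ss_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       breeds = c("AL", "SA"),
                       n_founder_males = 25, n_founder_females = 120,
                       years = 10, n_sires = 8, n_dams = 55,
                       sire_max_age = 3, dam_max_age = 6,
                       p_female = 0.7,
                       n_chr = 5, snps_per_chr = 400,
                       chr_length_m = 1.0, chr_length_bp = 1e8,
                       ld_rho = 0.95,
                       major_chr = 1, major_pos_bp = 5.5e7,
                       major_freqs = NULL,
                       major_effects = c(A = 1, B = 0.9, C = 0.55, E = 0.35,
                                         F = 0.05, O = 0),
                       major_var_frac = 0.40,
                       exclude_fo_oo = TRUE,
                       h2 = 0.5, repeatability = 0.6,
                       cv = NULL, sigma_p = 3,
                       herd_year_sd = 0.35, n_herds = 15,
                       max_parity = 3,
                       genotype_female_frac = 0.1,
                       casein_female_frac = 0.3,
                       n_causal_frac = 0.1,
                       assoc_snps = 25, assoc_decay = 0.75) {
  if (is.null(major_freqs)) {
    # allele A predominant in one breed; A, E, F frequent in the other
    major_freqs <- rbind(c(0.64, 0.10, 0.03, 0.16, 0.05, 0.02),
                         c(0.28, 0.06, 0.02, 0.42, 0.20, 0.02))
    major_freqs <- major_freqs[seq_along(breeds), , drop = FALSE]
    dimnames(major_freqs) <- list(breeds, CASEIN_ALLELES)
  }
  if (is.null(cv)) cv <- stats::setNames(c(0.11, 0.09)[seq_along(breeds)],
                                         breeds)
  stopifnot(all(abs(rowSums(major_freqs) - 1) < 1e-8),
            major_var_frac > 0, major_var_frac < 1, h2 > 0, h2 <= 1,
            repeatability >= h2, repeatability <= 1)
  structure(as.list(environment()), class = "ss_sim_config")
}

#' Simulate a pedigree with overlapping generations
#'
#' Founders (year 0) are unrelated; each subsequent year, `n_sires` males
#' and `n_dams` females alive and at least one year old are sampled per
#' breed, dams are assigned to sires at random, and each dam produces one
#' offspring. Matings never cross breeds and no animal is mated before its
#' birth year.
#'
#' @param cfg An [sim_config()]. RNG state is used as-is; call
#'   [sim_population()] for a seeded end-to-end run.
#' @return A sorted `ss_pedigree`.
#' @export
sim_pedigree <- function(cfg) {
  recs <- list()
  for (b in cfg$breeds) {
    nm <- cfg$n_founder_males
    nf <- cfg$n_founder_females
    founders <- tibble::tibble(
      animal = sprintf("%s%05d", b, seq_len(nm + nf)),
      sire = NA_character_, dam = NA_character_,
      birth_year = 0L,
      sex = c(rep("M", nm), rep("F", nf)),
      breed = b)
    ped <- founders
    counter <- nm + nf
    for (yr in seq_len(cfg$years)) {
      males <- ped$animal[ped$sex == "M" & ped$birth_year < yr &
                            ped$birth_year >= yr - cfg$sire_max_age]
      females <- ped$animal[ped$sex == "F" & ped$birth_year < yr &
                              ped$birth_year >= yr - cfg$dam_max_age]
      if (length(males) == 0) {
        males <- ped$animal[ped$sex == "M" & ped$birth_year < yr]
      }
      ns <- min(cfg$n_sires, length(males))
      nd <- min(cfg$n_dams, length(females))
      if (ns == 0 || nd == 0) stop("infeasible mating design in year ", yr)
      sires <- sample(males, ns)
      dams <- sample(females, nd)
      mate <- sample(rep_len(sires, nd))
      off <- tibble::tibble(
        animal = sprintf("%s%05d", b, counter + seq_len(nd)),
        sire = mate, dam = dams,
        birth_year = as.integer(yr),
        sex = ifelse(stats::runif(nd) < cfg$p_female, "F", "M"),
        breed = b)
      counter <- counter + nd
      ped <- dplyr::bind_rows(ped, off)
    }
    recs[[b]] <- ped
  }
  as_pedigree(dplyr::bind_rows(recs))
}

#' Simulate genomes by gene dropping
#'
#' Founder SNP haplotypes come from a first-order copying chain (allele at a
#' marker copies the previous marker's allele with probability `ld_rho`,
#' otherwise is drawn at the marker's frequency), which induces LD that
#' decays with distance. The major locus is embedded at its map position:
#' founder haplotypes are ranked by the allele count of the flanking SNPs
#' and casein alleles are assigned to contiguous rank blocks matching the
#' breed's allele frequencies, placing the locus in LD with its flanking
#' SNPs. Meiosis uses Poisson crossovers (Haldane model) on the chromosome's
#' genetic length, and the casein allele rides the same gametes.
#'
#' @param ped A sorted `ss_pedigree` from [sim_pedigree()].
#' @param cfg The [sim_config()].
#' @return A list: `geno` (`ss_genotypes` over all animals), `casein`
#'   (tibble `animal,allele1,allele2`), `map`.
#' @export
sim_genomes <- function(ped, cfg) {
  n <- nrow(ped)
  m <- cfg$n_chr * cfg$snps_per_chr
  map <- tibble::tibble(
    snp_id = sprintf("snp%01d_%04d", rep(seq_len(cfg$n_chr),
                                         each = cfg$snps_per_chr),
                     rep(seq_len(cfg$snps_per_chr), cfg$n_chr)),
    chr = rep(seq_len(cfg$n_chr), each = cfg$snps_per_chr),
    pos = rep(round(seq(1, cfg$chr_length_bp,
                        length.out = cfg$snps_per_chr)), cfg$n_chr))
  freq <- stats::runif(m, 0.1, 0.9)
  founder <- is.na(ped$sire) & is.na(ped$dam)
  nf <- sum(founder)

  # founder haplotypes: 2 per founder, copying chain along each chromosome
  drop_chain <- function(nhap) {
    H <- matrix(0L, nhap, m)
    for (ch in seq_len(cfg$n_chr)) {
      idx <- which(map$chr == ch)
      H[, idx[1]] <- stats::rbinom(nhap, 1, freq[idx[1]])
      for (jj in idx[-1]) {
        copy <- stats::runif(nhap) < cfg$ld_rho
        H[, jj] <- ifelse(copy, H[, jj - 1],
                          stats::rbinom(nhap, 1, freq[jj]))
      }
    }
    H
  }
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  cas1 <- character(n)
  cas2 <- character(n)
  hap1[founder, ] <- drop_chain(nf)
  hap2[founder, ] <- drop_chain(nf)

  # casein allele assignment to founder haplotypes, by breed, ranked on the
  # flanking-SNP allele count so the locus is in LD with its neighbourhood
  flank <- which(map$chr == cfg$major_chr)
  nfl <- min(cfg$assoc_snps, length(flank))
  flank <- flank[order(abs(map$pos[flank] - cfg$major_pos_bp))][seq_len(nfl)]
  for (b in cfg$breeds) {
    fb <- which(founder & ped$breed == b)
    haps <- rbind(hap1[fb, flank, drop = FALSE],
                  hap2[fb, flank, drop = FALSE])
    # haplotype-keyed assignment: local haplotypes are ordered
    # lexicographically with the nearest SNP as the leading digit, and
    # casein alleles fill contiguous blocks of that order matching the
    # breed frequencies. Identical local haplotypes always carry the same
    # allele, so the nearest flanking SNPs are strongly associated with
    # the locus, mirroring the haplotype structure around a real casein
    # cluster.
    score <- as.numeric(haps %*% cfg$assoc_decay^(seq_along(flank) - 1))
    counts <- round(cumsum(cfg$major_freqs[b, ]) * nrow(haps))
    counts[length(counts)] <- nrow(haps)
    r <- rank(score, ties.method = "first")
    grp <- findInterval(r - 0.5, c(0, counts))
    alle <- CASEIN_ALLELES[grp]
    cas1[fb] <- alle[seq_along(fb)]
    cas2[fb] <- alle[length(fb) + seq_along(fb)]
  }
  # forbid FO/OO in founders by re-drawing the second allele
  if (cfg$exclude_fo_oo) {
    for (i in which(founder)) {
      while (is_forbidden(cas1[i], cas2[i])) {
        b <- ped$breed[i]
        cas2[i] <- sample(CASEIN_ALLELES, 1, prob = cfg$major_freqs[b, ])
      }
    }
  }

  chr_of <- map$chr
  pos_m <- (map$pos / cfg$chr_length_bp) * cfg$chr_length_m
  major_m <- (cfg$major_pos_bp / cfg$chr_length_bp) * cfg$chr_length_m
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)

  gamete <- function(parent) {
    g <- integer(m)
    cas <- NA_character_
    for (ch in seq_len(cfg$n_chr)) {
      idx <- which(chr_of == ch)
      ncx <- stats::rpois(1, cfg$chr_length_m)
      cx <- sort(stats::runif(ncx, 0, cfg$chr_length_m))
      start <- stats::rbinom(1, 1, 0.5)
      parity <- (start + findInterval(pos_m[idx], cx)) %% 2
      g[idx] <- ifelse(parity == 0, hap1[parent, idx], hap2[parent, idx])
      if (ch == cfg$major_chr) {
        par_major <- (start + findInterval(major_m, cx)) %% 2
        cas <- if (par_major == 0) cas1[parent] else cas2[parent]
      }
    }
    list(snp = g, cas = cas, from = par_major)
  }

  for (i in which(!founder)) {
    gs <- gamete(si[i])
    gd <- gamete(di[i])
    if (cfg$exclude_fo_oo && is_forbidden(gs$cas, gd$cas)) {
      # flip the major-locus source haplotype on the side that can resolve it
      alt_s <- if (gs$cas == cas1[si[i]]) cas2[si[i]] else cas1[si[i]]
      alt_d <- if (gd$cas == cas1[di[i]]) cas2[di[i]] else cas1[di[i]]
      if (!is_forbidden(alt_s, gd$cas)) {
        gs$cas <- alt_s
      } else if (!is_forbidden(gs$cas, alt_d)) {
        gd$cas <- alt_d
      } else {
        gs$cas <- alt_s
        gd$cas <- alt_d
      }
    }
    hap1[i, ] <- gs$snp
    hap2[i, ] <- gd$snp
    cas1[i] <- gs$cas
    cas2[i] <- gd$cas
  }

  dosage <- hap1 + hap2
  storage.mode(dosage) <- "double"
  dimnames(dosage) <- list(ped$animal, map$snp_id)
  casein <- tibble::tibble(animal = ped$animal, allele1 = cas1,
                           allele2 = cas2)
  list(geno = genotypes(dosage, map), casein = casein, map = map)
}

is_forbidden <- function(a1, a2) {
  g <- paste(pmin(a1, a2), pmax(a1, a2))
  g %in% c("F O", "O O")
}

#' Simulate phenotypes and true breeding values
#'
#' True breeding values are the sum of a polygenic part (i.i.d. normal
#' effects on a random subset of SNPs) and the major-locus value
#' sum_a alpha_a y_a, with the locus effects rescaled so that the locus
#' explains the target fraction of the realized additive variance and the
#' total rescaled to the additive variance implied by `h2` and `sigma_p`.
#' Each female receives 1..max_parity lactation records
#' y = mu_breed + herd-year + parity + u + pe + e; males get no phenotype.
#' Breed means are set to sigma_y / CV_breed so that each breed hits its
#' target coefficient of variation with common variance components.
#'
#' @param ped A sorted `ss_pedigree`.
#' @param genomes Result of [sim_genomes()].
#' @param cfg The [sim_config()].
#' @return A list: `phenotypes` (tibble `animal,breed,herd_year,parity,
#'   year,protein`), `truth` (tibble `animal,u,u_poly,u_locus,pe`),
#'   `params` (named list of realized parameters).
#' @export
sim_phenotypes <- function(ped, genomes, cfg) {
  n <- nrow(ped)
  s2_P <- cfg$sigma_p^2
  s2_u <- cfg$h2 * s2_P
  s2_pe <- (cfg$repeatability - cfg$h2) * s2_P
  s2_e <- (1 - cfg$repeatability) * s2_P

  dos <- genomes$geno$dosage
  m <- ncol(dos)
  n_causal <- max(1, round(cfg$n_causal_frac * m))
  causal <- sort(sample.int(m, n_causal))
  b <- stats::rnorm(n_causal)
  u_poly <- as.numeric(dos[, causal, drop = FALSE] %*% b)
  u_poly <- u_poly - mean(u_poly)

  gc <- gene_content(genomes$casein)
  ycounts <- as.matrix(gc[, paste0("y_", CASEIN_ALLELES)])
  alpha0 <- cfg$major_effects[CASEIN_ALLELES]
  u_locus <- as.numeric(ycounts %*% alpha0)
  u_locus <- u_locus - mean(u_locus)

  f <- cfg$major_var_frac
  # choose c so that var(c*locus) / var(poly + c*locus) = f on the realized
  # draws, accounting for the locus-polygene covariance induced by shared
  # haplotypes: c^2 vl (1-f) - 2 f c cv - f vp = 0
  vl <- max(stats::var(u_locus), 1e-12)
  vp <- stats::var(u_poly)
  cv_lp <- stats::cov(u_locus, u_poly)
  scale_locus <- (f * cv_lp + sqrt(f^2 * cv_lp^2 + f * (1 - f) * vl * vp)) /
    (vl * (1 - f))
  u_locus <- u_locus * scale_locus
  u_raw <- u_poly + u_locus
  total_scale <- sqrt(s2_u / stats::var(u_raw))
  u <- u_raw * total_scale
  u_poly <- u_poly * total_scale
  u_locus <- u_locus * total_scale
  alpha_realized <- alpha0 * scale_locus * total_scale

  pe <- stats::rnorm(n, 0, sqrt(s2_pe))
  sigma_y <- sqrt(s2_P + (cfg$herd_year_sd * cfg$sigma_p)^2)
  mu_breed <- sigma_y / cfg$cv[cfg$breeds]
  parity_eff <- c(0, 0.4, 0.6, rep(0.6, max(0, cfg$max_parity - 3))) *
    cfg$sigma_p / 3

  females <- which(ped$sex == "F")
  herd <- sample.int(cfg$n_herds, n, replace = TRUE)
  n_lact <- sample(seq_len(cfg$max_parity), n, replace = TRUE,
                   prob = c(0.3, 0.35, 0.35)[seq_len(cfg$max_parity)])
  idx <- rep(females, n_lact[females])
  parities <- sequence(n_lact[females])
  recs <- tibble::tibble(animal = ped$animal[idx], breed = ped$breed[idx],
                         herd = herd[idx],
                         year = ped$birth_year[idx] + parities,
                         parity = parities)
  recs$herd_year <- paste0(recs$breed, "H", recs$herd, "Y", recs$year)
  hy_levels <- unique(recs$herd_year)
  hy_eff <- stats::setNames(
    stats::rnorm(length(hy_levels), 0, cfg$herd_year_sd * cfg$sigma_p),
    hy_levels)
  ui <- match(recs$animal, ped$animal)
  e <- stats::rnorm(nrow(recs), 0, sqrt(s2_e))
  recs$protein <- as.numeric(mu_breed[recs$breed] +
                               hy_eff[recs$herd_year] +
                               parity_eff[recs$parity] + u[ui] + pe[ui] + e)
  recs$parity <- factor(pmin(recs$parity, 3))

  truth <- tibble::tibble(animal = ped$animal, u = u, u_poly = u_poly,
                          u_locus = u_locus, pe = pe)
  phen_f <- unique(ui)
  realized_h2 <- stats::var(u[phen_f]) /
    (stats::var(u[phen_f]) + stats::var(pe[phen_f]) +
       if (s2_e > 0) stats::var(e) else 0)
  params <- list(s2_u = s2_u, s2_pe = s2_pe, s2_e = s2_e,
                 mu_breed = mu_breed, alpha = alpha_realized,
                 realized_h2 = realized_h2,
                 locus_var_frac = stats::var(u_locus) / stats::var(u))
  list(phenotypes = tibble::as_tibble(recs[, c("animal", "breed",
                                               "herd_year", "parity",
                                               "year", "protein")]),
       truth = truth, params = params)
}

#' Simulate a complete population
#'
#' Seeds the RNG from `cfg$seed` and chains [sim_pedigree()],
#' [sim_genomes()] and [sim_phenotypes()], then applies the genotyping rule
#' (all males SNP-genotyped plus a fraction of females; casein genotypes for
#' all SNP-genotyped animals plus a further fraction of females).
#'
#' @param cfg An [sim_config()].
#' @return A list of class `ss_sim`: `data` (an [ss_data()] bundle ready for
#'   evaluation), `truth`, `params`, `cfg`, and `geno_all` (genotypes of all
#'   animals, used by truth-based checks).
#' @export
sim_population <- function(cfg) {
  set.seed(cfg$seed)
  ped <- sim_pedigree(cfg)
  genomes <- sim_genomes(ped, cfg)
  phen <- sim_phenotypes(ped, genomes, cfg)

  males <- ped$animal[ped$sex == "M"]
  females <- ped$animal[ped$sex == "F"]
  snp_ids <- c(males, sample(females, round(cfg$genotype_female_frac *
                                              length(females))))
  snp_ids <- ped$animal[ped$animal %in% snp_ids]
  pool <- setdiff(females, snp_ids)
  cas_extra <- sample(pool, min(length(pool),
                                round(cfg$casein_female_frac *
                                        length(females))))
  cas_ids <- ped$animal[ped$animal %in% c(snp_ids, cas_extra)]

  geno <- genotypes(genomes$geno$dosage[snp_ids, , drop = FALSE],
                    genomes$geno$map)
  casein <- genomes$casein[match(cas_ids, genomes$casein$animal), ]
  data <- ss_data(ped, phen$phenotypes, geno = geno, casein = casein)
  structure(list(data = data, truth = phen$truth, params = phen$params,
                 cfg = cfg, geno_all = genomes$geno,
                 casein_all = genomes$casein),
            class = "ss_sim")
}

#' @export
print.ss_sim <- function(x, ...) {
  cat("<ss_sim> ", nrow(x$data$ped), " animals, ",
      nrow(x$data$phenotypes), " lactations, ",
      nrow(x$data$geno$dosage), " SNP-genotyped, ",
      nrow(x$data$casein), " casein-genotyped\n", sep = "")
  invisible(x)
}

#' Per-breed phenotype summary
#'
#' Counts, minimum/mean/maximum and coefficient of variation of the trait,
#' per breed - the usual descriptive table of a national recording system.
#'
#' @param sim An `ss_sim` (or an [ss_data()] with a `breed` column in the
#'   phenotypes).
#' @return A tibble with one row per breed.
#' @export
summary_stats <- function(sim) {
  ph <- if (inherits(sim, "ss_sim")) sim$data$phenotypes else sim$phenotypes
  dplyr::summarise(
    dplyr::group_by(ph, .data$breed),
    n_lactations = dplyr::n(),
    n_females = dplyr::n_distinct(.data$animal),
    min = min(.data$protein), mean = mean(.data$protein),
    max = max(.data$protein),
    cv = stats::sd(.data$protein) / mean(.data$protein),
    .groups = "drop")
}

#' Write a simulated population to disk in the standard input formats
#'
#' Writes `pedigree.csv`, `genotypes.csv` + `map.csv` (additive-dosage
#' dialect), `casein.csv`, `phenotypes.csv`, `truth.csv` and a
#' `summary.csv` descriptive table, all readable by the package loaders.
#'
#' @param sim An `ss_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(sim, dir) {
  stopifnot(inherits(sim, "ss_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  readr::write_csv(sim$data$ped, fp("pedigree.csv"), na = "")
  write_genotypes(sim$data$geno, fp("genotypes.csv"), fp("map.csv"))
  readr::write_csv(sim$data$casein, fp("casein.csv"), na = "")
  readr::write_csv(sim$data$phenotypes, fp("phenotypes.csv"))
  readr::write_csv(sim$truth, fp("truth.csv"))
  readr::write_csv(summary_stats(sim), fp("summary.csv"))
  invisible(dir)
}

#' Read a population written by [write_population()]
#'
#' @param dir Directory holding the CSV files.
#' @return An [ss_data()] bundle (plus `truth` attribute when present).
#' @export
read_population <- function(dir) {
  fp <- function(f) file.path(dir, f)
  ped <- read_pedigree(fp("pedigree.csv"))
  geno <- read_genotypes(fp("genotypes.csv"), fp("map.csv"), format = "csv")
  casein <- readr::read_csv(fp("casein.csv"),
                            col_types = readr::cols(.default = "c"))
  ph <- readr::read_csv(fp("phenotypes.csv"), col_types = readr::cols(
    animal = "c", breed = "c", herd_year = "c", parity = "c",
    year = "i", protein = "d"))
  out <- ss_data(ped, ph, geno = geno, casein = casein)
  tf <- fp("truth.csv")
  if (file.exists(tf)) {
    attr(out, "truth") <- readr::read_csv(tf, col_types = readr::cols(
      animal = "c", .default = "d"))
  }
  out
}
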