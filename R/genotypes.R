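#' Construct a genotype object
#'
#' Bundles an animals-by-SNP dosage matrix (entries 0/1/2 or `NA`) with its
#' map. Columns are reordered to map order (chromosome, then position); if
#' the supplied map is out of positional order it is re-sorted and the
#' original order recorded in the `reordered` attribute.
#'
#' @param dosage Integer/numeric matrix, rows = animals (rownames required),
#'   columns = SNPs (colnames = snp ids).
#' @param map Data frame with columns `snp_id`, `chr`, `pos` (1-based bp).
#' @return A list of class `ss_genotypes` with elements `dosage` and `map`.
#' @export
genotypes <- function(dosage, map) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  map <- tibble::as_tibble(map)
  stopifnot(all(c("snp_id", "chr", "pos") %in% names(map)))
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  if (anyDuplicated(rownames(dosage))) stop("duplicate animal id in genotypes")
  if (!setequal(colnames(dosage), map$snp_id)) {
    stop("snp ids in genotype matrix and map do not match")
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing")
  ord <- order(map$chr, map$pos)
  reordered <- !identical(ord, seq_len(nrow(map)))
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, map$snp_id, drop = FALSE]
  structure(list(dosage = dosage, map = map),
            reordered = reordered, class = "ss_genotypes")
}

#' @export
print.ss_genotypes <- function(x, ...) {
  cat("<ss_genotypes> ", nrow(x$dosage), " animals x ", ncol(x$dosage),
      " SNPs on ", length(unique(x$map$chr)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read genotypes and a SNP map from disk
#'
#' Supports two dialects: a PLINK `.raw`-style whitespace table (header
#' `FID IID PAT MAT SEX PHENOTYPE <snp...>`, dosages 0/1/2/NA) and an
#' additive-dosage CSV (`animal,<snp>,<snp>,...`). The map is either a PLINK
#' `.map` (chrom, snp id, cM, bp; no header) or a CSV with columns
#' `snp_id,chr,pos`. Optionally a VCF (biallelic sites only, GT field) can be
#' read when the `vcfR` package is available.
#'
#' @param geno_file Path to the genotype table (or VCF).
#' @param map_file Path to the map file; ignored for VCF input.
#' @param format One of `"auto"`, `"raw"`, `"csv"`, `"vcf"`.
#' @return An `ss_genotypes` object.
#' @export
read_genotypes <- function(geno_file, map_file = NULL,
                           format = c("auto", "raw", "csv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", geno_file)) "vcf"
    else if (grepl("\\.raw$", geno_file)) "raw" else "csv"
  }
  if (format == "vcf") return(read_genotypes_vcf(geno_file))
  if (is.null(map_file)) stop("map_file is required for raw/csv input")
  map <- read_snp_map(map_file)
  if (format == "raw") {
    tab <- utils::read.table(geno_file, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    idcol <- "IID"
    drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(tab))
    ids <- as.character(tab[[idcol]])
    snp_cols <- setdiff(names(tab), drop)
    # .raw columns carry a counted-allele suffix such as _A
    plain <- sub("_[A-Z0-9]+$", "", snp_cols)
    dn <- if (all(plain %in% map$snp_id)) plain else snp_cols
    dos <- as.matrix(tab[, snp_cols, drop = FALSE])
  } else {
    tab <- utils::read.csv(geno_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    dn <- names(tab)[-1]
    dos <- as.matrix(tab[, -1, drop = FALSE])
  }
  check_dosage_values(dos, geno_file)
  storage.mode(dos) <- "double"
  dimnames(dos) <- list(ids, dn)
  genotypes(dos, map)
}

check_dosage_values <- function(dos, file) {
  suppressWarnings(num <- matrix(as.numeric(dos), nrow = nrow(dos)))
  bad <- which(!(num %in% c(0, 1, 2)) & !is.na(num) |
                 (is.na(num) & !is.na(dos) & !(dos %in% c("NA", "na", "."))),
               arr.ind = TRUE)
  if (length(bad) > 0) {
    stop(sprintf("unknown dosage symbol '%s' in %s at data line %d",
                 dos[bad[1, 1], bad[1, 2]], file, bad[1, 1]))
  }
}

read_snp_map <- function(map_file) {
  if (grepl("\\.map$", map_file)) {
    m <- utils::read.table(map_file, header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(m) < 4) stop("PLINK .map needs 4 columns: chr, snp, cM, bp")
    tibble::tibble(snp_id = as.character(m[[2]]), chr = as.integer(m[[1]]),
                   pos = as.integer(m[[4]]))
  } else {
    m <- utils::read.csv(map_file, stringsAsFactors = FALSE)
    tibble::tibble(snp_id = as.character(m$snp_id), chr = as.integer(m$chr),
                   pos = as.integer(m$pos))
  }
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  if (any(!biallelic)) {
    warning(sum(!biallelic), " non-biallelic site(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", "."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  dos <- t(apply(gt, 1, count_alt))
  dimnames(dos) <- dimnames(gt)
  map <- tibble::tibble(snp_id = fix[biallelic, "ID"],
                        chr = as.integer(fix[biallelic, "CHROM"]),
                        pos = as.integer(fix[biallelic, "POS"]))
  genotypes(t(dos), map)
}

#' Write genotypes to the additive-dosage CSV dialect
#'
#' @param g An `ss_genotypes` object.
#' @param geno_file,map_file Output paths (dosage CSV and map CSV).
#' @export
write_genotypes <- function(g, geno_file, map_file) {
  df <- data.frame(animal = rownames(g$dosage), g$dosage,
                   check.names = FALSE)
  utils::write.csv(df, geno_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(g$map[, c("snp_id", "chr", "pos")], map_file,
                   row.names = FALSE, quote = FALSE)
  invisible(g)
}

#' Allele frequencies from dosages
#'
#' @param g An `ss_genotypes` object or a dosage matrix.
#' @return Named vector of counted-allele frequencies p = mean(dosage)/2 over
#'   non-missing calls.
#' @export
allele_freq <- function(g) {
  dos <- if (inherits(g, "ss_genotypes")) g$dosage else g
  nm <- colSums(!is.na(dos))
  if (any(nm == 0)) {
    stop("SNP(s) with no non-missing calls: ",
         paste(utils::head(colnames(dos)[nm == 0], 5), collapse = ", "))
  }
  colMeans(dos, na.rm = TRUE) / 2
}

#' Hardy-Weinberg goodness-of-fit chi-square per SNP
#'
#' One-df goodness-of-fit statistic of observed genotype counts against
#' expectations at the observed allele frequency. Monomorphic SNPs return 0
#' by convention (they are caught by the MAF filter).
#'
#' @param g An `ss_genotypes` object or a dosage matrix.
#' @return Named numeric vector of chi-square statistics.
#' @export
hwe_chi2 <- function(g) {
  dos <- if (inherits(g, "ss_genotypes")) g$dosage else g
  n0 <- colSums(dos == 0, na.rm = TRUE)
  n1 <- colSums(dos == 1, na.rm = TRUE)
  n2 <- colSums(dos == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  chi <- numeric(length(n))
  for (k in 1:3) {
    obs <- list(n0, n1, n2)[[k]]
    ex <- list(e0, e1, e2)[[k]]
    ok <- ex > 0
    chi[ok] <- chi[ok] + (obs[ok] - ex[ok])^2 / ex[ok]
  }
  chi[p == 0 | p == 1] <- 0
  stats::setNames(chi, colnames(dos))
}

#' Genotype quality control
#'
#' Applies the standard chip QC filters in a fixed order: SNP call rate,
#' minor allele frequency, Hardy-Weinberg chi-square, then animal call rate.
#' With a grouping vector (for example breed), the SNP filters are evaluated
#' independently within every group and a SNP is retained only if it passes
#' in all groups; animals are filtered within their own group.
#'
#' @param g An `ss_genotypes` object.
#' @param maf Minimum minor allele frequency (default 0.01).
#' @param snp_call_rate Minimum SNP call rate (default 0.95).
#' @param hwe_max Maximum Hardy-Weinberg chi-square (default 24).
#' @param animal_call_rate Minimum per-animal call rate (default 0.99).
#' @param group Optional vector (length = animals, or a named vector) giving
#'   the QC group of each animal.
#' @return A list of class `ss_qc` with elements `genotypes` (filtered
#'   `ss_genotypes`) and `report` (an `ss_qc_report` tibble itemising
#'   removals per filter).
#' @export
qc_genotypes <- function(g, maf = 0.01, snp_call_rate = 0.95, hwe_max = 24,
                         animal_call_rate = 0.99, group = NULL) {
  stopifnot(inherits(g, "ss_genotypes"))
  dos <- g$dosage
  if (is.null(group)) {
    group <- rep("all", nrow(dos))
  } else if (!is.null(names(group))) {
    group <- group[rownames(dos)]
  }
  group <- as.character(group)
  groups <- unique(group)

  snp_fail <- function(fun) {
    fails <- lapply(groups, function(gr) fun(dos[group == gr, , drop = FALSE]))
    Reduce(`|`, fails)
  }
  fail_cr <- snp_fail(function(d) colMeans(!is.na(d)) < snp_call_rate)
  keep1 <- !fail_cr
  d1 <- dos[, keep1, drop = FALSE]

  fail_maf <- rep(FALSE, ncol(d1))
  for (gr in groups) {
    p <- colMeans(d1[group == gr, , drop = FALSE], na.rm = TRUE) / 2
    p[is.nan(p)] <- 0
    fail_maf <- fail_maf | pmin(p, 1 - p) < maf
  }
  keep2 <- !fail_maf
  d2 <- d1[, keep2, drop = FALSE]

  fail_hwe <- rep(FALSE, ncol(d2))
  for (gr in groups) {
    fail_hwe <- fail_hwe | hwe_chi2(d2[group == gr, , drop = FALSE]) > hwe_max
  }
  keep3 <- !fail_hwe
  d3 <- d2[, keep3, drop = FALSE]

  acr <- rowMeans(!is.na(d3))
  keep_an <- acr >= animal_call_rate
  d4 <- d3[keep_an, , drop = FALSE]
  if (ncol(d4) == 0 || nrow(d4) == 0) {
    stop("no SNPs or animals survive QC")
  }

  report <- tibble::tibble(
    filter = c("snp_call_rate", "maf", "hwe", "animal_call_rate"),
    unit = c("snp", "snp", "snp", "animal"),
    threshold = c(snp_call_rate, maf, hwe_max, animal_call_rate),
    removed = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe), sum(!keep_an)),
    surviving = c(sum(keep1), sum(keep2), sum(keep3), sum(keep_an))
  )
  attr(report, "removed_snps") <- list(
    snp_call_rate = colnames(dos)[fail_cr],
    maf = colnames(d1)[fail_maf],
    hwe = colnames(d2)[fail_hwe]
  )
  attr(report, "removed_animals") <- rownames(d3)[!keep_an]
  attr(report, "input") <- c(animals = nrow(dos), snps = ncol(dos))
  class(report) <- c("ss_qc_report", class(report))

  out <- genotypes(d4, g$map[g$map$snp_id %in% colnames(d4), , drop = FALSE])
  structure(list(genotypes = out, report = report), class = "ss_qc")
}

#' @export
print.ss_qc_report <- function(x, ...) {
  inp <- attr(x, "input")
  cat("Genotype QC report:", inp["animals"], "animals x", inp["snps"],
      "SNPs in\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-17s (%s, threshold %g): removed %d, surviving %d\n",
                x$filter[i], x$unit[i], x$threshold[i], x$removed[i],
                x$surviving[i]))
  }
  invisible(x)
}

#' Serialise a QC report to JSON
#'
#' @param report An `ss_qc_report`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if written to a file.
#' @export
qc_report_json <- function(report, path = NULL) {
  obj <- list(
    input = as.list(attr(report, "input")),
    filters = lapply(seq_len(nrow(report)), function(i) {
      list(filter = report$filter[i], unit = report$unit[i],
           threshold = report$threshold[i], removed = report$removed[i],
           surviving = report$surviving[i])
    }),
    removed_snps = attr(report, "removed_snps"),
    removed_animals = attr(report, "removed_animals")
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Centered marker matrix with mean imputation
#'
#' Missing dosages are imputed to 2p (so they contribute zero after
#' centering) and every column is centered by twice its allele frequency.
#'
#' @param g An `ss_genotypes` object or dosage matrix.
#' @param p Allele frequencies; computed with [allele_freq()] if omitted.
#' @return Dense numeric matrix M (animals x SNPs).
#' @export
center_genotypes <- function(g, p = NULL) {
  dos <- if (inherits(g, "ss_genotypes")) g$dosage else g
  if (is.null(p)) p <- allele_freq(dos)
  M <- sweep(dos, 2, 2 * p, `-`)
  M[is.na(M)] <- 0
  M
}

#' Blended (weighted) genomic relationship matrix
#'
#' Builds G = blend * M D M' / k + (1 - blend) * A22 with
#' k = 2 * sum(p_i (1 - p_i)) and D a diagonal matrix of per-SNP weights.
#' With unit weights this is the usual blended genomic relationship matrix;
#' with WssGBLUP weights it is the weighted matrix G*.
#'
#' @param M Centered marker matrix (animals x SNPs), e.g. from
#'   [center_genotypes()].
#' @param p Allele frequencies of the SNPs in `M`.
#' @param a22 Pedigree relationships among the genotyped animals (same order
#'   as rows of `M`); required when `blend < 1`.
#' @param weights Optional per-SNP weights (default all ones).
#' @param blend Fraction of the marker-based matrix (default 0.95).
#' @return Dense symmetric matrix with attributes `blend`, `k` and `weights`.
#' @export
build_g <- function(M, p, a22 = NULL, weights = NULL, blend = 0.95) {
  m <- ncol(M)
  if (length(p) != m) stop("length(p) must equal ncol(M)")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("length(weights) must equal ncol(M)")
  if (any(weights < 0)) stop("weights must be non-negative")
  k <- 2 * sum(p * (1 - p))
  if (k <= 0) stop("all SNPs are monomorphic (k = 0); cannot scale G")
  Gm <- tcrossprod(sweep(M, 2, weights, `*`), M) / k
  if (blend < 1) {
    if (is.null(a22)) stop("a22 is required when blend < 1")
    stopifnot(all(dim(a22) == nrow(M)))
    G <- blend * Gm + (1 - blend) * a22
  } else {
    G <- Gm
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "blend") <- blend
  attr(G, "k") <- k
  attr(G, "weights") <- weights
  G
}

#' Association chi-square between a major-gene genotype and each SNP
#'
#' Contingency chi-square (no continuity correction) between the multi-class
#' major-gene genotype and the three-class SNP genotype. Animals missing
#' either call are excluded per SNP; SNPs with fewer than two observed
#' classes on either margin are reported as `NA`.
#'
#' @param gene_genotypes Data frame with columns `animal`, `allele1`,
#'   `allele2` (unordered pairs).
#' @param g An `ss_genotypes` object.
#' @return A tibble with columns `snp_id`, `chr`, `pos`, `chi2`.
#' @export
gene_snp_chi2 <- function(gene_genotypes, g) {
  stopifnot(inherits(g, "ss_genotypes"))
  common <- intersect(gene_genotypes$animal, rownames(g$dosage))
  if (length(common) == 0) stop("no overlapping animals")
  gg <- gene_genotypes[match(common, gene_genotypes$animal), ]
  cls <- paste(pmin(gg$allele1, gg$allele2), pmax(gg$allele1, gg$allele2))
  dos <- g$dosage[common, , drop = FALSE]
  chi <- vapply(seq_len(ncol(dos)), function(j) {
    ok <- !is.na(dos[, j]) & !is.na(cls)
    tab <- table(cls[ok], dos[ok, j])
    if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  }, numeric(1))
  tibble::tibble(snp_id = g$map$snp_id, chr = g$map$chr, pos = g$map$pos,
                 chi2 = chi)
}
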