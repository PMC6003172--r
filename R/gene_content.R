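CASEIN_ALLELES <- c("A", "B", "C", "E", "F", "O")

#' Gene content from major-gene genotypes
#'
#' Converts unordered allele pairs at a multi-allelic locus into per-allele
#' copy counts (0/1/2). Records with exactly one missing allele are dropped
#' with a warning (a half-genotype cannot be used); animals absent from the
#' table are simply ungenotyped and later treated as missing records.
#'
#' @param gene_genotypes Data frame with columns `animal`, `allele1`,
#'   `allele2`; alleles in `r toString(CASEIN_ALLELES)`.
#' @param alleles Allele set (default the six casein alleles A,B,C,E,F,O).
#' @return A tibble with column `animal` and one count column per allele
#'   (`y_A` ... `y_O`); counts sum to 2 per animal.
#' @export
gene_content <- function(gene_genotypes, alleles = CASEIN_ALLELES) {
  gg <- tibble::as_tibble(gene_genotypes)
  stopifnot(all(c("animal", "allele1", "allele2") %in% names(gg)))
  half <- xor(is.na(gg$allele1), is.na(gg$allele2))
  if (any(half)) {
    warning(sum(half), " record(s) with one missing allele removed")
    gg <- gg[!half, , drop = FALSE]
  }
  gg <- gg[!is.na(gg$allele1), , drop = FALSE]
  bad <- setdiff(unique(c(gg$allele1, gg$allele2)), alleles)
  if (length(bad) > 0) {
    stop("allele(s) outside {", paste(alleles, collapse = ","), "}: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(gg$animal)) stop("duplicate animal in gene genotypes")
  out <- tibble::tibble(animal = as.character(gg$animal))
  for (a in alleles) {
    out[[paste0("y_", a)]] <- (gg$allele1 == a) + (gg$allele2 == a)
  }
  out
}

#' Default genetic covariance for the gene-content model
#'
#' Derives the 7x7 genetic (co)variance across the quantitative trait and
#' the six per-allele gene-content traits from a single-locus model with
#' allele frequencies `p` and substitution effects `alpha`:
#' Var(u_a) = 2 p_a (1 - p_a), Cov(u_a, u_b) = -2 p_a p_b,
#' Cov(u, u_a) = 2 p_a (alpha_a - mean alpha), and
#' Var(u) = sigma2_poly + sum_a alpha_a * 2 p_a (alpha_a - mean alpha).
#' The gene-content block carries the sum-to-two constraint and is singular;
#' a ridge is added to its diagonal so the matrix factorises.
#'
#' @param p Named allele-frequency vector over the allele set (sums to 1).
#' @param alpha Named allele substitution effects (trait units per copy).
#' @param sigma2_poly Polygenic (non-locus) additive variance.
#' @param ridge Ridge added to the gene-content diagonal (default 1e-6).
#' @return A symmetric matrix of class `ss_gene_covariance` with dimnames
#'   `c("trait", alleles)` and attributes `p` and `ridge`.
#' @export
casein_covariance <- function(p, alpha, sigma2_poly, ridge = 1e-6) {
  alleles <- names(p)
  if (is.null(alleles)) stop("p must be a named allele-frequency vector")
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  alpha <- alpha[alleles]
  if (anyNA(alpha)) stop("alpha must be named like p")
  abar <- sum(p * alpha)
  na <- length(alleles)
  K <- matrix(0, na + 1, na + 1,
              dimnames = list(c("trait", alleles), c("trait", alleles)))
  for (i in seq_len(na)) {
    for (j in seq_len(na)) {
      K[i + 1, j + 1] <- if (i == j) 2 * p[i] * (1 - p[i]) else
        -2 * p[i] * p[j]
    }
  }
  K[1, -1] <- K[-1, 1] <- 2 * p * (alpha - abar)
  K[1, 1] <- sigma2_poly + sum(alpha * 2 * p * (alpha - abar))
  K[-1, -1] <- K[-1, -1] + diag(ridge, na)
  structure(K, p = p, ridge = ridge, class = c("ss_gene_covariance",
                                               class(K)))
}

#' Multi-trait gene-content evaluation
#'
#' Fits the quantitative trait jointly with six gene-content traits (one per
#' allele of the major locus) in a single mixed model: the trait keeps its
#' fixed effects and permanent-environment effect, each gene-content trait
#' has a mean-only fixed part, the 7-trait genetic covariance is
#' K (x) H (entering the equations through K-inverse and H-inverse), and
#' residual covariances between traits are zero. Gene-content records exist
#' only for genotyped animals; missing records are handled by equation
#' deletion. The model predicts gene contents (and hence major-locus
#' information) for ungenotyped animals through the pedigree.
#'
#' @param data An [ss_data()] bundle; `data$casein` must hold the major-gene
#'   genotype table (`animal,allele1,allele2`).
#' @param spec An [model_spec()] for the quantitative trait.
#' @param vc An [variance_components()]; only the residual and
#'   permanent-environment components are used (the genetic variance comes
#'   from `K["trait","trait"]`).
#' @param K Genetic covariance from [casein_covariance()] or user-supplied
#'   (positive definite after its ridge).
#' @param gene_residual_frac Residual variance of each gene-content trait as
#'   a fraction of its genetic variance (default 1e-3; gene content is
#'   noise-free in theory, the small positive value keeps the system
#'   identifiable).
#' @param blend Blending fraction for G (default 0.95).
#' @param G Optional precomputed genomic matrix.
#' @param phenotypes Optional replacement record table.
#' @return An object of class `ss_gene_content_fit`: `beta`, `u` (trait
#'   GEBV), `pe`, `mu` (allele means), `content` (predicted gene content per
#'   animal and allele), and solver diagnostics.
#' @export
gene_content_blup <- function(data, spec, vc, K, gene_residual_frac = 1e-3,
                              blend = 0.95, G = NULL, phenotypes = NULL) {
  stopifnot(inherits(data, "ss_data"), !is.null(data$casein),
            inherits(vc, "ss_varcomp"))
  alleles <- setdiff(rownames(K), "trait")
  Kinv <- tryCatch(solve(K), error = function(e) {
    stop("K is not invertible even with its ridge: ", e$message)
  })
  # require positive definiteness
  tryCatch(chol(K), error = function(e) stop("K is not positive definite"))

  ped <- data$ped
  n <- nrow(ped)
  ph <- if (is.null(phenotypes)) data$phenotypes else phenotypes
  design <- build_design(ph, spec, ped)
  a_inv <- a_inverse(ped)
  if (!is.null(data$geno) && nrow(data$geno$dosage) > 0) {
    ids <- rownames(data$geno$dosage)
    a22 <- a_submatrix(ped, ids)
    if (is.null(G)) {
      p <- allele_freq(data$geno)
      M <- center_genotypes(data$geno, p)
      G <- build_g(M, p, a22 = a22, weights = NULL, blend = blend)
    }
    h_inv <- build_h_inverse(a_inv, a22, G)
  } else {
    h_inv <- a_inv
  }

  gc <- gene_content(data$casein, alleles = alleles)
  gi <- match(gc$animal, ped$animal)
  if (anyNA(gi)) stop("casein-genotyped animal(s) absent from pedigree")

  X <- design$X; Z <- design$Z; W <- design$W
  nrec <- length(design$y)
  pb <- ncol(X)
  nal <- length(alleles)
  npe <- if (!is.null(W)) ncol(W) else 0
  ntr <- nal + 1
  # effect layout: [beta | mu_alleles | u (ntr blocks of n) | pe]
  off_mu <- pb
  off_u <- pb + nal
  off_pe <- off_u + ntr * n
  ncol_tot <- off_pe + npe

  blocks <- list()
  rhs <- numeric(ncol_tot)
  # protein records
  parts <- list(X,
                Matrix::Matrix(0, nrec, nal, sparse = TRUE),
                Z,
                Matrix::Matrix(0, nrec, (ntr - 1) * n, sparse = TRUE))
  if (!is.null(W)) parts <- c(parts, list(W))
  Tp <- do.call(cbind, parts)
  w_p <- 1 / vc$s2_e
  C <- Matrix::crossprod(Tp) * w_p
  rhs <- as.numeric(Matrix::crossprod(Tp, design$y)) * w_p
  # gene-content records, one block per allele
  ng <- nrow(gc)
  s2e_gene <- gene_residual_frac * diag(K)[alleles]
  for (t in seq_len(nal)) {
    ya <- gc[[paste0("y_", alleles[t])]]
    Ta <- Matrix::sparseMatrix(
      i = c(seq_len(ng), seq_len(ng)),
      j = c(rep(off_mu + t, ng), off_u + t * n + gi),
      x = rep(1, 2 * ng), dims = c(ng, ncol_tot))
    w_a <- 1 / s2e_gene[t]
    C <- C + Matrix::crossprod(Ta) * w_a
    rhs <- rhs + as.numeric(Matrix::crossprod(Ta, ya)) * w_a
  }
  # genetic penalty K^-1 (x) H^-1 and PE penalty
  pen <- kronecker(Matrix::Matrix(Kinv, sparse = TRUE), h_inv)
  iu <- off_u + seq_len(ntr * n)
  C[iu, iu] <- C[iu, iu] + pen
  if (npe > 0) {
    ip <- off_pe + seq_len(npe)
    C <- C + Matrix::sparseMatrix(i = ip, j = ip, x = 1 / vc$s2_p,
                                  dims = dim(C))
  }
  C <- Matrix::forceSymmetric(C)
  sol <- tryCatch(as.numeric(Matrix::solve(C, rhs)), error = function(e) {
    as.numeric(Matrix::solve(methods::as(C, "generalMatrix"), rhs))
  })
  resid <- as.numeric(C %*% sol - rhs)
  rel <- sqrt(sum(resid^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)

  beta <- tibble::tibble(term = design$terms, level = design$levels,
                         estimate = sol[seq_len(pb)], constrained = FALSE)
  mu <- tibble::tibble(allele = alleles,
                       mean = sol[off_mu + seq_len(nal)])
  u <- tibble::tibble(animal = ped$animal, gebv = sol[off_u + seq_len(n)])
  ua <- matrix(sol[off_u + n + seq_len(nal * n)], nrow = n)
  content <- tibble::as_tibble(sweep(ua, 2, mu$mean, `+`),
                               .name_repair = ~paste0("content_", alleles))
  content <- dplyr::bind_cols(tibble::tibble(animal = ped$animal), content)
  pe <- if (npe > 0) {
    tibble::tibble(animal = design$pe_ids,
                   pe = sol[off_pe + seq_len(npe)])
  } else {
    tibble::tibble(animal = character(0), pe = numeric(0))
  }
  structure(list(beta = beta, mu = mu, u = u, pe = pe, content = content,
                 observed = gc,
                 diagnostics = list(method = "direct",
                                    residual_norm = rel,
                                    n_equations = ncol_tot),
                 vc = vc, K = K),
            class = "ss_gene_content_fit")
}

#' @export
print.ss_gene_content_fit <- function(x, ...) {
  cat("<ss_gene_content_fit> ", nrow(x$u), " animals, ",
      nrow(x$mu), " allele traits; ", x$diagnostics$n_equations,
      " equations (relative residual ",
      sprintf("%.2e", x$diagnostics$residual_norm), ")\n", sep = "")
  invisible(x)
}
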