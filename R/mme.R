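#' Specify the repeated-records animal model
#'
#' Describes the single-trait model y = Xb + Zu + Wp + e: which column holds
#' the trait, which factor columns enter the fixed part, which column holds
#' the animal id, and whether a permanent-environment effect is fitted.
#' Interactions can be written as `"a:b"`; the interaction factor is built
#' from the pasted levels of the named columns.
#'
#' @param trait Name of the phenotype column.
#' @param fixed Character vector of factor columns (or `"a:b"` interactions).
#' @param animal Name of the animal id column (default `"animal"`).
#' @param permanent_env Fit a permanent-environment effect per phenotyped
#'   animal (default `TRUE`; appropriate for repeated lactation records).
#' @return A list of class `ss_model_spec`.
#' @export
model_spec <- function(trait, fixed, animal = "animal", permanent_env = TRUE) {
  structure(list(trait = trait, fixed = fixed, animal = animal,
                 permanent_env = permanent_env), class = "ss_model_spec")
}

#' Variance components for the repeated-records model
#'
#' Derives additive, permanent-environment and residual variances from
#' heritability and repeatability on a given phenotypic variance:
#' s2_u = h2 * s2_P, s2_p = (repeatability - h2) * s2_P,
#' s2_e = (1 - repeatability) * s2_P.
#'
#' @param h2 Heritability in (0,1) (default 0.5, a highly heritable
#'   milk-composition trait).
#' @param repeatability Repeatability in (h2, 1) (default 0.6).
#' @param phenotypic_var Phenotypic variance s2_P (trait squared units).
#' @return A list of class `ss_varcomp` with `s2_u`, `s2_p`, `s2_e`.
#' @export
variance_components <- function(h2 = 0.5, repeatability = 0.6,
                                phenotypic_var = 9) {
  stopifnot(h2 > 0, h2 < 1, repeatability >= h2, repeatability < 1,
            phenotypic_var > 0)
  structure(list(s2_u = h2 * phenotypic_var,
                 s2_p = (repeatability - h2) * phenotypic_var,
                 s2_e = (1 - repeatability) * phenotypic_var),
            class = "ss_varcomp")
}

#' Build design matrices for the animal model
#'
#' Constructs the sparse incidence matrices of the repeated-records model:
#' X with an explicit intercept and set-to-zero (drop-first) constraints on
#' every fixed factor, Z mapping records to all pedigree animals and W
#' mapping records to the permanent-environment effects of phenotyped
#' animals.
#'
#' @param phenotypes Data frame of records (one row per lactation).
#' @param spec An [model_spec()].
#' @param ped A sorted `ss_pedigree`; every phenotyped animal must appear.
#' @return A list of class `ss_design` with `X`, `Z`, `W`, `y`, level maps
#'   and record animal ids.
#' @export
build_design <- function(phenotypes, spec, ped) {
  assert_sorted(ped)
  stopifnot(inherits(spec, "ss_model_spec"))
  ph <- as.data.frame(phenotypes)
  if (!spec$trait %in% names(ph)) stop("trait column not found: ", spec$trait)
  an <- as.character(ph[[spec$animal]])
  zi <- match(an, ped$animal)
  if (anyNA(zi)) {
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(utils::head(unique(an[is.na(zi)]), 5), collapse = ", "))
  }
  nrec <- nrow(ph)

  fx <- data.frame(row.names = seq_len(nrec))
  for (f in spec$fixed) {
    parts <- strsplit(f, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(ph))
    if (length(miss) > 0) stop("fixed-effect column(s) not found: ",
                               paste(miss, collapse = ", "))
    v <- if (length(parts) == 1) ph[[parts]] else
      do.call(paste, c(ph[parts], sep = ":"))
    if (anyNA(v)) stop("missing level in fixed effect '", f, "'")
    fx[[f]] <- factor(v)
  }
  if (ncol(fx) > 0) {
    X <- Matrix::sparse.model.matrix(
      stats::as.formula(paste("~", paste(sprintf("`%s`", names(fx)),
                                         collapse = "+"))), fx)
    assign_map <- attr(X, "assign")
    terms <- c("(Intercept)", names(fx))[assign_map + 1]
  } else {
    X <- Matrix::sparseMatrix(i = seq_len(nrec), j = rep(1, nrec), x = 1,
                              dims = c(nrec, 1),
                              dimnames = list(NULL, "(Intercept)"))
    terms <- "(Intercept)"
  }
  constrained <- purrr::map_dfr(names(fx), function(f) {
    tibble::tibble(term = f, level = levels(fx[[f]])[1])
  })

  Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = zi, x = 1,
                            dims = c(nrec, nrow(ped)),
                            dimnames = list(NULL, ped$animal))
  if (spec$permanent_env) {
    pe_ids <- unique(an)
    W <- Matrix::sparseMatrix(i = seq_len(nrec), j = match(an, pe_ids), x = 1,
                              dims = c(nrec, length(pe_ids)),
                              dimnames = list(NULL, pe_ids))
  } else {
    pe_ids <- character(0)
    W <- NULL
  }
  structure(list(X = X, Z = Z, W = W, y = as.numeric(ph[[spec$trait]]),
                 terms = terms, levels = colnames(X),
                 constrained = constrained, record_animal = an,
                 pe_ids = pe_ids, animals = ped$animal),
            class = "ss_design")
}

#' Inverse of the combined pedigree-genomic relationship matrix
#'
#' H-inverse equals A-inverse plus (G-inverse - A22-inverse) on the genotyped
#' block, the standard single-step identity; H itself is never formed. Dense
#' work is restricted to the genotyped block.
#'
#' @param a_inv Sparse A-inverse over all pedigree animals (dimnames = ids).
#' @param a22 Dense pedigree relationships among the genotyped animals.
#' @param G Genomic relationship matrix over the same animals in the same
#'   order as `a22`.
#' @return Sparse symmetric H-inverse of class `ss_h_inverse` with attribute
#'   `genotyped`.
#' @export
build_h_inverse <- function(a_inv, a22, G) {
  ids <- rownames(a22)
  if (is.null(ids) || is.null(rownames(G))) {
    stop("a22 and G need animal-id dimnames")
  }
  stopifnot(identical(ids, rownames(G)))
  pos <- match(ids, rownames(a_inv))
  if (anyNA(pos)) stop("genotyped animal(s) not in pedigree A-inverse")
  G_inv <- tryCatch(chol2inv(chol(G)), error = function(e) {
    stop("G is singular; use blend < 1 when building G (", e$message, ")")
  })
  a22_inv <- chol2inv(chol(a22))
  delta <- G_inv - a22_inv
  n <- nrow(a_inv)
  Dlt <- Matrix::sparseMatrix(i = rep(pos, each = length(pos)),
                              j = rep(pos, times = length(pos)),
                              x = as.numeric(t(delta)), dims = c(n, n))
  h_inv <- methods::as(a_inv + Dlt, "generalMatrix")
  dimnames(h_inv) <- dimnames(a_inv)
  attr(h_inv, "genotyped") <- ids
  h_inv
}

#' Solve the mixed-model equations
#'
#' Assembles and solves Henderson's mixed-model equations for the
#' repeated-records animal model with an arbitrary relationship inverse
#' (A-inverse or H-inverse) on the additive effects. Below
#' `direct_threshold` equations a sparse Cholesky factorisation is used;
#' above it, Jacobi-preconditioned conjugate gradients.
#'
#' @param design An `ss_design` from [build_design()].
#' @param k_inv Sparse relationship inverse over `design$animals`.
#' @param vc An [variance_components()] object.
#' @param method `"auto"`, `"direct"` or `"pcg"`.
#' @param tol Relative residual convergence tolerance (default 1e-10).
#' @param max_iter Maximum PCG iterations (default 10000).
#' @param direct_threshold Equation count above which `"auto"` switches to
#'   PCG (default 20000).
#' @return An `ss_fit` object: tibbles `beta` (term, level, estimate,
#'   constrained), `u` (animal, gebv), `pe` (animal, pe), plus solver
#'   diagnostics and record-level fitted fixed effects.
#' @export
solve_mme <- function(design, k_inv, vc, method = c("auto", "direct", "pcg"),
                      tol = 1e-10, max_iter = 10000,
                      direct_threshold = 20000) {
  method <- match.arg(method)
  stopifnot(inherits(design, "ss_design"), inherits(vc, "ss_varcomp"))
  X <- design$X; Z <- design$Z; W <- design$W; y <- design$y
  lambda_u <- vc$s2_e / vc$s2_u
  has_pe <- !is.null(W)
  Tm <- if (has_pe) cbind(X, Z, W) else cbind(X, Z)
  C <- Matrix::crossprod(Tm)
  rhs <- as.numeric(Matrix::crossprod(Tm, y))
  p <- ncol(X); nu <- ncol(Z)
  iu <- p + seq_len(nu)
  C[iu, iu] <- C[iu, iu] + lambda_u * k_inv
  if (has_pe) {
    lambda_p <- vc$s2_e / vc$s2_p
    ip <- p + nu + seq_len(ncol(W))
    C <- C + Matrix::sparseMatrix(i = ip, j = ip, x = lambda_p,
                                  dims = dim(C))
  }
  neq <- ncol(C)
  if (method == "auto") {
    method <- if (neq <= direct_threshold) "direct" else "pcg"
  }
  C <- Matrix::forceSymmetric(C)
  if (method == "direct") {
    sol <- tryCatch(as.numeric(Matrix::solve(C, rhs)),
                    error = function(e) {
                      # Cholesky can fail on a barely-indefinite system; LU
                      as.numeric(Matrix::solve(
                        methods::as(C, "generalMatrix"), rhs))
                    })
    iters <- NA_integer_
  } else {
    pcg <- pcg_solve(C, rhs, tol = tol, max_iter = max_iter)
    sol <- pcg$x
    iters <- pcg$iterations
  }
  resid <- as.numeric(C %*% sol - rhs)
  rel <- sqrt(sum(resid^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)

  beta <- tibble::tibble(term = design$terms, level = design$levels,
                         estimate = sol[seq_len(p)], constrained = FALSE)
  if (nrow(design$constrained) > 0) {
    cons <- dplyr::mutate(design$constrained, estimate = 0, constrained = TRUE)
    cons$level <- paste0(cons$term, cons$level)
    beta <- dplyr::bind_rows(beta, cons)
  }
  u <- tibble::tibble(animal = design$animals, gebv = sol[iu])
  pe <- if (has_pe) {
    tibble::tibble(animal = design$pe_ids, pe = sol[p + nu + seq_along(design$pe_ids)])
  } else {
    tibble::tibble(animal = character(0), pe = numeric(0))
  }
  fitted_fixed <- as.numeric(X %*% sol[seq_len(p)])
  structure(list(beta = beta, u = u, pe = pe,
                 fitted_fixed = fitted_fixed,
                 record_animal = design$record_animal, y = y,
                 diagnostics = list(method = method, iterations = iters,
                                    residual_norm = rel, n_equations = neq),
                 vc = vc),
            class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  d <- x$diagnostics
  cat("<ss_fit> ", nrow(x$u), " breeding values; ", d$n_equations,
      " equations solved by ", d$method,
      sprintf(" (relative residual %.2e)\n", d$residual_norm), sep = "")
  invisible(x)
}

# Jacobi-preconditioned conjugate gradients for SPD sparse systems
pcg_solve <- function(C, b, tol = 1e-10, max_iter = 10000) {
  dinv <- 1 / Matrix::diag(C)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  pvec <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(C %*% pvec)
    alpha <- rz / sum(pvec * Ap)
    x <- x + alpha * pvec
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / bnorm
    history <- c(history, rel)
    if (rel < tol) {
      return(list(x = x, iterations = it, history = history))
    }
    z <- dinv * r
    rz_new <- sum(r * z)
    pvec <- z + (rz_new / rz) * pvec
    rz <- rz_new
  }
  stop("PCG did not converge after ", max_iter, " iterations; ",
       "last relative residuals: ",
       paste(signif(utils::tail(history, 5), 3), collapse = ", "))
}

#' Assemble a data bundle for evaluation
#'
#' @param ped A sorted `ss_pedigree` (or data frame passed to
#'   [as_pedigree()]).
#' @param phenotypes Record-level phenotype table.
#' @param geno Optional `ss_genotypes` of the genotyped animals.
#' @param casein Optional major-gene genotype table
#'   (`animal,allele1,allele2`).
#' @return A list of class `ss_data`.
#' @export
ss_data <- function(ped, phenotypes, geno = NULL, casein = NULL) {
  if (!inherits(ped, "ss_pedigree")) ped <- as_pedigree(ped)
  if (!is.null(geno)) {
    stopifnot(inherits(geno, "ss_genotypes"))
    out <- setdiff(rownames(geno$dosage), ped$animal)
    if (length(out) > 0) stop("genotyped animal(s) not in pedigree: ",
                              paste(utils::head(out, 5), collapse = ", "))
  }
  structure(list(ped = ped, phenotypes = tibble::as_tibble(phenotypes),
                 geno = geno, casein = casein),
            class = "ss_data")
}

#' Run a pedigree or single-step genomic evaluation
#'
#' Solves the repeated-records animal model with the relationship matrix set
#' to A (`mode = "pblup"`) or H (`mode = "ssgblup"`). Phenotype handling is
#' identical in the two modes. With no genotyped animals, ssGBLUP degenerates
#' to pedigree BLUP.
#'
#' @param data An [ss_data()] bundle.
#' @param spec An [model_spec()].
#' @param vc An [variance_components()] object.
#' @param mode `"pblup"` or `"ssgblup"`.
#' @param G Optional precomputed genomic matrix over the genotyped animals
#'   (row order = `rownames(data$geno$dosage)`); built with default blending
#'   if omitted.
#' @param weights Optional per-SNP weights used when `G` must be built.
#' @param blend Blending fraction for a G built here (default 0.95).
#' @param phenotypes Optional replacement record table (e.g. a training
#'   subset); defaults to `data$phenotypes`.
#' @param ... Passed to [solve_mme()].
#' @return An `ss_fit`.
#' @export
run_evaluation <- function(data, spec, vc, mode = c("pblup", "ssgblup"),
                           G = NULL, weights = NULL, blend = 0.95,
                           phenotypes = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "ss_data"))
  ph <- if (is.null(phenotypes)) data$phenotypes else phenotypes
  design <- build_design(ph, spec, data$ped)
  a_inv <- a_inverse(data$ped)
  if (mode == "ssgblup" && !is.null(data$geno) &&
      nrow(data$geno$dosage) > 0) {
    ids <- rownames(data$geno$dosage)
    a22 <- a_submatrix(data$ped, ids)
    if (is.null(G)) {
      p <- allele_freq(data$geno)
      M <- center_genotypes(data$geno, p)
      G <- build_g(M, p, a22 = a22, weights = weights, blend = blend)
    }
    k_inv <- build_h_inverse(a_inv, a22, G)
  } else {
    k_inv <- a_inv
  }
  fit <- solve_mme(design, k_inv, vc, ...)
  fit$mode <- mode
  fit
}
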