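#' Run one evaluation scenario end to end
#'
#' Splits the data by sire birth year, fits the requested method on the
#' training records, computes DYD for the validation sires from the
#' full-data pedigree-BLUP run and reports the validation accuracy. The
#' scenario is deterministic given the data and parameters.
#'
#' @param data An [ss_data()] bundle.
#' @param method One of `"pblup"`, `"ssgblup"`, `"wssgblup"`,
#'   `"wssgblup_max"`, `"wssgblup_sum"`, `"tablup"`, `"gene_content"`.
#' @param spec An [model_spec()].
#' @param vc An [variance_components()] object.
#' @param train_years,valid_years Inclusive sire birth-year ranges.
#' @param iterations WssGBLUP weighting iterations (default 2; the reported
#'   iteration).
#' @param window_size Window size for the Max/Sum variants.
#' @param k,side TABLUP subset size and side (`"top"`/`"bottom"`), or pass
#'   `selection` directly.
#' @param selection Optional `ss_snp_selection` for TABLUP.
#' @param rank_weights Optional weights tibble used to rank SNPs for TABLUP
#'   (defaults to WssGBLUP weights at `iterations`).
#' @param K Genetic covariance for `"gene_content"`
#'   (see [casein_covariance()]).
#' @param blend Blending fraction (default 0.95).
#' @param fit_full Optional precomputed full-data pedigree-BLUP `ss_fit`
#'   (reused across scenarios on the same data).
#' @return A list of class `ss_scenario`: `method`, `params`, `accuracy`,
#'   `n_validation`, `gebv` (validation sires), `dyd`, `fit` and
#'   diagnostics.
#' @export
run_scenario <- function(data, method, spec, vc, train_years, valid_years,
                         iterations = 2, window_size = 1, k = NULL,
                         side = "top", selection = NULL,
                         rank_weights = NULL, K = NULL, blend = 0.95,
                         fit_full = NULL) {
  method <- match.arg(method, c("pblup", "ssgblup", "wssgblup",
                                "wssgblup_max", "wssgblup_sum", "tablup",
                                "gene_content"))
  vsplit <- split_validation(data, train_years, valid_years)
  train <- vsplit$train_phenotypes
  if (is.null(fit_full)) {
    fit_full <- run_evaluation(data, spec, vc, mode = "pblup")
  }
  dyd_tbl <- compute_dyd(fit_full, vsplit)

  fit <- switch(
    method,
    pblup = run_evaluation(data, spec, vc, mode = "pblup",
                           phenotypes = train),
    ssgblup = run_evaluation(data, spec, vc, mode = "ssgblup",
                             blend = blend, phenotypes = train),
    wssgblup = ,
    wssgblup_max = ,
    wssgblup_sum = {
      mode <- switch(method, wssgblup = "none", wssgblup_max = "max",
                     wssgblup_sum = "sum")
      w <- wssgblup(data, spec, vc, n_iter = iterations,
                    window_size = if (mode == "none") 1 else window_size,
                    window_mode = mode, blend = blend, phenotypes = train)
      w$fits[[w$selected + 1]]
    },
    tablup = {
      if (is.null(selection)) {
        if (is.null(rank_weights)) {
          w <- wssgblup(data, spec, vc, n_iter = iterations, blend = blend,
                        phenotypes = train)
          rank_weights <- iteration_weights(w)
        }
        selection <- select_snps(rank_weights, k = k, side = side)
      }
      tablup(data, spec, vc, selection, blend = blend, phenotypes = train)
    },
    gene_content = {
      if (is.null(K)) stop("gene_content requires a K matrix")
      gfit <- gene_content_blup(data, spec, vc, K = K, blend = blend,
                                phenotypes = train)
      structure(list(beta = gfit$beta, u = gfit$u, pe = gfit$pe,
                     diagnostics = gfit$diagnostics, vc = vc,
                     mode = "gene_content"), class = "ss_fit")
    })

  gebv <- fit$u[fit$u$animal %in% dyd_tbl$sire, ]
  acc <- prediction_accuracy(gebv, dyd_tbl)
  structure(list(method = method,
                 params = list(iterations = iterations,
                               window_size = window_size, k = k,
                               side = side, blend = blend),
                 accuracy = acc, n_validation = nrow(dyd_tbl),
                 gebv = gebv, dyd = dyd_tbl, fit = fit,
                 train_years = train_years, valid_years = valid_years),
            class = "ss_scenario")
}

#' @export
print.ss_scenario <- function(x, ...) {
  cat("<ss_scenario> ", x$method, ": validation accuracy ",
      sprintf("%.3f", x$accuracy), " on ", x$n_validation, " sires\n",
      sep = "")
  invisible(x)
}

#' Compare scenarios: accuracy grid and pairwise dependent-correlation tests
#'
#' Builds the method-by-parameter accuracy table and the pairwise
#' Hotelling-Williams matrix over scenarios that share a validation set,
#' with significance stars at the 5, 3 and 1 percent thresholds.
#'
#' @param scenarios A list of `ss_scenario` objects on the same validation
#'   sires.
#' @return A list of class `ss_comparison`: `accuracies` (tibble) and
#'   `tests` (tibble of pairwise t statistics, p values and stars).
#' @export
compare_scenarios <- function(scenarios) {
  stopifnot(length(scenarios) >= 2)
  labs <- purrr::map_chr(scenarios, scenario_label)
  sires <- lapply(scenarios, function(s) sort(s$dyd$sire))
  if (!all(purrr::map_lgl(sires[-1], identical, sires[[1]]))) {
    stop("scenarios were validated on different sire sets")
  }
  acc <- purrr::map_dfr(seq_along(scenarios), function(i) {
    s <- scenarios[[i]]
    tibble::tibble(label = labs[i], method = s$method,
                   window_size = s$params$window_size %||% NA,
                   k = s$params$k %||% NA,
                   accuracy = s$accuracy, n = s$n_validation)
  })
  dyd <- scenarios[[1]]$dyd
  gv <- lapply(scenarios, function(s) {
    s$gebv$gebv[match(dyd$sire, s$gebv$animal)]
  })
  n <- nrow(dyd)
  pairs <- utils::combn(length(scenarios), 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(jj) {
    i <- pairs[1, jj]; j <- pairs[2, jj]
    r12 <- stats::cor(gv[[i]], dyd$dyd)
    r13 <- stats::cor(gv[[j]], dyd$dyd)
    r23 <- stats::cor(gv[[i]], gv[[j]])
    hw <- if (r23 > 1 - 1e-12) {
      # identical predictions: no test to run
      tibble::tibble(estimate = r12 - r13, statistic = 0, p.value = 1,
                     parameter = n - 3)
    } else {
      hotelling_williams(r12, r13, r23, n)
    }
    tibble::tibble(method_1 = labs[i], method_2 = labs[j],
                   r1 = r12, r2 = r13,
                   statistic = hw$statistic, p.value = hw$p.value,
                   stars = significance_stars(hw$p.value))
  })
  structure(list(accuracies = acc, tests = tests), class = "ss_comparison")
}

scenario_label <- function(s) {
  extra <- switch(s$method,
                  wssgblup_max = ,
                  wssgblup_sum = paste0("(w=", s$params$window_size, ")"),
                  tablup = paste0("(", s$params$side, "-", s$params$k, ")"),
                  "")
  paste0(s$method, extra)
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "***", p < 0.03 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "NS")
}

#' @export
print.ss_comparison <- function(x, ...) {
  cat("Validation accuracies:\n")
  print(as.data.frame(x$accuracies[, c("label", "accuracy", "n")]),
        row.names = FALSE)
  cat("\nPairwise Hotelling-Williams tests (*5%, **3%, ***1%):\n")
  print(as.data.frame(x$tests[, c("method_1", "method_2", "statistic",
                                  "p.value", "stars")]), row.names = FALSE)
  invisible(x)
}

#' Replicated signal-recovery study on simulated populations
#'
#' Runs the full comparative design on independently simulated populations:
#' for each replicate it simulates a population with a major locus, fits
#' pedigree BLUP, ssGBLUP and two WssGBLUP weighting iterations on the
#' training records, evaluates all of them against DYD of the validation
#' sires, and summarises where the SNP weights concentrate. A ssGBLUP run
#' without the causal chromosome quantifies the information carried by that
#' region.
#'
#' @param seeds Integer vector of simulation seeds (one replicate each).
#' @param cfg_base An [sim_config()]; its `seed` is replaced per replicate.
#' @param train_years,valid_years Sire birth-year split.
#' @param flank Number of SNPs around the major locus summarised as the
#'   flanking window (default 40).
#' @param spec,vc Model specification and variance components (defaults
#'   match the simulator's generative model).
#' @return A tibble with one row per replicate: accuracies of the four
#'   evaluations, the mean weight of the flanking SNPs (genome mean = 1),
#'   and the fraction of the top-50 weighted SNPs on the causal chromosome.
#' @export
signal_recovery <- function(seeds, cfg_base = sim_config(),
                            train_years = c(0, 5), valid_years = c(6, 10),
                            flank = 40,
                            spec = model_spec("protein",
                                              fixed = c("herd_year",
                                                        "parity")),
                            vc = variance_components(
                              h2 = cfg_base$h2,
                              repeatability = cfg_base$repeatability,
                              phenotypic_var = cfg_base$sigma_p^2)) {
  purrr::map_dfr(seeds, function(s) {
    cfg <- cfg_base
    cfg$seed <- s
    sim <- sim_population(cfg)
    fit_full <- run_evaluation(sim$data, spec, vc, mode = "pblup")
    vsplit <- split_validation(sim$data, train_years, valid_years)
    dyd <- compute_dyd(fit_full, vsplit)
    train <- vsplit$train_phenotypes

    fit_p <- run_evaluation(sim$data, spec, vc, mode = "pblup",
                            phenotypes = train)
    w <- wssgblup(sim$data, spec, vc, n_iter = 2, phenotypes = train)
    fit_s <- w$fits[[1]]       # iteration 0 = unweighted ssGBLUP
    fit_w <- w$fits[[w$selected + 1]]
    sel <- exclude_chromosome(sim$data$geno$map, cfg$major_chr)
    fit_x <- tablup(sim$data, spec, vc, sel, phenotypes = train)

    wt <- iteration_weights(w)  # weights of the reported (second-run) D
    on_chr <- which(wt$chr == cfg$major_chr)
    near <- on_chr[order(abs(wt$pos[on_chr] - cfg$major_pos_bp))]
    near <- near[seq_len(min(flank, length(near)))]
    tibble::tibble(
      seed = s,
      n_validation = nrow(dyd),
      acc_pblup = prediction_accuracy(fit_p$u, dyd),
      acc_ssgblup = prediction_accuracy(fit_s$u, dyd),
      acc_wssgblup = prediction_accuracy(fit_w$u, dyd),
      acc_excl_causal = prediction_accuracy(fit_x$u, dyd),
      flank_mean_weight = mean(wt$weight[near]),
      genome_mean_weight = mean(wt$weight),
      top50_causal_frac = mean(top_snps(wt, 50)$chr == cfg$major_chr))
  })
}
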