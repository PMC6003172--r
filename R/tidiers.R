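#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mixed-model fit
#'
#' Returns one row per solved effect: fixed-effect levels (including the
#' constrained ones at zero), breeding values and permanent-environment
#' effects.
#'
#' @param x An `ss_fit`.
#' @param effects Which effect groups to return.
#' @param ... Unused.
#' @return A tibble with columns `effect`, `level`, `estimate`.
#' @export
tidy.ss_fit <- function(x, effects = c("fixed", "animal", "pe"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    out$fixed <- tibble::tibble(effect = x$beta$term, level = x$beta$level,
                                estimate = x$beta$estimate)
  }
  if ("animal" %in% effects) {
    out$animal <- tibble::tibble(effect = "animal", level = x$u$animal,
                                 estimate = x$u$gebv)
  }
  if ("pe" %in% effects && nrow(x$pe) > 0) {
    out$pe <- tibble::tibble(effect = "permanent_env", level = x$pe$animal,
                             estimate = x$pe$pe)
  }
  dplyr::bind_rows(out)
}

#' Glance at a mixed-model fit
#'
#' @param x An `ss_fit`.
#' @param ... Unused.
#' @return A one-row tibble of solver diagnostics.
#' @export
glance.ss_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(mode = x$mode %||% NA_character_,
                 n_equations = d$n_equations,
                 n_records = length(x$y),
                 method = d$method,
                 residual_norm = d$residual_norm)
}

#' Tidy WssGBLUP weights
#'
#' @param x An `ss_wssgblup`.
#' @param ... Unused.
#' @return The long weights tibble (`snp_id,chr,pos,iteration,weight`).
#' @export
tidy.ss_wssgblup <- function(x, ...) x$weights

#' Glance at a WssGBLUP run
#'
#' @param x An `ss_wssgblup`.
#' @param ... Unused.
#' @return One-row tibble: iterations, window scheme, SNP count, weight sum
#'   at the reported iteration.
#' @export
glance.ss_wssgblup <- function(x, ...) {
  w <- iteration_weights(x)
  tibble::tibble(iterations = length(x$fits) - 1,
                 selected = x$selected,
                 window_mode = x$window$mode,
                 window_size = x$window$size,
                 n_snps = nrow(x$map),
                 weight_sum = sum(w$weight))
}

#' Tidy a gene-content fit
#'
#' @param x An `ss_gene_content_fit`.
#' @param ... Unused.
#' @return Long tibble of predicted gene contents (`animal,allele,content`).
#' @export
tidy.ss_gene_content_fit <- function(x, ...) {
  tidyr::pivot_longer(x$content, -"animal", names_to = "allele",
                      names_prefix = "content_", values_to = "content")
}

#' Plot SNP weights along the genome
#'
#' Manhattan-style plot of the per-SNP weights at one iteration, faceted
#' implicitly by alternating chromosome shading.
#'
#' @param object An `ss_wssgblup`.
#' @param iteration Iteration to plot (default the reported one).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_wssgblup <- function(object, iteration = object$selected, ...) {
  w <- iteration_weights(object, iteration)
  w <- dplyr::mutate(dplyr::group_by(w, .data$chr),
                     posx = .data$pos / max(.data$pos) + .data$chr - 1)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$posx, y = .data$weight,
                                  colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue4")) +
    ggplot2::labs(x = "chromosome", y = paste0("SNP weight (iteration ",
                                               iteration, ")")) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(unique(w$chr)) - 0.5,
      labels = sort(unique(w$chr))) +
    ggplot2::theme_minimal()
}

#' Plot a scenario comparison
#'
#' Bar chart of validation accuracies per method/parameter combination.
#'
#' @param object An `ss_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_comparison <- function(object, ...) {
  acc <- object$accuracies
  ggplot2::ggplot(acc, ggplot2::aes(x = stats::reorder(.data$label,
                                                       .data$accuracy),
                                    y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue4", width = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "validation accuracy (Pearson r)") +
    ggplot2::theme_minimal()
}
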