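#' Select SNPs by weight rank
#'
#' Picks the `k` largest- (or smallest-) weighted SNPs; ties are broken by
#' map order. Top-k and bottom-(m-k) selections partition the map.
#'
#' @param weights Tibble with columns `snp_id`, `chr`, `pos`, `weight` in
#'   map order (e.g. [iteration_weights()]).
#' @param k Number of SNPs to retain (1 <= k <= m).
#' @param side `"top"` (largest weights) or `"bottom"`.
#' @return An `ss_snp_selection`: tibble of the retained SNPs in map order
#'   with a `provenance` attribute.
#' @export
select_snps <- function(weights, k, side = c("top", "bottom")) {
  side <- match.arg(side)
  m <- nrow(weights)
  if (k < 1 || k > m) stop("k must be between 1 and ", m)
  ord <- if (side == "top") {
    order(-weights$weight, seq_len(m))
  } else {
    order(weights$weight, seq_len(m))
  }
  pick <- sort(ord[seq_len(k)])
  out <- weights[pick, c("snp_id", "chr", "pos")]
  structure(out, provenance = paste0(side, "-", k),
            class = c("ss_snp_selection", class(out)))
}

#' Retain all SNPs except one chromosome
#'
#' @param map SNP map tibble (`snp_id`, `chr`, `pos`).
#' @param chromosome Chromosome to exclude; must be present in the map.
#' @return An `ss_snp_selection` of the SNPs on the other chromosomes.
#' @export
exclude_chromosome <- function(map, chromosome) {
  if (!chromosome %in% map$chr) {
    stop("chromosome ", chromosome, " not present in map")
  }
  out <- map[map$chr != chromosome, c("snp_id", "chr", "pos")]
  if (nrow(out) == 0) stop("excluding chromosome ", chromosome,
                           " leaves no SNPs")
  structure(out, provenance = paste0("exclude-chr-", chromosome),
            class = c("ss_snp_selection", class(out)))
}

#' Read/write SNP selection lists (one snp id per line)
#'
#' @param selection An `ss_snp_selection` (for writing).
#' @param path File path.
#' @param map Map used to resolve ids when reading.
#' @return [write_snp_selection()] returns the selection invisibly;
#'   [read_snp_selection()] returns an `ss_snp_selection`.
#' @export
write_snp_selection <- function(selection, path) {
  writeLines(selection$snp_id, path)
  invisible(selection)
}

#' @rdname write_snp_selection
#' @export
read_snp_selection <- function(path, map) {
  ids <- readLines(path)
  miss <- setdiff(ids, map$snp_id)
  if (length(miss) > 0) stop("snp id(s) not in map: ",
                             paste(utils::head(miss, 5), collapse = ", "))
  out <- map[map$snp_id %in% ids, c("snp_id", "chr", "pos")]
  structure(out, provenance = "explicit-list",
            class = c("ss_snp_selection", class(out)))
}

#' Single-step evaluation on a SNP subset (TABLUP)
#'
#' Rebuilds the genomic relationship matrix from the selected SNPs only,
#' with equal weights (D = I); allele frequencies and the scaling constant
#' k are recomputed on the subset so G stays properly scaled, and the usual
#' blending with A22 is applied. With the full map this is exactly ssGBLUP.
#'
#' @param data An [ss_data()] bundle with genotypes.
#' @param spec An [model_spec()].
#' @param vc An [variance_components()] object.
#' @param selection An `ss_snp_selection` (non-empty).
#' @param blend Blending fraction (default 0.95).
#' @param phenotypes Optional replacement record table.
#' @param ... Passed to [solve_mme()].
#' @return An `ss_fit`.
#' @export
tablup <- function(data, spec, vc, selection, blend = 0.95,
                   phenotypes = NULL, ...) {
  stopifnot(inherits(data, "ss_data"), !is.null(data$geno))
  if (nrow(selection) == 0) stop("empty SNP selection")
  keep <- data$geno$map$snp_id %in% selection$snp_id
  sub <- genotypes(data$geno$dosage[, keep, drop = FALSE],
                   data$geno$map[keep, , drop = FALSE])
  sub_data <- data
  sub_data$geno <- sub
  run_evaluation(sub_data, spec, vc, mode = "ssgblup", blend = blend,
                 phenotypes = phenotypes, ...)
}
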