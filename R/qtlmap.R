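#' Weight-index mapping factor
#'
#' Ratio of output-layer weight count to SNP count. Because the conv stride
#' and pooling shrink positions by `stride * pool` while the filters expand
#' each position `q`-fold, a SNP at index `s` influences output weights near
#' `s * factor`. For the 9,723-SNP architecture with 64 filters the factor
#' is 155,584 / 9,723 = 16.002; it is conventionally quoted, and used in the
#' index arithmetic, at three decimals.
#'
#' @param n_weights Number of output-layer weights (flatten size).
#' @param p Number of SNPs in the input layer.
#' @param digits Decimals the factor is quoted at (default 3;
#'   `digits = NULL` returns the full-precision ratio).
#' @return The mapping factor.
#' @examples
#' mapping_factor(155584, 9723)
#' @export
mapping_factor <- function(n_weights, p, digits = 3) {
  if (n_weights < 1 || p < 1) stopf("n_weights and p must both be >= 1")
  f <- n_weights / p
  if (is.null(digits)) f else round(f, digits)
}

#' Map a SNP index to its output-layer weight index
#'
#' `round(snp_index * factor)`, rounding half away from zero; both axes are
#' 1-based.
#'
#' @param snp_index 1-based SNP index (vectorized).
#' @param factor Mapping factor from [mapping_factor()].
#' @param p Optional SNP count for range checking.
#' @return 1-based weight index.
#' @examples
#' snp_to_weight_index(931, 16.002)
#' @export
snp_to_weight_index <- function(snp_index, factor, p = NULL) {
  if (any(snp_index < 1)) stopf("snp_index must be >= 1")
  if (!is.null(p) && any(snp_index > p)) stopf("snp_index out of [1, p]")
  round_half_away(snp_index * factor)
}

#' Map an output-layer weight index back to a SNP index
#'
#' Default is plain rounding of `weight_index / factor` (clamped to
#' `[1, p]` when `p` is given); `method = "truncate"` floors instead, which
#' reproduces quoted back-mappings computed by truncation.
#'
#' @param weight_index 1-based weight index (vectorized).
#' @param factor Mapping factor.
#' @param p Optional SNP count for clamping.
#' @param method `"round"` (default) or `"truncate"`.
#' @return 1-based SNP index.
#' @export
weight_to_snp_index <- function(weight_index, factor, p = NULL,
                                method = c("round", "truncate")) {
  method <- match.arg(method)
  if (any(weight_index < 1)) stopf("weight_index must be >= 1")
  s <- if (method == "round") round_half_away(weight_index / factor)
       else floor(weight_index / factor)
  s <- pmax(s, 1)
  if (!is.null(p)) s <- pmin(s, p)
  s
}

#' Weight map for QTL localization
#'
#' Bundles the (model-averaged) output-layer weights with the SNP count and
#' the resulting mapping factor.
#'
#' @param weights Numeric vector of output-layer weights (e.g.
#'   `ensemble_result$weights_ma`).
#' @param p Number of SNPs in the input layer.
#' @return Object of class `weight_map`.
#' @export
weight_map <- function(weights, p) {
  structure(list(weights = as.numeric(weights), p = as.integer(p),
                 factor = mapping_factor(length(weights), p)),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("weight_map: %d weights over %d SNPs (factor %.3f)\n",
              length(x$weights), x$p, x$factor))
  invisible(x)
}

#' Extract candidate QTL peaks from output-layer weights
#'
#' Ranks weights by absolute value and reports those exceeding a threshold
#' (default: the `top_k` largest that also exceed `3 x` the median absolute
#' weight), each annotated with its mapped SNP index. Peaks are defined on
#' `|weight|`, so the extraction is equivariant under weight negation.
#'
#' @param wmap A [weight_map] (or a numeric weight vector plus `p`).
#' @param top_k Keep at most this many peaks (default 20).
#' @param threshold Absolute-weight cutoff; default `3 * median(|w|)`.
#' @param p SNP count when `wmap` is a bare numeric vector.
#' @return Data frame (`rank`, `weight_index`, `snp_index`, `weight`)
#'   sorted by `|weight|` descending.
#' @export
extract_peaks <- function(wmap, top_k = 20L, threshold = NULL, p = NULL) {
  if (!inherits(wmap, "weight_map")) {
    if (is.null(p)) stopf("supply a weight_map or a weight vector plus p")
    wmap <- weight_map(wmap, p)
  }
  w <- wmap$weights
  aw <- abs(w)
  threshold <- threshold %||% (3 * stats::median(aw))
  idx <- which(aw > threshold)
  if (length(idx) == 0) {
    return(data.frame(rank = integer(0), weight_index = integer(0),
                      snp_index = integer(0), weight = numeric(0)))
  }
  idx <- idx[order(aw[idx], decreasing = TRUE)]
  idx <- head(idx, top_k)
  data.frame(rank = seq_along(idx), weight_index = idx,
             snp_index = as.integer(weight_to_snp_index(idx, wmap$factor,
                                                        p = wmap$p)),
             weight = w[idx])
}
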