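# Model selection: least-squares AIC over ensembles and the statistical
# comparisons used to rank model variants.

#' Akaike information criterion for a least-squares fit
#'
#' `AIC = n * ln(SSE/n) + 2k`, with the small-sample correction
#' `AICc = AIC + 2k(k+1)/(n-k-1)` reported alongside (undefined and
#' flagged when `n <= k + 1`).
#'
#' @param sse residual sum of squares (`> 0`).
#' @param n_points number of data points.
#' @param n_params number of fitted parameters.
#' @return list with `aic`, `aicc`, `aicc_defined`.
#' @export
aic_score <- function(sse, n_points, n_params) {
  stopifnot(sse > 0, n_points > 0, n_params >= 0)
  aic <- n_points * log(sse / n_points) + 2 * n_params
  defined <- n_points > n_params + 1
  aicc <- if (defined) {
    aic + 2 * n_params * (n_params + 1) / (n_points - n_params - 1)
  } else NA_real_
  list(aic = aic, aicc = aicc, aicc_defined = defined)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; adjusted p-values via
#' [stats::p.adjust()] with rejection flags at the given FDR.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param fdr false discovery rate (default 0.05).
#' @return list with `adjusted` and `reject`.
#' @export
benjamini_hochberg <- function(p_values, fdr = 0.05) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = adj <= fdr)
}

#' AIC values of every ensemble member of a fit
#'
#' The SSE is the weighted objective restored to a per-residual sum (the
#' per-experiment normalized objective times the residual count), and `k`
#' is the number of freed constants.
#'
#' @param fit `phos_fit`.
#' @return numeric vector of AIC values, one per ensemble member.
#' @export
ensemble_aic <- function(fit) {
  n <- .n_residuals(fit)
  k <- length(fit$ensemble$parmap$names)
  vapply(fit$ensemble$objective, function(obj) {
    aic_score(max(obj, 1e-300) * n, n, k)$aic
  }, numeric(1))
}

#' Compare model variants by ensemble AIC
#'
#' Computes AIC per ensemble member per variant, then all pairwise
#' two-sided Mann-Whitney tests plus a one-way ANOVA on the log2-normalized
#' AIC distributions; pairwise p-values are Benjamini-Hochberg adjusted.
#' A variant is judged superior when its AIC is significantly lower.
#'
#' @param fits named list of `phos_fit` objects (the names label the
#'   variants), each with an ensemble of at least 3 members.
#' @param fdr false discovery rate for the pairwise verdicts.
#' @return object of class `phos_model_comparison`: a pairwise table and
#'   the ANOVA p-value.
#' @export
compare_variants <- function(fits, fdr = 0.05) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$variant, "")
  }
  aics <- lapply(fits, ensemble_aic)
  stopifnot(all(lengths(aics) >= 3))
  # log2 normalization for the ANOVA: shift to positive support, then log2
  allv <- unlist(aics)
  shift <- min(allv) - 1
  log2n <- lapply(aics, function(a) log2(a - shift))
  grp <- factor(rep(names(fits), lengths(log2n)))
  anova_p <- summary(stats::aov(unlist(log2n) ~ grp))[[1]][["Pr(>F)"]][1]
  pairs <- utils::combn(names(fits), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    identical_dist <- isTRUE(all.equal(sort(aics[[a]]), sort(aics[[b]])))
    p <- if (identical_dist) 1 else {
      suppressWarnings(
        stats::wilcox.test(aics[[a]], aics[[b]], exact = TRUE)$p.value)
    }
    data.frame(variant_a = a, variant_b = b,
               median_aic_a = stats::median(aics[[a]]),
               median_aic_b = stats::median(aics[[b]]),
               p_raw = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bh <- benjamini_hochberg(tab$p_raw, fdr)
  tab$p_adj <- bh$adjusted
  tab$verdict <- ifelse(!bh$reject, "indistinguishable",
                        ifelse(tab$median_aic_a < tab$median_aic_b,
                               tab$variant_a, tab$variant_b))
  structure(list(table = tab, anova_p = anova_p, aics = aics),
            class = "phos_model_comparison")
}

#' @export
print.phos_model_comparison <- function(x, ...) {
  cat("Model comparison by ensemble AIC (ANOVA on log2-normalized AIC: p =",
      signif(x$anova_p, 3), ")\n")
  print(transform(x$table,
                  median_aic_a = signif(median_aic_a, 4),
                  median_aic_b = signif(median_aic_b, 4),
                  p_raw = signif(p_raw, 3), p_adj = signif(p_adj, 3)),
        row.names = FALSE)
  invisible(x)
}
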