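#' Per-sample window DGV vectors
#'
#' For each stored posterior sample, the across-animal vector of window
#' genomic values `sum over member SNPs of dosage times sampled effect`,
#' centered per sample.
#'
#' @param fit A [wgr_fit()] object.
#' @param genotypes Dosage matrix used for the fit.
#' @param windows Window assignment from [assign_windows()].
#' @param window_id Window label, e.g. `"19_51"`.
#' @return Matrix (animals x stored samples) of centered window DGVs.
#' @export
window_dgv_samples <- function(fit, genotypes, windows, window_id) {
  members <- windows$snp_id[windows$window_id == window_id]
  if (length(members) == 0) abort(paste("window", window_id, "has no SNPs"))
  window_dgv_matrix(fit, genotypes, members)
}

#' Within-window DGV correlation between two traits
#'
#' Probes pleiotropy of a QTL window: the two traits are fitted in
#' independent chains (stored samples paired by index), and the
#' correlation is formed from posterior means of the per-sample
#' across-animal covariances and variances of the window DGVs:
#' `mean_s cov(a_s, b_s) / sqrt(mean_s var(a_s) * mean_s var(b_s))`,
#' clamped to `[-1, 1]`.
#'
#' @param fit_a,fit_b Two [wgr_fit()] objects over the same animals with
#'   equal stored-sample counts.
#' @param genotypes Dosage matrix common to both fits.
#' @param windows Window assignment.
#' @param window_id Window label.
#' @param method `"posterior"` (default: posterior-mean covariance over
#'   per-sample window DGVs) or `"point"` (correlate the posterior-mean
#'   window DGVs across animals).
#' @return Tibble `window_id`, `trait_a`, `trait_b`, `correlation`,
#'   `n_samples`; `correlation` is `NA` (with warning) when either
#'   trait's mean window variance is zero.
#' @export
region_correlation <- function(fit_a, fit_b, genotypes, windows, window_id,
                               method = c("posterior", "point")) {
  method <- match.arg(method)
  if (fit_a$n_stored != fit_b$n_stored) {
    abort("fits must store the same number of samples (paired by index)")
  }
  A <- window_dgv_samples(fit_a, genotypes, windows, window_id)
  B <- window_dgv_samples(fit_b, genotypes, windows, window_id)
  n <- nrow(A)
  S <- ncol(A)
  if (method == "posterior") {
    cov_s <- colSums(A * B) / (n - 1)
    var_a <- colSums(A^2) / (n - 1)
    var_b <- colSums(B^2) / (n - 1)
    den <- sqrt(mean(var_a) * mean(var_b))
    if (den == 0) {
      warn(sprintf("window %s has zero mean DGV variance for one trait: correlation NA",
                   window_id))
      r <- NA_real_
    } else {
      r <- mean(cov_s) / den
      r <- max(-1, min(1, r))
    }
  } else {
    a <- rowMeans(A)
    b <- rowMeans(B)
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }
  tibble::tibble(window_id = window_id, trait_a = fit_a$trait,
                 trait_b = fit_b$trait, correlation = r, n_samples = S)
}

#' Within-window DGV correlations for a set of traits and windows
#'
#' Convenience wrapper building the full lower-triangle grid of trait-pair
#' correlations for each window (the typical report set is the de novo
#' synthesis fatty acids at the few windows that dominate their genetic
#' variance).
#'
#' @param fits Named list of [wgr_fit()] objects (names = trait labels).
#' @param genotypes Dosage matrix common to all fits.
#' @param windows Window assignment.
#' @param window_ids Window labels to report.
#' @inheritParams region_correlation
#' @return A `region_cor` tibble in long format: `window_id`, `trait_a`,
#'   `trait_b`, `correlation`, `n_samples`.
#' @export
region_correlation_grid <- function(fits, genotypes, windows, window_ids,
                                    method = "posterior") {
  pairs <- tidyr::expand_grid(a = seq_along(fits), b = seq_along(fits)) |>
    dplyr::filter(.data$a <= .data$b)
  out <- purrr::map_dfr(window_ids, function(wid) {
    purrr::map2_dfr(pairs$a, pairs$b, function(i, j) {
      region_correlation(fits[[i]], fits[[j]], genotypes, windows, wid,
                         method = method)
    })
  })
  class(out) <- c("region_cor", class(out))
  out
}

#' @export
autoplot.region_cor <- function(object, ...) {
  sym <- dplyr::bind_rows(
    object,
    dplyr::rename(dplyr::filter(object, .data$trait_a != .data$trait_b),
                  trait_a = "trait_b", trait_b = "trait_a")
  )
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$trait_a, y = .data$trait_b,
                                    fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$correlation)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1), name = "r") +
    ggplot2::facet_wrap(~window_id) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
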