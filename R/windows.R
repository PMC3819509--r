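#' Assign SNPs to 1-Mb windows
#'
#' Window labels are `"chrom_Mb"` with the megabase index
#' `floor(position_bp / window_size_bp)` (0-based, so a SNP at
#' 51,384,922 bp on chromosome 19 falls in window `19_51`).  Unmapped SNPs
#' (missing chromosome or position) are pooled into the single extra
#' window `"unmapped"`.
#'
#' @param map SNP map tibble (`snp_id`, `chromosome`, `position_bp`).
#' @param window_size_bp Window size; default 1 Mb.
#' @param snp_ids Optional vector of SNP ids that must be covered (e.g.
#'   the genotype matrix columns); SNPs absent from the map are assigned
#'   to the unmapped window with a warning.
#' @return Tibble `snp_id`, `chromosome`, `position_bp`, `window_id`, in
#'   map order (then any map-absent SNPs).
#' @export
assign_windows <- function(map, window_size_bp = 1e6, snp_ids = NULL) {
  map <- tibble::as_tibble(map)
  if (!is.null(snp_ids)) {
    extra <- setdiff(snp_ids, map$snp_id)
    if (length(extra) > 0) {
      warn(sprintf("%d SNP(s) in genotypes absent from map: assigned to the unmapped window",
                   length(extra)))
      map <- dplyr::bind_rows(map, tibble::tibble(
        snp_id = extra, chromosome = NA_character_, position_bp = NA_real_
      ))
    }
    map <- map[map$snp_id %in% snp_ids, , drop = FALSE]
  }
  dplyr::mutate(
    map,
    window_id = dplyr::if_else(
      is.na(.data$chromosome) | is.na(.data$position_bp),
      "unmapped",
      paste0(.data$chromosome, "_", floor(.data$position_bp / window_size_bp))
    )
  )
}

# Per-sample window DGV variance fractions and PPI shared by window_scan()
# and the region-correlation routines.  Returns, for one window, the
# n_animals x n_stored matrix of centered window DGVs.
window_dgv_matrix <- function(fit, genotypes, member_snps) {
  idx <- match(member_snps, colnames(genotypes))
  if (length(idx) == 0 || anyNA(idx)) {
    abort("window has no member SNPs present in the genotype matrix")
  }
  W <- genotypes[, idx, drop = FALSE] %*% t(fit$chain$u[, idx, drop = FALSE])
  sweep(W, 2, colMeans(W))
}

col_vars <- function(m) colSums(m^2) / (nrow(m) - 1)  # columns pre-centered

#' Window genetic variance and posterior probability of inclusion
#'
#' For every stored posterior sample the genomic value of each animal is
#' computed window by window (`sum over member SNPs of dosage times the
#' sampled effect`); the across-animal variance of these window DGVs,
#' divided by the variance of the total DGV in the same sample, is that
#' sample's window variance fraction.  The reported percentage is the
#' posterior mean of the per-sample fractions (x100).  PPI is the fraction
#' of stored samples in which at least one member SNP has a nonzero
#' effect.  Samples with zero total genetic variance are skipped for the
#' variance fraction (their count is recorded in `n_skipped`).
#'
#' @param fit A [wgr_fit()] object.
#' @param genotypes Dosage matrix used for the fit.
#' @param windows Window assignment from [assign_windows()].
#' @return A `window_scan` tibble: `window_id`, `chromosome`, `n_snps`,
#'   `start_snp`, `end_snp`, `genetic_variance_pct`, `ppi`, `n_skipped`.
#' @export
window_scan <- function(fit, genotypes, windows) {
  U <- fit$chain$u
  S <- nrow(U)
  Gtot <- genotypes %*% t(U)
  Gtot <- sweep(Gtot, 2, colMeans(Gtot))
  v_tot <- col_vars(Gtot)
  keep <- v_tot > 0

  by_window <- windows |>
    dplyr::arrange(.data$window_id == "unmapped", .data$chromosome,
                   .data$position_bp) |>
    dplyr::group_by(.data$window_id) |>
    dplyr::summarise(
      chromosome = dplyr::first(.data$chromosome),
      n_snps = dplyr::n(),
      start_snp = dplyr::first(.data$snp_id),
      end_snp = dplyr::last(.data$snp_id),
      snps = list(.data$snp_id),
      .groups = "drop"
    )

  res <- purrr::pmap_dfr(
    list(by_window$window_id, by_window$snps),
    function(wid, snps) {
      idx <- match(snps, colnames(genotypes))
      idx <- idx[!is.na(idx)]
      Usub <- U[, idx, drop = FALSE]
      ppi <- mean(rowSums(Usub != 0) > 0)
      Gw <- genotypes[, idx, drop = FALSE] %*% t(Usub)
      Gw <- sweep(Gw, 2, colMeans(Gw))
      v_w <- col_vars(Gw)
      frac <- if (any(keep)) mean(v_w[keep] / v_tot[keep]) else NA_real_
      tibble::tibble(window_id = wid, ppi = ppi,
                     genetic_variance_pct = 100 * frac,
                     n_skipped = S - sum(keep))
    }
  )

  out <- by_window |>
    dplyr::select(-"snps") |>
    dplyr::left_join(res, by = "window_id") |>
    dplyr::relocate("genetic_variance_pct", "ppi", .after = "end_snp")
  class(out) <- c("window_scan", class(out))
  out
}

#' Select QTL-bearing windows by PPI
#'
#' Keeps windows whose posterior probability of inclusion strictly exceeds
#' the threshold (a window at exactly the threshold is excluded), sorted
#' by percent genetic variance, descending.
#'
#' @param scan A [window_scan()] result.
#' @param threshold PPI threshold, default 0.90.
#' @return Filtered, sorted `window_scan` tibble.
#' @export
significant_windows <- function(scan, threshold = 0.90) {
  out <- scan |>
    dplyr::filter(.data$ppi > threshold) |>
    dplyr::arrange(dplyr::desc(.data$genetic_variance_pct))
  class(out) <- unique(c("window_scan", class(out)))
  out
}

#' @export
autoplot.window_scan <- function(object, ppi_threshold = 0.90, ...) {
  df <- dplyr::filter(object, .data$window_id != "unmapped")
  df$significant <- df$ppi > ppi_threshold
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$window_id, y = .data$genetic_variance_pct,
    fill = .data$chromosome, alpha = .data$significant
  )) +
    ggplot2::geom_col(show.legend = c(fill = FALSE, alpha = TRUE)) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                name = sprintf("PPI > %.2f", ppi_threshold)) +
    ggplot2::labs(x = "1-Mb window", y = "Genetic variance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}
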