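#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = M M' / (2 sum p_j (1 - p_j))` with `M` the dosage matrix whose
#' columns are centered at twice the observed allele frequency.
#' Monomorphic SNPs contribute nothing to the numerator (their centered
#' column is zero) and are excluded from the denominator sum.
#'
#' @param genotypes Dosage matrix (animals x SNPs), missing values
#'   mean-imputed first.
#' @return Symmetric n x n matrix with animal ids as dimnames; rows sum
#'   to zero by construction.
#' @export
compute_grm <- function(genotypes) {
  genotypes <- impute_dosages(genotypes)
  if (nrow(genotypes) < 2) abort("need at least two animals for a GRM")
  p <- colMeans(genotypes) / 2
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  if (denom <= 0) abort("all SNPs are monomorphic: GRM denominator is zero")
  M <- sweep(genotypes, 2, 2 * p)
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  G
}

#' K-means validation folds from genomic relationships
#'
#' Animals are clustered so genomic relatedness is high within and low
#' between folds, which favors detecting linkage disequilibrium over mere
#' family linkage in cross-validation.  The GRM is turned into the squared
#' genomic distance `d_ij = g_ii + g_jj - 2 g_ij`; animals are embedded as
#' the rows of this distance matrix (or via classical MDS of it) and
#' clustered with Hartigan-Wong K-means (`K = 6`, 25 restarts, best
#' within-cluster SS kept).  The two smallest clusters are merged, giving
#' the standard 5 unequally sized folds.
#'
#' @param grm Genomic relationship matrix from [compute_grm()].
#' @param k Number of K-means clusters before merging (default 6).
#' @param n_folds Number of folds after merging small clusters (default 5).
#' @param nstart Random restarts for K-means.
#' @param embed `"distance_rows"` (default) or `"mds"`.
#' @param seed Optional integer seed.
#' @return Tibble `animal_id`, `cluster` (original K-means label),
#'   `fold` (1..`n_folds`).
#' @export
kmeans_folds <- function(grm, k = 6, n_folds = 5, nstart = 25,
                         embed = c("distance_rows", "mds"), seed = NULL) {
  embed <- match.arg(embed)
  n <- nrow(grm)
  if (k > n) abort("more clusters than animals")
  if (!is.null(seed)) set.seed(seed)
  d <- outer(diag(grm), diag(grm), "+") - 2 * grm
  coords <- switch(embed,
    distance_rows = d,
    mds = stats::cmdscale(stats::as.dist(d), k = min(n - 1, 10))
  )
  km <- tryCatch(
    stats::kmeans(coords, centers = k, nstart = nstart, iter.max = 100,
                  algorithm = "Hartigan-Wong"),
    error = function(e) abort(paste("K-means failed to find", k, "nonempty clusters:",
                                    conditionMessage(e)))
  )
  sizes <- table(km$cluster)
  if (length(sizes) < k) abort("K-means produced fewer nonempty clusters than requested")
  # merge the smallest clusters until n_folds remain
  ord <- order(sizes)          # ascending size
  fold_of <- integer(k)
  n_merge <- k - n_folds + 1
  fold_of[as.integer(names(sizes)[ord[seq_len(n_merge)]])] <- n_folds
  big <- as.integer(names(sizes)[ord[-seq_len(n_merge)]])
  fold_of[big[order(-sizes[as.character(big)])]] <- seq_len(n_folds - 1)
  tibble::tibble(
    animal_id = rownames(grm) %||% as.character(seq_len(n)),
    cluster = unname(km$cluster),
    fold = fold_of[km$cluster]
  )
}

#' Realized accuracy of genomic prediction
#'
#' @param pooled_r Pooled validation correlation between DGV and
#'   phenotype.
#' @param h2 Trait heritability in (0, 1].
#' @return `pooled_r / sqrt(h2)` (sign preserved).
#' @export
realized_accuracy <- function(pooled_r, h2) {
  if (any(h2 <= 0)) abort("heritability must be positive for realized accuracy")
  pooled_r / sqrt(h2)
}

#' Leave-one-group-out cross-validation of DGV
#'
#' For each fold, marker effects are estimated on the remaining folds and
#' used to predict DGV of the held-out animals.  Held-out phenotypes are
#' adjusted by the training-estimated fixed effects before comparison
#' (raw phenotypes would confound contemporary-group differences with the
#' genomic signal).  Per fold the regression coefficient of adjusted
#' phenotype on DGV (`b`) and their correlation (`r`) are computed, then
#' pooled across folds weighted by fold size; the realized accuracy is
#' the pooled `r` divided by `sqrt(h2)` with `h2` the full-data estimate.
#'
#' @param traits Trait table.
#' @param genotypes Dosage matrix.
#' @param trait Trait column name.
#' @param folds Fold assignment from [kmeans_folds()].
#' @param h2 Full-data heritability for the accuracy denominator
#'   (typically from [elicit_priors()]).
#' @param prior A `wgr_prior` elicited once on the full data and reused
#'   in every training fit (comparability across folds); if `NULL`, it is
#'   elicited here.
#' @param pi Mixing proportion for the training fits.
#' @param n_iter,n_burn,thin Chain settings for the training fits.
#' @param seed Optional integer seed.
#' @param covariates Covariate columns.
#' @return A `wgr_cv` object: per-fold tibble (`fold`, `n`, `b`, `r`),
#'   `pooled_b`, `pooled_r`, `h2`, `accuracy`.
#' @export
cross_validate <- function(traits, genotypes, trait, folds, h2 = NULL,
                           prior = NULL, pi = 0.999,
                           n_iter = 11040, n_burn = 1040, thin = 40,
                           seed = NULL,
                           covariates = c("fat_thickness", "lma", "hcw", "extracted_fat")) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- impute_dosages(genotypes)
  traits <- dplyr::inner_join(tibble::as_tibble(traits), folds[c("animal_id", "fold")],
                              by = "animal_id")
  if (is.null(prior) || is.null(h2)) {
    d_full <- build_design(traits, trait, covariates)
    Z_full <- genotypes[match(d_full$animal_id, rownames(genotypes)), , drop = FALSE]
    if (is.null(prior)) {
      prior <- elicit_priors(d_full$y, d_full$X, Z_full, pi = pi,
                             n_iter = n_iter, n_burn = n_burn, thin = thin)
    }
    if (is.null(h2)) h2 <- prior$h2
  }

  per_fold <- purrr::map_dfr(sort(unique(traits$fold)), function(f) {
    train <- traits[traits$fold != f, , drop = FALSE]
    valid <- traits[traits$fold == f, , drop = FALSE]
    fit <- wgr_fit(train, genotypes, trait, prior = prior, pi = pi,
                   n_iter = n_iter, n_burn = n_burn, thin = thin,
                   covariates = covariates)
    d_val <- build_design(valid, trait, covariates)
    Z_val <- genotypes[match(d_val$animal_id, rownames(genotypes)), , drop = FALSE]
    pred <- as.vector(Z_val %*% fit$u_hat)
    # map validation design columns onto training coefficients; columns
    # unseen in training contribute nothing (coefficient 0)
    bhat <- fit$b_hat[colnames(d_val$X)]
    bhat[is.na(bhat)] <- 0
    y_adj <- d_val$y - as.vector(d_val$X %*% bhat)
    if (stats::sd(pred) == 0) {
      warn(sprintf("fold %d has constant DGV: excluded from pooling", f))
      return(tibble::tibble(fold = f, n = nrow(valid), b = NA_real_, r = NA_real_))
    }
    tibble::tibble(fold = f, n = nrow(valid),
                   b = stats::cov(y_adj, pred) / stats::var(pred),
                   r = stats::cor(pred, y_adj))
  })

  ok <- !is.na(per_fold$r)
  w <- per_fold$n[ok] / sum(per_fold$n[ok])
  pooled_b <- sum(w * per_fold$b[ok])
  pooled_r <- sum(w * per_fold$r[ok])
  structure(list(trait = trait, per_fold = per_fold, pooled_b = pooled_b,
                 pooled_r = pooled_r, h2 = h2,
                 accuracy = realized_accuracy(pooled_r, h2)),
            class = "wgr_cv")
}

#' @export
print.wgr_cv <- function(x, ...) {
  cat(sprintf("<wgr_cv> trait '%s': pooled b = %.3f, pooled r = %.3f, h2 = %.3f, accuracy = %.3f\n",
              x$trait, x$pooled_b, x$pooled_r, x$h2, x$accuracy))
  invisible(x)
}

#' @export
tidy.wgr_cv <- function(x, ...) x$per_fold

#' @export
glance.wgr_cv <- function(x, ...) {
  tibble::tibble(trait = x$trait, pooled_b = x$pooled_b, pooled_r = x$pooled_r,
                 h2 = x$h2, accuracy = x$accuracy, n_folds = nrow(x$per_fold))
}
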