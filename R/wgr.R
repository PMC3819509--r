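#' Build the response and fixed-effect design for one trait
#'
#' Animals with an incomplete record (missing trait, contemporary group or
#' any covariate) are dropped with a reported count.  The design holds an
#' intercept (population mean), contemporary-group indicators with the
#' first level dropped, and the centered covariates, giving a full-rank
#' fixed-effect block.
#'
#' @param traits Trait table (tibble): `animal_id`, the trait column,
#'   `contemporary_group`, covariates.
#' @param trait Name of the trait column.
#' @param covariates Covariate columns to include (those present are
#'   used).
#' @return List: `y`, `X` (with named columns), `animal_id`, `n_dropped`.
#' @export
build_design <- function(traits, trait,
                         covariates = c("fat_thickness", "lma", "hcw", "extracted_fat")) {
  covariates <- intersect(covariates, names(traits))
  kept <- drop_incomplete(traits, trait, covariates)
  y <- kept[[trait]]
  cg <- factor(kept$contemporary_group)
  sizes <- table(cg)
  if (any(sizes == 1)) {
    warn(sprintf("%d contemporary group(s) with a single animal", sum(sizes == 1)))
  }
  X <- matrix(1, nrow(kept), 1, dimnames = list(NULL, "(Intercept)"))
  if (nlevels(cg) > 1) {
    cg_mat <- stats::model.matrix(~cg)[, -1, drop = FALSE]
    colnames(cg_mat) <- paste0("cg_", levels(cg)[-1])
    X <- cbind(X, cg_mat)
  }
  if (length(covariates) > 0) {
    cov_mat <- scale(as.matrix(kept[covariates]), center = TRUE, scale = FALSE)
    X <- cbind(X, cov_mat)
  }
  list(y = y, X = X, animal_id = kept$animal_id,
       n_dropped = attr(kept, "n_removed"))
}

new_wgr_prior <- function(pi, nu_u, s2_u, nu_e, s2_e, variant,
                          sigma2_g = NA_real_, sigma2_e = NA_real_, h2 = NA_real_) {
  structure(list(pi = pi, nu_u = nu_u, s2_u = s2_u, nu_e = nu_e, s2_e = s2_e,
                 variant = variant, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = h2),
            class = "wgr_prior")
}

#' Elicit BayesB priors from a preliminary BayesC run
#'
#' Fits a BayesC chain (common slab variance, default `pi = 0.95`) with
#' prior genetic and residual variances each set to half the phenotypic
#' variance, then converts its posterior genetic and residual variances
#' into scaled-inverse-chi-square scale parameters for a BayesB run:
#' `s2_u = sigma2_g * (nu_u - 2) / nu_u / ((1 - pi) * sum(2 p q))` and
#' `s2_e = sigma2_e * (nu_e - 2) / nu_e`, where `p` are observed allele
#' frequencies and `pi` is the BayesB mixing proportion.  The BayesC
#' posterior also yields the heritability estimate
#' `h2 = mean(sigma2_g) / (mean(sigma2_g) + mean(sigma2_e))` reported for
#' the trait.
#'
#' @param y,X From [build_design()].
#' @param genotypes Dosage matrix restricted to the analyzed animals.
#' @param pi Mixing proportion intended for the BayesB run.
#' @param pi_elicit BayesC mixing proportion (default 0.95).
#' @param nu_u,nu_e Prior degrees of freedom (defaults 4 and 10).
#' @param n_iter,n_burn,thin Chain settings for the elicitation run.
#' @param seed Optional integer seed.
#' @return A `wgr_prior` object carrying the BayesB scales, the BayesC
#'   posterior variances, and `h2`.
#' @export
elicit_priors <- function(y, X, genotypes, pi = 0.999, pi_elicit = 0.95,
                          nu_u = 4, nu_e = 10,
                          n_iter = 5040, n_burn = 1040, thin = 40,
                          seed = NULL) {
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) abort("phenotype is constant: cannot elicit priors")
  p <- colMeans(genotypes) / 2
  sum2pq <- sum(2 * p * (1 - p))
  s2_u_c <- (vy / 2) * (nu_u - 2) / nu_u / ((1 - pi_elicit) * sum2pq)
  s2_e_c <- (vy / 2) * (nu_e - 2) / nu_e
  if (!is.null(seed)) set.seed(seed)
  chain <- wgr_mcmc_cpp(y, X, genotypes, pi_elicit, nu_u, s2_u_c, nu_e, s2_e_c,
                        0L, as.integer(n_iter), as.integer(n_burn),
                        as.integer(thin), TRUE, TRUE, s2_u_c, vy / 2)
  sg <- mean(chain$sigma2_g)
  se <- mean(chain$sigma2_e)
  if (sg <= 0 || (1 - pi) * sum2pq <= 0) {
    warn("degenerate posterior genetic variance: flooring BayesB marker-variance scale")
    sg_eff <- max(sg, 1e-6 * vy)
  } else {
    sg_eff <- sg
  }
  new_wgr_prior(
    pi = pi, nu_u = nu_u,
    s2_u = sg_eff * (nu_u - 2) / nu_u / ((1 - pi) * sum2pq),
    nu_e = nu_e, s2_e = se * (nu_e - 2) / nu_e,
    variant = "BayesB", sigma2_g = sg, sigma2_e = se, h2 = sg / (sg + se)
  )
}

#' Fit the spike-and-slab whole-genome regression
#'
#' Single-site Gibbs sampling for `y = Xb + Zu + e`, where each marker
#' effect is zero with prior probability `pi` and otherwise normal with a
#' slab variance that is common to all markers (BayesC) or locus-specific
#' (BayesB).  Genetic variance per stored sample is the across-animal
#' variance of `Zu`, the same definition the window scan uses, so window
#' fractions are coherent with the genome-wide value.
#'
#' @param traits Trait table.
#' @param genotypes Dosage matrix (animals x SNPs); missing dosages are
#'   mean-imputed.
#' @param trait Trait column name.
#' @param prior A `wgr_prior` (from [elicit_priors()]); if `NULL`, priors
#'   are elicited first with the same chain settings.
#' @param pi Prior probability of a zero marker effect.
#' @param variant `"BayesB"` (locus-specific slab variances) or
#'   `"BayesC"` (common).
#' @param n_iter,n_burn,thin Iterations, burn-in iterations, thinning
#'   interval; `(n_iter - n_burn)` must be divisible by `thin`.  The
#'   full-scale configuration of record is 41,040 iterations with 1,040
#'   burn-in and thin 40 (1,000 stored samples).
#' @param seed Optional integer seed (controls the whole run).
#' @param update_variances Set `FALSE` to hold both variance components
#'   fixed at the prior scales (used for closed-form checks).
#' @param covariates Covariate columns for the fixed-effect design.
#' @return A `wgr_fit` object: posterior-mean effects `u_hat`, per-SNP
#'   inclusion frequencies, posterior means `sigma2_g`, `sigma2_e`, `h2`
#'   (ratio of posterior means), the thinned `chain`, and design metadata.
#' @export
wgr_fit <- function(traits, genotypes, trait, prior = NULL, pi = 0.999,
                    variant = c("BayesB", "BayesC"),
                    n_iter = 11040, n_burn = 1040, thin = 40, seed = NULL,
                    update_variances = TRUE,
                    covariates = c("fat_thickness", "lma", "hcw", "extracted_fat")) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  genotypes <- impute_dosages(genotypes)
  d <- build_design(traits, trait, covariates)
  Z <- genotypes[match(d$animal_id, rownames(genotypes)), , drop = FALSE]
  if (anyNA(Z)) abort("genotypes missing for some analyzed animals")
  if (is.null(prior)) {
    prior <- elicit_priors(d$y, d$X, Z, pi = pi,
                           n_iter = n_iter, n_burn = n_burn, thin = thin)
  }
  vy <- stats::var(d$y)
  chain <- wgr_mcmc_cpp(
    d$y, d$X, Z, pi, prior$nu_u, prior$s2_u, prior$nu_e, prior$s2_e,
    if (variant == "BayesB") 1L else 0L,
    as.integer(n_iter), as.integer(n_burn), as.integer(thin),
    update_variances, update_variances,
    prior$s2_u, if (update_variances) vy / 2 else prior$s2_e
  )
  colnames(chain$u) <- colnames(Z)
  colnames(chain$b) <- colnames(d$X)
  sg <- mean(chain$sigma2_g)
  se <- mean(chain$sigma2_e)
  structure(list(
    trait = trait, variant = variant, pi = pi, prior = prior,
    u_hat = colMeans(chain$u),
    inclusion = colMeans(chain$u != 0),
    b_hat = colMeans(chain$b),
    sigma2_g = sg, sigma2_e = se, h2 = heritability(sg, se),
    chain = chain, n_stored = nrow(chain$u),
    n_iter = n_iter, n_burn = n_burn, thin = thin,
    animal_id = d$animal_id, n_dropped = d$n_dropped
  ), class = "wgr_fit")
}

#' Heritability as a ratio of posterior-mean variances
#'
#' @param sigma2_g,sigma2_e Posterior means of the genetic and residual
#'   variances.
#' @return `sigma2_g / (sigma2_g + sigma2_e)`.
#' @export
heritability <- function(sigma2_g, sigma2_e) sigma2_g / (sigma2_g + sigma2_e)

#' Direct genomic breeding values
#'
#' `DGV_i = sum_j z_ij * u_hat_j`: dosage times posterior-mean marker
#' effect, summed over loci.
#'
#' @param genotypes Dosage matrix.
#' @param effects Either a `wgr_fit` object or a named numeric vector of
#'   posterior-mean effects covering all genotype columns.
#' @return Tibble `animal_id`, `dgv`.
#' @export
dgv <- function(genotypes, effects) {
  if (inherits(effects, "wgr_fit")) effects <- effects$u_hat
  if (is.null(names(effects)) || !all(colnames(genotypes) %in% names(effects))) {
    if (length(effects) != ncol(genotypes)) {
      abort("effects must cover every SNP in the genotype matrix")
    }
    names(effects) <- colnames(genotypes)
  }
  v <- as.vector(genotypes %*% effects[colnames(genotypes)])
  tibble::tibble(animal_id = rownames(genotypes) %||% as.character(seq_len(nrow(genotypes))),
                 dgv = v)
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("<wgr_fit> %s, trait '%s'\n", x$variant, x$trait))
  cat(sprintf("  pi = %g, %d stored samples (%d iters, %d burn-in, thin %d)\n",
              x$pi, x$n_stored, x$n_iter, x$n_burn, x$thin))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$h2))
  invisible(x)
}

#' @export
tidy.wgr_fit <- function(x, ...) {
  tibble::tibble(snp_id = names(x$u_hat), estimate = unname(x$u_hat),
                 inclusion = unname(x$inclusion))
}

#' @export
glance.wgr_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, variant = x$variant, pi = x$pi,
                 sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e, h2 = x$h2,
                 n_stored = x$n_stored, n_dropped = x$n_dropped)
}

#' @export
autoplot.wgr_fit <- function(object, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = abs(.data$estimate),
                                   alpha = .data$inclusion)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "SNP index (map order)", y = "|posterior mean effect|",
                  alpha = "Inclusion\nfrequency") +
    ggplot2::theme_minimal()
}
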