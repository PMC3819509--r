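#' Simulate a dosage matrix and SNP map
#'
#' Emulates a 50K-style biallelic panel at desk scale: per-SNP allele
#' frequencies are drawn uniformly from `maf_range` and dosages are
#' Binomial(2, p) per animal.  An optional first-order Markov correlation
#' between adjacent SNPs on the same chromosome mimics linkage
#' disequilibrium at the haplotype level (each haplotype allele copies its
#' left neighbour with probability `ld_rho`, otherwise is drawn fresh).
#' Positions are evenly spaced so that every 1-Mb window holds
#' `snps_per_window` SNPs; a fraction of SNPs can be left unmapped
#' (`NA` chromosome/position), mirroring panels whose assembly placement
#' is incomplete.
#'
#' @param n_animals,n_snps Matrix dimensions.
#' @param n_chromosomes Number of autosomes to spread SNPs over; SNPs are
#'   split evenly with any remainder assigned to the last chromosome.
#' @param snps_per_window SNP count per 1-Mb window.
#' @param maf_range Range of the uniform allele-frequency draw.
#' @param ld_rho Adjacent-SNP copying probability in (0,1); 0 = unlinked.
#' @param prop_unmapped Fraction of SNPs (randomly chosen) left unmapped.
#' @param seed Optional integer seed.
#' @return List with `genotypes` (dosage matrix, animals x SNPs, dimnames
#'   set) and `map` (tibble `snp_id`, `chromosome`, `position_bp`).
#' @export
simulate_genotypes <- function(n_animals, n_snps, n_chromosomes = 29,
                               snps_per_window = 20,
                               maf_range = c(0.05, 0.5), ld_rho = 0,
                               prop_unmapped = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_animals >= 1, n_snps >= 1, n_chromosomes >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, ld_rho >= 0, ld_rho < 1)
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  animal_ids <- sprintf("an%05d", seq_len(n_animals))
  p <- runif(n_snps, maf_range[1], maf_range[2])

  per_chrom <- rep(n_snps %/% n_chromosomes, n_chromosomes)
  per_chrom[n_chromosomes] <- per_chrom[n_chromosomes] + n_snps %% n_chromosomes
  chrom <- rep(as.character(seq_len(n_chromosomes)), per_chrom)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  spacing <- 1e6 / snps_per_window
  position <- floor((idx_in_chrom - 0.5) * spacing)

  if (ld_rho <= 0) {
    z <- matrix(rbinom(n_animals * n_snps, 2L, rep(p, each = n_animals)),
                nrow = n_animals, ncol = n_snps)
  } else {
    z <- matrix(0L, n_animals, n_snps)
    for (hap in 1:2) {
      h <- matrix(0L, n_animals, n_snps)
      for (j in seq_len(n_snps)) {
        fresh <- rbinom(n_animals, 1L, p[j])
        if (j > 1 && chrom[j] == chrom[j - 1]) {
          copy <- runif(n_animals) < ld_rho
          h[, j] <- ifelse(copy, h[, j - 1], fresh)
        } else {
          h[, j] <- fresh
        }
      }
      z <- z + h
    }
  }
  dimnames(z) <- list(animal_ids, snp_ids)

  map <- tibble::tibble(snp_id = snp_ids, chromosome = chrom,
                        position_bp = position)
  if (prop_unmapped > 0) {
    n_un <- round(prop_unmapped * n_snps)
    un <- sample.int(n_snps, n_un)
    map$chromosome[un] <- NA_character_
    map$position_bp[un] <- NA_real_
  }
  list(genotypes = z, map = map)
}

#' Simulate a quantitative trait with a sparse window-concentrated QTL
#' architecture
#'
#' Builds a phenotype `y = Xb + Zu + e` on top of a simulated (or real)
#' dosage matrix: QTL effects are drawn inside designated 1-Mb windows and
#' scaled so each window contributes its requested fraction of the genetic
#' variance; contemporary-group effects, four continuous covariates, and
#' normal residuals are added.  The residual scale is chosen so the
#' realized (sample) heritability equals `h2` exactly, and the full truth
#' (marker effects, breeding values, window fractions) is returned for
#' parameter-recovery testing.
#'
#' @param genotypes Dosage matrix (animals x SNPs).
#' @param map SNP map tibble (`snp_id`, `chromosome`, `position_bp`).
#' @param qtl_windows Data frame with columns `window_id` (e.g. `"3_7"`),
#'   `n_qtl` and `var_fraction` (fractions summing to at most 1).  Rows of
#'   zero fraction are allowed.  An empty frame gives a null trait.
#' @param h2 Target heritability in `[0, 1)`; realized
#'   `var(g)/(var(g)+var(e))` matches it exactly (up to the trivial case of
#'   a null trait, where it is 0).
#' @param n_groups Number of contemporary groups (uniformly assigned).
#' @param cg_sd SD of the normal contemporary-group effects.
#' @param covariate_coefs Named coefficients for the four standard-normal
#'   covariates.
#' @param trait Name of the trait column in the output.
#' @param seed Optional integer seed.
#' @return List with `traits` (tibble: `animal_id`, trait value,
#'   `contemporary_group`, covariates) and `truth` (list: `u_true`,
#'   `g_true`, `h2`, `window_fractions`, `qtl_snps`, fixed-effect values).
#' @export
simulate_trait <- function(genotypes, map, qtl_windows = NULL, h2 = 0.5,
                           n_groups = 5, cg_sd = 1,
                           covariate_coefs = c(fat_thickness = 0.2, lma = 0.1,
                                               hcw = 0.15, extracted_fat = 0.25),
                           trait = "trait", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  windows <- assign_windows(map)
  u_true <- stats::setNames(numeric(m), colnames(genotypes))
  qtl_snps <- character(0)

  if (!is.null(qtl_windows) && nrow(qtl_windows) > 0) {
    missing_w <- setdiff(qtl_windows$window_id, windows$window_id)
    if (length(missing_w) > 0) {
      abort(paste("QTL window(s) with no SNPs in the map:",
                  paste(missing_w, collapse = ", ")))
    }
    stopifnot(sum(qtl_windows$var_fraction) <= 1 + 1e-8)
    for (r in seq_len(nrow(qtl_windows))) {
      wid <- qtl_windows$window_id[r]
      frac <- qtl_windows$var_fraction[r]
      members <- windows$snp_id[windows$window_id == wid]
      k <- min(qtl_windows$n_qtl[r], length(members))
      if (k == 0 || frac <= 0) next
      picked <- sample(members, k)
      eff <- rnorm(k)
      g_w <- genotypes[, picked, drop = FALSE] %*% eff
      v_w <- stats::var(as.vector(g_w))
      if (v_w <= 0) next
      scale <- sqrt(frac / v_w)     # total genetic variance targeted at 1
      u_true[picked] <- u_true[picked] + eff * scale
      qtl_snps <- c(qtl_snps, picked)
    }
  }

  g_true <- as.vector(genotypes %*% u_true)
  v_g <- stats::var(g_true)
  if (v_g > 0 && h2 > 0) {
    e <- rnorm(n)
    e <- e / stats::sd(e) * sqrt(v_g * (1 - h2) / h2)
  } else {
    e <- rnorm(n)
  }
  realized_h2 <- if (v_g > 0) v_g / (v_g + stats::var(e)) else 0

  cg <- sample(paste0("cg", seq_len(n_groups)), n, replace = TRUE)
  cg_eff <- stats::setNames(rnorm(n_groups, 0, cg_sd), paste0("cg", seq_len(n_groups)))
  covs <- matrix(rnorm(n * length(covariate_coefs)), n,
                 dimnames = list(NULL, names(covariate_coefs)))
  y <- 10 + cg_eff[cg] + as.vector(covs %*% covariate_coefs) + g_true + e

  traits <- dplyr::bind_cols(
    tibble::tibble(animal_id = rownames(genotypes)),
    stats::setNames(tibble::tibble(y), trait),
    tibble::tibble(contemporary_group = cg),
    tibble::as_tibble(covs)
  )

  wf <- windows |>
    dplyr::group_by(.data$window_id) |>
    dplyr::summarise(true_fraction = {
      idx <- .data$snp_id
      gw <- genotypes[, idx, drop = FALSE] %*% u_true[idx]
      if (v_g > 0) stats::var(as.vector(gw)) / v_g else 0
    }, .groups = "drop")

  list(
    traits = traits,
    truth = list(u_true = u_true, g_true = g_true, h2 = realized_h2,
                 window_fractions = wf, qtl_snps = unique(qtl_snps),
                 cg_effects = cg_eff, covariate_coefs = covariate_coefs)
  )
}

#' Simulate a pleiotropic trait pair sharing one QTL window
#'
#' Builds two traits whose QTL lie in the same 1-Mb window with a
#' controlled degree of pleiotropy: the second effect vector is
#' constructed by Gram-Schmidt in the dosage-covariance inner product so
#' that the realized correlation of the two true window DGVs (across
#' animals) equals `dgv_cor` exactly.  Each trait is standardized to unit
#' genetic variance with residuals scaled to the target heritability; no
#' other fixed effects are added (a single contemporary group).
#'
#' @param genotypes Dosage matrix.
#' @param map SNP map.
#' @param window_id Window carrying the shared QTL.
#' @param n_qtl QTL count within the window.
#' @param dgv_cor Target realized correlation of the true window DGVs.
#' @param h2 Heritability of each trait.
#' @param trait_names Names of the two trait columns.
#' @param seed Optional integer seed.
#' @return List: `trait_a`, `trait_b` (trait tables), `u_a`, `u_b` (true
#'   effects), `qtl_snps`, `realized_cor`.
#' @export
simulate_pleiotropic_pair <- function(genotypes, map, window_id, n_qtl = 4,
                                      dgv_cor = 0.9, h2 = 0.5,
                                      trait_names = c("trait_a", "trait_b"),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  windows <- assign_windows(map)
  members <- windows$snp_id[windows$window_id == window_id]
  if (length(members) < n_qtl) abort("window has fewer SNPs than requested QTL")
  picked <- sample(members, n_qtl)
  C <- stats::cov(genotypes[, picked, drop = FALSE])
  ip <- function(a, b) as.numeric(crossprod(a, C %*% b))
  u1 <- rnorm(n_qtl)
  eta <- rnorm(n_qtl)
  perp <- eta - ip(eta, u1) / ip(u1, u1) * u1
  perp <- perp * sqrt(ip(u1, u1) / ip(perp, perp))
  u2 <- dgv_cor * u1 + sqrt(1 - dgv_cor^2) * perp

  make_trait <- function(eff, nm) {
    u <- stats::setNames(numeric(ncol(genotypes)), colnames(genotypes))
    u[picked] <- eff
    g <- as.vector(genotypes %*% u)
    gsd <- stats::sd(g)
    u <- u / gsd
    g <- g / gsd
    e <- rnorm(nrow(genotypes))
    e <- e / stats::sd(e) * sqrt((1 - h2) / h2)
    tt <- tibble::tibble(animal_id = rownames(genotypes), value = 5 + g + e,
                         contemporary_group = "cg1")
    names(tt)[2] <- nm
    list(traits = tt, u = u)
  }
  a <- make_trait(u1, trait_names[1])
  b <- make_trait(u2, trait_names[2])
  ga <- as.vector(genotypes %*% a$u)
  gb <- as.vector(genotypes %*% b$u)
  list(trait_a = a$traits, trait_b = b$traits, u_a = a$u, u_b = b$u,
       qtl_snps = picked, realized_cor = stats::cor(ga, gb))
}

#' Simulate per-animal fatty-acid composition profiles
#'
#' Draws independent log-normal weights per fatty acid per animal (means
#' and SDs default to the representative beef-basis profile in
#' [fa_reference()]), yielding a beef-basis table and, after closure, a
#' fat-percent table summing to 100 per animal.  Closure induces the mild
#' negative correlations inherent to compositional data; no genetic signal
#' is embedded (use [simulate_trait()] for that).
#'
#' @param n_animals Number of animals.
#' @param means,sds Named numeric vectors of per-acid means and SDs on the
#'   beef basis; defaults come from [fa_reference()].  Means must be
#'   positive.
#' @param seed Optional integer seed.
#' @return List with `beef` and `fat_percent` profile tibbles.
#' @export
simulate_fa_profiles <- function(n_animals, means = NULL, sds = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- fa_reference()
  if (is.null(means)) means <- stats::setNames(ref$mean_beef, ref$fatty_acid)
  if (is.null(sds)) sds <- stats::setNames(ref$sd_beef, ref$fatty_acid)[names(means)]
  if (any(means <= 0)) abort("fatty-acid mean weights must be positive")
  w <- vapply(names(means), function(nm) {
    m <- means[[nm]]; s <- sds[[nm]]
    sdlog2 <- log(1 + (s / m)^2)
    stats::rlnorm(n_animals, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  }, numeric(n_animals))
  if (n_animals == 1L) w <- matrix(w, nrow = 1L, dimnames = list(NULL, names(means)))
  beef <- dplyr::bind_cols(
    tibble::tibble(animal_id = sprintf("an%05d", seq_len(n_animals))),
    tibble::as_tibble(w)
  )
  list(beef = beef, fat_percent = to_fat_percent(beef))
}
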