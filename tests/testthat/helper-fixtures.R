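# Shared fixtures and small oracles, all built in code at test time.

# Minimal stand-in for a fitted model when only the stored effect samples
# matter (window bookkeeping, PPI, region correlations).
fake_fit <- function(U, trait = "toy") {
  structure(list(trait = trait, chain = list(u = U), n_stored = nrow(U),
                 u_hat = colMeans(U)),
            class = "wgr_fit")
}

# Closed-form posterior mean of (b, u) under flat b, fixed variances and
# pi = 0: joint ridge solve with penalty only on the marker block.
ridge_oracle <- function(y, X, Z, sigma2_u, sigma2_e) {
  W <- cbind(X, Z)
  lambda <- sigma2_e / sigma2_u
  P <- diag(c(rep(0, ncol(X)), rep(lambda, ncol(Z))))
  beta <- solve(crossprod(W) + P, crossprod(W, y))
  list(b = beta[seq_len(ncol(X))], u = beta[-seq_len(ncol(X))])
}

# Batch-means Monte Carlo standard error (robust to autocorrelation).
mcse <- function(x, n_batch = 20) {
  n <- length(x)
  bsize <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch),
               function(b) mean(x[((b - 1) * bsize + 1):(b * bsize)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}

# Genotypes for three well-separated families: family-specific allele
# frequencies pushed toward 0/1 so within-family relationships dominate.
sim_families <- function(n_per_family = 20, n_snps = 200, seed = 1) {
  set.seed(seed)
  fams <- 3
  p_fam <- matrix(runif(fams * n_snps, 0.05, 0.95), fams)
  z <- do.call(rbind, lapply(seq_len(fams), function(f) {
    matrix(rbinom(n_per_family * n_snps, 2, rep(p_fam[f, ], each = n_per_family)),
           n_per_family)
  }))
  dimnames(z) <- list(sprintf("an%03d", seq_len(fams * n_per_family)),
                      sprintf("snp%04d", seq_len(n_snps)))
  list(genotypes = z, family = rep(seq_len(fams), each = n_per_family))
}

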