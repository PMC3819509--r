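toy_geno <- function(n = 6, m = 4, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * m, 2, 0.5), n,
         dimnames = list(sprintf("a%02d", 1:n), paste0("s", 1:m)))
}

test_that("window labels follow floor(bp / 1e6) per chromosome", {
  map <- tibble::tibble(
    snp_id = c("fasn_snp", "scd_snp", "origin", "lost"),
    chromosome = c("19", "26", "1", NA),
    position_bp = c(51384922, 21132751, 0, NA)
  )
  w <- assign_windows(map)
  expect_equal(w$window_id, c("19_51", "26_21", "1_0", "unmapped"))
  # a SNP genotyped but absent from the map joins the unmapped window
  expect_warning(w2 <- assign_windows(map, snp_ids = c(map$snp_id, "ghost")),
                 "unmapped")
  expect_equal(w2$window_id[w2$snp_id == "ghost"], "unmapped")
})

test_that("PPI equals brute-force counting over stored samples", {
  # 4 SNPs in two windows; hand-built chain of 5 stored samples
  U <- rbind(c(0.5, 0, 0, 0),
             c(0, -0.2, 0, 0),
             c(0, 0, 0, 0),
             c(0.1, 0.3, 0, 0.4),
             c(0, 0, 0, 0))
  colnames(U) <- paste0("s", 1:4)
  Z <- toy_geno()
  map <- tibble::tibble(snp_id = paste0("s", 1:4),
                        chromosome = c("1", "1", "2", "2"),
                        position_bp = c(1e5, 9e5, 1e5, 9e5))
  w <- assign_windows(map)
  scan <- window_scan(fake_fit(U), Z, w)
  # brute force: window 1_0 hit in samples 1,2,4; window 2_0 in sample 4
  expect_equal(scan$ppi[scan$window_id == "1_0"], 3 / 5)
  expect_equal(scan$ppi[scan$window_id == "2_0"], 1 / 5)
  expect_equal(scan$n_snps, c(2L, 2L))

  # union monotonicity: merging windows cannot lower PPI below the max
  map_merged <- dplyr::mutate(map, chromosome = "1",
                              position_bp = c(1e5, 2e5, 3e5, 4e5))
  scan_m <- window_scan(fake_fit(U), Z, assign_windows(map_merged))
  expect_gte(scan_m$ppi, max(scan$ppi))
})

test_that("window variance fractions are exact in engineered cases", {
  Z <- toy_geno(n = 20, m = 4, seed = 2)
  map <- tibble::tibble(snp_id = paste0("s", 1:4),
                        chromosome = c("1", "1", "2", "2"),
                        position_bp = c(1e5, 9e5, 1.2e6, 1.8e6))
  w <- assign_windows(map)

  # single nonzero SNP in one window, every sample
  U1 <- matrix(0, 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  U1[, 2] <- 1
  scan1 <- window_scan(fake_fit(U1), Z, w)
  expect_equal(scan1$genetic_variance_pct[scan1$window_id == "1_0"], 100)
  expect_equal(scan1$genetic_variance_pct[scan1$window_id == "2_1"], 0)
  expect_equal(scan1$ppi, c(1, 0))

  # all-zero chain: every sample skipped, fraction undefined, ppi 0
  U0 <- matrix(0, 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  scan0 <- window_scan(fake_fit(U0), Z, w)
  expect_true(all(is.na(scan0$genetic_variance_pct)))
  expect_equal(scan0$ppi, c(0, 0))
  expect_equal(scan0$n_skipped, c(5L, 5L))
})

test_that("selection by PPI is strict and sorted by variance", {
  scan <- tibble::tibble(window_id = c("a", "b", "c", "d"),
                         genetic_variance_pct = c(5, 40, 20, 1),
                         ppi = c(0.90, 0.905, 1, 0.2))
  sig <- significant_windows(scan, threshold = 0.90)
  expect_equal(sig$window_id, c("b", "c"))   # 0.90 exactly is excluded
  expect_equal(sig$genetic_variance_pct, c(40, 20))
  expect_equal(nrow(significant_windows(scan[0, ])), 0L)
})

test_that("with unlinked genotypes window fractions approximately sum to one", {
  sim <- simulate_genotypes(300, 400, n_chromosomes = 4, seed = 101)
  qtl <- tibble::tibble(window_id = c("1_1", "3_2"), n_qtl = 3,
                        var_fraction = c(0.7, 0.3))
  tr <- simulate_trait(sim$genotypes, sim$map, qtl, h2 = 0.6, seed = 102)
  fit <- suppressMessages(wgr_fit(tr$traits, sim$genotypes, "trait", pi = 0.98,
                                  n_iter = 3040, n_burn = 1040, thin = 40,
                                  seed = 103))
  scan <- window_scan(fit, sim$genotypes, assign_windows(sim$map))
  total <- sum(scan$genetic_variance_pct) / 100
  expect_gt(total, 0.9)
  expect_lt(total, 1.1)
  expect_true(all(scan$genetic_variance_pct >= 0))
})
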