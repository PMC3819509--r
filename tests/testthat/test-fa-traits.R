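ref_profile <- function() {
  ref <- fa_reference()
  p <- tibble::as_tibble(as.list(stats::setNames(ref$mean_fat_pct, ref$fatty_acid)))
  dplyr::bind_cols(tibble::tibble(animal_id = "ref"), p)
}

test_that("fat-percent conversion closes to 100 and is idempotent", {
  p <- tibble::tibble(animal_id = "a1", `14:0` = 1, `16:0` = 2, `18:0` = 1)
  fp <- to_fat_percent(p)
  expect_equal(unlist(fp[1, -1], use.names = FALSE), c(25, 50, 25))
  expect_equal(to_fat_percent(fp), fp)

  single <- tibble::tibble(animal_id = "a1", `16:0` = 7)
  expect_equal(to_fat_percent(single)$`16:0`, 100)

  zeros <- tibble::tibble(animal_id = "a1", `16:0` = 0, `18:0` = 0)
  expect_error(to_fat_percent(zeros), "zero")
})

test_that("composite sums follow saturation class and chain length", {
  p <- tibble::tibble(animal_id = "a1", `14:0` = 10, `16:0` = 20,
                      `cis-9 18:1` = 30, `18:2` = 40)
  comp <- fa_composites(p, basis = "beef")
  expect_equal(comp$SFA, 30)
  expect_equal(comp$MUFA, 30)
  expect_equal(comp$PUFA, 40)
  expect_equal(comp$MCFA, 10)   # 14 carbons
  expect_equal(comp$LCFA, 90)   # 16+
  expect_true(is.na(comp$AI))   # ratio traits undefined on beef basis

  # literal text definitions remain available
  comp_txt <- fa_composites(p, basis = "beef", mcfa_def = "text")
  expect_equal(comp_txt$MCFA, 0)          # no 12:0/13:0 present
  expect_equal(comp_txt$LCFA, 100)        # 14+ carbons
})

test_that("MCFA + LCFA = 100 on the fat-percent basis and sums are linear", {
  set.seed(42)
  sim <- simulate_fa_profiles(40, seed = 42)
  comp <- fa_composites(sim$fat_percent)
  expect_equal(comp$MCFA + comp$LCFA, rep(100, 40), tolerance = 1e-9)
  # composite of the mean profile equals the mean of per-animal composites
  mean_prof <- dplyr::bind_cols(
    tibble::tibble(animal_id = "mean"),
    dplyr::summarise(sim$fat_percent[-1], dplyr::across(dplyr::everything(), mean))
  )
  comp_mean <- fa_composites(mean_prof)
  expect_equal(comp_mean$SFA, mean(comp$SFA), tolerance = 1e-9)
  expect_equal(comp_mean$PUFA, mean(comp$PUFA), tolerance = 1e-9)
})

test_that("ratio traits reproduce hand and table arithmetic on the reference profile", {
  comp <- fa_composites(ref_profile())
  # saturation index from the 14:0 and 16:0 means
  expect_equal(comp$`(14:0+16:0)/All`, 29.256, tolerance = 0.01)
  # atherogenic index from the printed equation
  expect_equal(comp$AI, 100 * (4 * 2.707 + 26.549) / (49.046 + 5.673),
               tolerance = 0.01)
  expect_equal(comp$AI, 68.31, tolerance = 0.05)
  expect_equal(comp$`PUFA/SFA`, 100 * comp$PUFA / comp$SFA)
})

test_that("atherogenic index handles degenerate profiles", {
  p0 <- tibble::tibble(animal_id = "a", `14:0` = 0, `16:0` = 0, `cis-9 18:1` = 50)
  expect_equal(atherogenic_index(p0), 0)
  p1 <- tibble::tibble(animal_id = "a", `14:0` = 1, `16:0` = 1, `cis-9 18:1` = 5)
  expect_equal(atherogenic_index(p1), 100 * 5 / 5)
  psat <- tibble::tibble(animal_id = "a", `14:0` = 1, `16:0` = 1)
  expect_warning(ai <- atherogenic_index(psat), "zero")
  expect_true(is.na(ai))
  expect_warning(expect_true(is.na(fa_composites(
    tibble::tibble(animal_id = "a", `18:2` = 1))$`PUFA/SFA`)), "zero")
})

test_that("summary statistics use the sample SD and CV x 100", {
  s <- fa_summary(tibble::tibble(animal_id = c("a", "b", "c"), x = c(1, 2, 3)))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv, 50)
  const <- fa_summary(tibble::tibble(animal_id = c("a", "b"), x = c(4, 4)))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_true(is.na(cv_pct(0, 1)))
})

test_that("simulated compositions close to 100 and track the reference means", {
  sim <- simulate_fa_profiles(400, seed = 9)
  sums <- rowSums(sim$fat_percent[-1])
  expect_equal(sums, rep(100, 400), tolerance = 1e-9)
  # a single-component profile closes to 100 for it
  one <- simulate_fa_profiles(3, means = c(`16:0` = 5), sds = c(`16:0` = 1), seed = 1)
  expect_equal(one$fat_percent$`16:0`, rep(100, 3))
  expect_error(simulate_fa_profiles(3, means = c(`16:0` = -1)), "positive")
  # beef-basis means recover the requested means (lognormal parameterization)
  expect_equal(mean(sim$beef$`16:0`), fa_reference()$mean_beef[7], tolerance = 0.1)
})
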