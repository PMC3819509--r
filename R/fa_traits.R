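#' Convert a beef-basis fatty-acid profile to the fat-percent basis
#'
#' On the beef basis each fatty acid is a weight (g x 1e-5 per g meat); on
#' the fat-percent basis it is expressed relative to the total extracted
#' fatty acid, times 100, so every animal's profile sums to 100 (closure).
#'
#' @param profile A data frame with an `animal_id` column and one numeric
#'   column per fatty acid, all values non-negative.
#' @return A tibble of the same shape whose fatty-acid columns sum to 100
#'   within each row.
#' @export
#' @examples
#' p <- tibble::tibble(animal_id = "a1", `14:0` = 1, `16:0` = 2, `18:0` = 1)
#' to_fat_percent(p)
to_fat_percent <- function(profile) {
  profile <- tibble::as_tibble(profile)
  fa_cols <- setdiff(names(profile), "animal_id")
  w <- as.matrix(profile[fa_cols])
  if (!is.numeric(w)) abort("fatty-acid columns must be numeric")
  if (any(w < 0, na.rm = TRUE)) abort("fatty-acid weights must be non-negative")
  tot <- rowSums(w)
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    abort("composition undefined: at least one profile has zero (or non-finite) total fatty acid")
  }
  profile[fa_cols] <- w / tot * 100
  profile
}

# Membership lists for composite traits.  The defaults reproduce the
# internally consistent convention of typical composition tables: medium
# chain = 10-15 carbons, long chain = 16+, the omega-3 sum runs over the
# full n-3 series; the literal short definitions sometimes printed in
# methods text (MCFA = 12:0 + 13:0, n3 = 18:3n3 + 20:3n3) are available
# via the *_def arguments.
fa_members <- function(mcfa_def = c("chain_length", "text"),
                       n3_def = c("series", "text"),
                       n6_def = c("series", "series_cla", "text")) {
  mcfa_def <- match.arg(mcfa_def)
  n3_def <- match.arg(n3_def)
  n6_def <- match.arg(n6_def)
  ref <- fa_reference()
  mcfa <- switch(mcfa_def,
    chain_length = ref$fatty_acid[ref$carbons <= 15],
    text = c("12:0", "13:0")
  )
  lcfa <- switch(mcfa_def,
    chain_length = ref$fatty_acid[ref$carbons >= 16],
    text = ref$fatty_acid[ref$carbons >= 14]
  )
  n3 <- switch(n3_def,
    series = ref$fatty_acid[!is.na(ref$series) & ref$series == "n3"],
    text = c("18:3n3", "20:3n3")
  )
  n6 <- switch(n6_def,
    series = ref$fatty_acid[!is.na(ref$series) & ref$series == "n6"],
    series_cla = ref$fatty_acid[!is.na(ref$series) & ref$series %in% c("n6", "cla")],
    text = c("18:3n6", "20:3n6")
  )
  list(
    MCFA = mcfa, LCFA = lcfa,
    MUFA = ref$fatty_acid[ref$class == "MUFA"],
    PUFA = ref$fatty_acid[ref$class == "PUFA"],
    SFA = ref$fatty_acid[ref$class == "SFA"],
    n3 = n3, n6 = n6
  )
}

row_sum <- function(m, cols) {
  cols <- intersect(cols, colnames(m))
  if (length(cols) == 0L) return(rep(0, nrow(m)))
  rowSums(m[, cols, drop = FALSE])
}

#' Atherogenic index of a fat-percent profile
#'
#' AI = (4 x 14:0 + 16:0) / (sum MUFA + sum PUFA), reported x100 so that it
#' sits on the same scale as composition tables that average per-animal
#' ratios (a value of 68 means a raw ratio of 0.68).
#'
#' @param profile Fat-percent basis profile (see [to_fat_percent()]).
#' @return Numeric vector, one AI value per animal; `NA` (with a warning)
#'   where the unsaturated denominator is zero, `0` where only the
#'   numerator is zero.
#' @export
atherogenic_index <- function(profile) {
  profile <- tibble::as_tibble(profile)
  w <- as.matrix(profile[setdiff(names(profile), "animal_id")])
  mem <- fa_members()
  num <- 4 * row_sum(w, "14:0") + row_sum(w, "16:0")
  den <- row_sum(w, mem$MUFA) + row_sum(w, mem$PUFA)
  out <- 100 * num / den
  bad <- den == 0
  if (any(bad)) {
    warn(sprintf("%d profile(s) with zero MUFA+PUFA denominator: AI set to NA", sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Composite fatty-acid traits and indices
#'
#' Computes the composite sums (MCFA, LCFA, MUFA, PUFA, SFA, omega-3 and
#' omega-6 totals) and the ratio/index traits (PUFA/SFA, (14:0+16:0)/All,
#' atherogenic index, n3/n6) from a per-animal fatty-acid profile.
#'
#' Ratio and index traits are defined on the fat-percent basis only and are
#' reported x100 (the scale obtained when per-animal percentage ratios are
#' averaged); on the beef basis they are returned as `NA`.  Sum-type
#' composites are computed on either basis.
#'
#' @param profile Data frame: `animal_id` plus one column per fatty acid.
#' @param basis `"fat_percent"` or `"beef"`.
#' @param mcfa_def `"chain_length"` (default: MCFA = 10-15 carbons, LCFA =
#'   16+) or `"text"` (MCFA = 12:0 + 13:0, LCFA = 14+ carbons).
#' @param n3_def `"series"` (default: full omega-3 series) or `"text"`
#'   (18:3n3 + 20:3n3 only).
#' @param n6_def `"series"` (default: 18:2, 18:3n6, 20:2, 20:3n6, 20:4,
#'   22:4), `"series_cla"` (adds the two CLA isomers), or `"text"`
#'   (18:3n6 + 20:3n6 only).
#' @return Tibble: `animal_id`, the seven composite sums, and the four
#'   ratio traits `PUFA/SFA`, `(14:0+16:0)/All`, `AI`, `n3/n6`.
#' @export
fa_composites <- function(profile, basis = c("fat_percent", "beef"),
                          mcfa_def = "chain_length", n3_def = "series",
                          n6_def = "series") {
  basis <- match.arg(basis)
  profile <- tibble::as_tibble(profile)
  w <- as.matrix(profile[setdiff(names(profile), "animal_id")])
  mem <- fa_members(mcfa_def, n3_def, n6_def)
  out <- tibble::tibble(animal_id = profile$animal_id)
  for (nm in names(mem)) out[[nm]] <- row_sum(w, mem[[nm]])
  if (basis == "fat_percent") {
    all_fa <- rowSums(w)
    safe_ratio <- function(num, den, label) {
      r <- 100 * num / den
      bad <- den == 0
      if (any(bad)) {
        warn(sprintf("%d zero denominator(s) in %s: NA returned", sum(bad), label))
        r[bad] <- NA_real_
      }
      r
    }
    out[["PUFA/SFA"]] <- safe_ratio(out$PUFA, out$SFA, "PUFA/SFA")
    out[["(14:0+16:0)/All"]] <-
      safe_ratio(row_sum(w, "14:0") + row_sum(w, "16:0"), all_fa, "(14:0+16:0)/All")
    out[["AI"]] <- atherogenic_index(profile)
    out[["n3/n6"]] <- safe_ratio(out$n3, out$n6, "n3/n6")
  } else {
    out[["PUFA/SFA"]] <- NA_real_
    out[["(14:0+16:0)/All"]] <- NA_real_
    out[["AI"]] <- NA_real_
    out[["n3/n6"]] <- NA_real_
  }
  out
}

#' Derive the full analyzed trait set from a fatty-acid profile
#'
#' Binds the individual fatty-acid measurements to their composites and
#' indices, yielding the full per-animal trait table (38 individual acids
#' plus 11 composite/ratio traits when all are present).
#'
#' @inheritParams fa_composites
#' @return Tibble: `animal_id`, one column per individual fatty acid, then
#'   the composite and ratio traits.
#' @export
derive_traits <- function(profile, basis = c("fat_percent", "beef"), ...) {
  basis <- match.arg(basis)
  dplyr::left_join(tibble::as_tibble(profile),
                   fa_composites(profile, basis = basis, ...),
                   by = "animal_id")
}

#' Per-trait summary statistics (mean, SD, CV x 100)
#'
#' @param traits Data frame of per-animal trait values; every column except
#'   `animal_id` is summarized.
#' @return Tibble with columns `trait`, `mean`, `sd`, `cv` where `cv` is
#'   the coefficient of variation times 100 (sample SD, n-1 denominator);
#'   `cv` is `NA` when the mean is zero.
#' @export
fa_summary <- function(traits) {
  traits <- tibble::as_tibble(traits)
  cols <- setdiff(names(traits), "animal_id")
  purrr::map_dfr(cols, function(nm) {
    x <- traits[[nm]]
    x <- x[is.finite(x)]
    if (length(x) < 2) {
      return(tibble::tibble(trait = nm, mean = mean(x), sd = NA_real_, cv = NA_real_))
    }
    m <- mean(x)
    s <- stats::sd(x)
    tibble::tibble(trait = nm, mean = m, sd = s,
                   cv = if (m == 0) NA_real_ else 100 * s / m)
  })
}

#' Coefficient of variation times 100
#'
#' @param mean,sd Trait mean and sample standard deviation.
#' @return `100 * sd / mean`, `NA` when the mean is zero.
#' @export
cv_pct <- function(mean, sd) ifelse(mean == 0, NA_real_, 100 * sd / mean)
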