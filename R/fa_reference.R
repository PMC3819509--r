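#' Reference list of the 38 analyzed fatty acids
#'
#' One row per fatty acid measured by gas chromatography in beef longissimus
#' muscle, with its carbon-chain length, number of double bonds, saturation
#' class, omega series where applicable, and a representative Angus
#' longissimus profile (mean and SD on the beef basis, g x 1e-5 per g meat,
#' and on the fat-percent basis, % of total extracted fatty acids).  The
#' representative profile is the package default for
#' [simulate_fa_profiles()] and for worked examples; real analyses supply
#' their own measurements.
#'
#' Saturation class follows bond count: `SFA` (0 double bonds), `MUFA` (1),
#' `PUFA` (2+, conjugated linoleic acids included).  The `series` column
#' marks omega-3 and omega-6 membership of the polyunsaturates; the two CLA
#' isomers are tagged `cla` so that either convention for the omega-6 sum
#' can be assembled (see [fa_composites()]).
#'
#' @return A tibble with columns `fatty_acid`, `carbons`, `double_bonds`,
#'   `class`, `series`, `mean_beef`, `sd_beef`, `mean_fat_pct`,
#'   `sd_fat_pct`.
#' @export
#' @examples
#' fa_reference()
fa_reference <- function() {
  ref <- tibble::tribble(
    ~fatty_acid,          ~carbons, ~double_bonds, ~series, ~mean_beef, ~sd_beef, ~mean_fat_pct, ~sd_fat_pct,
    "10:0",                10L, 0L, NA,        1.96,    2.72,  0.035, 0.049,
    "12:0",                12L, 0L, NA,        3.59,    3.38,  0.062, 0.055,
    "13:0",                13L, 0L, NA,        0.27,    0.57,  0.005, 0.010,
    "14:0",                14L, 0L, NA,      160.34,   73.46,  2.707, 0.574,
    "14:1",                14L, 1L, NA,       33.32,   17.45,  0.565, 0.196,
    "15:0",                15L, 0L, NA,       33.84,   18.79,  0.593, 0.330,
    "16:0",                16L, 0L, NA,     1558.61,  596.70, 26.549, 1.792,
    "16:1",                16L, 1L, NA,      206.06,   92.83,  3.478, 0.710,
    "17:0",                17L, 0L, NA,       81.07,   42.57,  1.347, 0.392,
    "17:1",                17L, 1L, NA,       64.24,   34.59,  1.071, 0.369,
    "18:0",                18L, 0L, NA,      790.43,  292.08, 13.637, 1.887,
    "cis-9 18:1",          18L, 1L, NA,     2281.82,  923.99, 38.555, 2.787,
    "cis-11 18:1",         18L, 1L, NA,        5.89,    6.93,  0.099, 0.105,
    "cis-12 18:1",         18L, 1L, NA,       15.59,   13.05,  0.255, 0.162,
    "cis-13 18:1",         18L, 1L, NA,        5.87,    7.47,  0.097, 0.103,
    "trans-6/9 18:1",      18L, 1L, NA,        8.09,   12.48,  0.128, 0.190,
    "trans-10/11 18:1",    18L, 1L, NA,      212.59,  119.07,  3.599, 1.380,
    "trans-12 18:1",       18L, 1L, NA,        3.98,   10.09,  0.063, 0.128,
    "trans-15 18:1",       18L, 1L, NA,       61.99,   39.95,  1.037, 0.506,
    "18:2",                18L, 2L, "n6",    217.59,   70.66,  3.948, 1.313,
    "18:3n3",              18L, 3L, "n3",     10.52,   11.19,  0.171, 0.158,
    "18:3n6",              18L, 3L, "n6",      0.88,    2.32,  0.014, 0.033,
    "20:0",                20L, 0L, NA,        1.10,    1.95,  0.020, 0.034,
    "20:1",                20L, 1L, NA,        4.88,    5.99,  0.094, 0.110,
    "20:2",                20L, 2L, "n6",      2.07,    2.87,  0.037, 0.048,
    "20:3n3",              20L, 3L, "n3",      1.49,    5.48,  0.024, 0.093,
    "20:3n6",              20L, 3L, "n6",      7.25,    8.88,  0.122, 0.154,
    "20:4",                20L, 4L, "n6",     41.38,   16.37,  0.773, 0.378,
    "20:5",                20L, 5L, "n3",      6.80,   12.89,  0.133, 0.282,
    "22:0",                22L, 0L, NA,        5.45,    7.03,  0.110, 0.152,
    "22:1",                22L, 1L, NA,        0.30,    3.20,  0.005, 0.056,
    "22:4",                22L, 4L, "n6",      3.18,    6.71,  0.062, 0.135,
    "22:5",                22L, 5L, "n3",      7.50,    8.81,  0.130, 0.162,
    "22:6",                22L, 6L, "n3",      4.02,    7.43,  0.083, 0.161,
    "23:0",                23L, 0L, NA,        3.54,    8.11,  0.069, 0.170,
    "24:0",                24L, 0L, NA,        7.27,   17.32,  0.143, 0.367,
    "CLAc9t11",            18L, 2L, "cla",     7.32,    8.29,  0.125, 0.127,
    "CLAt10c12",           18L, 2L, "cla",     3.32,    5.06,  0.051, 0.071
  )
  dplyr::mutate(
    ref,
    class = dplyr::case_when(
      .data$double_bonds == 0L ~ "SFA",
      .data$double_bonds == 1L ~ "MUFA",
      TRUE ~ "PUFA"
    ),
    .after = "double_bonds"
  )
}

#' Names of the 38 individual fatty-acid traits
#' @return Character vector of fatty-acid names in reporting order.
#' @export
fa_names <- function() fa_reference()$fatty_acid
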