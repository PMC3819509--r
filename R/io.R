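# Sniff the delimiter (tab, comma, or runs of whitespace) from the header
# line; all readers accept any of the three.
read_delim_auto <- function(path, na) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    readr::read_tsv(path, na = na, show_col_types = FALSE, progress = FALSE)
  } else if (grepl(",", first)) {
    readr::read_csv(path, na = na, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_table(path, na = na, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read an animals-by-SNPs dosage matrix
#'
#' Reads allele dosages (counts of the B allele from an A/B-calling chip, so
#' values 0/1/2) from delimited text.  The default layout is a header row of
#' SNP identifiers with the first column holding animal identifiers.  The
#' `"raw"` dialect accepts a PLINK `--recode A`-style export (leading FID,
#' IID, PAT, MAT, SEX, PHENOTYPE columns; FID_IID becomes the animal id).
#'
#' Entries coded `NA`, `-9` or `.` are treated as missing; any other
#' non-\{0,1,2\} value is a format error naming the offending row and
#' column.
#'
#' @param path Path to a whitespace- or tab/comma-delimited text file.
#' @param format `"tsv"` (default) or `"raw"`.
#' @return Numeric matrix (animals x SNPs) with animal ids as rownames and
#'   SNP ids as colnames; missing dosages are `NA`.
#' @export
read_genotypes <- function(path, format = c("tsv", "raw")) {
  format <- match.arg(format)
  df <- read_delim_auto(path, na = c("NA", "-9", "."))
  if (format == "raw") {
    lead <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(df))
    if (!all(c("FID", "IID") %in% lead)) abort("raw format requires FID and IID columns")
    ids <- paste(df$FID, df$IID, sep = "_")
    df <- df[setdiff(names(df), lead)]
    # PLINK appends the counted allele to the SNP name (snp_A); strip it
    names(df) <- sub("_[ACGT0-9]+$", "", names(df))
  } else {
    ids <- as.character(df[[1]])
    df <- df[-1]
  }
  if (anyDuplicated(ids)) abort("duplicate animal ids in genotype file")
  if (anyDuplicated(names(df))) abort("duplicate SNP ids in genotype file")
  orig_na <- as.matrix(is.na(df))
  z <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) z <- matrix(z, nrow = 1L, dimnames = list(NULL, names(df)))
  bad <- which(!is.na(z) & !z %in% c(0, 1, 2), arr.ind = TRUE)
  nonnum <- which(is.na(z) & !orig_na, arr.ind = TRUE)
  bad <- rbind(bad, nonnum)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "invalid dosage at row %s (animal '%s'), column '%s': dosages must be 0, 1 or 2",
      bad[1, 1], ids[bad[1, 1]], colnames(z)[bad[1, 2]]
    ))
  }
  rownames(z) <- ids
  z
}

#' Mean-impute missing dosages
#'
#' Missing entries of a dosage matrix are replaced by twice the observed
#' allele frequency of the SNP (the column mean), which preserves allele
#' frequencies.
#'
#' @param genotypes Dosage matrix from [read_genotypes()] or
#'   [simulate_genotypes()].
#' @return The matrix with no missing values.
#' @export
impute_dosages <- function(genotypes) {
  miss <- is.na(genotypes)
  if (!any(miss)) return(genotypes)
  mu <- colMeans(genotypes, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(miss, arr.ind = TRUE)
  genotypes[miss] <- mu[idx[, 2]]
  genotypes
}

#' Read a SNP map
#'
#' @param path Delimited text with header columns `snp_id`, `chromosome`,
#'   `position_bp`.  Unmapped SNPs carry `NA` chromosome/position.
#' @return Tibble with those three columns (`chromosome` as character,
#'   `position_bp` as double).
#' @export
read_marker_map <- function(path) {
  df <- read_delim_auto(path, na = c("NA", ""))
  need <- c("snp_id", "chromosome", "position_bp")
  if (!all(need %in% names(df))) {
    abort(paste("marker map must have columns:", paste(need, collapse = ", ")))
  }
  dplyr::mutate(df[need],
                snp_id = as.character(.data$snp_id),
                chromosome = as.character(.data$chromosome),
                position_bp = as.numeric(.data$position_bp))
}

#' Read a phenotype / fixed-effect table
#'
#' @param path Delimited text with header; must contain `animal_id` and
#'   `contemporary_group` columns, plus trait and covariate columns.
#' @return Tibble.
#' @export
read_traits <- function(path) {
  df <- read_delim_auto(path, na = c("NA", ""))
  need <- c("animal_id", "contemporary_group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste("trait table missing required column(s):", paste(miss, collapse = ", ")))
  }
  dplyr::mutate(df, animal_id = as.character(.data$animal_id),
                contemporary_group = as.character(.data$contemporary_group))
}

#' Write a result table as TSV
#'
#' Plain TSV writer used by every stage; numeric values are written at full
#' precision so that write-then-read round-trips losslessly.
#'
#' @param x Data frame (or dosage matrix, written with an `animal_id`
#'   first column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- dplyr::bind_cols(tibble::tibble(animal_id = rownames(x)),
                          tibble::as_tibble(x, .name_repair = "minimal"))
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Drop animals with incomplete records
#'
#' Removes animals missing the trait value, contemporary group, or any
#' covariate, and reports how many were removed.
#'
#' @param traits Trait table.
#' @param trait Name of the trait column to require.
#' @param covariates Covariate column names to require (present columns
#'   only are checked).
#' @return The filtered tibble with attribute `n_removed`; the count is
#'   also reported via a message.
#' @export
drop_incomplete <- function(traits, trait,
                            covariates = c("fat_thickness", "lma", "hcw", "extracted_fat")) {
  traits <- tibble::as_tibble(traits)
  covariates <- intersect(covariates, names(traits))
  need <- c(trait, "contemporary_group", covariates)
  ok <- rep(TRUE, nrow(traits))
  for (nm in need) ok <- ok & !is.na(traits[[nm]]) & traits[[nm]] != ""
  n_removed <- sum(!ok)
  inform(sprintf("%d animal(s) with incomplete records removed; %d analyzed",
                 n_removed, sum(ok)))
  out <- traits[ok, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}
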