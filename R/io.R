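parse_numeric_table <- function(path, what, integer_codes = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop(what, " file must have sample ids plus data columns")
  ids <- df[[1L]]
  out <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                dimnames = list(ids, colnames(df)[-1L]))
  for (j in seq_len(ncol(out))) {
    cell <- df[[j + 1L]]
    missing <- is.na(cell) | cell %in% c("", "NA", "na", ".")
    val <- suppressWarnings(as.numeric(cell))
    bad <- !missing & is.na(val)
    if (!is.null(integer_codes))
      bad <- bad | (!missing & !is.na(val) & !(val %in% integer_codes))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("malformed %s value '%s' at row %d (sample '%s'), column '%s'",
                   what, cell[i], i, ids[i], colnames(out)[j]))
    }
    val[missing] <- NA_real_
    out[, j] <- val
  }
  out
}

#' Read and align the three study inputs
#'
#' Each input is a TSV with a header row and sample identifiers in the
#' first column.  Genotypes must be coded 0/1/2 (or `NA`).  Samples are
#' aligned by inner join across the three files; dropped samples are
#' counted in the `dropped_samples` attribute.
#'
#' @param genotype_path,expression_path,phenotype_path file paths.
#' @return a [cg_data] with an attribute `dropped_samples`.
#' @export
read_inputs <- function(genotype_path, expression_path, phenotype_path) {
  g <- parse_numeric_table(genotype_path, "genotype", integer_codes = 0:2)
  e <- parse_numeric_table(expression_path, "expression")
  d <- parse_numeric_table(phenotype_path, "phenotype")
  if (ncol(d) != 1L) stop("phenotype file must have exactly one value column")
  shared <- Reduce(intersect, list(rownames(g), rownames(e), rownames(d)))
  if (!length(shared)) stop("the three inputs share no sample identifiers")
  dropped <- length(unique(c(rownames(g), rownames(e), rownames(d)))) -
    length(shared)
  if (dropped > 0L)
    message(dropped, " sample(s) not present in all three inputs were dropped")
  out <- cg_data(genotypes = g[shared, , drop = FALSE],
                 expression = e[shared, , drop = FALSE],
                 phenotype = d[shared, 1L],
                 phenotype_name = colnames(d))
  attr(out, "sample_ids") <- shared
  attr(out, "dropped_samples") <- dropped
  out
}

#' Write result tables as TSV
#'
#' @param tables a named list of data frames (or a single data frame).
#' @param paths character vector of output paths, one per table.
#' @return the paths, invisibly.
#' @export
write_results <- function(tables, paths) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) == length(paths))
  for (k in seq_along(tables))
    utils::write.table(tables[[k]], paths[[k]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Removes SNPs whose fraction of missing genotypes exceeds `max_missing`
#' or whose minor allele frequency falls below `min_maf` (strict `<`).
#' The allele frequency is computed from allele counts over non-missing
#' genotypes: `(2 * n_hom + n_het) / (2 * n_nonmissing)` for each allele,
#' the minor being the rarer; a monomorphic SNP has MAF 0 and is removed.
#'
#' @param genotypes samples x SNPs matrix of codes 0/1/2 or `NA` (code 1 =
#'   heterozygote).
#' @param max_missing maximum tolerated missing fraction (default 0.3).
#' @param min_maf minimum minor allele frequency (default 0.1).
#' @return list with `genotypes` (the retained columns) and `report` (one
#'   row per SNP: `snp`, `missing_frac`, `maf`, `removed`, `reason`).
#' @export
filter_snps <- function(genotypes, max_missing = 0.3, min_maf = 0.1) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  g <- as.matrix(genotypes)
  if (is.null(colnames(g))) colnames(g) <- paste0("L", seq_len(ncol(g)))
  report <- data.frame(snp = colnames(g), missing_frac = NA_real_,
                       maf = NA_real_, removed = FALSE, reason = "",
                       stringsAsFactors = FALSE)
  for (j in seq_len(ncol(g))) {
    x <- g[, j]
    miss <- mean(is.na(x))
    x <- x[!is.na(x)]
    maf <- if (length(x)) {
      f <- (2 * sum(x == 2) + sum(x == 1)) / (2 * length(x))
      min(f, 1 - f)
    } else 0
    report$missing_frac[j] <- miss
    report$maf[j] <- maf
    if (miss > max_missing) {
      report$removed[j] <- TRUE
      report$reason[j] <- "missingness"
    } else if (maf < min_maf) {
      report$removed[j] <- TRUE
      report$reason[j] <- "maf"
    }
  }
  list(genotypes = g[, !report$removed, drop = FALSE], report = report)
}

#' Construct a dose-response record
#'
#' @param subject subject identifier.
#' @param doses strictly increasing positive doses (e.g. nM or mM).
#' @param viability percent cell viability at each dose; may contain `NA`.
#' @return an object of class `dose_response`.
#' @export
dose_response <- function(subject, doses, viability) {
  doses <- as.numeric(doses)
  viability <- as.numeric(viability)
  stopifnot(length(doses) == length(viability))
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (any(!is.na(viability) & (viability < 0 | viability > 200)))
    stop("viability outside the plausible [0, 200] range")
  structure(list(subject = as.character(subject), doses = doses,
                 viability = viability), class = "dose_response")
}

#' Area under the log-dose response curve
#'
#' Trapezoidal area of viability against natural-log dose over the
#' observed dose range; a large area indicates strong chemo-resistance.
#' Used as the quantitative phenotype summarizing a subject's cytotoxicity
#' profile.
#'
#' @param dr a [dose_response()] with no missing viability (impute first
#'   with [impute_missing_dose()]).
#' @return the area (viability-percent times log-dose units).
#' @export
auc_log_dose <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  if (anyNA(dr$viability))
    stop("missing viability values; impute first with impute_missing_dose()")
  if (length(dr$doses) < 2L) stop("need at least two doses")
  x <- log(dr$doses)
  v <- dr$viability
  sum((v[-1L] + v[-length(v)]) / 2 * diff(x))
}

#' Impute missing viability values within a subject
#'
#' Fits an ordinary least-squares line of viability on log-dose (or raw
#' dose) over the subject's non-missing observations and fills each
#' missing value with its prediction; missing the first dose would
#' otherwise bias the area under the curve downward.  Non-missing values
#' are untouched.
#'
#' @param dr a [dose_response()].
#' @param on_log_dose regress on `log(dose)` (default) rather than raw
#'   dose.
#' @return a [dose_response()] with no missing viability.
#' @export
impute_missing_dose <- function(dr, on_log_dose = TRUE) {
  stopifnot(inherits(dr, "dose_response"))
  miss <- is.na(dr$viability)
  if (!any(miss)) return(dr)
  if (sum(!miss) < 2L)
    stop("subject '", dr$subject,
         "': need at least two non-missing viability values to impute")
  x <- if (on_log_dose) log(dr$doses) else dr$doses
  fit <- stats::lm(v ~ x, data = data.frame(v = dr$viability[!miss],
                                            x = x[!miss]))
  pred <- stats::predict(fit, newdata = data.frame(x = x[miss]))
  out <- dr
  out$viability[miss] <- as.numeric(pred)
  out
}
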