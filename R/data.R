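#' Longitudinal phenotype records
#'
#' Long-format records: one row per measurement, columns `id`, `time`,
#' `value`. Repeat counts may differ between individuals.
#'
#' @param id individual identifiers (coerced to character).
#' @param time numeric recording times.
#' @param value numeric phenotypic values.
#' @return A data frame of class `"longitudinal_data"`.
#' @export
longitudinal_data <- function(id, time, value) {
  id <- as.character(id)
  stopifnot(length(id) == length(time), length(time) == length(value))
  if (!all(is.finite(time))) stop("longitudinal_data: non-finite time(s)")
  if (!all(is.finite(value))) stop("longitudinal_data: non-finite value(s)")
  out <- data.frame(id = id, time = as.numeric(time),
                    value = as.numeric(value), stringsAsFactors = FALSE)
  class(out) <- c("longitudinal_data", "data.frame")
  out
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat(sprintf("<longitudinal_data> %d records on %d individuals, time %g..%g\n",
              nrow(x), length(unique(x$id)), min(x$time), max(x$time)))
  invisible(x)
}

#' Read longitudinal phenotypes from TSV
#'
#' Requires a header with columns `id`, `time`, `value`; lines starting with
#' `#` are ignored. Extra columns are preserved as attributes for use as
#' additional fixed covariates.
#'
#' @param path file path.
#' @return A [longitudinal_data()] object.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "time", "value")
  if (!all(need %in% names(df))) {
    stop("read_phenotypes: header must contain id, time, value; got: ",
         paste(names(df), collapse = ", "))
  }
  out <- longitudinal_data(df$id, df$time, df$value)
  extra <- setdiff(names(df), need)
  if (length(extra)) attr(out, "covariates") <- df[extra]
  out
}

#' Genotype matrix
#'
#' SNPs in rows, individuals in columns; values are additive allele dosages
#' of the coded (ALT/second) allele, `0/1/2` hard calls or dosages in
#' `[0, 2]`. The coded-allele frequency per SNP is computed from the sample.
#'
#' @param values numeric matrix (SNPs x individuals) with rownames = SNP ids
#'   and colnames = individual ids.
#' @param map optional data frame with columns `snp`, `chrom`, `pos`.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values, map = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("snp", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("genotype_matrix: individual ids (column names) are required")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("genotype_matrix: dosages must lie in [0, 2]")
  }
  structure(list(values = values,
                 snp_ids = rownames(values),
                 ind_ids = colnames(values),
                 freq = rowMeans(values, na.rm = TRUE) / 2,
                 map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d individuals\n",
              length(x$snp_ids), length(x$ind_ids)))
  invisible(x)
}

#' Read genotypes from a TSV matrix or a VCF
#'
#' TSV: first column is the SNP id, remaining columns one individual each
#' (header = individual ids), values 0/1/2 or dosages. VCF (`.vcf`): parsed
#' with the vcfR package; the DS FORMAT field is used when present,
#' otherwise GT allele counts of the ALT allele.
#'
#' @param path file path (`.tsv`/`.txt` or `.vcf`).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(.read_genotypes_vcf(path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- as.character(df[[1]])
  storage.mode(vals) <- "double"
  genotype_matrix(vals)
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotypes: reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(v@gt[, "FORMAT"])
  if (any(grepl("(^|:)DS(:|$)", fmt))) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      sapply(strsplit(col, "[/|]"), function(a) {
        if (all(is.na(a)) || any(a == ".")) NA_real_ else sum(a != "0")
      })
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(v@gt), byrow = FALSE)
  }
  ids <- v@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(ds) <- ids
  map <- data.frame(snp = ids, chrom = v@fix[, "CHROM"],
                    pos = as.numeric(v@fix[, "POS"]), stringsAsFactors = FALSE)
  genotype_matrix(ds, map = map)
}

#' Model specification: basis orders
#'
#' @param nf order of the population-mean curve (and of SNP effect curves).
#' @param nr1 order of the additive genetic random regression.
#' @param nr2 order of the permanent environmental random regression.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(nf = 2L, nr1 = 2L, nr2 = 2L) {
  for (o in list(nf, nr1, nr2)) {
    if (!is.numeric(o) || length(o) != 1L || o < 0 || o != round(o)) {
      stop("model_spec: orders must be non-negative integers")
    }
  }
  structure(list(nf = as.integer(nf), nr1 = as.integer(nr1),
                 nr2 = as.integer(nr2)), class = "model_spec")
}

#' Covariance components of the random regression model
#'
#' @param G covariance matrix of the additive-genetic regression
#'   coefficients, `(nr1+1) x (nr1+1)`.
#' @param P covariance matrix of the permanent-environment coefficients,
#'   `(nr2+1) x (nr2+1)`.
#' @param sigma_e2 residual variance (scalar, > 0).
#' @return An object of class `"variance_components"`.
#' @export
variance_components <- function(G, P, sigma_e2) {
  G <- as.matrix(G); P <- as.matrix(P)
  stopifnot(isSymmetric(unname(G), tol = 1e-8), isSymmetric(unname(P), tol = 1e-8),
            is.numeric(sigma_e2), length(sigma_e2) == 1L)
  if (sigma_e2 <= 0) stop("variance_components: sigma_e2 must be positive")
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8 ||
      min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("variance_components: G and P must be positive semi-definite")
  }
  structure(list(G = G, P = P, sigma_e2 = as.numeric(sigma_e2)),
            class = "variance_components")
}
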