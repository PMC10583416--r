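#' Construct a SummaryStats object from a data.frame
#'
#' Validates per-variant GWAS summary records and wraps them in a
#' [SummaryStats-class] object.  Rows violating the field invariants can
#' either abort construction (`on_invalid = "error"`) or be dropped with a
#' per-row reason attached as the `"load_report"` attribute
#' (`on_invalid = "drop"`), mirroring what [readSummaryStats()] does for
#' files.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name trait label.
#' @param trait_type `"quantitative"` (beta in SD units) or `"binary"`
#'   (beta in log-odds).
#' @param on_invalid `"error"` or `"drop"`.
#' @return A [SummaryStats-class] object; when `on_invalid = "drop"` the
#'   attribute `"load_report"` holds a data.frame (`variant_id`, `reason`)
#'   of rejected rows.
#' @export
SummaryStats <- function(records, trait_name, trait_type = c("quantitative", "binary"),
                         on_invalid = c("error", "drop")) {
  trait_type <- match.arg(trait_type)
  on_invalid <- match.arg(on_invalid)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records missing mandatory column(s): ", paste(miss, collapse = ", "))
  records <- records[, req, drop = FALSE]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    records[[col]] <- as.numeric(records[[col]])

  report <- validateRecords(records)
  if (nrow(report)) {
    if (on_invalid == "error")
      stop("invalid summary records: ",
           paste(unique(report$reason), collapse = "; "))
    records <- records[!records$variant_id %in% report$variant_id, , drop = FALSE]
  }
  rownames(records) <- NULL
  out <- new("SummaryStats", traitName = trait_name, traitType = trait_type,
             records = records)
  attr(out, "load_report") <- report
  out
}

# Per-row invariant checks; returns a (variant_id, reason) report.
validateRecords <- function(r) {
  reasons <- vector("list", nrow(r))
  flag <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  flag(is.na(r$variant_id) | !nzchar(r$variant_id), "missing variant_id")
  flag(!r$effect_allele %in% VALID_BASES | !r$other_allele %in% VALID_BASES,
       "allele not a single base A/C/G/T")
  flag(r$effect_allele == r$other_allele, "identical alleles")
  flag(!is.finite(r$se) | r$se <= 0, "nonpositive se")
  flag(!is.finite(r$beta), "missing beta")
  flag(!is.finite(r$pval) | r$pval <= 0 | r$pval > 1, "pval outside (0,1]")
  flag(!is.na(r$eaf) & (r$eaf < 0 | r$eaf > 1), "eaf outside [0,1]")
  flag(!is.finite(r$n) | r$n <= 0, "nonpositive n")
  flag(!is.finite(r$pos), "missing pos")
  flag(duplicated(r$variant_id), "duplicate variant_id")
  bad <- !vapply(reasons, is.null, logical(1))
  data.frame(variant_id = r$variant_id[bad],
             reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated table with a header row, renames columns through
#' `column_map`, validates every row, and returns a [SummaryStats-class]
#' object.  Invalid rows are rejected (not fatal) and listed, with reasons,
#' in the `"load_report"` attribute of the result.
#'
#' @param path file path to a TSV with a header row.
#' @param column_map named character vector mapping the canonical field
#'   names (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n`) to the file's column names.
#'   Defaults to the identity mapping.
#' @param trait_name,trait_type as in [SummaryStats()].
#' @param sep field separator (default tab).
#' @return A [SummaryStats-class]; rejected rows in `attr(, "load_report")`.
#' @export
readSummaryStats <- function(path, column_map = NULL, trait_name,
                             trait_type = c("quantitative", "binary"),
                             sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L)
    stop("empty summary-statistics file: ", path)
  std <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  if (is.null(column_map)) column_map <- setNames(std, std)
  for (field in std) {
    src <- if (field %in% names(column_map)) column_map[[field]] else field
    if (!src %in% names(raw))
      stop("missing mandatory column '", field, "' (looked for '", src, "')")
    raw[[field]] <- raw[[src]]
  }
  SummaryStats(raw[, std, drop = FALSE], trait_name = trait_name,
               trait_type = trait_type, on_invalid = "drop")
}

#' Write SummaryStats (and its load report) to TSV
#'
#' @param object a [SummaryStats-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(object, path) {
  write.table(records(object), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct an LDMatrix
#'
#' @param r square numeric correlation matrix.
#' @param variant_ids variant ids in matrix order; defaults to rownames.
#' @return An [LDMatrix-class].  Asymmetries within 1e-8 are symmetrized
#'   and the diagonal is set to exactly 1; larger violations are errors.
#' @export
LDMatrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(variant_ids)) stop("variant ids required")
  if (any(!is.finite(r))) stop("LD matrix entries must be finite")
  if (max(abs(r)) > 1 + 1e-8)
    stop("LD correlations must lie in [-1, 1] (max |r| = ",
         format(max(abs(r))), ")")
  if (max(abs(r - t(r))) > 1e-8)
    stop("LD matrix asymmetric beyond tolerance 1e-8")
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- NULL
  new("LDMatrix", variantIds = as.character(variant_ids), r = r)
}

#' Read an LD matrix from TSV
#'
#' Expects a header row of variant ids and a leading id column; the body is
#' the square matrix of pairwise correlations r.
#'
#' @param path TSV path.
#' @return An [LDMatrix-class].
#' @export
readLDMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m))
    stop("LD matrix file is not square: ", nrow(m), " x ", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column ids disagree")
  LDMatrix(m, variant_ids = rownames(m))
}

#' Write an LDMatrix to TSV
#'
#' @param object an [LDMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(object, path) {
  m <- ldValues(object)
  df <- data.frame(variant_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Subset a SummaryStats to the given variant ids (keeping their order where
# present); internal convenience used throughout selection and harmonization.
subsetStats <- function(stats, ids) {
  r <- records(stats)
  r <- r[match(ids[ids %in% r$variant_id], r$variant_id), , drop = FALSE]
  rownames(r) <- NULL
  new("SummaryStats", traitName = traitName(stats),
      traitType = traitType(stats), records = r)
}
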