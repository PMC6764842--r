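#' Construct a validated summary-statistics table
#'
#' Per-variant univariate GWAS results: the marginal effect of each variant
#' on the trait from one-at-a-time regressions, as shared by GWAS and
#' meta-GWAS consortia. For binary traits `beta` holds the log odds ratio.
#'
#' @param variant_id character vector of unique variant identifiers.
#' @param chrom chromosome labels (coerced to character).
#' @param pos 1-based base-pair positions.
#' @param effect_allele,other_allele single-character alleles in A/C/G/T;
#'   `beta` is per copy of `effect_allele`.
#' @param beta univariate effect estimates (linear scale, or log-OR when
#'   `is_binary`).
#' @param se standard errors, strictly positive.
#' @param eaf effect-allele frequencies in (0, 1); may be `NA` and filled in
#'   from a reference panel during [harmonize()].
#' @param n GWAS sample size, scalar or per-variant.
#' @param is_binary logical flag: `beta` is a log odds ratio.
#' @return a `data.frame` of class `summary_stats` with attribute
#'   `is_binary`.
#' @export
summary_stats <- function(variant_id, chrom, pos, effect_allele, other_allele,
                          beta, se, eaf = NA_real_, n, is_binary = FALSE) {
  x <- data.frame(
    variant_id = as.character(variant_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta = as.numeric(beta),
    se = as.numeric(se),
    eaf = as.numeric(eaf),
    n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  validate_summary_stats(x)
  attr(x, "is_binary") <- isTRUE(is_binary)
  class(x) <- c("summary_stats", "data.frame")
  x
}

validate_summary_stats <- function(x) {
  if (anyDuplicated(x$variant_id))
    stop("duplicate variant_id in summary statistics", call. = FALSE)
  if (any(!is.finite(x$se)) || any(x$se <= 0))
    stop("all standard errors must be finite and > 0", call. = FALSE)
  ok_eaf <- is.na(x$eaf) | (x$eaf > 0 & x$eaf < 1)
  if (!all(ok_eaf))
    stop("eaf must lie strictly in (0, 1) where present", call. = FALSE)
  if (any(!is.finite(x$n)) || any(x$n <= 0))
    stop("n must be positive", call. = FALSE)
  invisible(x)
}

default_column_map <- c(
  variant_id = "snp", chrom = "chr", pos = "bp",
  effect_allele = "a1", other_allele = "a2",
  beta = "beta", se = "se", eaf = "eaf", n = "n"
)

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a whitespace/tab-delimited header-bearing file and maps its columns
#' onto the canonical [summary_stats()] fields. Rows with missing `beta`,
#' `se`, or `eaf` (when an eaf column is present), or with `se <= 0`, are
#' dropped with a reported count.
#'
#' @param path path to the file.
#' @param column_map named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `eaf`, `n`) to column names in the file; entries you omit fall
#'   back to the defaults `snp, chr, bp, a1, a2, beta, se, eaf, n`.
#' @param n GWAS sample size to use when the file has no `n` column.
#' @param is_binary are the effects log odds ratios?
#' @return a [summary_stats()] object.
#' @export
read_summary_stats <- function(path, column_map = NULL, n = NULL,
                               is_binary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- default_column_map
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad))
      stop("unknown column_map entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    map[names(column_map)] <- column_map
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "beta", "se")
  missing_cols <- mandatory[!map[mandatory] %in% names(dt)]
  if (length(missing_cols))
    stop("mandatory column(s) absent from ", path, ": ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)

  has_eaf <- map[["eaf"]] %in% names(dt)
  has_n <- map[["n"]] %in% names(dt)
  if (!has_n && is.null(n))
    stop("no sample-size column '", map[["n"]], "' and no n= supplied",
         call. = FALSE)

  keep <- is.finite(dt[[map[["beta"]]]]) & is.finite(dt[[map[["se"]]]]) &
    dt[[map[["se"]]]] > 0
  if (has_eaf) keep <- keep & is.finite(dt[[map[["eaf"]]]])
  n_drop <- sum(!keep)
  if (n_drop > 0)
    warning(n_drop, " row(s) dropped for missing beta/se/eaf or se <= 0",
            call. = FALSE)
  dt <- dt[keep, , drop = FALSE]
  if (nrow(dt) == 0)
    stop("no rows survive validation in ", path, call. = FALSE)

  summary_stats(
    variant_id = dt[[map[["variant_id"]]]],
    chrom = dt[[map[["chrom"]]]],
    pos = dt[[map[["pos"]]]],
    effect_allele = dt[[map[["effect_allele"]]]],
    other_allele = dt[[map[["other_allele"]]]],
    beta = dt[[map[["beta"]]]],
    se = dt[[map[["se"]]]],
    eaf = if (has_eaf) dt[[map[["eaf"]]]] else NA_real_,
    n = if (has_n) dt[[map[["n"]]]] else n,
    is_binary = is_binary
  )
}

#' Write summary statistics to a tab-delimited file
#'
#' Uses the default column names understood by [read_summary_stats()], so a
#' write/read round trip is the identity.
#'
#' @param stats a [summary_stats()] object.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(
    snp = stats$variant_id, chr = stats$chrom, bp = stats$pos,
    a1 = stats$effect_allele, a2 = stats$other_allele,
    beta = stats$beta, se = stats$se, eaf = stats$eaf, n = stats$n
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
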