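#' Construct a reference genotype panel
#'
#' Holds an `n_ref x P` dosage matrix (counts of allele `a1`, values in
#' `[0, 2]`, `NA` allowed before QC) together with ordered variant metadata.
#' The panel supplies the plug-in estimate of the genetic correlation
#' matrix `X'X` used by the block-wise likelihood.
#'
#' @param genotypes numeric matrix, individuals in rows, variants in columns.
#' @param variants `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `a1`, `a2`, one row per genotype column, in column order.
#' @return an object of class `reference_panel`.
#' @export
reference_panel <- function(genotypes, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  need <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(variants)))
    stop("variants must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(variants) != ncol(genotypes))
    stop("variants rows (", nrow(variants), ") must match genotype columns (",
         ncol(genotypes), ")", call. = FALSE)
  rng <- range(genotypes, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]", call. = FALSE)
  variants <- data.frame(
    variant_id = as.character(variants$variant_id),
    chrom = as.character(variants$chrom),
    pos = as.integer(variants$pos),
    a1 = toupper(as.character(variants$a1)),
    a2 = toupper(as.character(variants$a2)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in panel", call. = FALSE)
  colnames(genotypes) <- variants$variant_id
  structure(list(genotypes = genotypes, variants = variants,
                 n_ref = nrow(genotypes)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", x$n_ref, "individuals x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

# subset a panel to a set of variant columns (index vector), keeping order
panel_subset <- function(panel, cols) {
  reference_panel(panel$genotypes[, cols, drop = FALSE],
                  panel$variants[cols, , drop = FALSE])
}

# 2-bit PLINK genotype codes -> dosage of .bim allele1
# 00 -> 2 copies of a1, 01 -> missing, 10 -> het, 11 -> 0 copies
plink_code_lut <- local({
  lut <- matrix(NA_real_, 256, 4)
  dose <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  for (b in 0:255) {
    codes <- c(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, (b %/% 64) %% 4)
    lut[b + 1, ] <- dose[as.character(codes)]
  }
  lut
})

#' Read a PLINK 1 binary fileset or transposed-raw text dosage matrix
#'
#' For a PLINK prefix, reads `<prefix>.bed` (SNP-major), `<prefix>.bim`, and
#' `<prefix>.fam`; dosages count copies of the `.bim` allele 1, with `NA`
#' for missing. A path ending in `.traw` (PLINK `--recode A-transpose`) is
#' read as a plain-text dosage matrix instead, which is handy for tests.
#'
#' @param path PLINK prefix (no extension) or a `.traw` file path.
#' @return a [reference_panel()].
#' @export
read_reference_genotypes <- function(path) {
  if (grepl("\\.traw$", path)) return(read_traw(path))
  bed <- paste0(path, ".bed"); bim <- paste0(path, ".bim")
  fam <- paste0(path, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f, call. = FALSE)

  bimdat <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chrom", "variant_id", "cm", "pos",
                                     "a1", "a2"))
  famdat <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famdat); P <- nrow(bimdat)
  nbytes <- ceiling(n / 4)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 ||
      !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file: ", bed, call. = FALSE)
  body <- raw[-(1:3)]
  if (length(body) != nbytes * P)
    stop(".bed size inconsistent with .bim/.fam dimensions (expected ",
         nbytes * P, " genotype bytes, found ", length(body), ")",
         call. = FALSE)

  codes <- plink_code_lut[as.integer(body) + 1L, , drop = FALSE]
  g <- matrix(t(codes), nrow = 4 * nbytes, ncol = P)
  g <- g[seq_len(n), , drop = FALSE]

  reference_panel(g, data.frame(
    variant_id = bimdat$variant_id, chrom = bimdat$chrom, pos = bimdat$pos,
    a1 = bimdat$a1, a2 = bimdat$a2, stringsAsFactors = FALSE))
}

read_traw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  meta_cols <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
  if (!all(meta_cols %in% names(dt)))
    stop(".traw file must have columns ", paste(meta_cols, collapse = ", "),
         call. = FALSE)
  g <- t(as.matrix(dt[, setdiff(names(dt), meta_cols), drop = FALSE]))
  reference_panel(g, data.frame(
    variant_id = dt$SNP, chrom = dt$CHR, pos = dt$POS,
    a1 = dt$COUNTED, a2 = dt$ALT, stringsAsFactors = FALSE))
}

#' Write a panel as a PLINK 1 binary fileset
#'
#' Dosages must be integer 0/1/2 or `NA`; they are encoded as counts of the
#' `.bim` allele 1 in a SNP-major `.bed`. Individuals are given synthetic
#' IDs `ind1..indN` unless `iid` is supplied.
#'
#' @param panel a [reference_panel()].
#' @param prefix output path prefix (writes `.bed`, `.bim`, `.fam`).
#' @param iid optional character vector of individual IDs.
#' @param pheno optional phenotype vector for the `.fam` file (default -9).
#' @export
write_reference_panel <- function(panel, prefix, iid = NULL, pheno = NULL) {
  g <- panel$genotypes
  if (any(abs(g - round(g)) > 1e-9, na.rm = TRUE))
    stop("PLINK .bed requires hard-call dosages 0/1/2", call. = FALSE)
  n <- nrow(g); P <- ncol(g); nbytes <- ceiling(n / 4)

  # dosage of a1 -> 2-bit code
  code <- matrix(3L, 4 * nbytes, P)  # pad with hom-a2 (code 3 -> dosage 0)
  gm <- round(g)
  cd <- matrix(0L, n, P)
  cd[gm == 2] <- 0L; cd[gm == 1] <- 2L; cd[gm == 0] <- 3L
  cd[is.na(gm)] <- 1L
  code[seq_len(n), ] <- cd
  i1 <- seq(1, 4 * nbytes, by = 4)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] + 64L * code[i1 + 3, , drop = FALSE]

  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  close(con)

  v <- panel$variants
  write.table(data.frame(v$chrom, v$variant_id, 0, v$pos, v$a1, v$a2),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (is.null(iid)) iid <- paste0("ind", seq_len(n))
  if (is.null(pheno)) pheno <- rep(-9, n)
  write.table(data.frame(iid, iid, 0, 0, 0, pheno),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read/write a PLINK-style phenotype file (FID IID PHENO)
#' @param path file path.
#' @return numeric phenotype vector named by IID.
#' @export
read_phenotype <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(d[[3]]), d[[2]])
}

#' @rdname read_phenotype
#' @param y phenotype vector; names are used as IIDs when present.
#' @export
write_phenotype <- function(y, path) {
  iid <- names(y) %||% paste0("ind", seq_along(y))
  write.table(data.frame(iid, iid, as.numeric(y)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
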