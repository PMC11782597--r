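#' Construct an LD matrix object
#'
#' Pairwise correlation (r, signed) between variant dosages. The sign of r
#' is defined with respect to each variant's counted allele, which must be
#' the effect allele of the accompanying summary statistics for signed
#' operations (proxy allele mapping); r-squared based operations (clumping,
#' region merging) are sign-invariant.
#'
#' @param r square numeric matrix of correlations.
#' @param rsids variant identifiers, in matrix order.
#' @param positions base-pair positions aligned to `rsids` (1-based).
#' @param tol symmetry tolerance.
#' @return object of class `ld_matrix` with elements `rsids`, `r`,
#'   `positions`.
#' @export
ld_matrix <- function(r, rsids, positions, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (length(rsids) != nrow(r)) stop("rsids length must match matrix dimension")
  if (length(positions) != nrow(r)) stop("positions length must match matrix dimension")
  if (any(abs(r - t(r)) > tol)) stop("LD matrix asymmetric beyond tolerance")
  if (any(abs(r) > 1 + tol)) stop("LD entries must satisfy |r| <= 1")
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rsids, rsids)
  out <- list(rsids = as.character(rsids), r = r, positions = as.numeric(positions))
  class(out) <- "ld_matrix"
  out
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants, span %s-%s bp\n",
              length(x$rsids), format(min(x$positions)), format(max(x$positions))))
  invisible(x)
}

#' Read a square LD matrix from tab-separated text
#'
#' Expects a header row of rsids, and one row per variant with the rsid in
#' the first column. Positions, if not supplied, are taken from an optional
#' `#positions` comment line (tab-separated, written by [write_ld_matrix()]);
#' otherwise they default to the variant index.
#'
#' @param path file path.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  positions <- NULL
  skip <- 0L
  if (startsWith(first, "#positions")) {
    positions <- as.numeric(strsplit(first, "\t")[[1]][-1])
    skip <- 1L
  }
  m <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                         row.names = 1, check.names = FALSE)
  r <- as.matrix(m)
  if (!identical(rownames(r), colnames(r))) {
    stop("LD matrix row and column rsids disagree")
  }
  if (is.null(positions)) positions <- seq_len(nrow(r))
  ld_matrix(r, rsids = rownames(r), positions = positions)
}

#' Write an LD matrix to tab-separated text
#'
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#positions", sprintf("%.0f", ld$positions)), collapse = "\t"), con)
  df <- as.data.frame(apply(ld$r, 2, function(col) sprintf("%.17g", col)))
  names(df) <- ld$rsids
  rn <- ld$rsids
  utils::write.table(cbind(rsid = rn, df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compute an LD matrix from a 0/1 haplotype panel
#'
#' @param haplotypes matrix with rows = haplotypes, columns = variants,
#'   entries 0/1 (counted allele = effect allele of the matching summary
#'   statistics).
#' @param rsids variant identifiers per column.
#' @param positions base-pair positions per column.
#' @return an [ld_matrix()] of empirical correlations.
#' @export
ld_from_haplotypes <- function(haplotypes, rsids, positions) {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% c(0, 1))) stop("haplotype entries must be 0/1")
  sds <- apply(haplotypes, 2, stats::sd)
  if (any(sds == 0)) stop("monomorphic variant in haplotype panel")
  r <- stats::cor(haplotypes)
  ld_matrix(r, rsids = rsids, positions = positions)
}

# Signed r between two variants; NA when either is absent from the matrix.
ld_r <- function(ld, rsid1, rsid2) {
  i <- match(rsid1, ld$rsids)
  j <- match(rsid2, ld$rsids)
  if (is.na(i) || is.na(j)) return(NA_real_)
  ld$r[i, j]
}
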