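#' Construct a validated GWAS summary-statistic set
#'
#' A `sumstat_set` holds per-variant association records for one trait:
#' rsid, chromosome, 1-based position, effect/other allele (single
#' nucleotides A/C/G/T), effect-allele frequency, beta, standard error,
#' p-value, per-SNP sample size, and (for binary traits) case/control
#' counts. Rows violating the record invariants are dropped and tallied in
#' the `drop_report` attribute, so validation is total: every input row is
#' either kept or accounted for.
#'
#' Units convention: `beta` is per copy of the effect allele, in SD units
#' for quantitative traits and log-odds for binary traits. Coordinates are
#' 1-based and all genomic intervals in this package are fully closed.
#'
#' @param records data.frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, and
#'   optionally `n_case`, `n_control`.
#' @param trait_id character scalar identifying the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param platform free-text provenance tag (e.g. measurement platform).
#' @param build genome-build label, treated as opaque metadata; the caller
#'   is responsible for build consistency across sets.
#' @param check_zp if `TRUE`, drop rows whose p-value disagrees with the
#'   |beta/se| z-score by more than `zp_tol` (relative, on the z scale).
#'   Off by default: p-values from mixed-model GWAS need not match the
#'   Wald z exactly.
#' @param zp_tol relative tolerance for the z-vs-p check.
#' @return An object of class `sumstat_set`: a list with elements
#'   `trait_id`, `trait_type`, `platform`, `build` and `records`, plus a
#'   `drop_report` attribute (data.frame of rsid/reason for dropped rows).
#' @export
sumstat_set <- function(records, trait_id, trait_type = c("quantitative", "binary"),
                        platform = NA_character_, build = NA_character_,
                        check_zp = FALSE, zp_tol = 0.1) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"n_case" %in% names(records)) records$n_case <- NA_real_
  if (!"n_control" %in% names(records)) records$n_control <- NA_real_
  records <- records[, c(needed, "n_case", "n_control")]
  records$rsid <- as.character(records$rsid)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case", "n_control")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  val <- validate_records(records, check_zp = check_zp, zp_tol = zp_tol)
  out <- list(trait_id = trait_id, trait_type = trait_type,
              platform = platform, build = build, records = val$kept)
  class(out) <- "sumstat_set"
  attr(out, "drop_report") <- val$dropped
  out
}

# Row-wise invariant checks; returns kept rows and a rsid/reason table for
# the rest. Reasons are checked in a fixed order so each row gets exactly
# one reason and counts add up.
validate_records <- function(records, check_zp = FALSE, zp_tol = 0.1) {
  nucl <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(!(records$effect_allele %in% nucl) |
                 !(records$other_allele %in% nucl), "invalid_allele")
  reason <- flag(records$effect_allele == records$other_allele, "identical_alleles")
  reason <- flag(records$pos < 1, "invalid_position")
  reason <- flag(!(records$se > 0), "nonpositive_se")
  reason <- flag(!(records$eaf > 0 & records$eaf < 1), "eaf_out_of_range")
  reason <- flag(!(records$pval > 0 & records$pval <= 1), "pval_out_of_range")
  reason <- flag(!(records$n > 0), "nonpositive_n")
  reason <- flag(is.na(records$beta), "missing_beta")
  has_cc <- !is.na(records$n_case) & !is.na(records$n_control)
  reason <- flag(has_cc &
                 abs(records$n_case + records$n_control - records$n) > 0.5,
                 "case_control_mismatch")
  if (check_zp) {
    z_beta <- abs(records$beta / records$se)
    z_p <- stats::qnorm(pmin(records$pval, 1) / 2, lower.tail = FALSE)
    ok <- is.finite(z_beta) & is.finite(z_p) &
      (pmax(z_beta, z_p) < 1 | abs(z_beta - z_p) <= zp_tol * pmax(z_beta, z_p))
    reason <- flag(!ok, "z_p_inconsistent")
  }
  dup <- duplicated(records$rsid)
  reason <- flag(dup, "duplicate_rsid")

  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  dropped <- data.frame(rsid = records$rsid[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(kept = kept, dropped = dropped)
}

#' @export
print.sumstat_set <- function(x, ...) {
  dr <- attr(x, "drop_report")
  cat(sprintf("<sumstat_set> trait '%s' (%s), platform %s: %d variants, %d dropped\n",
              x$trait_id, x$trait_type,
              ifelse(is.na(x$platform), "-", x$platform),
              nrow(x$records), if (is.null(dr)) 0L else nrow(dr)))
  invisible(x)
}

#' Drop report of a summary-statistic set
#'
#' @param set a `sumstat_set`.
#' @return data.frame with columns `rsid` and `reason`, one row per input
#'   row dropped during validation.
#' @export
drop_report <- function(set) {
  dr <- attr(set, "drop_report")
  if (is.null(dr)) dr <- data.frame(rsid = character(), reason = character())
  dr
}

#' Column-name presets for common summary-statistic layouts
#'
#' Returns a named character vector mapping internal field names to the
#' source column names of a known layout. Presets ship for a
#' deCODE-like, a UKB-PPP-like and a FinnGen-like dialect; `"internal"` is
#' this package's own output layout.
#'
#' @param name one of `"internal"`, `"decode"`, `"ukb_ppp"`, `"finngen"`.
#' @return named character vector usable as `column_map` in
#'   [read_sumstats()].
#' @export
column_preset <- function(name = c("internal", "decode", "ukb_ppp", "finngen")) {
  name <- match.arg(name)
  switch(name,
    internal = c(rsid = "rsid", chrom = "chrom", pos = "pos",
                 effect_allele = "effect_allele", other_allele = "other_allele",
                 eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n",
                 n_case = "n_case", n_control = "n_control"),
    decode = c(rsid = "rsids", chrom = "Chrom", pos = "Pos",
               effect_allele = "effectAllele", other_allele = "otherAllele",
               eaf = "ImpMAF", beta = "Beta", se = "SE", pval = "Pval", n = "N"),
    ukb_ppp = c(rsid = "ID", chrom = "CHROM", pos = "GENPOS",
                effect_allele = "ALLELE1", other_allele = "ALLELE0",
                eaf = "A1FREQ", beta = "BETA", se = "SE", pval = "P", n = "N"),
    finngen = c(rsid = "rsids", chrom = "#chrom", pos = "pos",
                effect_allele = "alt", other_allele = "ref",
                eaf = "af_alt", beta = "beta", se = "sebeta", pval = "pval",
                n = "n", n_case = "n_cases", n_control = "n_controls"))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated file (gzip-transparent) with a header row, renames
#' columns according to `column_map`, validates every row, and returns a
#' [sumstat_set()]. Rows failing validation are dropped and reported via
#' [drop_report()].
#'
#' @param path file path.
#' @param column_map named character vector mapping internal field names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`, optionally `n_case`, `n_control`) to source
#'   column names, or a preset name accepted by [column_preset()].
#' @param trait_id,trait_type,platform,build trait metadata, see
#'   [sumstat_set()].
#' @param sep field separator.
#' @inheritParams sumstat_set
#' @return a `sumstat_set`.
#' @export
read_sumstats <- function(path, column_map = "internal", trait_id,
                          trait_type = c("quantitative", "binary"),
                          platform = NA_character_, build = NA_character_,
                          sep = "\t", check_zp = FALSE, zp_tol = 0.1) {
  if (is.character(column_map) && length(column_map) == 1L && is.null(names(column_map))) {
    column_map <- column_preset(column_map)
  }
  mandatory <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
  miss_map <- setdiff(mandatory, names(column_map))
  if (length(miss_map) > 0L) {
    stop("column_map lacks mapping for: ", paste(miss_map, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L && ncol(raw) == 0L) stop("empty summary-statistics file: ", path)
  present <- column_map[column_map %in% names(raw)]
  miss_src <- setdiff(column_map[mandatory], names(raw))
  if (length(miss_src) > 0L) {
    stop("file lacks mapped column(s): ", paste(miss_src, collapse = ", "))
  }
  records <- raw[, unname(present), drop = FALSE]
  names(records) <- names(present)
  sumstat_set(records, trait_id = trait_id, trait_type = trait_type,
              platform = platform, build = build,
              check_zp = check_zp, zp_tol = zp_tol)
}

#' Write a summary-statistic set to tab-separated text
#'
#' Columns are emitted in a fixed order and floating-point values with
#' enough digits (`%.17g`) that write/read round-trips are value-identical.
#' Case/control columns are emitted only when populated.
#'
#' @param set a `sumstat_set`.
#' @param path output file path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(set, path) {
  stopifnot(inherits(set, "sumstat_set"))
  rec <- set$records
  cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  if (nrow(rec) > 0L && any(!is.na(rec$n_case))) {
    cols <- c(cols, "n_case", "n_control")
  }
  out <- rec[, cols, drop = FALSE]
  for (col in intersect(c("eaf", "beta", "se", "pval"), cols)) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  for (col in intersect(c("pos", "n", "n_case", "n_control"), cols)) {
    out[[col]] <- sprintf("%.0f", out[[col]])
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations (gene, chromosome, transcription start site)
#'
#' @param path 3-column TSV with header `gene`, `chrom`, `tss`.
#' @return data.frame with columns `gene_symbol`, `chrom`, `tss`.
#' @export
read_gene_annotations <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(g)[1:3] <- c("gene_symbol", "chrom", "tss")
  g$chrom <- as.character(g$chrom)
  g$tss <- as.numeric(g$tss)
  if (any(g$tss < 1)) stop("transcription start sites must be >= 1")
  g
}
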