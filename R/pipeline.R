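#' Run the full proteome screen
#'
#' End-to-end orchestration: per-study genomic control and fixed-effect
#' meta-analysis of the two disease GWAS (when two are supplied) with
#' heterogeneity filtering; cis instrument selection for every protein on
#' both platforms; forward MR of platform A against the meta-analysis and
#' platform B against the second cohort alone (avoiding re-use of the same
#' samples on both sides); Steiger directionality with liability-scale
#' variance; reverse MR from clumped disease instruments (relaxed
#' threshold fallback); windowed colocalization for proteins meeting the
#' four screening criteria; and candidate-tier assignment.
#'
#' The pipeline draws no random numbers: rerunning on the same inputs
#' gives identical output.
#'
#' @param proteins named list; each element a list with `platform_a` and
#'   `platform_b` ([sumstat_set()]s, quantitative) and `gene` (one-row
#'   annotation with `gene_symbol`, `chrom`, `tss`). A `screen_bundle`
#'   from [simulate_screen()] can be passed via [pipeline_config()].
#' @param disease_sets list of one or two binary [sumstat_set()]s; with
#'   two, they are meta-analysed for the platform-A outcome and the second
#'   serves as the platform-B outcome.
#' @param prevalences numeric vector of population prevalences, one per
#'   disease set.
#' @param prevalence_weights weights for [weighted_prevalence()]; defaults
#'   to the disease sets' sample sizes.
#' @param ld_list optional named list of [ld_matrix()] objects keyed by
#'   protein ID (cis regions) used for region merging and proxy lookup.
#' @param selection_cfg,harmonize_cfg,coloc_cfg stage configurations.
#' @param het_threshold heterogeneity-filter bound (inclusive; default
#'   0.05).
#' @param h4_threshold colocalization evidence bound.
#' @param out_dir optional directory; when given, per-stage TSVs, a
#'   markdown summary and a JSON of candidate records are written.
#' @return list of class `screen_report`: `candidates` (list of
#'   `candidate_record`s), `forward` / `reverse` / `steiger_tab` result
#'   tables, `coloc` (per-protein window tables), `meta` (pooled disease
#'   set and per-study lambdas), `disease_instruments`, and `summary`
#'   (named counts).
#' @export
run_pipeline <- function(proteins, disease_sets, prevalences,
                         prevalence_weights = NULL, ld_list = NULL,
                         selection_cfg = selection_config(),
                         harmonize_cfg = harmonize_config(),
                         coloc_cfg = coloc_config(),
                         het_threshold = 0.05, h4_threshold = 0.8,
                         out_dir = NULL) {
  stopifnot(length(disease_sets) >= 1L,
            length(prevalences) == length(disease_sets))
  n_eff <- vapply(disease_sets, function(s) {
    r <- s$records
    if (nrow(r) > 0L && any(!is.na(r$n_case))) {
      stats::median(4 / (1 / r$n_case + 1 / r$n_control), na.rm = TRUE)
    } else stats::median(r$n)
  }, numeric(1))
  if (is.null(prevalence_weights)) prevalence_weights <- n_eff

  # Disease outcome(s)
  lambdas <- NA_real_
  if (length(disease_sets) >= 2L) {
    met <- meta_analyse(disease_sets[[1L]], disease_sets[[2L]],
                        apply_gc = TRUE, cfg = harmonize_cfg)
    lambdas <- met$lambda
    filt <- filter_heterogeneity(met$set, threshold = het_threshold)
    outcome_a <- filt$set
    outcome_b <- disease_sets[[2L]]
    k_a <- weighted_prevalence(prevalences, prevalence_weights)
    k_b <- prevalences[[2L]]
    n_het_removed <- filt$n_removed
  } else {
    outcome_a <- outcome_b <- disease_sets[[1L]]
    k_a <- k_b <- prevalences[[1L]]
    n_het_removed <- 0L
  }
  case_frac <- function(set) {
    r <- set$records
    if (nrow(r) == 0L || all(is.na(r$n_case))) return(0.5)
    stats::median(r$n_case / r$n, na.rm = TRUE)
  }
  lp_a <- liability_params(k_a, case_frac(outcome_a))
  lp_b <- liability_params(k_b, case_frac(outcome_b))

  # Reverse-MR instruments from the pooled (or single) disease GWAS
  rev_relaxed <- FALSE
  rev_instruments <- clump(outcome_a, ld = NULL, cfg = selection_cfg,
                           p_threshold = selection_cfg$pthreshold_outcome)
  if (nrow(rev_instruments) == 0L &&
      !is.null(selection_cfg$pthreshold_outcome_relaxed)) {
    rev_instruments <- clump(outcome_a, ld = NULL, cfg = selection_cfg,
                             p_threshold = selection_cfg$pthreshold_outcome_relaxed)
    rev_relaxed <- nrow(rev_instruments) > 0L
  }

  candidates <- vector("list", length(proteins))
  names(candidates) <- names(proteins)
  forward_tab <- list()
  steiger_tab <- list()
  reverse_tab <- list()
  coloc_list <- list()

  for (pid in names(proteins)) {
    pr <- proteins[[pid]]
    ld <- if (!is.null(ld_list)) ld_list[[pid]] else NULL
    inst_a <- select_cis_instrument(pr$platform_a, pr$gene, ld, selection_cfg)
    inst_b <- select_cis_instrument(pr$platform_b, pr$gene, ld, selection_cfg)

    fwd <- function(inst, protein_set, outcome, lp) {
      if (is.null(inst)) return(NULL)
      rows <- harmonize_set(inst$snps, outcome, ld = ld, cfg = harmonize_cfg)
      rows <- rows[rows$action != "dropped", , drop = FALSE]
      if (nrow(rows) == 0L) return(NULL)
      res <- wald_ratio(rows, exposure_id = pid,
                        outcome_id = outcome$trait_id, binary_outcome = TRUE)
      st <- steiger(rows, outcome_binary = TRUE, lp = lp)
      res$f_stat <- inst$f_stat
      list(mr = res, steiger = st, rows = rows)
    }
    fa <- fwd(inst_a, pr$platform_a, outcome_a, lp_a)
    fb <- fwd(inst_b, pr$platform_b, outcome_b, lp_b)

    # A disease instrument inside this protein's cis region would test the
    # protein against its own pQTL; reverse MR asks whether disease
    # liability moves the protein through *other* loci, so such
    # instruments are excluded per protein.
    rev_inst_p <- rev_instruments[
      !(rev_instruments$chrom == pr$gene$chrom &
          abs(rev_instruments$pos - pr$gene$tss) <= selection_cfg$cis_window_bp),
      , drop = FALSE]
    rev_a <- reverse_mr(rev_inst_p, pr$platform_a, cfg = harmonize_cfg,
                        ld = ld, relaxed_threshold = rev_relaxed)
    rev_b <- reverse_mr(rev_inst_p, pr$platform_b, cfg = harmonize_cfg,
                        ld = ld, relaxed_threshold = rev_relaxed)
    rev_list <- Filter(Negate(is.null), list(rev_a, rev_b))

    cand <- evaluate_candidate(pid,
                               forward_a = if (is.null(fa)) NULL else fa$mr,
                               forward_b = if (is.null(fb)) NULL else fb$mr,
                               reverse = rev_list,
                               steiger_a = if (is.null(fa)) NULL else fa$steiger,
                               steiger_b = if (is.null(fb)) NULL else fb$steiger,
                               h4_threshold = h4_threshold)
    # Colocalization only for proteins passing the four criteria
    if (identical(cand$tier, "consistent_candidate") && !is.null(inst_a)) {
      cl <- windowed_coloc(pr$platform_a, outcome_a,
                           cis_snp = inst_a$snps$rsid[1L], cfg = coloc_cfg)
      coloc_list[[pid]] <- cl
      cand <- evaluate_candidate(pid, fa$mr, fb$mr, rev_list,
                                 fa$steiger, fb$steiger, coloc = cl,
                                 h4_threshold = h4_threshold)
    }
    candidates[[pid]] <- cand

    for (side in c("a", "b")) {
      f <- if (side == "a") fa else fb
      if (!is.null(f)) {
        forward_tab[[paste(pid, side)]] <- cbind(platform = side, f$mr)
        steiger_tab[[paste(pid, side)]] <- cbind(protein_id = pid,
                                                 platform = side, f$steiger)
      }
    }
    for (i in seq_along(rev_list)) {
      reverse_tab[[paste(pid, i)]] <- cbind(platform = c("a", "b")[i],
                                            rev_list[[i]])
    }
  }

  bind <- function(lst) if (length(lst) == 0L) NULL else {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  tiers <- vapply(candidates, `[[`, character(1), "tier")
  crit <- lapply(candidates, `[[`, "criteria")
  summary <- list(
    n_proteins = length(proteins),
    n_instrumented_both = sum(tiers != "not_shared"),
    n_consistent_direction = sum(vapply(crit, function(cr)
      isTRUE(cr[["consistent_direction"]]), logical(1))),
    n_candidates = sum(tiers %in% c("consistent_candidate",
                                    "colocalized_candidate")),
    n_colocalized = sum(tiers == "colocalized_candidate"),
    n_het_removed = n_het_removed,
    lambda = lambdas,
    reverse_relaxed_threshold = rev_relaxed,
    n_reverse_instruments = nrow(rev_instruments))

  report <- list(candidates = candidates, forward = bind(forward_tab),
                 reverse = bind(reverse_tab), steiger_tab = bind(steiger_tab),
                 coloc = coloc_list,
                 meta = list(set = outcome_a, lambda = lambdas),
                 disease_instruments = rev_instruments,
                 summary = summary)
  class(report) <- "screen_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Assemble `run_pipeline()` arguments from a simulated screen bundle
#'
#' @param bundle a `screen_bundle` from [simulate_screen()] or a single
#'   `scenario_bundle` from [simulate_scenario()].
#' @param prevalences per-cohort prevalences; defaults to the bundle's
#'   generating prevalence for both cohorts.
#' @return named list of arguments for [run_pipeline()].
#' @export
pipeline_config <- function(bundle, prevalences = NULL) {
  if (inherits(bundle, "scenario_bundle")) {
    k <- bundle$truth$prevalence_k
    proteins <- list(GENE1 = list(platform_a = bundle$protein_sets$platform_a,
                                  platform_b = bundle$protein_sets$platform_b,
                                  gene = bundle$genes[1L, , drop = FALSE]))
    ld_list <- list(GENE1 = bundle$ld)
    disease_sets <- bundle$disease_sets
  } else if (inherits(bundle, "screen_bundle")) {
    k <- bundle$truth$prevalence_k
    proteins <- bundle$proteins
    ld_list <- bundle$ld_list
    disease_sets <- bundle$disease_sets
  } else stop("unsupported bundle class")
  if (is.null(prevalences)) k <- rep(k, length(disease_sets)) else k <- prevalences
  list(proteins = proteins, disease_sets = disease_sets, prevalences = k,
       ld_list = ld_list)
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<screen_report> %d proteins; %d instrumented on both ",
                     "platforms; %d consistent direction; %d candidates ",
                     "(%d colocalized)\n"),
              s$n_proteins, s$n_instrumented_both, s$n_consistent_direction,
              s$n_candidates, s$n_colocalized))
  invisible(x)
}

# Write per-stage TSVs, a markdown summary and a machine-readable JSON of
# candidate records.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wtsv(report$forward, "forward_mr.tsv")
  wtsv(report$reverse, "reverse_mr.tsv")
  wtsv(report$steiger_tab, "steiger.tsv")
  wtsv(report$disease_instruments, "disease_instruments.tsv")
  if (length(report$coloc) > 0L) {
    cl <- do.call(rbind, lapply(names(report$coloc), function(p)
      cbind(protein_id = p, report$coloc[[p]])))
    wtsv(cl, "coloc.tsv")
  }
  cand_json <- lapply(report$candidates, function(cr) {
    list(protein_id = cr$protein_id, tier = cr$tier,
         criteria = as.list(cr$criteria), h4_max = cr$h4_max)
  })
  jsonlite::write_json(cand_json, file.path(out_dir, "candidates.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  s <- report$summary
  md <- c("# Proteome screen summary", "",
          sprintf("- proteins screened: %d", s$n_proteins),
          sprintf("- instrumented on both platforms: %d", s$n_instrumented_both),
          sprintf("- consistent forward direction: %d", s$n_consistent_direction),
          sprintf("- candidates (all four criteria): %d", s$n_candidates),
          sprintf("- with colocalization support (h4): %d", s$n_colocalized),
          sprintf("- variants removed by heterogeneity filter: %d", s$n_het_removed),
          sprintf("- reverse-MR instruments: %d%s", s$n_reverse_instruments,
                  if (isTRUE(s$reverse_relaxed_threshold)) " (relaxed threshold)" else ""))
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
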