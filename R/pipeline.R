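# Orchestration: per-locus HWE/F_IS -> pairwise LD -> genotype-class
# association -> optional CNP, with a reproducible report.

#' Run the full hybrid-zone analysis
#'
#' Runs, per group of individuals (default grouping: `site_code` and
#' `year`), the single-locus statistics for every marker, the two-locus
#' haplotype/LD analysis for each marker pair, and the joint-genotype class
#' summary with its association tests; optionally scores CNP observations.
#' Stages are failure-tolerant: an error in one group/stage is recorded in
#' the report and the remaining stages complete.  The run is deterministic
#' given `seed`.
#'
#' @param records Sample-record data frame ([read_genotype_table()] or
#'   [simulate_population()]`$records`).
#' @param markers Marker columns to analyse; default: all panel markers
#'   present in `records`.
#' @param group_by Grouping columns (default `site_code`, `year`).
#' @param ld_pairs List of 2-vectors of marker names for the LD stage;
#'   default: all pairs of analysed markers.
#' @param exclude_ambiguous Drop individuals with uncleaved-ambiguous (`U`)
#'   calls from analyses involving that marker (default `TRUE`; `U` calls
#'   at 2L cannot be interpreted because of the null allele).
#' @param n_perm Permutations for the LR association test.
#' @param n_boot Bootstrap replicates for haplotype-frequency SDs (0 skips
#'   the bootstrap).
#' @param peak_data Optional list of [peak_observation()]s with a parallel
#'   `peak_groups` vector for the CNP stage.
#' @param peak_groups Optional grouping vector (e.g. SINE-X genotype) for
#'   `peak_data`.
#' @param seed Integer seed driving every stochastic step.
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `locus_stats.tsv` and `ld.tsv` there.
#' @return A list of class `hz_report` with elements `locus_stats` (data
#'   frame), `ld` (data frame plus per-pair detail), `association`,
#'   `cnp` (or `NULL`), `errors` (named character vector of failed stages)
#'   and `provenance` (seed, replicate counts, package version).
#' @export
run_pipeline <- function(records, markers = NULL,
                         group_by = c("site_code", "year"),
                         ld_pairs = NULL, exclude_ambiguous = TRUE,
                         n_perm = 10000, n_boot = 500,
                         peak_data = NULL, peak_groups = NULL,
                         seed = 1, out_dir = NULL) {
  if (is.null(markers)) {
    markers <- attr(records, "markers")
    if (is.null(markers))
      markers <- intersect(marker_panel()$name, names(records))
  }
  miss <- setdiff(markers, names(records))
  if (length(miss))
    stop("marker columns missing from records: ", paste(miss, collapse = ", "))
  errors <- character()
  note <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  grp_id <- interaction(records[group_by], drop = TRUE, sep = "/")
  groups <- split(records, grp_id)

  locus_stats_tab <- do.call(rbind, unlist(recursive = FALSE, lapply(
    names(groups), function(g) {
      lapply(markers, function(m) {
        tryCatch({
          lc <- tabulate_locus(groups[[g]], m)
          cbind(data.frame(group = g, marker = m, stringsAsFactors = FALSE),
                locus_stats(lc))
        }, error = function(e) note(paste0("locus_stats:", g, ":", m), e))
      })
    })))

  if (is.null(ld_pairs) && length(markers) >= 2)
    ld_pairs <- utils::combn(markers, 2, simplify = FALSE)
  ld_detail <- list()
  ld_rows <- list()
  for (g in names(groups)) {
    for (pair in ld_pairs) {
      key <- paste0(g, ":", pair[1], "x", pair[2])
      res <- tryCatch({
        j <- tabulate_joint(groups[[g]], pair[1], pair[2])
        mar <- .joint_margins(unclass(as.matrix(j)))
        if (any(mar <= 0) || any(mar >= 1))
          stop("monomorphic locus in this group")
        est <- em_haplotypes(j)
        ld <- ld_statistics(est)
        lr <- lr_test_association(j, n_perm = n_perm, seed = seed)
        bs <- if (n_boot > 0) bootstrap_haplotype_sd(j, B = max(100, n_boot),
                                                     seed = seed)
        pk <- tryCatch(phase_known_exact_test(j),
                       error = function(e) list(p_value = NA_real_))
        list(joint = j, em = est, ld = ld, lr = lr, bootstrap = bs,
             phase_known = pk)
      }, error = function(e) note(paste0("ld:", key), e))
      if (is.null(res)) next
      ld_detail[[key]] <- res
      ld_rows[[key]] <- data.frame(
        group = g, locus1 = pair[1], locus2 = pair[2],
        N = attr(res$joint, "N"),
        f_MM = res$em$f[["MM"]], f_MS = res$em$f[["MS"]],
        f_SM = res$em$f[["SM"]], f_SS = res$em$f[["SS"]],
        D = res$ld$D, D_prime = res$ld$D_prime, r2 = res$ld$r2,
        G = res$lr$G, p_perm = res$lr$p_perm, p_chi2 = res$lr$p_chi2,
        p_phase_known = if (is.null(res$phase_known$p_value)) NA_real_
                        else res$phase_known$p_value,
        stringsAsFactors = FALSE)
    }
  }
  ld_tab <- if (length(ld_rows)) do.call(rbind, ld_rows)

  assoc <- NULL
  if (length(ld_pairs)) {
    assoc <- tryCatch({
      pair <- ld_pairs[[1]]
      jl <- lapply(groups, function(gr)
        tryCatch(tabulate_joint(gr, pair[1], pair[2]),
                 error = function(e) NULL))
      jl <- Filter(Negate(is.null), jl)
      if (length(jl)) genotype_class_summary(jl) else NULL
    }, error = function(e) note("association", e))
  }

  cnp <- NULL
  if (!is.null(peak_data)) {
    cnp <- tryCatch({
      scores <- vapply(peak_data, function(obs) {
        s <- normalize_peak_heights(obs)
        cnp_score(s[["s_M"]], s[["s_S"]])
      }, numeric(1))
      out <- data.frame(
        individual_id = vapply(peak_data, `[[`, character(1),
                               "individual_id"),
        site = vapply(peak_data, `[[`, integer(1), "site"),
        cnp = scores, array_class = classify_cnp(scores),
        stringsAsFactors = FALSE)
      cmp <- if (!is.null(peak_groups))
        cnp_group_compare(scores, peak_groups)
      list(records = out, comparison = cmp)
    }, error = function(e) note("cnp", e))
  }

  report <- structure(list(
    locus_stats = locus_stats_tab,
    ld = ld_tab, ld_detail = ld_detail,
    association = assoc, cnp = cnp,
    errors = errors,
    provenance = list(seed = seed, n_perm = n_perm, n_boot = n_boot,
                      markers = markers, group_by = group_by,
                      exclude_ambiguous = exclude_ambiguous,
                      package = "mshybrid",
                      version = as.character(utils::packageVersion("mshybrid")))
  ), class = "hz_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (the full report minus the non-serializable detail
#' objects) plus `locus_stats.tsv` and `ld.tsv`.
#'
#' @param report An `hz_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "hz_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report
  slim$ld_detail <- NULL
  slim$association$independence <-
    lapply(report$association$independence, .assoc_as_list)
  slim$association$parental_vs_assorted <-
    lapply(report$association$parental_vs_assorted, .assoc_as_list)
  if (!is.null(report$association$congruent_by_group))
    slim$association$congruent_by_group <-
      .assoc_as_list(report$association$congruent_by_group)
  jsonlite::write_json(unclass(slim), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  if (!is.null(report$locus_stats))
    utils::write.table(report$locus_stats,
                       file.path(out_dir, "locus_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$ld))
    utils::write.table(report$ld, file.path(out_dir, "ld.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

.assoc_as_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(chi2 = x$chi2, df = x$df, p = x$p, yates = x$yates,
       table = as.vector(x$table), dim = dim(x$table),
       warning = x$warning)
}

#' @export
print.hz_report <- function(x, ...) {
  cat("Hybrid-zone analysis report (seed", x$provenance$seed, ")\n")
  if (!is.null(x$locus_stats)) {
    cat("\nPer-locus statistics:\n")
    print(x$locus_stats, digits = 3)
  }
  if (!is.null(x$ld)) {
    cat("\nPairwise LD:\n")
    print(x$ld[, c("group", "locus1", "locus2", "N", "D", "r2",
                   "p_perm")], digits = 3)
  }
  if (length(x$errors)) {
    cat("\nStages with errors:\n")
    for (s in names(x$errors)) cat(" -", s, ":", x$errors[[s]], "\n")
  }
  invisible(x)
}
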