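# Genotype table I/O and reconstruction of integer counts from published
# frequency tables.

# Column order of published joint-genotype tables (X-genotype / 3L-genotype).
.joint_order <- c("MM/MM", "SS/SS", "MS/MS", "MM/MS", "MM/SS",
                  "MS/MM", "MS/SS", "SS/MS", "SS/MM")
.geno_levels <- c("MM", "MS", "SS")

#' Single-locus genotype counts
#'
#' Container for diploid genotype counts at one biallelic diagnostic locus in
#' one population sample.
#'
#' @param n_MM,n_MS,n_SS Non-negative integer counts of the three diploid
#'   genotype classes (M homozygote, M/S heterozygote, S homozygote).
#' @return An object of class `locus_counts`: a named integer vector with an
#'   `N` attribute (total sample size).
#' @examples
#' locus_counts(58, 3, 40)
#' @export
locus_counts <- function(n_MM, n_MS, n_SS) {
  x <- c(MM = n_MM, MS = n_MS, SS = n_SS)
  if (any(is.na(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8))
    stop("genotype counts must be non-negative integers")
  x <- as.integer(round(x))
  names(x) <- .geno_levels
  if (sum(x) == 0L) stop("total sample size N must be positive")
  structure(x, N = sum(x), class = "locus_counts")
}

#' @export
print.locus_counts <- function(x, ...) {
  cat("Single-locus genotype counts (N =", attr(x, "N"), ")\n")
  print(unclass(x)[1:3])
  invisible(x)
}

#' Two-locus joint genotype counts
#'
#' @param counts A 3x3 non-negative integer matrix of joint diploid genotype
#'   counts, rows indexed by the X-locus genotype (MM, MS, SS) and columns by
#'   the 3L-locus genotype (same order).
#' @return An object of class `joint_counts`.
#' @examples
#' joint_counts(matrix(c(50, 5, 0, 1, 1, 0, 1, 9, 30), 3, byrow = TRUE))
#' @export
joint_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)))
    stop("joint counts must form a 3x3 table")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("joint genotype counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(X = .geno_levels, L3 = .geno_levels)
  if (sum(counts) == 0L) stop("total sample size N must be positive")
  structure(counts, N = sum(counts), class = c("joint_counts", "matrix"))
}

#' @export
print.joint_counts <- function(x, ...) {
  cat("Two-locus joint genotype counts (N =", attr(x, "N"), ")\n")
  print(matrix(as.integer(x), 3, 3, dimnames = dimnames(x)))
  invisible(x)
}

#' Reconstruct integer counts from published frequencies
#'
#' Published genotype tables print relative frequencies and the sample size N
#' but not the underlying integer counts.  This reverses the rounding by
#' largest-remainder apportionment: each cell receives `floor(freq * N)`
#' individuals, and the residual units are assigned to cells in decreasing
#' order of fractional remainder, ties broken by the listed cell order.  The
#' result always sums exactly to `N`.
#'
#' @param freqs Numeric vector of non-negative cell frequencies summing to 1
#'   within 0.02 (printed tables are rounded to 2-3 decimals).
#' @param N Integer sample size.
#' @return Integer vector of counts, same length and names as `freqs`.
#' @examples
#' counts_from_frequencies(c(0.57, 0.03, 0.40), 101)  # 58 3 40
#' @export
counts_from_frequencies <- function(freqs, N) {
  if (any(is.na(freqs)) || any(freqs < 0))
    stop("frequencies must be non-negative")
  if (length(N) != 1L || is.na(N) || N <= 0)
    stop("N must be a positive integer")
  if (abs(sum(freqs) - 1) > 0.02)
    stop(sprintf(
      "frequencies sum to %.3f; deviation from 1 exceeds 0.02 (table mis-transcription?)",
      sum(freqs)))
  x <- freqs * N
  base <- floor(x + 1e-9)
  rem <- round(x - base, 9)
  resid <- as.integer(round(N - sum(base)))
  counts <- as.integer(base)
  if (resid > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(resid)]
    counts[take] <- counts[take] + 1L
  } else if (resid < 0) {
    # over-allocation can only arise from upward-rounded printed frequencies;
    # remove units from the cells rounded up the most (smallest remainder)
    give <- order(rem, seq_along(rem))[seq_len(-resid)]
    counts[give] <- counts[give] - 1L
  }
  names(counts) <- names(freqs)
  counts
}

#' Reconstruct a 3x3 joint genotype table from a published frequency row
#'
#' Applies [counts_from_frequencies()] to a 9-cell frequency vector given in
#' the published column order (MM/MM, SS/SS, MS/MS, MM/MS, MM/SS, MS/MM,
#' MS/SS, SS/MS, SS/MM; first index = X-locus genotype, second = 3L genotype)
#' and rearranges the counts into a 3x3 [joint_counts()] table.
#'
#' @param freq9 Numeric 9-vector of joint genotype frequencies in the
#'   published column order.
#' @param N Integer sample size.
#' @return A `joint_counts` object.
#' @examples
#' joint_counts_from_frequencies(
#'   c(0.515, 0.309, 0.010, 0.052, 0, 0.010, 0.000, 0.093, 0.010), 97)
#' @export
joint_counts_from_frequencies <- function(freq9, N) {
  if (length(freq9) != 9L)
    stop("freq9 must have 9 cells in the published column order")
  cnt <- counts_from_frequencies(freq9, N)
  names(cnt) <- .joint_order
  m <- matrix(0L, 3, 3, dimnames = list(X = .geno_levels, L3 = .geno_levels))
  for (k in seq_along(.joint_order)) {
    g <- strsplit(.joint_order[k], "/", fixed = TRUE)[[1]]
    m[g[1], g[2]] <- cnt[k]
  }
  joint_counts(m)
}

#' Read a genotype matrix from a headered TSV file
#'
#' The native format is a tab-separated table with columns `individual_id`,
#' `site_code`, `year`, then one column per marker holding one of the tokens
#' `MM`, `MS`, `SS`, `NA` (missing) or `U` (uncleaved-ambiguous RFLP pattern;
#' see [apply_null_allele()]).
#'
#' @param path Path to the TSV file.
#' @param panel Marker panel data frame; marker columns are those whose names
#'   appear in `panel$name`.  Defaults to [marker_panel()].
#' @param strict If `TRUE` (default) a genotype token outside the vocabulary
#'   is a hard error naming the offending row and column; if `FALSE` unknown
#'   tokens are mapped to missing with a warning.
#' @return A data frame of sample records, one row per individual, genotype
#'   columns as character vectors with `NA` for missing calls.
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, panel = marker_panel(), strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_panel(panel)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  need <- c("individual_id", "site_code", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  markers <- intersect(panel$name, names(df))
  if (!length(markers))
    stop("no marker columns found; expected some of: ",
         paste(panel$name, collapse = ", "))
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup))
    stop("duplicated individual_id: ", paste(unique(dup), collapse = ", "))
  df$year <- as.integer(df$year)
  for (m in markers) {
    tok <- df[[m]]
    bad <- !(tok %in% .genotype_tokens) & !is.na(tok) & tok != ""
    if (any(bad)) {
      where <- which(bad)[1]
      msg <- sprintf(
        "invalid genotype token '%s' at row %d (individual %s), column %s",
        tok[where], where, df$individual_id[where], m)
      if (strict) stop(msg)
      warning(msg, "; mapping unknown tokens to missing")
      tok[bad] <- NA_character_
    }
    tok[tok %in% c("NA", "")] <- NA_character_
    df[[m]] <- tok
  }
  attr(df, "markers") <- markers
  df
}

#' Write a genotype matrix to TSV or Genepop format
#'
#' @param records Data frame of sample records as returned by
#'   [read_genotype_table()] or [simulate_population()].
#' @param path Output file path.
#' @param format `"tsv"` round-trips the native format; `"genepop"` writes a
#'   Genepop 4-digit export (M allele = 01, S allele = 02, missing = 0000,
#'   uncleaved-ambiguous exported as missing) with one population per
#'   `site_code`.
#' @param title Header line for Genepop output.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(records, path, format = c("tsv", "genepop"),
                                 title = "mshybrid genotype export") {
  format <- match.arg(format)
  markers <- attr(records, "markers")
  if (is.null(markers))
    markers <- intersect(marker_panel()$name, names(records))
  if (format == "tsv") {
    out <- records[, c("individual_id", "site_code", "year", markers)]
    for (m in markers) out[[m]][is.na(out[[m]])] <- "NA"
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  code <- function(g) {
    vapply(g, function(x) {
      switch(ifelse(is.na(x), "NA", x),
             MM = "0101", MS = "0102", SS = "0202",
             "0000")
    }, character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, markers), con)
  for (site in unique(records$site_code)) {
    writeLines("POP", con)
    sub <- records[records$site_code == site, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      writeLines(paste0(sub$individual_id[i], " ,  ",
                        paste(code(unlist(sub[i, markers])), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Tabulate single-locus genotype counts from sample records
#'
#' @param records Data frame of sample records.
#' @param marker Marker column name.
#' @return A [locus_counts()] object.  Missing and uncleaved-ambiguous calls
#'   are excluded.
#' @export
tabulate_locus <- function(records, marker) {
  g <- records[[marker]]
  if (is.null(g)) stop("no column '", marker, "' in records")
  g <- g[g %in% .geno_levels]
  if (!length(g)) stop("no scorable genotypes at ", marker)
  tab <- table(factor(g, levels = .geno_levels))
  locus_counts(tab[["MM"]], tab[["MS"]], tab[["SS"]])
}

#' Tabulate two-locus joint genotype counts from sample records
#'
#' @param records Data frame of sample records.
#' @param marker_x,marker_y Marker column names (conventionally the X-linked
#'   and 3L markers).  Individuals missing or ambiguous at either locus are
#'   excluded (pairwise-complete).
#' @return A [joint_counts()] object.
#' @export
tabulate_joint <- function(records, marker_x, marker_y) {
  gx <- records[[marker_x]]
  gy <- records[[marker_y]]
  if (is.null(gx) || is.null(gy))
    stop("marker columns not found in records")
  keep <- gx %in% .geno_levels & gy %in% .geno_levels
  if (!any(keep)) stop("no individuals scorable at both loci")
  joint_counts(table(factor(gx[keep], .geno_levels),
                     factor(gy[keep], .geno_levels)))
}

#' Load the packaged far-west survey frequency tables
#'
#' Returns the published genotype-frequency tables (SINE-X and 3L single-locus
#' tables plus the joint SINE-X/3L table) for the Gambian and Guinean samples,
#' shipped with the package as YAML.  Counts are not part of the publication;
#' reconstruct them with [counts_from_frequencies()] /
#' [joint_counts_from_frequencies()].
#'
#' @return A list with elements `sine_x`, `locus_3l`, `joint_x_3l` (data
#'   frames with columns `sample`, `country`, `year`, `N` and a list-column
#'   `freq`), plus `genotype_order` and `joint_order` character vectors.
#' @export
load_survey_tables <- function() {
  path <- system.file("extdata", "farwest_survey.yaml", package = "mshybrid")
  if (path == "") stop("packaged survey tables not found")
  raw <- yaml::read_yaml(path)
  as_df <- function(rows) {
    df <- data.frame(
      sample  = vapply(rows, `[[`, character(1), "sample"),
      country = vapply(rows, `[[`, character(1), "country"),
      year    = vapply(rows, function(r) as.integer(r$year), integer(1)),
      N       = vapply(rows, function(r) as.integer(r$N), integer(1)),
      flag    = vapply(rows, function(r)
        if (is.null(r$flag)) NA_character_ else r$flag, character(1)),
      stringsAsFactors = FALSE
    )
    df$freq <- lapply(rows, function(r) as.numeric(r$freq))
    df
  }
  list(sine_x = as_df(raw$sine_x),
       locus_3l = as_df(raw$locus_3l),
       joint_x_3l = as_df(raw$joint_x_3l),
       genotype_order = unlist(raw$genotype_order),
       joint_order = unlist(raw$joint_order))
}
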