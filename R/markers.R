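# Diagnostic marker panel and genotype-call vocabulary shared by all modules.

#' Default diagnostic marker panel
#'
#' The five assays routinely used to discriminate the M and S molecular forms
#' of *Anopheles gambiae* s.s.: the M-form specific SINE insertion in division
#' 6 of the X chromosome (`SINE-X`), the two form-diagnostic SNPs in the rDNA
#' intergenic spacer (`IGS-581`: M = T, S = C; `IGS-690`: M = A, S = T), and
#' the pericentromeric SNP-RFLP markers on chromosome arms 2L (position
#' 209,536, AgamP3) and 3L (position 296,923, AgamP3).
#'
#' @return A data frame with one row per marker and columns `name`,
#'   `chromosome_arm`, `assembly_position` (1-based, `NA` where the assay is
#'   not tied to a single assembly coordinate), `m_allele_label`,
#'   `s_allele_label` and `assay_kind` (one of `"insertion-PCR"`,
#'   `"IGS-RFLP"`, `"SNP-RFLP"`).
#' @examples
#' marker_panel()
#' @export
marker_panel <- function() {
  data.frame(
    name              = c("SINE-X", "IGS-581", "IGS-690", "2L", "3L"),
    chromosome_arm    = c("X", "X", "X", "2L", "3L"),
    assembly_position = c(NA, NA, NA, 209536L, 296923L),
    m_allele_label    = c("insertion", "T", "A", "M", "M"),
    s_allele_label    = c("absence", "C", "T", "S", "S"),
    assay_kind        = c("insertion-PCR", "IGS-RFLP", "IGS-RFLP",
                          "SNP-RFLP", "SNP-RFLP"),
    stringsAsFactors  = FALSE
  )
}

# Genotype tokens used in the native TSV format.  "U" marks an RFLP pattern
# that cannot be interpreted because of the second-site null allele (all
# amplicon copies uncleaved); it is only meaningful for SNP-RFLP assays.
.genotype_tokens <- c("MM", "MS", "SS", "NA", "U")

.validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel), "name" %in% names(panel))
  if (anyDuplicated(panel$name))
    stop("marker names must be unique within a panel")
  pos <- panel$assembly_position
  if (any(!is.na(pos) & pos <= 0))
    stop("assembly_position must be positive when present")
  invisible(panel)
}
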