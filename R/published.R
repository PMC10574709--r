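#' Published discriminant functions for the honeysuckle authentication study
#'
#' The three-class stepwise LDA reported for the 100-batch Lonicera cohort
#' reduces to seven TMS-normalized bucket variables (V17, V31, V66, V145,
#' V147, V184, V186; V184/V186 sit in the saponin methyl region
#' 0.65--1.80 ppm, V145/V147 in the secoiridoid region 2.65--2.95 ppm) and
#' one Fisher classification function per class:
#' cultivated Lonicerae japonicae flos (cLJF), Lonicerae flos (LF) and wild
#' LJF (wLJF).  This constructor returns those functions as an `lda_model`
#' ready for [classify()], e.g. to score new normalized bucket rows.
#'
#' @return an `lda_model` over variables V17, V31, V66, V145, V147, V184,
#'   V186 with classes cLJF, LF, wLJF.
#' @export
published_lonicera_functions <- function() {
  vars <- c("V17", "V31", "V66", "V145", "V147", "V184", "V186")
  coef <- rbind(
    cLJF = c(245.678, -321.509, 71.423, 19.730, 176.163, 471.194, -954.988),
    LF   = c(311.308, 1139.664, 472.028, -350.766, -1371.149, 8174.827, -6550.292),
    wLJF = c(-4229.002, 1114.710, 35.912, 434.342, -452.648, 1229.008, -953.914)
  )
  colnames(coef) <- vars
  intercepts <- c(cLJF = -10.103, LF = -92.660, wLJF = -29.427)
  lda_from_functions(coef, intercepts, classes = rownames(coef),
                     variable_names = vars)
}
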