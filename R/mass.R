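#' Signed parts-per-million mass error
#'
#' `ppm_error()` returns the signed relative deviation
#' `1e6 * (mz_measured - mz_theoretical) / mz_theoretical`;
#' `ppm_error_mag()` its magnitude rounded to one decimal, the form mass
#' accuracies are usually reported in.
#'
#' @param mz_measured Measured m/z (Da). Vectorized.
#' @param mz_theoretical Theoretical m/z (Da), must be positive.
#' @return Signed ppm error (or its rounded magnitude).
#' @examples
#' ppm_error_mag(279.234, 279.2329)  # 3.9 ppm for deprotonated FA(18:2)
#' @export
ppm_error <- function(mz_measured, mz_theoretical) {
  if (any(mz_theoretical <= 0)) {
    stop("mz_theoretical must be positive")
  }
  1e6 * (mz_measured - mz_theoretical) / mz_theoretical
}

#' @rdname ppm_error
#' @export
ppm_error_mag <- function(mz_measured, mz_theoretical) {
  round(abs(ppm_error(mz_measured, mz_theoretical)), 1)
}

#' Reference list of breast-tissue marker lipid ions
#'
#' The nine lipid ions differentially abundant between invasive breast
#' cancer and normal breast adipose in negative-mode REIMS spectra:
#' fatty acids and glycerophospholipids enriched in cancer, diglyceride
#' and triglyceride (chloride-adduct) species enriched in normal adipose.
#' For each ion the table carries the 0.1 Da bin it falls in, the measured
#' and theoretical m/z, and the reported mass error in ppm.
#'
#' Three triglyceride rows carry a reported ppm value that is not
#' arithmetically consistent with their own measured/theoretical m/z pair;
#' these are kept verbatim and exposed through `ppm_consistent = FALSE`
#' together with the recomputed value, rather than silently corrected.
#'
#' @return A data.frame with columns `putative_id`, `ion`, `class_enriched`
#'   (`"cancer"` or `"normal"`), `mz_bin`, `mz_measured`, `mz_theoretical`,
#'   `ppm_reported`, `ppm_recomputed`, `ppm_consistent`.
#' @export
lipid_reference <- function() {
  ref <- data.frame(
    putative_id = c("FA(18:2)", "FA(18:1)", "FA(20:4)", "DG(18:1/16:0)",
                    "PE(18:1/18:0)", "TG(50:2)", "TG(52:2)", "TG(54:3)",
                    "TG(58:10)"),
    ion = c("[M-H]-", "[M-H]-", "[M-H]-", "[M+Cl]-", "[M-H]-", "[M+Cl]-",
            "[M+Cl]-", "[M+Cl]-", "[M-H]-"),
    class_enriched = c("cancer", "normal", "cancer", "normal", "cancer",
                       "normal", "normal", "normal", "normal"),
    mz_bin = c(279.25, 281.25, 303.25, 629.45, 744.55, 865.75, 893.75,
               919.75, 925.75),
    mz_measured = c(279.234, 281.248, 303.233, 629.488, 744.555, 865.710,
                    893.733, 919.748, 925.725),
    mz_theoretical = c(279.2329, 281.2486, 303.2329, 629.4917, 744.5549,
                       865.7057, 893.7370, 919.7527, 925.7291),
    ppm_reported = c(3.9, 2.1, 0.3, 5.9, 0.1, 4.9, 4.4, 5.5, 4.4),
    stringsAsFactors = FALSE
  )
  ref$ppm_recomputed <- ppm_error_mag(ref$mz_measured, ref$mz_theoretical)
  ref$ppm_consistent <- ref$ppm_recomputed == ref$ppm_reported
  ref
}
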