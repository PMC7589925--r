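#' Relative-quantification log2 fold-change from Ct values
#'
#' The standard 2^-ddCt convention for qPCR: with
#' `ddCt = (Ct_target,stress - Ct_housekeeping,stress) -
#' (Ct_target,control - Ct_housekeeping,control)`, the fold-change of the
#' target under stress relative to control is `2^-ddCt`, so the log2
#' fold-change is simply `-ddCt`.
#'
#' @param ct_target_stress,ct_housekeeping_stress Ct values under the
#'   stress (or numerator) condition.
#' @param ct_target_control,ct_housekeeping_control Ct values under the
#'   control (or denominator) condition.
#' @return log2 fold-change (vectorized over the inputs).
#' @export
log2fc_ddct <- function(ct_target_stress, ct_housekeeping_stress,
                        ct_target_control, ct_housekeeping_control) {
  stopifnot(is.finite(ct_target_stress), is.finite(ct_housekeeping_stress),
            is.finite(ct_target_control), is.finite(ct_housekeeping_control))
  ddct <- (ct_target_stress - ct_housekeeping_stress) -
    (ct_target_control - ct_housekeeping_control)
  -ddct
}
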