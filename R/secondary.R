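# Calculators behind the secondary assays: qPCR copy-number ratios,
# delta-delta-Ct expression folds, and respiration fold-changes under
# alternative normalizations.

#' Mitochondrial-to-nuclear DNA copy-number ratio from qPCR
#'
#' Relative mtDNA/nuDNA abundance from the cycle thresholds of a
#' mitochondrially encoded probe (e.g. mtND2) and a nuclear probe (e.g.
#' Alu): `efficiency^(Ct_nuclear - Ct_mito)` under the perfect-efficiency
#' exponential amplification model (efficiency fixed at 2 by default).
#'
#' @param ct_mito,ct_nuclear Cycle thresholds (finite, vectorized).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Numeric ratio(s).
#' @export
mtdna_ratio <- function(ct_mito, ct_nuclear, efficiency = 2) {
  stopifnot(all(is.finite(ct_mito)), all(is.finite(ct_nuclear)),
            efficiency > 1)
  efficiency^(ct_nuclear - ct_mito)
}

#' Delta-delta-Ct relative expression fold
#'
#' `fold = efficiency^(-ddCt)` with
#' `ddCt = (Ct_target - Ct_reference)_treated - (Ct_target - Ct_reference)_control`,
#' the standard relative quantification against a reference transcript
#' (e.g. Actb).
#'
#' @param ct_target_treated,ct_ref_treated Treated-group cycle thresholds of
#'   the target and reference assays.
#' @param ct_target_control,ct_ref_control Control-group cycle thresholds.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Numeric fold change(s).
#' @export
ddct_fold <- function(ct_target_treated, ct_ref_treated,
                      ct_target_control, ct_ref_control, efficiency = 2) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  stopifnot(all(is.finite(cts)), efficiency > 1)
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  efficiency^(-ddct)
}

#' Respiration fold change under a chosen normalization
#'
#' Mean normalized oxygen consumption rate in the treated group divided by
#' the control-group mean. Normalizers (cell count, cell volume, total
#' protein, or none) reproduce the size-correction schemes under which an
#' increase in respiration can be compared.
#'
#' @param treated,control Data frames with columns `sample_id`, `basal_ocr`,
#'   `uncoupled_ocr` and the normalizer columns `cell_count`, `cell_volume`,
#'   `total_protein` (positive).
#' @param normalizer One of `"total_protein"`, `"cell_count"`,
#'   `"cell_volume"`, `"none"`.
#' @param state `"uncoupled"` (default) or `"basal"`.
#' @return List with `fold`, `treated_mean`, `control_mean`, `normalizer`,
#'   `state`.
#' @export
respiration_fold <- function(treated, control,
                             normalizer = c("total_protein", "cell_count",
                                            "cell_volume", "none"),
                             state = c("uncoupled", "basal")) {
  normalizer <- match.arg(normalizer)
  state <- match.arg(state)
  ocr_col <- paste0(state, "_ocr")
  grp_mean <- function(df, label) {
    if (nrow(df) < 1L) stop_ms("%s group is empty", label)
    ocr <- df[[ocr_col]]
    if (is.null(ocr)) stop_ms("missing column %s", ocr_col)
    if (any(!is.finite(ocr)) || any(ocr < 0))
      stop_ms("%s group has invalid OCR values", label)
    if (normalizer == "none") return(mean(ocr))
    nv <- df[[normalizer]]
    if (is.null(nv)) stop_ms("missing normalizer column %s", normalizer)
    bad <- which(!is.finite(nv) | nv <= 0)
    if (length(bad) > 0)
      stop_ms("nonpositive %s for sample(s): %s", normalizer,
              paste(df$sample_id[bad], collapse = ", "))
    mean(ocr / nv)
  }
  tm <- grp_mean(treated, "treated")
  cm <- grp_mean(control, "control")
  list(fold = tm / cm, treated_mean = tm, control_mean = cm,
       normalizer = normalizer, state = state)
}
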