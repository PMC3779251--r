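#' Comparative-Ct fold change (2^-ddCt)
#'
#' Relative expression of a target gene between a treated and a control
#' sample, normalized to a reference (housekeeping) gene measured in both:
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)` and the fold change is
#' `2^-ddCt`. Invariant to adding a constant to all four Ct values; swapping
#' the treated and control roles inverts the result.
#'
#' @param ct_target_treated,ct_ref_treated Ct of the target and reference
#'   gene in the treated sample.
#' @param ct_target_control,ct_ref_control Same in the control sample.
#' @return Numeric fold change(s).
#' @examples
#' fold_change(22, 18, 20, 18)  # ddCt = 2 -> 0.25
#' @export
fold_change <- function(ct_target_treated, ct_ref_treated,
                        ct_target_control, ct_ref_control) {
  ct <- cbind(ct_target_treated, ct_ref_treated,
              ct_target_control, ct_ref_control)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("all Ct values must be finite and > 0", call. = FALSE)
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Per-gene fold changes from a tidy qPCR Ct table
#'
#' Technical replicates (rows sharing gene and condition) are averaged
#' before the comparison. Conditions are compared as treated vs control for
#' every gene present in both, normalized to `reference_gene`.
#'
#' @param data Data frame with columns `gene`, `condition`, `ct` (a `sample`
#'   column, if present, is ignored beyond replicate averaging).
#' @param reference_gene Housekeeping gene used for normalization.
#' @param control,treated Labels of the two conditions in `condition`.
#' @return Tibble with columns `gene` and `fold_change`, one row per
#'   non-reference gene.
#' @export
ddct_fold_changes <- function(data, reference_gene,
                              control = "control", treated = "treated") {
  stopifnot(all(c("gene", "condition", "ct") %in% names(data)))
  means <- data |>
    dplyr::filter(.data$condition %in% c(control, treated)) |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "ct")
  if (!reference_gene %in% means$gene) {
    stop("reference gene ", reference_gene, " not found in data", call. = FALSE)
  }
  if (!all(c(control, treated) %in% names(means))) {
    stop("need Ct values for both conditions '", control, "' and '",
         treated, "'", call. = FALSE)
  }
  ref <- means[means$gene == reference_gene, , drop = FALSE]
  out <- means[means$gene != reference_gene, , drop = FALSE]
  tibble::tibble(
    gene = out$gene,
    fold_change = fold_change(out[[treated]], ref[[treated]],
                              out[[control]], ref[[control]])
  )
}
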