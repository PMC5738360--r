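#' Clamp qPCR Ct values at the detection threshold
#'
#' Applies the reporting rule used for SYBR qPCR with water-control-derived
#' thresholds: any detected Ct above 35 cycles, and any well with no Ct
#' reported within 50 cycles (undetected, `NA`), is set to a Ct of 35.
#' Idempotent.
#'
#' @param ct Numeric vector of Ct values; `NA` marks undetected wells.
#' @param threshold Clamping threshold in cycles (default 35).
#' @return Clamped Ct values (no `NA` remains).
#' @export
clamp_ct <- function(ct, threshold = 35) {
  if (any(!is.na(ct) & (ct <= 0 | ct > 50)))
    stop("detected Ct values must lie in (0, 50]", call. = FALSE)
  ct[is.na(ct) | ct > threshold] <- threshold
  ct
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes `2^-dCt_diff` with
#' `dCt_diff = (ct_goi - ct_gapdh) - (ct_goi_ref - ct_gapdh_ref)`:
#' the gene of interest is first normalized to the housekeeping gene within
#' each condition, then compared against the reference condition. Inputs
#' are assumed already clamped (see [clamp_ct()]).
#'
#' @param ct_goi Gene-of-interest Ct in the condition of interest.
#' @param ct_gapdh Housekeeping Ct in the condition of interest.
#' @param ct_goi_ref Gene-of-interest Ct in the reference condition.
#' @param ct_gapdh_ref Housekeeping Ct in the reference condition.
#' @return Relative expression factor (dimensionless, > 0).
#' @examples
#' relative_expression(30, 20, 29, 20)  # one extra cycle -> 0.5
#' @export
relative_expression <- function(ct_goi, ct_gapdh, ct_goi_ref,
                                ct_gapdh_ref) {
  if (any(is.na(c(ct_goi, ct_gapdh, ct_goi_ref, ct_gapdh_ref))))
    stop("missing Ct: clamp undetected wells before computing expression",
         call. = FALSE)
  ddct <- (ct_goi - ct_gapdh) - (ct_goi_ref - ct_gapdh_ref)
  2^(-ddct)
}

#' Fold change between treated and untreated conditions
#'
#' @param rel_treated Relative expression in the treated condition (> 0).
#' @param rel_untreated Relative expression in the untreated condition
#'   (> 0).
#' @return Ratio `rel_treated / rel_untreated`.
#' @export
fold_change <- function(rel_treated, rel_untreated) {
  if (any(rel_untreated <= 0) || any(rel_treated <= 0))
    stop("relative expressions must be > 0", call. = FALSE)
  rel_treated / rel_untreated
}

#' Relative expression for a whole qPCR plate
#'
#' Plate-level driver: clamps every Ct at the threshold, averages Ct within
#' each sample x gene condition (mean of technical replicates in Ct space,
#' before the delta-delta-Ct formula), then computes relative expression of
#' every non-housekeeping gene in every sample against the reference
#' sample.
#'
#' @param plate A `qpcr_plate` data frame (columns `sample`, `gene`,
#'   `replicate`, `ct`; `NA` ct = undetected).
#' @param reference_sample Label of the reference condition (e.g. the free
#'   effector + non-targeting guide control).
#' @param housekeeping Housekeeping gene label (default `"GAPDH"`).
#' @param threshold Ct clamping threshold.
#' @return A data frame (class `expression_table`) with columns `sample`,
#'   `gene`, `relative_expression`, `n_replicates_used`, `n_clamped`.
#' @export
qpcr_relative_expression <- function(plate, reference_sample,
                                     housekeeping = "GAPDH",
                                     threshold = 35) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(plate)))
    stop("plate must have columns sample, gene, replicate, ct",
         call. = FALSE)
  if (!reference_sample %in% plate$sample)
    stop("reference sample '", reference_sample, "' not present in plate",
         call. = FALSE)
  if (!housekeeping %in% plate$gene)
    stop("housekeeping gene '", housekeeping, "' not present in plate",
         call. = FALSE)
  clamped <- clamp_ct(plate$ct, threshold)
  key <- interaction(plate$sample, plate$gene, drop = TRUE)
  mean_ct <- tapply(clamped, key, mean)
  n_used <- tapply(clamped, key, length)
  n_clamped <- tapply(is.na(plate$ct) | plate$ct > threshold, key, sum)
  cond <- do.call(rbind, strsplit(names(mean_ct), ".", fixed = TRUE))
  tab <- data.frame(sample = cond[, 1L], gene = cond[, 2L],
                    mean_ct = as.numeric(mean_ct),
                    n_replicates_used = as.integer(n_used),
                    n_clamped = as.integer(n_clamped))
  hk <- tab[tab$gene == housekeeping, c("sample", "mean_ct")]
  names(hk)[2L] <- "hk_ct"
  tab <- merge(tab[tab$gene != housekeeping, ], hk, by = "sample")
  ref <- tab[tab$sample == reference_sample,
             c("gene", "mean_ct", "hk_ct")]
  if (!nrow(ref))
    stop("reference sample has no target-gene records", call. = FALSE)
  names(ref)[2:3] <- c("ref_ct", "ref_hk_ct")
  tab <- merge(tab, ref, by = "gene")
  tab$relative_expression <- relative_expression(
    tab$mean_ct, tab$hk_ct, tab$ref_ct, tab$ref_hk_ct)
  out <- tab[order(tab$sample, tab$gene),
             c("sample", "gene", "relative_expression",
               "n_replicates_used", "n_clamped")]
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}
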