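# Expression-matrix transforms and phenotype formulas: log2 FPKM,
# 2^-ddCt relative expression, survival rate and leaf relative water
# content.

#' Log2-transform an FPKM matrix
#'
#' Elementwise `log2(x + pseudocount)`. The pseudocount (default 1) keeps
#' zero-FPKM entries finite; with pseudocount 1, an FPKM of 0 maps to 0.
#'
#' @param mat numeric matrix (or vector) of FPKM values, all >= 0.
#' @param pseudocount non-negative offset added before the log.
#' @return transformed matrix of the same shape.
#' @export
log2_fpkm <- function(mat, pseudocount = 1) {
  if (any(mat < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  log2(mat + pseudocount)
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per sample; the fold change
#' of a sample against the calibrator is `2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param ct_target,ct_ref Ct replicate values for the target and reference
#'   (internal-control) gene in the sample of interest.
#' @param ct_target_cal,ct_ref_cal the same for the calibrator sample.
#' @return fold change relative to the calibrator.
#' @export
relative_expression <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  check_ct <- function(x, what) {
    if (length(x) < 1L || any(x <= 0 | x >= 45)) {
      stop(what, " Ct values must lie in (0, 45) with >= 1 replicate")
    }
  }
  check_ct(ct_target, "target"); check_ct(ct_ref, "reference")
  check_ct(ct_target_cal, "calibrator target"); check_ct(ct_ref_cal, "calibrator reference")
  dct <- mean(ct_target) - mean(ct_ref)
  dct_cal <- mean(ct_target_cal) - mean(ct_ref_cal)
  2^-(dct - dct_cal)
}

#' Fold changes from a long-format qPCR Ct table
#'
#' Computes 2^-ddCt fold changes for every (sample, gene) combination in a
#' long table of Ct replicates, against a named reference gene and
#' calibrator sample.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `ct`
#'   (one row per replicate well).
#' @param reference_gene internal-control gene name.
#' @param calibrator_sample sample used as the 1x calibrator.
#' @return data.frame with columns `sample`, `gene`, `fold`.
#' @export
qpcr_fold_changes <- function(ct_table, reference_gene, calibrator_sample) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  }
  if (!reference_gene %in% ct_table$gene) {
    stop("reference gene '", reference_gene, "' absent from the table")
  }
  if (!calibrator_sample %in% ct_table$sample) {
    stop("calibrator sample '", calibrator_sample, "' absent from the table")
  }
  get_ct <- function(s, g) ct_table$ct[ct_table$sample == s & ct_table$gene == g]
  genes <- setdiff(unique(ct_table$gene), reference_gene)
  samples <- unique(ct_table$sample)
  rows <- list()
  for (g in genes) {
    cal_t <- get_ct(calibrator_sample, g)
    cal_r <- get_ct(calibrator_sample, reference_gene)
    if (length(cal_t) == 0L) next
    for (s in samples) {
      t_ct <- get_ct(s, g)
      r_ct <- get_ct(s, reference_gene)
      if (length(t_ct) == 0L) next
      if (length(r_ct) == 0L) stop("sample '", s, "' lacks reference-gene wells")
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = g,
        fold = relative_expression(t_ct, r_ct, cal_t, cal_r),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seedling survival rate
#'
#' `SR% = 100 * survived / total`.
#'
#' @param survived surviving plant count, `0 <= survived <= total`.
#' @param total total plant count, > 0.
#' @return survival rate in percent.
#' @export
#' @examples
#' survival_rate(10, 16)  # 62.5
survival_rate <- function(survived, total) {
  stopifnot(all(total > 0), all(survived >= 0), all(survived <= total))
  100 * survived / total
}

#' Leaf relative water content
#'
#' `RWC% = 100 * (FW - DW) / (TW - DW)` from fresh, turgid and dry weights.
#'
#' @param fw fresh weight.
#' @param tw turgid weight (must exceed dry weight).
#' @param dw dry weight (must not exceed fresh weight).
#' @return RWC in percent.
#' @export
#' @examples
#' relative_water_content(2, 3, 1)  # 50
relative_water_content <- function(fw, tw, dw) {
  if (any(tw <= dw)) stop("turgid weight must exceed dry weight")
  if (any(fw < dw)) stop("fresh weight must be >= dry weight")
  100 * (fw - dw) / (tw - dw)
}

#' Plot an expression heatmap
#'
#' Convenience wrapper: log2-transformed FPKM rendered with
#' \pkg{pheatmap}, rows optionally ordered/annotated by tree class.
#' Cosmetic only; all quantitative output comes from [log2_fpkm()].
#'
#' @param mat genes x samples FPKM matrix.
#' @param classes optional named class vector (as from [assign_classes()]).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_expression_heatmap <- function(mat, classes = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_expression_heatmap requires the 'pheatmap' package")
  }
  x <- log2_fpkm(mat)
  ann <- NULL
  if (!is.null(classes)) {
    ord <- order(classes[rownames(x)])
    x <- x[ord, , drop = FALSE]
    ann <- data.frame(class = factor(classes[rownames(x)]))
    rownames(ann) <- rownames(x)
  }
  p <- pheatmap::pheatmap(x, cluster_rows = is.null(classes),
                          annotation_row = ann, ...)
  invisible(p)
}
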