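# Published characterization values for the maize serine peptidase S8
# (ZmSPS8) family, usable as worked-example inputs: the per-protein GRAVY
# column of the family characterization table, and the paralogous-pair
# Ka/Ks table used for selection-pressure and divergence-dating examples.

#' Published GRAVY values for the maize SPS8 family
#'
#' Grand-average-of-hydropathicity values for the 18 maize serine peptidase
#' S8 proteins, as printed in the family's published characterization table.
#'
#' @return named numeric vector of 18 GRAVY values.
#' @export
#' @examples
#' table(classify_hydropathy(maize_sps8_gravy()))
maize_sps8_gravy <- function() {
  c(
    ZmSPS8.1.3  =  0.054,
    ZmSPS8.1.9  =  0.108,
    ZmSPS8.1.10 = -0.007,
    ZmSPS8.1.4  =  0.009,
    ZmSPS8.1.5  =  0.150,
    ZmSPS8.2.0  = -0.026,
    ZmSPS8.1.14 = -0.461,
    ZmSPS8.1.12 =  0.074,
    ZmSPS8.1.6  =  0.024,
    ZmSPS8.1.8  = -0.153,
    ZmSPS8.1.1  = -0.039,
    ZmSPS8.1.13 = -0.012,
    ZmSPS8.3.2  = -0.137,
    ZmSPS8.3.1  =  0.324,
    ZmSPS8.1.11 =  0.239,
    ZmSPS8.1.2  =  0.106,
    ZmSPS8.1.7  = -0.055,
    ZmSPS8.3.3  = -0.238
  )
}

#' Published paralogous-pair table for the maize SPS8 family
#'
#' The three duplicated gene pairs of the maize serine peptidase S8 family
#' with their published alignment coverage and per-site Ka and Ks estimates.
#' Ka/Ks ratios, selection classes and divergence times are recomputed from
#' these inputs by [kaks_ratio()], [selection_class()] and
#' [divergence_time()].
#'
#' @return data.frame with columns `gene_a`, `gene_b`, `coverage`, `ka`, `ks`.
#' @export
#' @examples
#' pairs <- maize_sps8_pairs()
#' divergence_time(pairs$ks)
maize_sps8_pairs <- function() {
  data.frame(
    gene_a = c("ZmSPS8.3.2", "ZmSPS8.3.1", "ZmSPS8.3.3"),
    gene_b = c("ZmSPS8.3.3", "ZmSPS8.3.2", "ZmSPS8.3.1"),
    coverage = c(0.993, 0.957, 0.966),
    ka = c(0.004817359, 0.062432033, 0.558916065),
    ks = c(0.014907323, 0.038079244, 0.803034338),
    stringsAsFactors = FALSE
  )
}
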