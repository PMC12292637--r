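#' Bundled worked-example selection tables
#'
#' Two small per-k tables from a published cluster-conditioned generation
#' analysis of H&E tumor tiles, bundled as worked examples for the two
#' selection procedures: the five internal validity indices for cluster
#' counts k = 10..16 (consumed by [consensusSelectK()]) and the three
#' generation-quality metrics for the same counts (consumed by
#' [selectBestClusterSet()]). In both tables the 14-cluster set wins every
#' column in its favorable direction.
#'
#' @return a `data.frame`: `referenceIndexTable()` with columns `k`, `ch`,
#'   `c_index`, `dunn`, `hartigan`, `mcclain_rao`;
#'   `referenceMetricTable()` with columns `k`, `ssim`, `ms_ssim`, `lpips`.
#' @export
#' @examples
#' consensusSelectK(referenceIndexTable())$k    # 14
#' selectBestClusterSet(referenceMetricTable())$k  # 14
referenceIndexTable <- function() {
  utils::read.csv(system.file("extdata", "reference_validity_indices.csv",
                              package = "HistoCLDM"))
}

#' @rdname referenceIndexTable
#' @export
referenceMetricTable <- function() {
  utils::read.csv(system.file("extdata", "reference_generation_metrics.csv",
                              package = "HistoCLDM"))
}
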