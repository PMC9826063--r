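#' Control parameters for the anchored phasing pipeline
#'
#' Collects every tunable threshold of the pipeline in one validated list,
#' in the spirit of [glm.control()]. Defaults follow the published filter
#' settings of the method (coverage strictly greater than 20x, allele
#' frequency between 20% and 80% inclusive, heterozygosity confidence of at
#' least 0.96) together with documented operational choices for the
#' quantities the method describes only qualitatively.
#'
#' @param min_depth minimum pileup depth for a variant call; the comparison
#'   is strict (`depth > min_depth`).
#' @param af_window inclusive allele-frequency window for heterozygous
#'   candidate calls, as `c(low, high)`.
#' @param min_conf minimum posterior probability of heterozygosity under the
#'   symmetric-error binomial genotype model.
#' @param wes_min_depth minimum exome depth for a position to count as
#'   WES-covered during error polishing; below this the exome is treated as
#'   uninformative rather than contradictory.
#' @param isnp_min_parent_depth minimum exome depth in *each* parent for a
#'   trio informative SNP (inclusive).
#' @param parental_support_af minimum allele fraction for a parental
#'   long-read pileup to support an allele when typing intronic iSNPs.
#' @param parental_min_depth minimum parental long-read depth for such
#'   typing.
#' @param min_group_agreement minimum majority-base fraction inside the
#'   DNM-alt read group for a candidate to count as linked (the anchored
#'   group must look effectively homozygous).
#' @param min_spanning minimum number of reads spanning both the DNM and the
#'   iSNP (and minimum per-group coverage for the linkage check).
#' @param short_read_span distance (bp) within which an iSNP is considered
#'   reachable by paired short reads (phasing category 1).
#' @param long_window distance (bp) within which an exome-typed iSNP can be
#'   phased with proband long reads alone (category 2).
#' @param trio_window search radius (bp) for intronic iSNPs typed from
#'   parental long reads (category 3).
#' @param prezygotic_band inclusive band of polished mutant allele fractions
#'   regarded as consistent with a prezygotic (germline) event.
#' @param third_allele_floor minimum fraction for a third allelic form to be
#'   credible, chosen above the typical background allele noise.
#' @param third_allele_k multiple of the largest single false-allele
#'   fraction that a credible third allelic form must exceed.
#' @param wes_allele_min_reads minimum reads per allele for a WES-only
#'   phasing result to be marked acceptable (strict, `> wes_allele_min_reads`).
#' @param qc_quality,qc_min_len end-trimming quality threshold and minimum
#'   retained read length for read QC.
#' @param error_floor numerical floor for the estimated sequencing error
#'   rate inside the genotype confidence model.
#'
#' @return A named list of class `phase_control`.
#' @export
phase_control <- function(min_depth = 20L,
                          af_window = c(0.20, 0.80),
                          min_conf = 0.96,
                          wes_min_depth = 10L,
                          isnp_min_parent_depth = 5L,
                          parental_support_af = 0.20,
                          parental_min_depth = 20L,
                          min_group_agreement = 0.80,
                          min_spanning = 20L,
                          short_read_span = 300L,
                          long_window = 10000L,
                          trio_window = 5000L,
                          prezygotic_band = c(0.40, 0.60),
                          third_allele_floor = 0.05,
                          third_allele_k = 2.0,
                          wes_allele_min_reads = 10L,
                          qc_quality = 10L,
                          qc_min_len = 30L,
                          error_floor = 1e-3) {
  stopifnot(min_depth >= 0, length(af_window) == 2L,
            af_window[1] <= af_window[2],
            af_window[1] >= 0, af_window[2] <= 1,
            min_conf >= 0, min_conf <= 1,
            min_group_agreement > 0.5, min_group_agreement <= 1,
            length(prezygotic_band) == 2L,
            prezygotic_band[1] < prezygotic_band[2],
            third_allele_floor >= 0, third_allele_k >= 0,
            error_floor > 0)
  structure(list(
    min_depth = as.integer(min_depth),
    af_window = as.numeric(af_window),
    min_conf = min_conf,
    wes_min_depth = as.integer(wes_min_depth),
    isnp_min_parent_depth = as.integer(isnp_min_parent_depth),
    parental_support_af = parental_support_af,
    parental_min_depth = as.integer(parental_min_depth),
    min_group_agreement = min_group_agreement,
    min_spanning = as.integer(min_spanning),
    short_read_span = as.integer(short_read_span),
    long_window = as.integer(long_window),
    trio_window = as.integer(trio_window),
    prezygotic_band = as.numeric(prezygotic_band),
    third_allele_floor = third_allele_floor,
    third_allele_k = third_allele_k,
    wes_allele_min_reads = as.integer(wes_allele_min_reads),
    qc_quality = as.integer(qc_quality),
    qc_min_len = as.integer(qc_min_len),
    error_floor = error_floor
  ), class = "phase_control")
}

BASES <- c("A", "C", "G", "T")
DEL_MARK <- "-"
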