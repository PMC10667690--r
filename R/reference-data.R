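#' Published reference tables from a rice anaerobic-germination screen
#'
#' Two small reference tables distributed with the package, transcribed
#' from the published summary statistics of a screenhouse donor-screening
#' study of 200 rice landraces/lines plus 8 checks under flooded and
#' control germination:
#' \describe{
#'   \item{\code{referenceTraitSummaries()}}{per experiment-group and
#'     trait, the minimum, mean and maximum of genotype-level summaries
#'     (groups: each experiment x condition, the per-condition
#'     across-experiment rows, and the overall across row).}
#'   \item{\code{referenceDonorCandidates()}}{the published donor
#'     candidate list: genotype, selection rule, selection index,
#'     germination-21-DAS percentage, and Entry/Check remark.}
#' }
#' They serve as worked-example inputs: re-applying [selectDonors()] to
#' the candidate list reproduces the published rule counts, and the
#' summary means feed [percentReduction()] stress-impact arithmetic.
#'
#' @return A data.frame (see above).
#' @examples
#' ref <- referenceDonorCandidates()
#' table(ref$condition)
#' @name referenceData
NULL

#' @rdname referenceData
#' @export
referenceTraitSummaries <- function() {
  utils::read.table(system.file("extdata", "reference_trait_summaries.tsv",
                                package = "anaerGS"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname referenceData
#' @export
referenceDonorCandidates <- function() {
  utils::read.table(system.file("extdata", "reference_donor_candidates.tsv",
                                package = "anaerGS"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}
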