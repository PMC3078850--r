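# Deterministic seed ladder: one named substream per stochastic stage, so that
# toggling e.g. the statin stage never perturbs the event draws of another run
# with the same base seed. All arithmetic stays below 2^53 and the result below
# 2^31, so it is exact in doubles and valid for set.seed().

.stage_ids <- c(
  demography = 1L,
  genotype   = 2L,
  statin     = 3L,
  events     = 4L,
  fatality   = 5L
)

#' Derive the seed for one stochastic stage of one replicate
#'
#' Mixes a base seed, a replicate index and a stage label into a distinct
#' 31-bit seed. Used internally by [simulate_cohort()] so that each stage
#' (population sampling, genotype assignment, statin assignment, event draws,
#' fatality draws) consumes an independent, reproducible stream.
#'
#' @param base_seed integer base seed for the whole experiment.
#' @param replicate replicate index (1-based).
#' @param stage one of `"demography"`, `"genotype"`, `"statin"`, `"events"`,
#'   `"fatality"`.
#' @return a single integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' stage_seed(1, 1, "events")
#' @export
stage_seed <- function(base_seed, replicate, stage) {
  stage <- match.arg(stage, names(.stage_ids))
  b <- as.double(base_seed) %% 2147483647
  r <- as.double(replicate) %% 2147483647
  h <- (b * 48271 + r * 69621 + .stage_ids[[stage]] * 16807) %% 2147483647
  as.integer(h)
}
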