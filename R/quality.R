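#' Facility quality level from volume and 30-day readmission rate
#'
#' Scores a hospital structure on a six-step scale in \{0, 0.2, 0.4, 0.6,
#' 0.8, 1\}. A facility performing 72 or fewer hip-replacement interventions
#' in the reference year is not considered attractive and scores 0 regardless
#' of outcome. Above that volume gate the score is a non-increasing step
#' function of the risk-adjusted 30-day readmission rate `ret30` (percent),
#' with inclusive upper bounds: `ret30 <= 3` scores 1, `(3, 4.5]` scores 0.8,
#' `(4.5, 6]` scores 0.6, `(6, 7.5]` scores 0.4, `(7.5, 9]` scores 0.2 and
#' anything above 9 scores 0. Ties at the cut points resolve to the higher
#' score. The 73-intervention eligibility threshold reflects the national
#' minimum-volume standard of 80 with a 10% tolerance; it is used as a fixed
#' constant, not recomputed.
#'
#' @param interventions Nonnegative annual intervention count(s) (vectorised).
#' @param ret30 Nonnegative adjusted 30-day readmission rate(s), in percent.
#' @return Quality level(s) in \{0, 0.2, 0.4, 0.6, 0.8, 1\}.
#' @export
#' @examples
#' quality_level(100, 2.5)   # 1
#' quality_level(100, 4.0)   # 0.8
#' quality_level(72, 0)      # 0: below the volume gate
quality_level <- function(interventions, ret30) {
  stopifnot(is.numeric(interventions), is.numeric(ret30))
  if (any(interventions < 0, na.rm = TRUE)) stop("interventions must be nonnegative")
  if (any(ret30 < 0, na.rm = TRUE)) stop("ret30 must be nonnegative")
  n <- max(length(interventions), length(ret30))
  interventions <- rep_len(interventions, n)
  ret30 <- rep_len(ret30, n)
  # left.open makes the bands (b, b'] so a rate exactly at a cut point falls
  # in the band below it (inclusive upper bounds)
  band <- findInterval(ret30, c(3, 4.5, 6, 7.5, 9), left.open = TRUE)
  ql <- c(1, 0.8, 0.6, 0.4, 0.2, 0)[band + 1L]
  ql[interventions <= 72] <- 0
  ql
}
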