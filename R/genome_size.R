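#' Physical anchor: a clone tying genetic to physical distance
#'
#' An anchor is a clone (for example a BAC) whose two end markers are mapped,
#' so that a known physical insert size (kb) corresponds to a measured genetic
#' separation (cM). Several anchors may be held in one object.
#'
#' @param genetic_d genetic separation(s) of the end-marker pairs, cM (`> 0`).
#' @param physical_kb insert size(s) in kb (`> 0`).
#' @return object of class `physical_anchor`.
#' @export
physical_anchor <- function(genetic_d, physical_kb) {
  genetic_d <- as.numeric(genetic_d)
  physical_kb <- as.numeric(physical_kb)
  stopifnot(length(genetic_d) == length(physical_kb))
  if (any(genetic_d <= 0)) stop("genetic_d must be positive")
  if (any(physical_kb <= 0)) stop("physical_kb must be positive")
  structure(list(genetic_d = genetic_d, physical_kb = physical_kb),
            class = "physical_anchor")
}

#' Anchor-based genome-size estimate
#'
#' Extrapolates the physical-to-genetic scale of each anchor
#' (`physical_kb / genetic_d`, kb per cM) over the total map length:
#' `Mb = (physical_kb / genetic_d) * total_map_cm / 1000`. With several
#' anchors the per-anchor estimates are returned; their mean is attached as
#' the attribute `"mean"`.
#'
#' @param anchor a [physical_anchor()].
#' @param total_map_cm total (corrected) map length in cM (`> 0`).
#' @return numeric vector of per-anchor genome sizes in Mb, with attribute
#'   `mean`.
#' @export
size_from_anchor <- function(anchor, total_map_cm) {
  stopifnot(inherits(anchor, "physical_anchor"))
  if (total_map_cm <= 0) stop("total map length must be positive")
  est <- anchor$physical_kb / anchor$genetic_d * total_map_cm / 1000
  attr(est, "mean") <- mean(est)
  est
}

#' Cytometry-based genome-size estimate
#'
#' Physical genome size from a (bias-corrected) DNA-content ratio against a
#' reference genome of known size: the plain product of the two.
#'
#' @param corrected_ratio query/reference DNA-content ratio after any staining
#'   bias correction (`> 0`).
#' @param reference_size_mb reference genome size in Mb (`> 0`).
#' @return genome size in Mb.
#' @export
size_from_cytometry <- function(corrected_ratio, reference_size_mb) {
  if (corrected_ratio <= 0 || reference_size_mb <= 0) {
    stop("ratio and reference size must be positive")
  }
  corrected_ratio * reference_size_mb
}

#' Correct an AT-biased DNA-content ratio
#'
#' Intercalating stains biased towards the AT fraction of the genome
#' under-report the DNA content of the more GC-rich genome; the measured
#' query/reference ratio then needs correcting upwards when the query's
#' AT content is below the reference's. No single published arithmetic is
#' canonical, so three models are offered:
#' \describe{
#'   \item{`"proportional"`}{`corrected = measured * at_ref / at_query` —
#'     assumes the stain signal scales with the AT fraction.}
#'   \item{`"fixed"`}{`corrected = measured * factor` with a user-supplied
#'     multiplicative factor (use this to apply an externally derived
#'     correction).}
#'   \item{`"none"`}{identity.}
#' }
#'
#' @param measured_ratio measured query/reference ratio.
#' @param at_query,at_ref AT contents in percent, in `(0, 100)` (required for
#'   the proportional model).
#' @param model correction model tag.
#' @param factor multiplicative factor for `model = "fixed"`.
#' @return corrected ratio.
#' @export
at_corrected_ratio <- function(measured_ratio, at_query = NULL, at_ref = NULL,
                               model = c("proportional", "none", "fixed"),
                               factor = NULL) {
  model <- match.arg(model)
  if (measured_ratio <= 0) stop("measured ratio must be positive")
  switch(model,
    none = measured_ratio,
    fixed = {
      if (is.null(factor) || factor <= 0) stop("model 'fixed' needs a positive factor")
      measured_ratio * factor
    },
    proportional = {
      if (is.null(at_query) || is.null(at_ref)) {
        stop("model 'proportional' needs at_query and at_ref")
      }
      if (at_query <= 0 || at_query >= 100 || at_ref <= 0 || at_ref >= 100) {
        stop("AT contents must lie in (0, 100)")
      }
      measured_ratio * at_ref / at_query
    })
}

#' Genome-wide recombination rate
#'
#' Total map length divided by physical genome size, in cM/Mb.
#'
#' @param total_map_cm total map length in cM (`>= 0`).
#' @param genome_mb genome size in Mb (`> 0`).
#' @return recombination rate in cM/Mb.
#' @export
recombination_rate <- function(total_map_cm, genome_mb) {
  if (genome_mb <= 0) stop("genome size must be positive")
  if (total_map_cm < 0) stop("map length must be non-negative")
  total_map_cm / genome_mb
}

#' Consensus of several genome-size estimates
#'
#' Plain mean of independent genome-size estimates (Mb); the conventional
#' working value when anchor- and cytometry-based estimates agree to within a
#' few percent.
#'
#' @param estimates numeric vector of sizes in Mb.
#' @return mean size in Mb.
#' @export
genome_size_consensus <- function(estimates) {
  if (!length(estimates) || any(estimates <= 0)) {
    stop("estimates must be positive")
  }
  mean(estimates)
}
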