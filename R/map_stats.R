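#' Per-LG and genome-wide map statistics
#'
#' Computes the classic map summary table: per linkage group the observed
#' length (span between terminal markers), marker count, distorted-marker
#' count, average marker distance and the chromosome-end corrected length,
#' plus genome-wide totals. Conventions (fixed by validation against published
#' map tables of this design):
#' \itemize{
#'   \item average marker distance = LG length / marker \emph{count} (not
#'     interval count);
#'   \item corrected length = length + 2 x average distance, i.e.
#'     `length * (1 + 2 / n)` exactly — terminal chromosome segments beyond
#'     the outermost markers cannot carry markers, so each end is credited
#'     one average marker spacing;
#'   \item the genome-wide average marker distance is the unweighted mean of
#'     the per-LG averages, with the sample (n-1) SD.
#' }
#'
#' @param map a `genetic_map` (or `linkage_map`).
#' @param distortion_alpha p-value threshold below which a marker counts as
#'   distorted (default 0.05).
#' @return object of class `map_summary`: list with `per_lg` (data frame),
#'   `total_length_cm`, `total_corrected_cm`, `total_markers`,
#'   `total_distorted`, `mean_avg_dist`, `sd_avg_dist` and `coverage_pct`.
#' @export
summarize_map <- function(map, distortion_alpha = 0.05) {
  stopifnot(inherits(map, "genetic_map"))
  lgs <- lg_split(map)
  per <- lapply(names(lgs), function(nm) {
    d <- lgs[[nm]]
    len <- max(d$pos) - min(d$pos)
    n <- nrow(d)
    nd <- if (all(is.na(d$distortion_p))) NA_integer_ else {
      sum(d$distortion_p < distortion_alpha, na.rm = TRUE)
    }
    if (n == 1L) {
      warning("linkage group ", nm, " has a single marker; length undefined (0)")
    }
    data.frame(lg = nm, length_cm = len, n_markers = n, n_distorted = nd,
               avg_dist_cm = len / n,
               corrected_length_cm = len * (1 + 2 / n),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  new_map_summary(per)
}

new_map_summary <- function(per) {
  structure(list(
    per_lg = per,
    total_length_cm = sum(per$length_cm),
    total_corrected_cm = sum(per$corrected_length_cm),
    total_markers = sum(per$n_markers),
    total_distorted = if (all(is.na(per$n_distorted))) NA_integer_ else {
      sum(per$n_distorted, na.rm = TRUE)
    },
    mean_avg_dist = mean(per$avg_dist_cm),
    sd_avg_dist = stats::sd(per$avg_dist_cm),
    coverage_pct = 100 * sum(per$length_cm) / sum(per$corrected_length_cm)
  ), class = "map_summary")
}

#' Build a map summary from per-LG primitives
#'
#' Same statistics as [summarize_map()] but starting from already-tabulated
#' per-LG lengths and marker counts (for instance a published summary table)
#' instead of a marker-level map.
#'
#' @param lg LG labels.
#' @param length_cm observed LG lengths (cM).
#' @param n_markers marker counts.
#' @param n_distorted distorted-marker counts (optional).
#' @return a `map_summary`.
#' @export
lg_summary_from_lengths <- function(lg, length_cm, n_markers,
                                    n_distorted = NA_integer_) {
  stopifnot(length(lg) == length(length_cm),
            length(lg) == length(n_markers),
            all(length_cm >= 0), all(n_markers >= 1))
  per <- data.frame(lg = as.character(lg), length_cm = as.numeric(length_cm),
                    n_markers = as.integer(n_markers),
                    n_distorted = as.integer(rep_len(n_distorted, length(lg))),
                    stringsAsFactors = FALSE)
  per$avg_dist_cm <- per$length_cm / per$n_markers
  per$corrected_length_cm <- per$length_cm * (1 + 2 / per$n_markers)
  new_map_summary(per)
}

#' @export
print.map_summary <- function(x, ...) {
  df <- x$per_lg
  df$avg_dist_cm <- round(df$avg_dist_cm, 2)
  df$corrected_length_cm <- round(df$corrected_length_cm, 2)
  print(df, row.names = FALSE)
  cat(sprintf("SUM/MEAN  %.2f cM, %d markers, %s distorted, %.2f +/- %.2f cM spacing, %.2f cM corrected, %.2f%% coverage\n",
              x$total_length_cm, x$total_markers,
              ifelse(is.na(x$total_distorted), "NA", x$total_distorted),
              x$mean_avg_dist, x$sd_avg_dist, x$total_corrected_cm,
              x$coverage_pct))
  invisible(x)
}

#' @export
as.data.frame.map_summary <- function(x, ...) {
  df <- x$per_lg
  tot <- data.frame(lg = "SUM/MEAN", length_cm = x$total_length_cm,
                    n_markers = x$total_markers,
                    n_distorted = x$total_distorted,
                    avg_dist_cm = x$mean_avg_dist,
                    corrected_length_cm = x$total_corrected_cm,
                    stringsAsFactors = FALSE)
  rbind(df, tot)
}

#' Genome coverage of a map
#'
#' Percentage of the (end-corrected) genome length spanned by the observed
#' map: `100 * observed / corrected`.
#'
#' @param observed_total observed total map length (cM), `> 0`.
#' @param corrected_total end-corrected total length (cM), `>= observed`.
#' @return coverage percentage.
#' @export
genome_coverage_pct <- function(observed_total, corrected_total) {
  if (corrected_total <= 0) stop("corrected length must be positive")
  if (observed_total <= 0) stop("observed length must be positive")
  if (corrected_total < observed_total) {
    stop("corrected length cannot be smaller than the observed length")
  }
  100 * observed_total / corrected_total
}

#' Map-saturation coverage function
#'
#' Expected proportion of the genome lying within `d` cM of at least one of
#' `m` randomly placed markers on a genome of genetic length `L`:
#' `c = 1 - exp(-2 m d / L)` (the random-marker saturation model).
#'
#' @param m number of markers (`>= 1`).
#' @param d distance in cM (`>= 0`).
#' @param L total (corrected) map length in cM (`> 0`).
#' @return proportion in `[0, 1)`.
#' @export
proportion_within <- function(m, d, L) {
  if (any(L <= 0)) stop("map length L must be positive")
  if (any(m < 1)) stop("need at least one marker")
  if (any(d < 0)) stop("distance must be non-negative")
  1 - exp(-2 * m * d / L)
}

#' Inverse of the saturation function
#'
#' Distance `d` such that a proportion `c` of the genome lies within `d` cM of
#' a marker: `d = -L ln(1 - c) / (2 m)`.
#'
#' @param m number of markers.
#' @param c target proportion in `[0, 1)`.
#' @param L total map length in cM.
#' @return distance in cM.
#' @export
distance_for_coverage <- function(m, c, L) {
  if (any(c < 0 | c >= 1)) stop("coverage proportion must lie in [0, 1)")
  if (any(L <= 0)) stop("map length L must be positive")
  -L * log(1 - c) / (2 * m)
}

#' Correlation between LG length and marker count
#'
#' Pearson product-moment correlation of observed LG lengths against marker
#' counts, with the two-sided t-test p-value (n - 2 df).
#'
#' @param summary a `map_summary`.
#' @return list with `r`, `p` and `df`.
#' @export
length_marker_correlation <- function(summary) {
  stopifnot(inherits(summary, "map_summary"))
  per <- summary$per_lg
  if (nrow(per) < 3L) stop("need at least 3 linkage groups")
  if (stats::sd(per$length_cm) == 0 || stats::sd(per$n_markers) == 0) {
    stop("zero variance in LG length or marker count")
  }
  ct <- stats::cor.test(per$length_cm, per$n_markers, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter))
}
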