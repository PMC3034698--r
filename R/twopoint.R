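#' Chi-square test for segregation distortion
#'
#' Tests observed haploid allele counts against the Mendelian 1:1 expectation
#' with a 1-df chi-square statistic (no continuity correction). The star
#' annotation follows the conventional seven-level scale: p below
#' 0.1, 0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001 gives 1-7 stars.
#'
#' @param count0,count1 non-negative integer counts of the two alleles;
#'   `count0 + count1` must be at least 1.
#' @return list with `chi2`, `p` and `stars` (a string of `*`, possibly empty).
#' @examples
#' segregation_test(60, 40) # chi2 = 4, p ~ 0.0455, two stars
#' @export
segregation_test <- function(count0, count1) {
  if (count0 < 0 || count1 < 0) stop("counts must be non-negative")
  n <- count0 + count1
  if (n < 1) stop("at least one observation is required")
  e <- n / 2
  chi2 <- (count0 - e)^2 / e + (count1 - e)^2 / e
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  thr <- c(0.1, 0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001)
  list(chi2 = chi2, p = p, stars = strrep("*", sum(p < thr)))
}

#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction into a map distance under Kosambi's
#' function, `d = 25 ln((1 + 2 theta) / (1 - 2 theta))` cM, which accounts for
#' moderate crossover interference, and back (`theta = tanh(d / 50) / 2`).
#'
#' @param theta recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return `kosambi_cm()`: distance in cM; `kosambi_theta()`: recombination
#'   fraction. The two are exact inverses (round trip well below 1e-10).
#' @examples
#' kosambi_cm(0.10)            # 10.14 cM
#' kosambi_theta(kosambi_cm(0.23))
#' @export
kosambi_cm <- function(theta) {
  if (any(theta < 0 | theta >= 0.5)) {
    stop("theta must lie in [0, 0.5); 0.5 maps to infinite distance")
  }
  25 * log((1 + 2 * theta) / (1 - 2 * theta))
}

#' @rdname kosambi_cm
#' @export
kosambi_theta <- function(d) {
  if (any(d < 0)) stop("distance must be non-negative")
  tanh(d / 50) / 2
}

# G2 independence statistic of a 2x2 table given the four cell counts;
# zero observed cells contribute 0.
g2_stat <- function(n00, n01, n10, n11) {
  n <- n00 + n01 + n10 + n11
  r0 <- n00 + n01; r1 <- n10 + n11
  c0 <- n00 + n10; c1 <- n01 + n11
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  2 * (term(n00, r0 * c0 / n) + term(n01, r0 * c1 / n) +
       term(n10, r1 * c0 / n) + term(n11, r1 * c1 / n))
}

#' Two-point linkage between one marker pair
#'
#' Estimates the recombination fraction and independence LOD for a marker pair
#' from a haploid genotype matrix, phase-unknown: counts are taken over the
#' complete-case individuals, the relative phase is chosen to minimise the
#' recombinant count, `theta = min(R, n - R) / n`, and the LOD is the
#' likelihood-ratio independence statistic of the 2x2 haplotype table divided
#' by `2 ln 10`. A pair monomorphic in its informative subset is flagged and
#' returned with `lod = 0`, `theta = 0.5` and phase `NA`.
#'
#' @param gm integer genotype matrix (individuals x markers, calls 0/1/NA).
#' @param a,b marker ids (column names of `gm`).
#' @return one-row data frame with columns `a`, `b`, `n` (informative
#'   individuals), `R` (recombinants under the inferred phase), `theta`,
#'   `lod`, `phase` (`"coupling"`/`"repulsion"`/`NA`) and `flag`.
#' @export
pairwise_linkage <- function(gm, a, b) {
  stopifnot(is.matrix(gm), a %in% colnames(gm), b %in% colnames(gm))
  ga <- gm[, a]; gb <- gm[, b]
  keep <- !is.na(ga) & !is.na(gb)
  if (sum(keep) < 2) stop("fewer than 2 individuals informative for ", a, "/", b)
  ga <- ga[keep]; gb <- gb[keep]
  n00 <- sum(ga == 0 & gb == 0); n01 <- sum(ga == 0 & gb == 1)
  n10 <- sum(ga == 1 & gb == 0); n11 <- sum(ga == 1 & gb == 1)
  n <- n00 + n01 + n10 + n11
  mono <- (n00 + n01) == 0 || (n10 + n11) == 0 || (n00 + n10) == 0 || (n01 + n11) == 0
  if (mono) {
    return(data.frame(a = a, b = b, n = n, R = NA_integer_, theta = 0.5,
                      lod = 0, phase = NA_character_, flag = "monomorphic",
                      stringsAsFactors = FALSE))
  }
  cross <- n01 + n10
  same <- n00 + n11
  R <- min(cross, same)
  phase <- if (cross <= same) "coupling" else "repulsion"
  data.frame(a = a, b = b, n = n, R = R, theta = R / n,
             lod = g2_stat(n00, n01, n10, n11) / (2 * log(10)),
             phase = phase, flag = "", stringsAsFactors = FALSE)
}

#' All-pairs two-point linkage table
#'
#' Vectorised computation of [pairwise_linkage()] over every marker pair,
#' using cross-products of the 0/1 indicator matrices so that a full
#' 500-marker, 400-individual matrix takes well under a second.
#'
#' @param gm integer genotype matrix (individuals x markers, calls 0/1/NA).
#' @return data frame with one row per unordered pair, columns as in
#'   [pairwise_linkage()].
#' @export
twopoint_table <- function(gm) {
  stopifnot(is.matrix(gm), !is.null(colnames(gm)))
  if (ncol(gm) < 2) stop("need at least two markers")
  M1 <- matrix(as.numeric(!is.na(gm) & gm == 1), nrow(gm))
  M0 <- matrix(as.numeric(!is.na(gm) & gm == 0), nrow(gm))
  n00 <- crossprod(M0); n01 <- crossprod(M0, M1)
  n10 <- t(n01); n11 <- crossprod(M1)
  up <- upper.tri(n00)
  idx <- which(up, arr.ind = TRUE)
  c00 <- n00[up]; c01 <- n01[up]; c10 <- n10[up]; c11 <- n11[up]
  n <- c00 + c01 + c10 + c11
  mono <- (c00 + c01) == 0 | (c10 + c11) == 0 | (c00 + c10) == 0 | (c01 + c11) == 0
  cross <- c01 + c10; same <- c00 + c11
  R <- pmin(cross, same)
  theta <- ifelse(mono, 0.5, R / n)
  lod <- ifelse(mono | n == 0, 0, g2_stat(c00, c01, c10, c11) / (2 * log(10)))
  phase <- ifelse(mono, NA_character_,
                  ifelse(cross <= same, "coupling", "repulsion"))
  mk <- colnames(gm)
  data.frame(a = mk[idx[, 1L]], b = mk[idx[, 2L]], n = n,
             R = ifelse(mono, NA_integer_, R), theta = theta, lod = lod,
             phase = phase, flag = ifelse(mono, "monomorphic", ""),
             stringsAsFactors = FALSE)
}
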