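#' Construct a genetic map
#'
#' A genetic map is an ordered collection of linkage groups (LGs), each an
#' ordered list of markers with map positions in centiMorgan (cM). Linkage
#' group labels are opaque strings kept in first-appearance order (so
#' chromosome-style namings such as `B01 ... B18` are preserved); within each
#' LG markers are sorted by position and positions are normalised so that the
#' first marker sits at 0 cM.
#'
#' @param markers data frame with columns `marker` (unique id), `lg`
#'   (linkage-group label), `pos` (cM, finite and non-negative) and optional
#'   `mclass` (one of `"SSR"`, `"AFLP"`, `"other"`) and `distortion_p`
#'   (segregation-distortion p-value in `[0, 1]`).
#' @param name map name.
#' @param normalize if `TRUE` (default), shift each LG so its first marker is
#'   at position 0.
#' @return An object of class `genetic_map`: a list with elements `markers`
#'   (the canonicalised data frame) and `name`.
#' @examples
#' gm <- genetic_map(data.frame(marker = c("A", "B"), lg = "LG1", pos = c(5, 15)))
#' lg_lengths(gm)
#' @export
genetic_map <- function(markers, name = "map", normalize = TRUE) {
  stopifnot(is.data.frame(markers))
  req <- c("marker", "lg", "pos")
  miss <- setdiff(req, names(markers))
  if (length(miss)) {
    stop("markers is missing required column(s): ", paste(miss, collapse = ", "))
  }
  markers$marker <- as.character(markers$marker)
  markers$lg <- as.character(markers$lg)
  markers$pos <- as.numeric(markers$pos)
  if (nrow(markers) == 0L) stop("a genetic map needs at least one marker")
  dup <- unique(markers$marker[duplicated(markers$marker)])
  if (length(dup)) {
    stop("duplicate marker id(s): ", paste(dup, collapse = ", "))
  }
  bad <- !is.finite(markers$pos) | markers$pos < 0
  if (any(bad)) {
    stop("non-finite or negative position for marker(s): ",
         paste(markers$marker[bad], collapse = ", "))
  }
  if (!"mclass" %in% names(markers)) markers$mclass <- "other"
  markers$mclass <- as.character(markers$mclass)
  ok_class <- markers$mclass %in% c("SSR", "AFLP", "other")
  if (any(!ok_class)) {
    stop("mclass must be one of SSR/AFLP/other; offending marker(s): ",
         paste(markers$marker[!ok_class], collapse = ", "))
  }
  if (!"distortion_p" %in% names(markers)) markers$distortion_p <- NA_real_
  markers$distortion_p <- as.numeric(markers$distortion_p)
  p <- markers$distortion_p
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("distortion_p must lie in [0, 1]")

  lg_levels <- unique(markers$lg)  # first-appearance order, never lexicographic
  ord <- order(match(markers$lg, lg_levels), markers$pos, markers$marker)
  markers <- markers[ord, c("marker", "lg", "pos", "mclass", "distortion_p")]
  if (normalize) {
    markers$pos <- markers$pos - stats::ave(markers$pos, markers$lg, FUN = min)
  }
  rownames(markers) <- NULL
  structure(list(markers = markers, name = as.character(name)[1]),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  sp <- lg_lengths(x)
  cat(sprintf("Genetic map '%s': %d markers on %d linkage group(s), %.2f cM total span\n",
              x$name, nrow(x$markers), length(sp), sum(sp)))
  invisible(x)
}

#' Linkage-group labels of a map (first-appearance order)
#' @param map a `genetic_map`.
#' @return character vector of LG labels.
#' @export
lg_names <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  unique(map$markers$lg)
}

#' Observed linkage-group lengths
#'
#' Length of each LG as the span between its first and last marker (cM).
#' @param map a `genetic_map`.
#' @return named numeric vector, one entry per LG in map order.
#' @export
lg_lengths <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  sp <- vapply(split(map$markers$pos, map$markers$lg)[lg_names(map)],
               function(p) max(p) - min(p), numeric(1))
  sp
}

# split the marker table by LG, preserving LG order
lg_split <- function(map) {
  split(map$markers, map$markers$lg)[lg_names(map)]
}

#' Plot a genetic map
#'
#' Draws each linkage group as a vertical bar with a tick per marker, the
#' classic linkage-map chart.
#'
#' @param x a `genetic_map`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.genetic_map <- function(x, ...) {
  lgs <- lg_split(x)
  k <- length(lgs)
  ymax <- max(x$markers$pos)
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = c(ymax, 0),
                 xaxt = "n", xlab = "", ylab = "position (cM)",
                 main = x$name, ...)
  graphics::axis(1, at = seq_len(k), labels = names(lgs), las = 2, cex.axis = 0.8)
  for (i in seq_len(k)) {
    p <- lgs[[i]]$pos
    graphics::segments(i, min(p), i, max(p), lwd = 3, col = "grey60")
    graphics::segments(i - 0.15, p, i + 0.15, p)
  }
  invisible(x)
}
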