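#' Partition markers into linkage groups
#'
#' Linkage groups are the connected components of the marker graph whose edges
#' are pairs with an independence LOD at or above the threshold. Group labels
#' are deterministic: groups are ordered by decreasing size, ties broken by
#' their smallest marker id.
#'
#' @param results two-point table from [twopoint_table()] (or a superset of
#'   the threshold graph).
#' @param lod_threshold minimum LOD for an edge (default 5, the standard
#'   grouping threshold for this design).
#' @param markers optional character vector of all marker ids; defaults to the
#'   ids present in `results`. Markers without any qualifying edge form
#'   singleton groups.
#' @return named list of character vectors (`G01`, `G02`, ...), each the
#'   marker set of one group.
#' @export
group_markers <- function(results, lod_threshold = 5, markers = NULL) {
  stopifnot(is.data.frame(results), all(c("a", "b", "lod") %in% names(results)))
  if (is.null(markers)) markers <- sort(unique(c(results$a, results$b)))
  edges <- results[results$lod >= lod_threshold, c("a", "b")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  groups <- split(markers, comp$membership[markers])
  first <- vapply(groups, function(x) min(x), character(1))
  ord <- order(-lengths(groups), first)
  groups <- lapply(groups[ord], function(x) sort(x))
  names(groups) <- sprintf("G%02d", seq_along(groups))
  groups
}

# permutations of 1..n (n small), in lexicographic order
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# LOD-weighted least-squares criterion of an order: coordinates are the
# cumulative Kosambi distances between adjacent markers; the score sums
# lod * (pairwise Kosambi distance - coordinate difference)^2 over usable pairs.
order_score <- function(o, D, W) {
  x <- cumsum(c(0, D[cbind(o[-length(o)], o[-1L])]))
  A <- abs(outer(x, x, "-"))
  sum(W[o, o] * (D[o, o] - A)^2) / 2
}

#' Order the markers of one linkage group
#'
#' Re-implementation of the regression-mapping skeleton used by standard
#' map-construction software: markers are added one at a time in decreasing
#' informativeness, each insertion position minimising a LOD-weighted
#' least-squares criterion of pairwise Kosambi distances against map
#' coordinates; after every insertion a "ripple" tests all permutations of
#' each window of consecutive markers (using up to `ripple_neighbors` flanking
#' markers for scoring) and keeps the best order. Only linkages with
#' `theta < max_theta` and `lod > min_lod` inform the fit. Markers that cannot
#' be placed in one pass are retried in later rounds.
#'
#' Output positions are the cumulative Kosambi distances between adjacent
#' markers; the order is normalised so the lexicographically smaller terminal
#' marker sits at 0 cM. Zero-distance ties are resolved by a tiny jitter so
#' positions are strictly increasing.
#'
#' @param group character vector of marker ids (one group from
#'   [group_markers()]).
#' @param results two-point table covering the group.
#' @param max_theta,min_lod usable-linkage filter (defaults 0.40 and 1.0).
#' @param ripple_window size of the rippled window (default 3, i.e. 3-point
#'   orders).
#' @param ripple_neighbors flanking markers used when scoring a ripple window
#'   (default 10).
#' @param rounds maximum number of insertion passes (default 3).
#' @param tie_jitter distance assigned to zero-recombination adjacencies so
#'   positions stay strictly sorted (default 1e-6 cM).
#' @return object of class `ordered_group`: list with `markers`, `positions`,
#'   `rounds_used`, `unplaced` and the final criterion value `score`.
#' @export
order_markers <- function(group, results, max_theta = 0.40, min_lod = 1.0,
                          ripple_window = 3, ripple_neighbors = 10,
                          rounds = 3, tie_jitter = 1e-6) {
  group <- sort(unique(group))
  m <- length(group)
  og <- function(markers, positions, rounds_used, unplaced = character(0),
                 score = 0) {
    structure(list(markers = markers, positions = positions,
                   rounds_used = rounds_used, unplaced = unplaced,
                   score = score), class = "ordered_group")
  }
  if (m == 1L) return(og(group, 0, 0L))

  rel <- results[results$a %in% group & results$b %in% group, , drop = FALSE]
  theta <- matrix(NA_real_, m, m, dimnames = list(group, group))
  lod <- matrix(0, m, m, dimnames = list(group, group))
  theta[cbind(rel$a, rel$b)] <- rel$theta
  theta[cbind(rel$b, rel$a)] <- rel$theta
  lod[cbind(rel$a, rel$b)] <- rel$lod
  lod[cbind(rel$b, rel$a)] <- rel$lod
  usable <- !is.na(theta) & theta < max_theta & lod > min_lod
  diag(usable) <- FALSE

  # the group must hang together under the linkage filter
  gph <- igraph::graph_from_adjacency_matrix(usable, mode = "undirected")
  comp <- igraph::components(gph)
  if (comp$no > 1L) {
    frags <- split(group, comp$membership)
    stop("group disconnected under the linkage filter (theta < ", max_theta,
         ", lod > ", min_lod, "); fragments: ",
         paste(vapply(frags, paste, character(1), collapse = ","),
               collapse = " | "))
  }

  D <- kosambi_cm(pmin(ifelse(is.na(theta), 0.4999, theta), 0.4999))
  diag(D) <- 0
  W <- lod * usable

  if (m == 2L) {
    return(og(group, c(0, max(D[1, 2], tie_jitter)), 1L))
  }

  # seed with the strongest usable linkage
  wl <- W; wl[lower.tri(wl, diag = TRUE)] <- -Inf
  seed <- which(wl == max(wl), arr.ind = TRUE)
  seed <- seed[order(seed[, 1L], seed[, 2L]), , drop = FALSE][1L, ]
  ord <- as.integer(seed)

  n_usable <- colSums(usable)
  sum_lod <- colSums(W)
  queue <- setdiff(seq_len(m), ord)
  queue <- queue[order(-n_usable[queue], -sum_lod[queue], group[queue])]

  pset <- perms(ripple_window)
  ripple <- function(o) {
    k <- length(o)
    w <- ripple_window
    if (k <= w) {
      cand <- lapply(perms(k), function(p) o[p])
      sc <- vapply(cand, order_score, numeric(1), D = D, W = W)
      return(cand[[which.min(sc)]])
    }
    for (t in seq_len(k - w + 1L)) {
      lo <- max(1L, t - ripple_neighbors)
      hi <- min(k, t + w - 1L + ripple_neighbors)
      sub <- o[lo:hi]
      off <- t - lo
      best <- order_score(sub, D, W)
      best_p <- NULL
      for (p in pset[-1L]) {
        cand <- sub
        cand[off + seq_len(w)] <- sub[off + p]
        sc <- order_score(cand, D, W)
        if (sc < best - 1e-9) { best <- sc; best_p <- p }
      }
      if (!is.null(best_p)) o[t:(t + w - 1L)] <- o[(t - 1L) + best_p]
    }
    o
  }

  rounds_used <- 0L
  for (r in seq_len(rounds)) {
    if (!length(queue)) break
    rounds_used <- r
    deferred <- integer(0)
    progressed <- FALSE
    for (mk in queue) {
      if (!any(usable[mk, ord])) { deferred <- c(deferred, mk); next }
      cands <- lapply(0:length(ord), function(g) append(ord, mk, after = g))
      sc <- vapply(cands, order_score, numeric(1), D = D, W = W)
      ord <- cands[[which.min(sc)]]
      ord <- ripple(ord)
      progressed <- TRUE
    }
    queue <- deferred
    if (!progressed) break
  }

  unplaced <- group[queue]
  if (length(unplaced)) {
    warning("marker(s) not placeable within ", rounds, " round(s): ",
            paste(unplaced, collapse = ", "))
  }

  # orientation: lexicographically smaller terminal marker at 0
  if (group[ord[length(ord)]] < group[ord[1L]]) ord <- rev(ord)
  dadj <- D[cbind(ord[-length(ord)], ord[-1L])]
  dadj <- pmax(dadj, tie_jitter)
  og(group[ord], cumsum(c(0, dadj)), rounds_used, unplaced,
     order_score(ord, D, W))
}

#' @export
print.ordered_group <- function(x, ...) {
  cat(sprintf("Ordered group: %d markers, %.2f cM, %d round(s)\n",
              length(x$markers), max(x$positions), x$rounds_used))
  invisible(x)
}

# count phase-inconsistent adjacent triples along an ordered LG
phase_conflicts <- function(markers, results) {
  if (length(markers) < 3L) return(0L)
  ph <- matrix(NA_character_, length(markers), length(markers),
               dimnames = list(markers, markers))
  rel <- results[results$a %in% markers & results$b %in% markers, , drop = FALSE]
  ph[cbind(rel$a, rel$b)] <- rel$phase
  ph[cbind(rel$b, rel$a)] <- rel$phase
  s <- function(x) ifelse(is.na(x), NA, ifelse(x == "coupling", 1, -1))
  n <- 0L
  for (i in seq_len(length(markers) - 2L)) {
    a <- markers[i]; b <- markers[i + 1L]; c <- markers[i + 2L]
    sab <- s(ph[a, b]); sbc <- s(ph[b, c]); sac <- s(ph[a, c])
    if (!anyNA(c(sab, sbc, sac)) && sab * sbc != sac) n <- n + 1L
  }
  n
}

#' Build a genetic map from a haploid genotype matrix
#'
#' The full map-construction fit: per-marker segregation-distortion tests
#' (distorted markers are annotated, never excluded), an all-pairs two-point
#' linkage table, linkage-group detection at the grouping LOD, and per-group
#' marker ordering with the ripple procedure ([order_markers()]). A phase
#' consistency pass over adjacent marker triples counts conflicting phase
#' assignments; conflicts are reported as a warning count on the object.
#'
#' @param gm integer genotype matrix (individuals x markers, calls 0/1/NA).
#' @param lod_group grouping LOD threshold (default 5).
#' @param max_theta,min_lod,ripple_window,ripple_neighbors,rounds ordering
#'   parameters, see [order_markers()].
#' @param name map name.
#' @return object of class `c("linkage_map", "genetic_map")`; additionally
#'   carries `segregation` (per-marker chi2/p/stars), `twopoint` (the pair
#'   table), `groups`, `params` and `phase_conflicts`.
#' @seealso [summarize_map()] for Table-style statistics on the result.
#' @export
build_map <- function(gm, lod_group = 5, max_theta = 0.40, min_lod = 1.0,
                      ripple_window = 3, ripple_neighbors = 10, rounds = 3,
                      name = "linkage map") {
  if (!is.matrix(gm) || nrow(gm) == 0L || ncol(gm) == 0L) {
    stop("genotype matrix is empty")
  }
  seg <- data.frame(marker = colnames(gm),
                    n0 = colSums(gm == 0, na.rm = TRUE),
                    n1 = colSums(gm == 1, na.rm = TRUE),
                    stringsAsFactors = FALSE, row.names = NULL)
  st <- mapply(function(a, b) segregation_test(a, b), seg$n0, seg$n1,
               SIMPLIFY = FALSE)
  seg$chi2 <- vapply(st, `[[`, numeric(1), "chi2")
  seg$p <- vapply(st, `[[`, numeric(1), "p")
  seg$stars <- vapply(st, `[[`, character(1), "stars")

  tp <- twopoint_table(gm)
  groups <- group_markers(tp, lod_threshold = lod_group,
                          markers = colnames(gm))
  ordered <- lapply(groups, order_markers, results = tp,
                    max_theta = max_theta, min_lod = min_lod,
                    ripple_window = ripple_window,
                    ripple_neighbors = ripple_neighbors, rounds = rounds)

  dfs <- mapply(function(o, i) {
    data.frame(marker = o$markers, lg = sprintf("LG%02d", i),
               pos = o$positions, stringsAsFactors = FALSE)
  }, ordered, seq_along(ordered), SIMPLIFY = FALSE)
  df <- do.call(rbind, dfs)
  df$distortion_p <- seg$p[match(df$marker, seg$marker)]
  map <- genetic_map(df, name = name)
  map$segregation <- seg
  map$twopoint <- tp
  map$groups <- groups
  map$params <- list(lod_group = lod_group, max_theta = max_theta,
                     min_lod = min_lod, ripple_window = ripple_window,
                     ripple_neighbors = ripple_neighbors, rounds = rounds)
  map$phase_conflicts <- sum(vapply(ordered, function(o) {
    phase_conflicts(o$markers, tp)
  }, integer(1)))
  map$unplaced <- unlist(lapply(ordered, `[[`, "unplaced"), use.names = FALSE)
  class(map) <- c("linkage_map", "genetic_map")
  map
}

#' @export
print.linkage_map <- function(x, ...) {
  NextMethod()
  nd <- sum(x$segregation$p < 0.05, na.rm = TRUE)
  cat(sprintf("  %d individual(s); %d distorted marker(s) at p < 0.05; %d phase conflict(s)\n",
              max(x$twopoint$n), nd, x$phase_conflicts))
  invisible(x)
}

#' @export
summary.linkage_map <- function(object, distortion_alpha = 0.05, ...) {
  summarize_map(object, distortion_alpha = distortion_alpha)
}
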