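# Independent oracles and small fixture builders used across the suite.

# all permutations of 1..n (tiny n), independent of the package internals
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_perms(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

# brute-force marker ordering: minimise the sum of adjacent Kosambi distances
# over every possible order
brute_force_order <- function(markers, theta_mat) {
  n <- length(markers)
  D <- kosambi_cm(pmin(theta_mat, 0.4999))
  best <- NULL; best_s <- Inf
  for (p in all_perms(n)) {
    s <- sum(D[cbind(p[-n], p[-1L])])
    if (s < best_s - 1e-12) { best_s <- s; best <- p }
  }
  markers[best]
}

# adjacency-enumeration synteny oracle: a query-adjacent pair is syntenic iff
# it also appears in the set of target-adjacent pairs (order-insensitive)
oracle_synteny <- function(query_order, target_pos) {
  t_order <- names(sort(target_pos))
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  t_adj <- vapply(seq_len(length(t_order) - 1L), function(i) {
    pair_key(t_order[i], t_order[i + 1L])
  }, character(1))
  vapply(seq_len(length(query_order) - 1L), function(i) {
    pair_key(query_order[i], query_order[i + 1L]) %in% t_adj
  }, logical(1))
}

# haploid genotype matrix realising the four 2x2 haplotype counts
geno_from_counts <- function(n00, n01, n10, n11, markers = c("A", "B")) {
  g <- rbind(
    matrix(rep(c(0L, 0L), n00), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), n01), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 0L), n10), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 1L), n11), ncol = 2, byrow = TRUE)
  )
  colnames(g) <- markers
  rownames(g) <- sprintf("I%03d", seq_len(nrow(g)))
  g
}

# G2-based independence LOD computed the long way (loop over cells)
oracle_lod <- function(n00, n01, n10, n11) {
  o <- c(n00, n01, n10, n11)
  n <- sum(o)
  r <- c(n00 + n01, n00 + n01, n10 + n11, n10 + n11)
  cc <- c(n00 + n10, n01 + n11, n00 + n10, n01 + n11)
  g2 <- 0
  for (i in 1:4) if (o[i] > 0) g2 <- g2 + 2 * o[i] * log(o[i] / (r[i] * cc[i] / n))
  g2 / (2 * log(10))
}

# toy one-LG comparison fixture: query markers m1..mk at 0,10,20,... whose
# hits point to the given target LGs at the given target positions
toy_comparison <- function(target_lgs, target_pos, min_markers = 3) {
  k <- length(target_lgs)
  ids <- sprintf("m%02d", seq_len(k))
  map <- genetic_map(data.frame(marker = ids, lg = "Q1",
                                pos = 10 * (seq_len(k) - 1L)))
  hits <- data.frame(marker_id = ids, target_lg = target_lgs,
                     target_pos = target_pos, align_len = 100, score = 100,
                     identity = 90, annotation = NA_character_,
                     stringsAsFactors = FALSE)
  ct <- build_contingency(map, hits)
  asg <- match_lgs(ct, min_markers = min_markers)
  red <- reduce_to_homologs(map, hits, asg)
  list(map = map, hits = hits, ct = ct, asg = asg, red = red)
}

# per-LG marker-set partition of a map, as a canonical sorted list
map_partition <- function(map) {
  p <- lapply(split(map$markers$marker, map$markers$lg), sort)
  unname(p[order(vapply(p, `[`, character(1), 1L))])
}
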