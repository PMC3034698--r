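#' Filter homology hits on alignment quality
#'
#' Default rule: keep a hit iff its homologous alignment is longer than
#' `min_len` bp AND it clears either the score or the identity threshold
#' (all thresholds strict `>`). The alternative `"any"` rule keeps a hit that
#' clears any one of the three thresholds (pure-OR, for sensitivity
#' analysis).
#'
#' @param hits hit data frame ([read_homology_hits()] layout).
#' @param min_len minimum alignment length, bp (default 30).
#' @param min_score minimum alignment score (default 45).
#' @param min_identity minimum percent identity (default 67).
#' @param rule `"len_and_quality"` (default) or `"any"`.
#' @return the filtered hit data frame.
#' @export
filter_hits <- function(hits, min_len = 30, min_score = 45, min_identity = 67,
                        rule = c("len_and_quality", "any")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
    len_and_quality = hits$align_len > min_len &
      (hits$score > min_score | hits$identity > min_identity),
    any = hits$align_len > min_len | hits$score > min_score |
      hits$identity > min_identity)
  hits[keep, , drop = FALSE]
}

#' Query-LG by target-LG contingency table
#'
#' Counts of mapped homologous markers by (query LG, target LG), with an
#' `"Un"` column for hits to unassigned target sequences. Hits whose marker is
#' not on the query map are excluded with a warning (count kept in the
#' `n_excluded` attribute).
#'
#' @param map query `genetic_map`.
#' @param hits filtered hit data frame.
#' @return matrix of class `lg_contingency` (rows: query LGs in map order;
#'   columns: sorted target LGs then `"Un"`), with attributes `n_excluded`
#'   and `grand_total`.
#' @export
build_contingency <- function(map, hits) {
  stopifnot(inherits(map, "genetic_map"))
  on_map <- hits$marker_id %in% map$markers$marker
  if (any(!on_map)) {
    warning(sum(!on_map), " hit(s) reference unmapped markers and were excluded")
  }
  h <- hits[on_map, , drop = FALSE]
  qlg <- map$markers$lg[match(h$marker_id, map$markers$marker)]
  tlevels <- sort(setdiff(unique(h$target_lg), "Un"))
  tlevels <- c(tlevels, "Un")
  ct <- table(factor(qlg, levels = lg_names(map)),
              factor(h$target_lg, levels = tlevels))
  ct <- unclass(ct)
  dimnames(ct) <- list(lg_names(map), tlevels)
  structure(ct, class = c("lg_contingency", "matrix"),
            n_excluded = sum(!on_map), grand_total = sum(ct))
}

#' @export
print.lg_contingency <- function(x, ...) {
  cat("Query-LG x target-LG homolog counts (grand total ",
      attr(x, "grand_total"), ")\n", sep = "")
  print(matrix(x, nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Match query linkage groups to target linkage groups
#'
#' A target LG is an assigned segment of a query LG when at least
#' `min_markers` of the query LG's homologs map to it (the `"Un"` column
#' never counts). A query LG with one segment is `matched`, with two or more
#' `composite`, with none `unmatched`. Composites with more than two segments
#' are flagged in the `note` column.
#'
#' @param ct an [build_contingency()] result.
#' @param min_markers minimum supporting homolog count per segment
#'   (default 3).
#' @return data frame with one row per query LG: `query_lg`, `segments`
#'   (list column of target-LG labels), `n_segments`, `status`, `note`.
#' @export
match_lgs <- function(ct, min_markers = 3) {
  stopifnot(inherits(ct, "lg_contingency"))
  tcols <- setdiff(colnames(ct), "Un")
  rows <- lapply(rownames(ct), function(q) {
    segs <- tcols[ct[q, tcols] >= min_markers]
    data.frame(query_lg = q, segments = I(list(segs)),
               n_segments = length(segs),
               status = if (length(segs) == 0L) "unmatched"
                        else if (length(segs) == 1L) "matched" else "composite",
               note = if (length(segs) > 2L) "more than two segments" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Restrict both maps to the shared homologous markers
#'
#' Builds the homolog-only pair of maps the comparative stage runs on: the
#' query map restricted to markers with a kept, assigned hit (hits to `"Un"`
#' are dropped here — they stay in the contingency but carry no position), and
#' a target pseudo-map of the same markers at their target coordinates,
#' grouped by target LG.
#'
#' @param map query `genetic_map`.
#' @param hits filtered hit data frame.
#' @param assignment a [match_lgs()] result (carried through for downstream
#'   steps).
#' @return list of class `reduced_pair`: `query` and `target` (both
#'   `genetic_map`s, positions kept un-normalised so spans match the full
#'   map), `hits`, `assignments`.
#' @export
reduce_to_homologs <- function(map, hits, assignment) {
  stopifnot(inherits(map, "genetic_map"))
  h <- hits[hits$marker_id %in% map$markers$marker & hits$target_lg != "Un", ,
            drop = FALSE]
  mk <- map$markers[map$markers$marker %in% h$marker_id, , drop = FALSE]
  i <- match(mk$marker, h$marker_id)
  query <- structure(list(markers = mk, name = paste0(map$name, " (homologs)")),
                     class = "genetic_map")
  tdf <- data.frame(marker = mk$marker, lg = h$target_lg[i],
                    pos = h$target_pos[i], mclass = mk$mclass,
                    distortion_p = NA_real_, stringsAsFactors = FALSE)
  tdf <- tdf[order(tdf$lg, tdf$pos, tdf$marker), , drop = FALSE]
  rownames(tdf) <- NULL
  target <- structure(list(markers = tdf, name = "target (homologs)"),
                      class = "genetic_map")
  structure(list(query = query, target = target,
                 hits = h[i, , drop = FALSE], assignments = assignment),
            class = "reduced_pair")
}

# per query LG: reduced markers in query order with their target location
reduced_lg_frames <- function(reduced) {
  q <- reduced$query$markers
  i <- match(q$marker, reduced$hits$marker_id)
  q$target_lg <- reduced$hits$target_lg[i]
  q$target_pos <- reduced$hits$target_pos[i]
  split(q, q$lg)[lg_names(reduced$query)]
}

segments_of <- function(assignments, qlg) {
  i <- match(qlg, assignments$query_lg)
  if (is.na(i)) character(0) else assignments$segments[[i]]
}

#' Detect single- and double-marker insertions
#'
#' On each homolog-reduced query LG with at least one assigned segment, an
#' insertion event is a maximal run of at most `max_run` consecutive markers
#' whose target LG is not among the LG's assigned segments, flanked on both
#' sides by markers of an assigned segment. Longer or terminal (unflanked)
#' foreign runs are kept in the output with `classified = FALSE`.
#'
#' @param reduced a [reduce_to_homologs()] result.
#' @param assignments a [match_lgs()] result.
#' @param max_run maximum insertion size in markers (default 2).
#' @return data frame of foreign runs: `query_lg`, `start_index`,
#'   `n_markers`, `markers`, `target_lgs`, `flanked`, `classified`.
#' @export
classify_insertions <- function(reduced, assignments, max_run = 2) {
  frames <- reduced_lg_frames(reduced)
  out <- list()
  for (qlg in names(frames)) {
    segs <- segments_of(assignments, qlg)
    if (!length(segs)) next
    d <- frames[[qlg]]
    foreign <- !(d$target_lg %in% segs)
    if (!any(foreign)) next
    r <- rle(foreign)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]
      flanked <- s > 1L && e < nrow(d)
      out[[length(out) + 1L]] <- data.frame(
        query_lg = qlg, start_index = s, n_markers = e - s + 1L,
        markers = paste(d$marker[s:e], collapse = ","),
        target_lgs = paste(unique(d$target_lg[s:e]), collapse = ","),
        flanked = flanked,
        classified = flanked && (e - s + 1L) <= max_run,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(query_lg = character(0), start_index = integer(0),
                      n_markers = integer(0), markers = character(0),
                      target_lgs = character(0), flanked = logical(0),
                      classified = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify adjacent homolog pairs as syntenic or rearranged
#'
#' Classified insertion markers are pruned first, so a lone foreign marker
#' does not break an otherwise conserved neighbourhood. Then, for every pair
#' of markers adjacent on the pruned query LG whose hits lie on one assigned
#' target LG, the pair is \emph{syntenic} iff the two markers are also
#' adjacent among that target LG's shared homologous markers (adjacency is
#' orientation-insensitive per pair, so fully inverted segments stay
#' syntenic), and \emph{rearranged} otherwise. Pairs whose members lie on two
#' different assigned segments are labelled `insertion_flank` when their query
#' interval spans a pruned insertion and `unclassified` otherwise; pairs
#' touching unclassified foreign markers are `unclassified`. Syntenic runs are
#' maximal chains of syntenic pairs with consistent orientation.
#'
#' @param reduced a [reduce_to_homologs()] result.
#' @param assignments a [match_lgs()] result.
#' @param insertions a [classify_insertions()] result; computed with
#'   `max_run` if omitted.
#' @param max_run passed to [classify_insertions()] when `insertions` is
#'   missing.
#' @return list with `intervals` (one row per adjacent pair: `query_lg`,
#'   `marker_a`, `marker_b`, `span_q`, `span_t`, `target_lg`, `klass`,
#'   `orientation`, `spans_insertion`) and `runs` (maximal syntenic chains:
#'   `query_lg`, `target_lg`, `n_pairs`, `n_markers`, `markers`,
#'   `orientation`).
#' @export
detect_synteny <- function(reduced, assignments, insertions = NULL,
                           max_run = 2) {
  if (is.null(insertions)) {
    insertions <- classify_insertions(reduced, assignments, max_run = max_run)
  }
  frames <- reduced_lg_frames(reduced)
  # target adjacency: order of shared markers within each target LG
  tsp <- split(reduced$target$markers, reduced$target$markers$lg)
  trank <- lapply(tsp, function(d) {
    stats::setNames(seq_len(nrow(d)), d$marker)
  })
  pruned_markers <- unlist(strsplit(
    insertions$markers[insertions$classified], ",", fixed = TRUE),
    use.names = FALSE)

  iv <- list(); runs <- list()
  for (qlg in names(frames)) {
    segs <- segments_of(assignments, qlg)
    if (!length(segs)) next
    d <- frames[[qlg]]
    pruned_here <- d$marker %in% pruned_markers
    dd <- d[!pruned_here, , drop = FALSE]
    if (nrow(dd) < 2L) next
    gap_has_insertion <- logical(nrow(dd) - 1L)
    # a gap spans an insertion iff a pruned marker sat between the two in d
    pos_in_d <- match(dd$marker, d$marker)
    gap_has_insertion <- (pos_in_d[-1L] - pos_in_d[-nrow(dd)]) > 1L

    for (i in seq_len(nrow(dd) - 1L)) {
      a <- dd[i, ]; b <- dd[i + 1L, ]
      span_q <- b$pos - a$pos
      same_lg <- a$target_lg == b$target_lg
      both_assigned <- a$target_lg %in% segs && b$target_lg %in% segs
      if (same_lg && both_assigned) {
        rk <- trank[[a$target_lg]]
        adj <- abs(rk[[a$marker]] - rk[[b$marker]]) == 1L
        klass <- if (adj) "syntenic" else "rearranged"
        span_t <- abs(b$target_pos - a$target_pos)
        orient <- sign(b$target_pos - a$target_pos)
        tlg <- a$target_lg
      } else if (both_assigned) {
        klass <- if (gap_has_insertion[i]) "insertion_flank" else "unclassified"
        span_t <- NA_real_; orient <- NA_real_; tlg <- NA_character_
      } else {
        klass <- "unclassified"
        span_t <- NA_real_; orient <- NA_real_; tlg <- NA_character_
      }
      iv[[length(iv) + 1L]] <- data.frame(
        query_lg = qlg, marker_a = a$marker, marker_b = b$marker,
        span_q = span_q, span_t = span_t, target_lg = tlg, klass = klass,
        orientation = orient, spans_insertion = gap_has_insertion[i],
        stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(iv)) do.call(rbind, iv) else {
    data.frame(query_lg = character(0), marker_a = character(0),
               marker_b = character(0), span_q = numeric(0),
               span_t = numeric(0), target_lg = character(0),
               klass = character(0), orientation = numeric(0),
               spans_insertion = logical(0), stringsAsFactors = FALSE)
  }

  # chain syntenic pairs into runs of consistent orientation
  for (qlg in unique(intervals$query_lg)) {
    sub <- intervals[intervals$query_lg == qlg, , drop = FALSE]
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      data.frame(query_lg = qlg, target_lg = cur$tlg, n_pairs = cur$n,
                 n_markers = cur$n + 1L,
                 markers = paste(cur$markers, collapse = ","),
                 orientation = cur$orient, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      if (row$klass != "syntenic") {
        runs[[length(runs) + 1L]] <- flush(cur); cur <- NULL; next
      }
      extends <- !is.null(cur) && cur$last == row$marker_a &&
        cur$tlg == row$target_lg &&
        (cur$orient == 0 || row$orientation == 0 ||
           cur$orient == row$orientation)
      if (extends) {
        cur$n <- cur$n + 1L
        cur$last <- row$marker_b
        cur$markers <- c(cur$markers, row$marker_b)
        if (cur$orient == 0) cur$orient <- row$orientation
      } else {
        runs[[length(runs) + 1L]] <- flush(cur)
        cur <- list(n = 1L, last = row$marker_b, tlg = row$target_lg,
                    orient = row$orientation,
                    markers = c(row$marker_a, row$marker_b))
      }
    }
    runs[[length(runs) + 1L]] <- flush(cur)
  }
  runs <- runs[!vapply(runs, is.null, logical(1))]
  runs <- if (length(runs)) do.call(rbind, runs) else {
    data.frame(query_lg = character(0), target_lg = character(0),
               n_pairs = integer(0), n_markers = integer(0),
               markers = character(0), orientation = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(intervals = intervals, runs = runs)
}

#' Per-LG and genome-wide comparison summary
#'
#' Aggregates interval classes into the standard comparison table: per query
#' LG the syntenic pair count, syntenic spans on both maps and their ratio,
#' the rearranged-block count and span, insertion count, and the synteny /
#' rearranged / conserved percentages. Percentages use the \emph{corrected} LG
#' lengths as denominators; `conserved_pct = synteny_pct + rearranged_pct`.
#' Genome-wide totals sum over all LGs; the genome-wide percentages are
#' unweighted means over the LGs having at least one homologous marker pair,
#' and the genome-wide span ratio is the ratio of the summed spans.
#'
#' Pairs labelled `insertion_flank` (same composite LG, interval bridging a
#' pruned insertion) are counted with the rearranged spans: their markers are
#' on matched chromosomes but not in conserved order.
#'
#' @param classes a [detect_synteny()] result (list with `intervals`).
#' @param insertions a [classify_insertions()] result.
#' @param map_summary the query map's [summarize_map()] result.
#' @return object of class `comparison_summary`: `per_lg` data frame plus a
#'   `totals` list.
#' @export
summarize_comparison <- function(classes, insertions, map_summary) {
  stopifnot(inherits(map_summary, "map_summary"))
  intervals <- classes$intervals
  per <- map_summary$per_lg
  rows <- lapply(seq_len(nrow(per)), function(i) {
    qlg <- per$lg[i]
    corr <- per$corrected_length_cm[i]
    sub <- intervals[intervals$query_lg == qlg, , drop = FALSE]
    syn <- sub[sub$klass == "syntenic", , drop = FALSE]
    rea <- sub$klass %in% c("rearranged", "insertion_flank")
    blocks <- if (nrow(sub)) {
      r <- rle(rea); sum(r$values)
    } else 0L
    syn_q <- sum(syn$span_q)
    syn_t <- sum(syn$span_t)
    rea_q <- sum(sub$span_q[rea])
    ins <- insertions[insertions$query_lg == qlg & insertions$classified, ,
                      drop = FALSE]
    syn_pct <- if (corr > 0) 100 * syn_q / corr else 0
    rea_pct <- if (corr > 0) 100 * rea_q / corr else 0
    data.frame(lg = qlg, n_syntenic_pairs = nrow(syn),
               synteny_q_cm = syn_q, synteny_t_cm = syn_t,
               ratio_qt = if (syn_t > 0) syn_q / syn_t else NA_real_,
               synteny_pct = syn_pct,
               n_rearranged_blocks = blocks, rearranged_q_cm = rea_q,
               rearranged_pct = rea_pct,
               n_insertions = nrow(ins),
               conserved_pct = syn_pct + rea_pct,
               has_homolog_pair = nrow(syn) > 0 || any(rea),
               stringsAsFactors = FALSE)
  })
  per_lg <- do.call(rbind, rows)
  hom <- per_lg$has_homolog_pair
  totals <- list(
    n_syntenic_pairs = sum(per_lg$n_syntenic_pairs),
    synteny_q_cm = sum(per_lg$synteny_q_cm),
    synteny_t_cm = sum(per_lg$synteny_t_cm),
    ratio_qt = if (sum(per_lg$synteny_t_cm) > 0) {
      sum(per_lg$synteny_q_cm) / sum(per_lg$synteny_t_cm)
    } else NA_real_,
    mean_synteny_pct = mean(per_lg$synteny_pct[hom]),
    n_rearranged_blocks = sum(per_lg$n_rearranged_blocks),
    rearranged_q_cm = sum(per_lg$rearranged_q_cm),
    mean_rearranged_pct = mean(per_lg$rearranged_pct[hom]),
    n_insertions = sum(per_lg$n_insertions),
    mean_conserved_pct = mean(per_lg$conserved_pct[hom]),
    genome_synteny_pct = 100 * sum(per_lg$synteny_q_cm) /
      map_summary$total_corrected_cm,
    genome_rearranged_pct = 100 * sum(per_lg$rearranged_q_cm) /
      map_summary$total_corrected_cm,
    genome_conserved_pct = 100 *
      (sum(per_lg$synteny_q_cm) + sum(per_lg$rearranged_q_cm)) /
      map_summary$total_corrected_cm,
    n_lgs_with_homolog_pairs = sum(hom)
  )
  structure(list(per_lg = per_lg, totals = totals),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  df <- x$per_lg
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(df[, setdiff(names(df), "has_homolog_pair")], row.names = FALSE)
  t <- x$totals
  cat(sprintf("Totals: %d syntenic pairs (%.2f q-cM, %.2f t-cM), %d rearranged blocks (%.2f cM), %d insertions\n",
              t$n_syntenic_pairs, t$synteny_q_cm, t$synteny_t_cm,
              t$n_rearranged_blocks, t$rearranged_q_cm, t$n_insertions))
  cat(sprintf("Genome: %.2f%% syntenic, %.2f%% rearranged, %.2f%% conserved; per-LG means %.2f / %.2f / %.2f%%\n",
              t$genome_synteny_pct, t$genome_rearranged_pct,
              t$genome_conserved_pct, t$mean_synteny_pct,
              t$mean_rearranged_pct, t$mean_conserved_pct))
  invisible(x)
}

#' @export
as.data.frame.comparison_summary <- function(x, ...) {
  df <- x$per_lg[, setdiff(names(x$per_lg), "has_homolog_pair")]
  t <- x$totals
  tot <- data.frame(lg = "SUM/MEAN", n_syntenic_pairs = t$n_syntenic_pairs,
                    synteny_q_cm = t$synteny_q_cm,
                    synteny_t_cm = t$synteny_t_cm, ratio_qt = t$ratio_qt,
                    synteny_pct = t$mean_synteny_pct,
                    n_rearranged_blocks = t$n_rearranged_blocks,
                    rearranged_q_cm = t$rearranged_q_cm,
                    rearranged_pct = t$mean_rearranged_pct,
                    n_insertions = t$n_insertions,
                    conserved_pct = t$mean_conserved_pct,
                    stringsAsFactors = FALSE)
  rbind(df, tot)
}

#' Compare a query map against a target genome through homology hits
#'
#' The full comparative fit: hit filtering, the LG contingency table, LG
#' matching (composites included), reduction to the shared homologs, insertion
#' detection, synteny/rearrangement classification and the summary table.
#'
#' @param map_q query `genetic_map`.
#' @param hits raw hit data frame.
#' @param min_len,min_score,min_identity,filter_rule see [filter_hits()].
#' @param min_markers see [match_lgs()].
#' @param max_run see [classify_insertions()].
#' @return object of class `map_comparison`: list with `contingency`,
#'   `assignments`, `reduced`, `insertions`, `intervals`, `runs`, `summary`,
#'   `params`.
#' @export
compare_maps <- function(map_q, hits, min_len = 30, min_score = 45,
                         min_identity = 67, filter_rule = "len_and_quality",
                         min_markers = 3, max_run = 2) {
  fh <- filter_hits(hits, min_len = min_len, min_score = min_score,
                    min_identity = min_identity, rule = filter_rule)
  ct <- build_contingency(map_q, fh)
  asg <- match_lgs(ct, min_markers = min_markers)
  red <- reduce_to_homologs(map_q, fh, asg)
  ins <- classify_insertions(red, asg, max_run = max_run)
  cls <- detect_synteny(red, asg, insertions = ins)
  summ <- summarize_comparison(cls, ins, summarize_map(map_q))
  structure(list(contingency = ct, assignments = asg, reduced = red,
                 insertions = ins, intervals = cls$intervals,
                 runs = cls$runs, summary = summ,
                 params = list(min_len = min_len, min_score = min_score,
                               min_identity = min_identity,
                               filter_rule = filter_rule,
                               min_markers = min_markers, max_run = max_run)),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  st <- table(factor(x$assignments$status,
                     levels = c("matched", "composite", "unmatched")))
  cat(sprintf("Map comparison: %d kept hits, %d query LGs (%d matched, %d composite, %d unmatched)\n",
              attr(x$contingency, "grand_total"), nrow(x$assignments),
              st[["matched"]] + st[["composite"]], st[["composite"]],
              st[["unmatched"]]))
  t <- x$summary$totals
  cat(sprintf("  %d syntenic pairs, %d rearranged blocks, %d insertions; %.2f%% of the map conserved\n",
              t$n_syntenic_pairs, t$n_rearranged_blocks, t$n_insertions,
              t$genome_conserved_pct))
  invisible(x)
}

#' @export
summary.map_comparison <- function(object, ...) object$summary
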