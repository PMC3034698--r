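#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study system the package was validated on: a haploid-male mapping
#' population descending from a single phase-known queen, an 18-chromosome
#' genome of roughly 29 markers and 106 cM per chromosome, about half the
#' markers with a recoverable homolog in the target genome, and a handful of
#' inversions, reciprocal translocations and small transpositions separating
#' the two descendant genomes. A seed is mandatory: every piece of randomness
#' in the generator flows from it.
#'
#' @param seed integer seed (mandatory).
#' @param n_lg number of linkage groups (default 18).
#' @param markers_per_lg markers per ancestral LG (default 29).
#' @param lg_length_cm ancestral LG length in cM (default 106).
#' @param n_inversions,n_translocations,n_transpositions rearrangement event
#'   counts applied to the query lineage (defaults 12, 5, 21; transpositions
#'   move 1-2 consecutive markers into another LG).
#' @param homolog_fraction fraction of query markers with a homology hit
#'   (default 0.47).
#' @param spurious_hit_rate fraction of hits pointing to a random wrong
#'   location (default 0.05).
#' @param un_fraction fraction of hits to unassigned (`"Un"`) target
#'   sequences (default 0.06).
#' @param fail_filter_rate fraction of hits drawn with alignment-quality
#'   fields below the filtering thresholds (default 0.05).
#' @param n_individuals haploid progeny count (default 384).
#' @param genotyping_error_rate per-call allele-flip probability
#'   (default 0.005).
#' @param missing_rate per-call missingness probability (default 0.1).
#' @param distortion_markers named numeric vector: marker id -> transmission
#'   probability of allele 1 (default none; 0.5 is Mendelian).
#' @param crossover_model `"poisson"` (no interference, Haldane-consistent)
#'   or `"gamma"` (positive interference, stationary gamma renewal).
#' @param gamma_nu gamma shape for `crossover_model = "gamma"` (default 4).
#' @param symmetric_events if `TRUE`, rearrangements are split between the
#'   two lineages instead of all applied to the query (default `FALSE`, so
#'   the target map is the ancestral order and truth is simplest).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed, n_lg = 18, markers_per_lg = 29,
                       lg_length_cm = 106, n_inversions = 12,
                       n_translocations = 5, n_transpositions = 21,
                       homolog_fraction = 0.47, spurious_hit_rate = 0.05,
                       un_fraction = 0.06, fail_filter_rate = 0.05,
                       n_individuals = 384, genotyping_error_rate = 0.005,
                       missing_rate = 0.1, distortion_markers = NULL,
                       crossover_model = c("poisson", "gamma"), gamma_nu = 4,
                       symmetric_events = FALSE) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory; no unseeded randomness is allowed")
  }
  crossover_model <- match.arg(crossover_model)
  rates <- c(homolog_fraction, spurious_hit_rate, un_fraction,
             fail_filter_rate, genotyping_error_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (!is.null(distortion_markers)) {
    if (is.null(names(distortion_markers)) ||
        any(distortion_markers < 0 | distortion_markers > 1)) {
      stop("distortion_markers must be a named vector of probabilities")
    }
  }
  stopifnot(n_lg >= 1, markers_per_lg >= 2, lg_length_cm > 0,
            n_individuals >= 1, gamma_nu > 0)
  structure(list(seed = as.integer(seed), n_lg = as.integer(n_lg),
                 markers_per_lg = as.integer(markers_per_lg),
                 lg_length_cm = lg_length_cm,
                 n_inversions = as.integer(n_inversions),
                 n_translocations = as.integer(n_translocations),
                 n_transpositions = as.integer(n_transpositions),
                 homolog_fraction = homolog_fraction,
                 spurious_hit_rate = spurious_hit_rate,
                 un_fraction = un_fraction,
                 fail_filter_rate = fail_filter_rate,
                 n_individuals = as.integer(n_individuals),
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate,
                 distortion_markers = distortion_markers,
                 crossover_model = crossover_model, gamma_nu = gamma_nu,
                 symmetric_events = symmetric_events),
            class = "sim_config")
}

# apply one rearrangement event to a list of per-LG marker-id vectors
apply_event <- function(orders, ev) {
  if (ev$type == "inversion") {
    o <- orders[[ev$lg]]
    seg <- ev$start:(ev$start + ev$len - 1L)
    o[seg] <- rev(o[seg])
    orders[[ev$lg]] <- o
  } else if (ev$type == "translocation") {
    a <- orders[[ev$lg_a]]; b <- orders[[ev$lg_b]]
    tail_a <- a[(ev$cut_a + 1L):length(a)]
    tail_b <- b[(ev$cut_b + 1L):length(b)]
    orders[[ev$lg_a]] <- c(a[1:ev$cut_a], tail_b)
    orders[[ev$lg_b]] <- c(b[1:ev$cut_b], tail_a)
  } else if (ev$type == "transposition") {
    src <- orders[[ev$lg_from]]
    seg <- src[ev$start:(ev$start + ev$len - 1L)]
    orders[[ev$lg_from]] <- src[-(ev$start:(ev$start + ev$len - 1L))]
    dst <- orders[[ev$lg_to]]
    orders[[ev$lg_to]] <- append(dst, seg, after = ev$insert_after)
  } else stop("unknown event type: ", ev$type)
  orders
}

#' Replay a truth log's rearrangement events
#'
#' Applies the logged events to the logged ancestral marker order and returns
#' the resulting per-LG orders; by construction this reproduces the simulated
#' descendant orders exactly (tested invariant).
#'
#' @param truth `truth` component of a [simulate_genome_pair()] result.
#' @param lineage `"query"` or `"target"`.
#' @return list of per-LG marker-id vectors.
#' @export
replay_events <- function(truth, lineage = c("query", "target")) {
  lineage <- match.arg(lineage)
  orders <- truth$ancestral_order
  for (ev in truth$events) {
    if (ev$lineage == lineage) orders <- apply_event(orders, ev)
  }
  orders
}

orders_to_map <- function(orders, spacing, name, lg_prefix) {
  keep <- lengths(orders) > 0L
  orders <- orders[keep]
  dfs <- mapply(function(o, i) {
    data.frame(marker = o, lg = sprintf("%s%02d", lg_prefix, i),
               pos = (seq_along(o) - 1) * spacing, stringsAsFactors = FALSE)
  }, orders, seq_along(orders), SIMPLIFY = FALSE)
  genetic_map(do.call(rbind, dfs), name = name, normalize = FALSE)
}

#' Simulate a rearranged genome pair with homology hits and a truth log
#'
#' Ancestral markers are uniformly spaced on `n_lg` linkage groups; the
#' configured numbers of inversions (a contiguous within-LG segment reversed),
#' reciprocal translocations (two LGs exchange terminal segments) and 1-2
#' marker transpositions (a short segment moved into another LG) are then
#' applied — to the query lineage only by default, so the target map is the
#' ancestral order. An event that would not fit its LG is rejected and
#' resampled. Homology hits are generated for `homolog_fraction` of the query
#' markers with exact target coordinates, contaminated with spurious hits
#' (random wrong location), hits to unassigned target sequences, and a
#' fraction whose alignment-quality fields fall below the default filtering
#' thresholds.
#'
#' @param cfg a [sim_config()].
#' @return list with `map_q`, `map_t` (both `genetic_map`s), `hits` (data
#'   frame) and `truth` (ancestral order, event list, per-marker hit truth,
#'   spacing).
#' @export
simulate_genome_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$markers_per_lg
  spacing <- cfg$lg_length_cm / (m - 1L)
  ancestral <- lapply(seq_len(cfg$n_lg), function(i) {
    sprintf("M%02d_%03d", i, seq_len(m))
  })
  names(ancestral) <- NULL

  events <- list()
  n_ev <- c(inversion = cfg$n_inversions, translocation = cfg$n_translocations,
            transposition = cfg$n_transpositions)
  lineages <- c("query", "target")
  draw_lineage <- function() {
    if (cfg$symmetric_events) sample(lineages, 1L) else "query"
  }
  orders <- list(query = ancestral, target = ancestral)
  for (type in names(n_ev)) {
    for (k in seq_len(n_ev[[type]])) {
      for (try in 1:100) {
        lin <- draw_lineage()
        cur <- orders[[lin]]
        ev <- switch(type,
          inversion = {
            lg <- sample.int(length(cur), 1L)
            len_lg <- length(cur[[lg]])
            if (len_lg < 2L) NULL else {
              len <- sample(2:min(len_lg, max(2L, m %/% 3L)), 1L)
              start <- sample.int(len_lg - len + 1L, 1L)
              list(type = "inversion", lineage = lin, lg = lg,
                   start = start, len = len)
            }
          },
          translocation = {
            ok <- which(lengths(cur) >= 2L)
            if (length(ok) < 2L) NULL else {
              ab <- sample(ok, 2L)
              list(type = "translocation", lineage = lin,
                   lg_a = ab[1L], lg_b = ab[2L],
                   cut_a = sample.int(length(cur[[ab[1L]]]) - 1L, 1L),
                   cut_b = sample.int(length(cur[[ab[2L]]]) - 1L, 1L))
            }
          },
          transposition = {
            len <- sample(1:2, 1L)
            ok <- which(lengths(cur) >= len + 1L)
            if (!length(ok) || length(cur) < 2L) NULL else {
              from <- if (length(ok) == 1L) ok else sample(ok, 1L)
              to <- sample(setdiff(seq_along(cur), from), 1L)
              list(type = "transposition", lineage = lin, lg_from = from,
                   lg_to = to,
                   start = sample.int(length(cur[[from]]) - len + 1L, 1L),
                   len = len,
                   insert_after = sample(0:length(cur[[to]]), 1L))
            }
          })
        if (!is.null(ev)) {
          orders[[lin]] <- apply_event(cur, ev)
          events[[length(events) + 1L]] <- ev
          break
        }
      }
    }
  }

  map_q <- orders_to_map(orders$query, spacing, "query", "Q")
  map_t <- orders_to_map(orders$target, spacing, "target", "T")

  # homology hits: truth plus contamination
  qmk <- map_q$markers
  tmk <- map_t$markers
  is_hom <- stats::runif(nrow(qmk)) < cfg$homolog_fraction
  hit_rows <- list()
  hit_type <- character(0)
  tlgs <- lg_names(map_t)
  for (i in which(is_hom)) {
    id <- qmk$marker[i]
    j <- match(id, tmk$marker)
    u <- stats::runif(1)
    if (u < cfg$spurious_hit_rate) {
      type <- "spurious"
      tlg <- sample(tlgs, 1L)
      tpos <- stats::runif(1, 0, max(tmk$pos[tmk$lg == tlg]))
    } else if (u < cfg$spurious_hit_rate + cfg$un_fraction) {
      type <- "un"; tlg <- "Un"; tpos <- NA_real_
    } else {
      type <- "true"; tlg <- tmk$lg[j]; tpos <- tmk$pos[j]
    }
    weak <- stats::runif(1) < cfg$fail_filter_rate
    if (weak) {
      align_len <- sample(5:30, 1L)
      score <- stats::runif(1, 5, 45)
      identity <- stats::runif(1, 30, 67)
    } else {
      align_len <- sample(40:400, 1L)
      score <- stats::runif(1, 50, 200)
      identity <- stats::runif(1, 70, 99.9)
    }
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      marker_id = id, target_lg = tlg, target_pos = tpos,
      align_len = align_len, score = score, identity = identity,
      annotation = NA_character_, stringsAsFactors = FALSE)
    hit_type <- c(hit_type, if (weak) paste0(type, "_weak") else type)
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else {
    data.frame(marker_id = character(0), target_lg = character(0),
               target_pos = numeric(0), align_len = numeric(0),
               score = numeric(0), identity = numeric(0),
               annotation = character(0), stringsAsFactors = FALSE)
  }
  truth <- list(ancestral_order = ancestral, events = events,
                spacing = spacing,
                hit_truth = data.frame(marker_id = hits$marker_id,
                                       type = hit_type,
                                       stringsAsFactors = FALSE),
                query_order = orders$query, target_order = orders$target)
  list(map_q = map_q, map_t = map_t, hits = hits, truth = truth)
}

# crossover points on [0, L] (cM) for one meiosis
crossover_points <- function(L, model, nu) {
  if (model == "poisson") {
    n <- stats::rpois(1L, L / 100)
    if (n == 0L) numeric(0) else sort(stats::runif(n, 0, L))
  } else {
    # stationary gamma renewal, mean spacing 100 cM; burn in from the left
    x <- -500
    pts <- numeric(0)
    while (x <= L) {
      x <- x + stats::rgamma(1L, shape = nu, rate = nu / 100)
      if (x >= 0 && x <= L) pts <- c(pts, x)
    }
    pts
  }
}

#' Simulate haploid progeny of a phase-known queen
#'
#' Each haploid male inherits one recombinant haplotype of a fully
#' heterozygous queen: per LG, crossovers are placed either as a Poisson
#' process (rate 1 per 100 cM, no interference) or as a stationary gamma
#' renewal process (positive interference, shape `gamma_nu`), and the
#' individual's allele at each marker is the starting strand flipped once per
#' crossover to the left. Genotyping errors flip calls, missingness masks
#' calls, and per-marker transmission distortion biases the allele-1
#' frequency towards the configured probability while preserving the
#' linkage structure (calls are flipped one-sidedly, never redrawn).
#'
#' @param map a `genetic_map` (true marker positions).
#' @param cfg a [sim_config()]; uses `seed + 1` so genome and progeny draws
#'   are independent streams.
#' @return integer matrix (individuals x markers) with `NA` for missing.
#' @export
simulate_progeny <- function(map, cfg) {
  stopifnot(inherits(map, "genetic_map"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  lgs <- lg_split(map)
  n <- cfg$n_individuals
  g <- matrix(NA_integer_, n, nrow(map$markers),
              dimnames = list(sprintf("I%04d", seq_len(n)),
                              map$markers$marker))
  col0 <- 0L
  for (d in lgs) {
    pos <- d$pos - min(d$pos)
    L <- max(pos)
    for (i in seq_len(n)) {
      xo <- crossover_points(L, cfg$crossover_model, cfg$gamma_nu)
      parity <- vapply(pos, function(p) sum(xo <= p) %% 2, numeric(1))
      start <- stats::rbinom(1L, 1L, 0.5)
      g[i, col0 + seq_along(pos)] <- as.integer(xor(start, parity))
    }
    col0 <- col0 + length(pos)
  }
  # transmission distortion: one-sided flips reach the target marginal
  if (!is.null(cfg$distortion_markers)) {
    for (mk in names(cfg$distortion_markers)) {
      if (!mk %in% colnames(g)) next
      p <- cfg$distortion_markers[[mk]]
      if (p > 0.5) {
        flip <- g[, mk] == 0L & stats::runif(n) < (2 * p - 1)
        g[flip, mk] <- 1L
      } else if (p < 0.5) {
        flip <- g[, mk] == 1L & stats::runif(n) < (1 - 2 * p)
        g[flip, mk] <- 0L
      }
    }
  }
  if (cfg$genotyping_error_rate > 0) {
    err <- matrix(stats::runif(length(g)) < cfg$genotyping_error_rate,
                  nrow(g))
    g[err] <- 1L - g[err]
  }
  if (cfg$missing_rate > 0) {
    mis <- matrix(stats::runif(length(g)) < cfg$missing_rate, nrow(g))
    g[mis] <- NA_integer_
  }
  g
}

#' Physical-anchor fixture with known truth
#'
#' Draws one anchor (a clone of known physical size whose end markers are a
#' known genetic distance apart) at the given physical-to-genetic scale, plus
#' the genome size it implies for the configured map, so that
#' [size_from_anchor()] recovers the implied size exactly.
#'
#' @param kb_per_cm physical-to-genetic scale, kb per cM (`> 0`).
#' @param cfg a [sim_config()] (supplies the seed and the total map length
#'   `n_lg * lg_length_cm`); uses `seed + 2`.
#' @return list with `anchor` (a [physical_anchor()]), `total_map_cm` and
#'   `implied_mb`.
#' @export
make_anchor_fixture <- function(kb_per_cm, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (kb_per_cm <= 0) stop("scale must be positive")
  set.seed(cfg$seed + 2L)
  total <- cfg$n_lg * cfg$lg_length_cm
  d <- stats::runif(1, 0.2, 2)
  list(anchor = physical_anchor(d, kb_per_cm * d),
       total_map_cm = total,
       implied_mb = kb_per_cm * total / 1000)
}
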