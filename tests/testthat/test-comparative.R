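test_that("hit filtering applies len AND (score OR identity), all strict", {
  h <- data.frame(marker_id = c("a", "b", "c", "d"),
                  target_lg = "L1", target_pos = 1:4,
                  align_len = c(31, 30, 31, 31),
                  score = c(46, 100, 10, 45),
                  identity = c(50, 99, 68, 67),
                  annotation = NA_character_, stringsAsFactors = FALSE)
  kept <- filter_hits(h)$marker_id
  expect_setequal(kept, c("a", "c"))  # b fails len, d fails both quality cuts

  # pure-OR mode keeps anything clearing any one threshold
  expect_setequal(filter_hits(h, rule = "any")$marker_id,
                  c("a", "b", "c", "d"))
})

test_that("the contingency counts every mapped filtered hit exactly once", {
  cfg <- sim_config(seed = 14, n_lg = 4, markers_per_lg = 15,
                    lg_length_cm = 60, homolog_fraction = 0.6,
                    spurious_hit_rate = 0.1, un_fraction = 0.1,
                    fail_filter_rate = 0.2)
  sim <- simulate_genome_pair(cfg)
  fh <- filter_hits(sim$hits)
  ct <- build_contingency(sim$map_q, fh)
  expect_equal(sum(ct), nrow(fh))
  expect_equal(attr(ct, "grand_total"), nrow(fh))

  # empty hits give an all-zero table; off-map hits are excluded with warning
  ct0 <- build_contingency(sim$map_q, fh[0, ])
  expect_equal(sum(ct0), 0)
  bad <- fh
  bad$marker_id[1] <- "not_on_map"
  expect_warning(ctb <- build_contingency(sim$map_q, bad), "excluded")
  expect_equal(sum(ctb), nrow(fh) - 1L)
})

test_that("one marker per LG yields a diagonal-like contingency", {
  map <- genetic_map(data.frame(marker = c("x", "y"), lg = c("Q1", "Q2"),
                                pos = 0))
  hits <- data.frame(marker_id = c("x", "y"), target_lg = c("T1", "T2"),
                     target_pos = 0, align_len = 100, score = 100,
                     identity = 90, annotation = NA_character_)
  ct <- build_contingency(map, hits)
  expect_equal(ct["Q1", "T1"], 1)
  expect_equal(ct["Q2", "T2"], 1)
  expect_equal(sum(ct), 2)
})

test_that("LG matching assigns segments at the min-marker rule", {
  map <- genetic_map(data.frame(marker = sprintf("m%d", 1:4), lg = "Q1",
                                pos = 0:3 * 10))
  mk_hits <- function(tlg) data.frame(marker_id = sprintf("m%d", 1:4),
                                      target_lg = tlg, target_pos = 1:4,
                                      align_len = 100, score = 100,
                                      identity = 90,
                                      annotation = NA_character_)
  asg <- match_lgs(build_contingency(map, mk_hits(c("A", "A", "B", "B"))))
  expect_identical(asg$status, "unmatched")
  asg <- match_lgs(build_contingency(map, mk_hits(rep("A", 4))))
  expect_identical(asg$status, "matched")
  expect_identical(asg$segments[[1]], "A")
  asg <- match_lgs(build_contingency(map, mk_hits(rep("A", 4))), min_markers = 5)
  expect_identical(asg$status, "unmatched")
})

test_that("homolog reduction keeps exactly the assigned-hit markers", {
  cfg <- sim_config(seed = 15, n_lg = 3, markers_per_lg = 12,
                    lg_length_cm = 55, homolog_fraction = 0.5,
                    un_fraction = 0.1, spurious_hit_rate = 0,
                    fail_filter_rate = 0)
  sim <- simulate_genome_pair(cfg)
  fh <- filter_hits(sim$hits)
  asg <- match_lgs(build_contingency(sim$map_q, fh))
  red <- reduce_to_homologs(sim$map_q, fh, asg)
  expect_setequal(red$query$markers$marker,
                  fh$marker_id[fh$target_lg != "Un"])
  expect_setequal(red$target$markers$marker, red$query$markers$marker)

  # all markers homologous -> reduced map is the input map
  cfg2 <- sim_config(seed = 16, n_lg = 2, markers_per_lg = 8,
                     lg_length_cm = 35, homolog_fraction = 1, un_fraction = 0,
                     spurious_hit_rate = 0, fail_filter_rate = 0,
                     n_inversions = 0, n_translocations = 0,
                     n_transpositions = 0)
  sim2 <- simulate_genome_pair(cfg2)
  red2 <- reduce_to_homologs(sim2$map_q, filter_hits(sim2$hits),
                             match_lgs(build_contingency(sim2$map_q,
                                                         filter_hits(sim2$hits))))
  expect_identical(red2$query$markers$marker, sim2$map_q$markers$marker)
})

test_that("insertion classification follows the flanked short-run rule", {
  # [L1, L1, L2, L1]: one single-marker insertion
  tc <- toy_comparison(c("L1", "L1", "L2", "L1"), c(0, 10, 5, 20))
  ins <- classify_insertions(tc$red, tc$asg)
  expect_equal(nrow(ins), 1)
  expect_true(ins$classified)
  expect_equal(ins$n_markers, 1L)

  # [L2, L1, L1, L1]: terminal foreign marker, unflanked, not an insertion
  tc <- toy_comparison(c("L2", "L1", "L1", "L1"), c(5, 0, 10, 20))
  ins <- classify_insertions(tc$red, tc$asg)
  expect_equal(sum(ins$classified), 0)
  expect_false(ins$flanked[1])

  # [L1, L1, L2, L2, L1]: one double-marker insertion at max_run = 2
  tc <- toy_comparison(c("L1", "L1", "L2", "L2", "L1"), c(0, 10, 5, 6, 20))
  ins <- classify_insertions(tc$red, tc$asg)
  expect_equal(sum(ins$classified), 1)
  expect_equal(ins$n_markers[ins$classified], 2L)
  # ... but not at max_run = 1
  ins <- classify_insertions(tc$red, tc$asg, max_run = 1)
  expect_equal(sum(ins$classified), 0)
})

test_that("synteny classification matches the adjacency rule on worked cases", {
  # identity order: all pairs syntenic, one run of 4, query span 30
  tc <- toy_comparison(rep("L1", 4), c(0, 10, 20, 30))
  cls <- detect_synteny(tc$red, tc$asg)
  expect_identical(cls$intervals$klass, rep("syntenic", 3))
  expect_equal(sum(cls$intervals$span_q), 30)
  expect_equal(nrow(cls$runs), 1)
  expect_equal(cls$runs$n_markers, 4L)

  # target order A,C,B,D: only the (B,C) pair stays adjacent
  tc <- toy_comparison(rep("L1", 4), c(0, 20, 10, 30))
  cls <- detect_synteny(tc$red, tc$asg)
  expect_identical(cls$intervals$klass,
                   c("rearranged", "syntenic", "rearranged"))

  # full inversion: orientation-insensitive adjacency keeps all pairs syntenic
  tc <- toy_comparison(rep("L1", 4), c(30, 20, 10, 0))
  cls <- detect_synteny(tc$red, tc$asg)
  expect_identical(cls$intervals$klass, rep("syntenic", 3))
  expect_equal(nrow(cls$runs), 1)
  expect_equal(cls$runs$orientation, -1)
})

test_that("a pruned insertion does not break the surrounding synteny", {
  tc <- toy_comparison(c("L1", "L1", "L2", "L1", "L1"),
                       c(0, 10, 3, 20, 30))
  ins <- classify_insertions(tc$red, tc$asg)
  expect_equal(sum(ins$classified), 1)
  cls <- detect_synteny(tc$red, tc$asg, insertions = ins)
  # four remaining markers, three pairs, all syntenic; the bridging pair
  # spans the pruned marker
  expect_identical(cls$intervals$klass, rep("syntenic", 3))
  expect_true(cls$intervals$spans_insertion[2])
})

test_that("synteny classification equals the adjacency-enumeration oracle", {
  set.seed(909)
  for (rep in 1:100) {
    k <- sample(3:8, 1)
    tpos <- sample(seq(0, 100, by = 2), k)
    tc <- toy_comparison(rep("L1", k), tpos, min_markers = 3)
    cls <- detect_synteny(tc$red, tc$asg)
    want <- oracle_synteny(tc$map$markers$marker,
                           setNames(tpos, tc$map$markers$marker))
    expect_identical(cls$intervals$klass == "syntenic", unname(want))
  }
})

test_that("clean simulated pairs are fully syntenic; inversions never create insertions", {
  cfg <- sim_config(seed = 17, n_lg = 3, markers_per_lg = 10,
                    lg_length_cm = 45, n_inversions = 0, n_translocations = 0,
                    n_transpositions = 0, homolog_fraction = 1,
                    spurious_hit_rate = 0, un_fraction = 0,
                    fail_filter_rate = 0)
  sim <- simulate_genome_pair(cfg)
  cmp <- compare_maps(sim$map_q, sim$hits)
  expect_identical(unique(cmp$intervals$klass), "syntenic")
  expect_equal(sum(cmp$insertions$classified), 0)
  expect_equal(cmp$summary$totals$n_rearranged_blocks, 0)

  cfg_inv <- sim_config(seed = 18, n_lg = 3, markers_per_lg = 10,
                        lg_length_cm = 45, n_inversions = 4,
                        n_translocations = 0, n_transpositions = 0,
                        homolog_fraction = 1, spurious_hit_rate = 0,
                        un_fraction = 0, fail_filter_rate = 0)
  sim <- simulate_genome_pair(cfg_inv)
  cmp <- compare_maps(sim$map_q, sim$hits)
  expect_equal(sum(cmp$insertions$classified), 0)
  # every adjacent homolog pair on matched LGs is syntenic or rearranged
  expect_true(all(cmp$intervals$klass %in% c("syntenic", "rearranged")))
  expect_equal(nrow(cmp$intervals),
               sum(vapply(split(cmp$reduced$query$markers$lg,
                                cmp$reduced$query$markers$lg),
                          length, integer(1)) - 1L))
})

test_that("a planted inversion flags exactly its boundary pairs", {
  cfg <- sim_config(seed = 23, n_lg = 2, markers_per_lg = 10,
                    lg_length_cm = 45, n_inversions = 1, n_translocations = 0,
                    n_transpositions = 0, homolog_fraction = 1,
                    spurious_hit_rate = 0, un_fraction = 0,
                    fail_filter_rate = 0)
  sim <- simulate_genome_pair(cfg)
  ev <- sim$truth$events[[1]]
  expect_identical(ev$type, "inversion")
  cmp <- compare_maps(sim$map_q, sim$hits)
  # expected rearranged pairs: the query-adjacent pairs straddling the two
  # breakpoints (when interior)
  ord <- sim$truth$query_order[[ev$lg]]
  bad <- character(0)
  if (ev$start > 1L) {
    bad <- c(bad, paste(sort(ord[(ev$start - 1L):ev$start]), collapse = "|"))
  }
  e <- ev$start + ev$len - 1L
  if (e < length(ord)) {
    bad <- c(bad, paste(sort(ord[e:(e + 1L)]), collapse = "|"))
  }
  got <- cmp$intervals
  got_key <- apply(cbind(got$marker_a, got$marker_b), 1, function(x) {
    paste(sort(x), collapse = "|")
  })
  expect_setequal(got_key[got$klass == "rearranged"], bad)
  expect_true(all(got$klass[!got_key %in% bad] == "syntenic"))
})

test_that("the comparison summary uses corrected denominators and adds up", {
  cfg <- sim_config(seed = 19, n_lg = 4, markers_per_lg = 12,
                    lg_length_cm = 55, n_inversions = 2, n_translocations = 1,
                    n_transpositions = 2, homolog_fraction = 0.8,
                    spurious_hit_rate = 0.03, un_fraction = 0.05,
                    fail_filter_rate = 0.05)
  sim <- simulate_genome_pair(cfg)
  cmp <- compare_maps(sim$map_q, sim$hits)
  s <- cmp$summary$per_lg
  ms <- summarize_map(sim$map_q)$per_lg
  corr <- ms$corrected_length_cm[match(s$lg, ms$lg)]
  expect_equal(s$synteny_pct, 100 * s$synteny_q_cm / corr, tolerance = 1e-9)
  expect_equal(s$conserved_pct, s$synteny_pct + s$rearranged_pct,
               tolerance = 1e-12)
  # ratio absent when the target span is zero
  expect_true(all(is.na(s$ratio_qt[s$synteny_t_cm == 0])))
})
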