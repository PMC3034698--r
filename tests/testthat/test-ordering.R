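fake_result <- function(a, b, theta, lod,
                        phase = "coupling") {
  data.frame(a = a, b = b, n = 100L, R = round(100 * theta), theta = theta,
             lod = lod, phase = phase, flag = "", stringsAsFactors = FALSE)
}

test_that("grouping returns the connected components of the LOD graph", {
  tp <- rbind(
    fake_result("a1", "a2", 0.1, 20), fake_result("a2", "a3", 0.1, 20),
    fake_result("a1", "a3", 0.2, 12),
    fake_result("b1", "b2", 0.1, 20), fake_result("b2", "b3", 0.1, 20),
    fake_result("b1", "b3", 0.2, 12),
    fake_result("a3", "b1", 0.5, 0.3)
  )
  gr <- group_markers(tp, lod_threshold = 5)
  expect_length(gr, 2)
  expect_setequal(gr$G01, c("a1", "a2", "a3"))
  expect_setequal(gr$G02, c("b1", "b2", "b3"))

  gr <- group_markers(tp, lod_threshold = 100)
  expect_length(gr, 6)
  expect_true(all(lengths(gr) == 1))
})

test_that("grouping recovers the true chromosome partition from progeny", {
  cfg <- sim_config(seed = 202, n_lg = 18, markers_per_lg = 8,
                    lg_length_cm = 35, n_inversions = 0,
                    n_translocations = 0, n_transpositions = 0,
                    n_individuals = 300, genotyping_error_rate = 0,
                    missing_rate = 0.05)
  sim <- simulate_genome_pair(cfg)
  g <- simulate_progeny(sim$map_q, cfg)
  gr <- group_markers(twopoint_table(g), lod_threshold = 5,
                      markers = colnames(g))
  expect_length(gr, 18)
  truth <- map_partition(sim$map_q)
  got <- unname(lapply(gr, sort))
  got <- got[order(vapply(got, `[`, character(1), 1L))]
  expect_identical(got, truth)
})

test_that("a three-marker chain is ordered and measured in Kosambi cM", {
  tp <- rbind(fake_result("A", "B", 0.10, 20),
              fake_result("B", "C", 0.10, 20),
              fake_result("A", "C", 0.18, 15))
  og <- order_markers(c("A", "B", "C"), tp)
  expect_identical(og$markers, c("A", "B", "C"))
  expect_equal(og$positions, c(0, kosambi_cm(0.1), 2 * kosambi_cm(0.1)),
               tolerance = 1e-9)
  expect_equal(round(max(og$positions), 1), 20.3)
})

test_that("two markers are trivially ordered at their Kosambi distance", {
  tp <- fake_result("A", "B", 0.2, 10)
  og <- order_markers(c("B", "A"), tp)
  expect_identical(og$markers, c("A", "B"))
  expect_equal(max(og$positions), kosambi_cm(0.2), tolerance = 1e-9)
})

test_that("a group disconnected under the linkage filter errors with fragments", {
  tp <- rbind(fake_result("A", "B", 0.1, 20),
              fake_result("C", "D", 0.1, 20),
              fake_result("B", "C", 0.45, 6))  # linked but theta >= max_theta
  expect_error(order_markers(c("A", "B", "C", "D"), tp), "fragments")
})

test_that("noiseless simulated orders are recovered exactly (up to reversal)", {
  df <- data.frame(marker = sprintf("m%02d", 1:10), lg = "LG1",
                   pos = seq(0, 45, by = 5))
  map <- genetic_map(df)
  cfg <- sim_config(seed = 31, n_lg = 1, markers_per_lg = 10,
                    lg_length_cm = 45, n_individuals = 500,
                    genotyping_error_rate = 0, missing_rate = 0)
  g <- simulate_progeny(map, cfg)
  og <- order_markers(colnames(g), twopoint_table(g))
  tau <- cor(seq_len(10), match(df$marker, og$markers), method = "kendall")
  expect_equal(abs(tau), 1)
})

test_that("ordering agrees with the exhaustive minimum-length oracle", {
  # noiseless 7-marker groups; the brute-force oracle minimises the summed
  # adjacent Kosambi distances over all 7! orders
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    df <- data.frame(marker = sprintf("m%d", 1:7), lg = "LG1",
                     pos = c(0, cumsum(5 + 4 * ((s * 7 + 1:6) %% 3))))
    map <- genetic_map(df)
    cfg <- sim_config(seed = 4000 + s, n_lg = 1, markers_per_lg = 7,
                      lg_length_cm = max(df$pos), n_individuals = 250,
                      genotyping_error_rate = 0, missing_rate = 0)
    g <- simulate_progeny(map, cfg)
    tp <- twopoint_table(g)
    theta_mat <- matrix(0.4999, 7, 7,
                        dimnames = list(colnames(g), colnames(g)))
    theta_mat[cbind(tp$a, tp$b)] <- tp$theta
    theta_mat[cbind(tp$b, tp$a)] <- tp$theta
    bf <- brute_force_order(colnames(g), theta_mat)
    og <- order_markers(colnames(g), tp)
    same <- identical(og$markers, bf) || identical(og$markers, rev(bf))
    hits <- hits + same
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("build_map reproduces a hand-computed Kosambi chain on clean data", {
  # 4 markers, exact recombinant layout: theta(12)=0.1, theta(23)=0.2,
  # theta(34)=0.1, no double recombinants within adjacent pairs
  n <- 100
  h <- matrix(0L, n, 4, dimnames = list(NULL, c("w", "x", "y", "z")))
  h[, 2] <- h[, 1]; h[1:10, 2] <- 1L - h[1:10, 2]
  h[, 3] <- h[, 2]; h[11:30, 3] <- 1L - h[11:30, 3]
  h[, 4] <- h[, 3]; h[31:40, 4] <- 1L - h[31:40, 4]
  flip <- seq(1, n, by = 2)  # half the progeny carry the mirrored haplotype
  h[flip, ] <- 1L - h[flip, ]
  map <- build_map(h)
  expect_length(lg_names(map), 1)
  expect_identical(map$markers$marker, c("w", "x", "y", "z"))
  expect_equal(map$markers$pos,
               cumsum(c(0, kosambi_cm(0.1), kosambi_cm(0.2), kosambi_cm(0.1))),
               tolerance = 1e-9)
  expect_equal(map$phase_conflicts, 0L)
})

test_that("build_map rejects an empty matrix", {
  expect_error(build_map(matrix(integer(0), 0, 0)), "empty")
})

test_that("map length is invariant under marker and individual relabeling", {
  cfg <- sim_config(seed = 88, n_lg = 2, markers_per_lg = 8,
                    lg_length_cm = 35, n_inversions = 0, n_translocations = 0,
                    n_transpositions = 0, n_individuals = 250,
                    genotyping_error_rate = 0, missing_rate = 0.05)
  sim <- simulate_genome_pair(cfg)
  g <- simulate_progeny(sim$map_q, cfg)
  m1 <- build_map(g)
  set.seed(1)
  g2 <- g[sample(nrow(g)), sample(ncol(g))]
  rownames(g2) <- rev(rownames(g2))
  m2 <- build_map(g2)
  expect_equal(sum(lg_lengths(m1)), sum(lg_lengths(m2)), tolerance = 1e-9)
})
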