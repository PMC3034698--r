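test_that("the generator is fully seeded: identical config, identical output", {
  cfg <- sim_config(seed = 55, n_lg = 3, markers_per_lg = 9,
                    lg_length_cm = 40, n_individuals = 50)
  s1 <- simulate_genome_pair(cfg)
  s2 <- simulate_genome_pair(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_progeny(s1$map_q, cfg),
                   simulate_progeny(s2$map_q, cfg))
  expect_error(sim_config(n_lg = 2), "seed")
})

test_that("replaying the truth log reproduces both descendant orders", {
  cfg <- sim_config(seed = 66, n_lg = 4, markers_per_lg = 12,
                    lg_length_cm = 55, n_inversions = 3, n_translocations = 2,
                    n_transpositions = 4)
  sim <- simulate_genome_pair(cfg)
  expect_identical(replay_events(sim$truth, "query"), sim$truth$query_order)
  expect_identical(replay_events(sim$truth, "target"), sim$truth$target_order)
  # the maps are the replayed orders laid out at the ancestral spacing
  for (i in seq_along(sim$truth$query_order)) {
    lg <- sprintf("Q%02d", i)
    expect_identical(sim$map_q$markers$marker[sim$map_q$markers$lg == lg],
                     sim$truth$query_order[[i]])
  }
})

test_that("with no rearrangements and full homology the hits are the identity map", {
  cfg <- sim_config(seed = 77, n_lg = 3, markers_per_lg = 8,
                    lg_length_cm = 35, n_inversions = 0, n_translocations = 0,
                    n_transpositions = 0, homolog_fraction = 1,
                    spurious_hit_rate = 0, un_fraction = 0,
                    fail_filter_rate = 0)
  sim <- simulate_genome_pair(cfg)
  expect_equal(nrow(sim$hits), nrow(sim$map_q$markers))
  t_of <- sim$map_t$markers
  i <- match(sim$hits$marker_id, t_of$marker)
  expect_identical(sim$hits$target_lg, t_of$lg[i])
  expect_equal(sim$hits$target_pos, t_of$pos[i])
})

test_that("a zero-length LG yields identical calls up to error", {
  map <- genetic_map(data.frame(marker = c("a", "b", "c"), lg = "L1", pos = 0))
  cfg <- sim_config(seed = 88, n_lg = 1, markers_per_lg = 3, lg_length_cm = 1,
                    n_individuals = 200, genotyping_error_rate = 0,
                    missing_rate = 0)
  g <- simulate_progeny(map, cfg)
  expect_true(all(g[, "a"] == g[, "b"] & g[, "b"] == g[, "c"]))
})

test_that("the recombinant fraction matches the Haldane expectation", {
  map <- genetic_map(data.frame(marker = c("p", "q"), lg = "L1",
                                pos = c(0, 10)))
  cfg <- sim_config(seed = 99, n_lg = 1, markers_per_lg = 2, lg_length_cm = 10,
                    n_individuals = 10000, genotyping_error_rate = 0,
                    missing_rate = 0)
  g <- simulate_progeny(map, cfg)
  r_hat <- mean(g[, "p"] != g[, "q"])
  r_true <- (1 - exp(-0.2)) / 2                    # ~ 0.0906
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("gamma interference shortens the inter-crossover variance, rate kept", {
  map <- genetic_map(data.frame(marker = c("p", "q"), lg = "L1",
                                pos = c(0, 10)))
  cfg <- sim_config(seed = 101, n_lg = 1, markers_per_lg = 2,
                    lg_length_cm = 10, n_individuals = 8000,
                    genotyping_error_rate = 0, missing_rate = 0,
                    crossover_model = "gamma", gamma_nu = 6)
  g <- simulate_progeny(map, cfg)
  r_hat <- mean(g[, "p"] != g[, "q"])
  # interference suppresses double crossovers; at 10 cM the recombinant
  # fraction stays close to 0.1 (within a generous band)
  expect_gt(r_hat, 0.07)
  expect_lt(r_hat, 0.13)
})

test_that("planted transmission distortion is detected by the chi-square scan", {
  map <- genetic_map(data.frame(marker = c("m1", "m2", "m3"), lg = "L1",
                                pos = c(0, 10, 20)))
  flagged <- 0L
  for (s in 1:50) {
    cfg <- sim_config(seed = 6000 + s, n_lg = 1, markers_per_lg = 3,
                      lg_length_cm = 20, n_individuals = 384,
                      genotyping_error_rate = 0, missing_rate = 0,
                      distortion_markers = c(m2 = 0.75))
    g <- simulate_progeny(map, cfg)
    p <- segregation_test(sum(g[, "m2"] == 0), sum(g[, "m2"] == 1))$p
    flagged <- flagged + (p < 0.001)
  }
  expect_gte(flagged / 50, 0.95)
  # the marginal allele-1 frequency approaches the configured probability
  cfg <- sim_config(seed = 6100, n_lg = 1, markers_per_lg = 3,
                    lg_length_cm = 20, n_individuals = 10000,
                    genotyping_error_rate = 0, missing_rate = 0,
                    distortion_markers = c(m2 = 0.75))
  g <- simulate_progeny(map, cfg)
  expect_equal(mean(g[, "m2"]), 0.75, tolerance = 0.02)
})

test_that("anchor fixtures recover their implied genome size exactly", {
  cfg <- sim_config(seed = 111, n_lg = 1, lg_length_cm = 2047.09)
  fx <- make_anchor_fixture(208.2996, cfg)
  expect_equal(as.numeric(size_from_anchor(fx$anchor, fx$total_map_cm)),
               fx$implied_mb, tolerance = 1e-9)
  expect_equal(round(fx$implied_mb, 2), 426.41)

  cfg <- sim_config(seed = 112, n_lg = 1, lg_length_cm = 100)
  fx <- make_anchor_fixture(100, cfg)
  expect_equal(fx$implied_mb, 10)
  # exact for arbitrary seeds (algebraic identity)
  for (s in 1:5) {
    cfg <- sim_config(seed = 200 + s, n_lg = 3, lg_length_cm = 70)
    fx <- make_anchor_fixture(150, cfg)
    expect_equal(as.numeric(size_from_anchor(fx$anchor, fx$total_map_cm)),
                 fx$implied_mb, tolerance = 1e-9)
  }
})
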