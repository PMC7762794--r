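test_that("community profiles enforce their invariants", {
  expect_error(community_profile(tibble::tibble(
    taxon_id = c("A", "B"), abundance = c(0.6, 0.6), viability = c(0.1, 0.1))),
    "sum to 1")
  expect_error(community_profile(tibble::tibble(
    taxon_id = c("A", "A"), abundance = c(0.5, 0.5), viability = c(0.1, 0.1))),
    "unique")
  expect_error(community_profile(tibble::tibble(
    taxon_id = "A", abundance = 1, viability = 1.2)), "\\[0, 1\\]")
  comm <- community_profile(tibble::tibble(
    taxon_id = c("A", "B"), abundance = c(0.9, 0.1), viability = c(0.1, 0),
    lineage = c("Bacteria;Cyanobacteria;Oxyphotobacteria;Chloroplast", "Bacteria")))
  expect_identical(comm$is_chloroplast, c(TRUE, FALSE))
})

test_that("design validation catches inconsistent layouts", {
  expect_error(htc_design(0, 5), "positive integer")
  expect_error(htc_design(10, 0), "positive")
  expect_error(htc_design(10, 5, depth_mean = 100, depth_min = 500), "depth_min")
  expect_error(htc_design(10, 5, contamination = 1), "contamination")
})

test_that("wells with zero viability everywhere are all negative", {
  comm <- toy_community(abundance = c(0.5, 0.5), viability = c(0, 0),
                        ids = c("A", "B"))
  wells <- simulate_wells(comm, htc_design(200, 5), seed = 1)
  expect_false(any(wells$positive))
  expect_true(all(as.matrix(wells[, c("A", "B")]) == 0))
})

test_that("positive-well fraction matches the Poisson void probability", {
  n <- 1e5
  des <- htc_design(n, 5)
  # fully viable single taxon: 1 - exp(-5)
  comm1 <- uniform_community(1, 1)
  w1 <- simulate_wells(comm1, des, seed = 11)
  p1 <- expected_positive_fraction(comm1, 5)
  expect_equal(p1, 0.99326, tolerance = 1e-4)
  expect_lt(abs(mean(w1$positive) - p1), 3 * sqrt(p1 * (1 - p1) / n))
  # viability at the scale of a 5-cell marine inoculum: 1 - exp(-0.1556)
  comm2 <- uniform_community(1, 0.0311)
  w2 <- simulate_wells(comm2, des, seed = 12)
  p2 <- expected_positive_fraction(comm2, 5)
  expect_equal(p2, 1 - exp(-5 * 0.0311))
  expect_equal(p2, 0.144, tolerance = 5e-3)  # the scale of 83/576 positives
  expect_lt(abs(mean(w2$positive) - p2), 3 * sqrt(p2 * (1 - p2) / n))
})

test_that("closed-form positive and pure-well fractions evaluate correctly", {
  expect_equal(expected_positive_fraction(uniform_community(2, 0), 5), 0)
  expect_equal(expected_positive_fraction(uniform_community(1, 0.02), 105),
               1 - exp(-2.1))
  # single taxon: pure coincides with positive
  comm <- uniform_community(1, 0.4)
  expect_equal(expected_pure_well_fraction(comm, 3),
               expected_positive_fraction(comm, 3))
  # two taxa with lambda = 0.1 each: 2 * (1 - e^-0.1) * e^-0.1
  comm2 <- toy_community(abundance = c(0.5, 0.5), viability = c(0.2, 0.2),
                         ids = c("A", "B"))
  expect_equal(expected_pure_well_fraction(comm2, 1),
               2 * (1 - exp(-0.1)) * exp(-0.1))
  expect_equal(expected_pure_well_fraction(comm2, 1), 0.17221, tolerance = 1e-4)
  expect_equal(expected_pure_well_fraction(uniform_community(3, 0), 5), 0)
  expect_error(expected_positive_fraction(comm2, -1), "non-negative")
})

test_that("pure-well oracle agrees with Monte Carlo over simulated wells", {
  comm <- toy_community(abundance = c(0.5, 0.3, 0.2),
                        viability = c(0.3, 0.2, 0.1), ids = c("A", "B", "C"))
  n <- 4e4
  wells <- simulate_wells(comm, htc_design(n, 2), seed = 3)
  founders <- as.matrix(wells[, c("A", "B", "C")])
  pure <- rowSums(founders > 0) == 1
  expected <- expected_pure_well_fraction(comm, 2)
  expect_lt(abs(mean(pure) - expected),
            3 * sqrt(expected * (1 - expected) / n))
})

test_that("read simulation distributes depth by founder counts", {
  comm <- toy_community(abundance = c(0.5, 0.5), viability = c(0.5, 0.5),
                        ids = c("T1", "T2"))
  des <- htc_design(1, 5, depth_mean = 9000, depth_sd = 0, depth_min = 679,
                    depth_max = 57557, contamination = 0)
  wells <- tibble::tibble(well_id = "W1", T1 = 2L, T2 = 1L, positive = TRUE)
  reads <- simulate_reads(wells, comm, des, seed = 5)
  expect_equal(sum(reads$T1, reads$T2), 9000)
  se <- sqrt(9000 * 2 / 3 * 1 / 3)
  expect_lt(abs(reads$T1 - 6000), 3 * se)
  # single-founder well: every read on that taxon
  wells1 <- tibble::tibble(well_id = "W1", T1 = 1L, T2 = 0L, positive = TRUE)
  reads1 <- simulate_reads(wells1, comm, des, seed = 5)
  expect_equal(reads1$T1, 9000)
  expect_equal(reads1$T2, 0)
  # negative wells yield all-zero rows
  wells0 <- tibble::tibble(well_id = "W1", T1 = 0L, T2 = 0L, positive = FALSE)
  reads0 <- simulate_reads(wells0, comm, des, seed = 5)
  expect_equal(unlist(reads0[-1]), c(T1 = 0L, T2 = 0L))
})

test_that("depth model matches its mean and range over many wells", {
  n <- 1e4
  comm <- uniform_community(1, 1, ids = "T1")
  des <- htc_design(n, 5)
  wells <- tibble::tibble(well_id = sprintf("W%05d", 1:n), T1 = 1L,
                          positive = TRUE)
  reads <- simulate_reads(wells, comm, des, seed = 7)
  depths <- reads$T1
  expect_lt(abs(mean(depths) - 14047) / 14047, 0.05)
  expect_gte(min(depths), 679)
  expect_lte(max(depths), 57557)
})

test_that("environmental sample is one multinomial draw over all taxa", {
  comm <- toy_community(abundance = c(0.5, 0.5), viability = c(0.1, 0.1),
                        ids = c("A", "B"))
  env <- simulate_environment(comm, env_depth = 65924, seed = 9)
  expect_equal(sum(env$A, env$B), 65924)
  se <- sqrt(65924 * 0.25)
  expect_lt(abs(env$A - 32962), 3 * se)
  # chloroplast taxa are included in the draw
  commc <- community_profile(tibble::tibble(
    taxon_id = c("A", "CHL"), abundance = c(0.9, 0.1), viability = c(0.1, 0),
    is_chloroplast = c(FALSE, TRUE)))
  envc <- simulate_environment(commc, env_depth = 50000, seed = 9)
  expect_lt(abs(envc$CHL - 5000), 3 * sqrt(50000 * 0.1 * 0.9))
  expect_error(simulate_environment(comm, env_depth = 0), "positive")
})

test_that("simulation is reproducible and depth-bounded", {
  comm <- toy_community()
  des <- htc_design(300, 5, contamination = 0.005)
  sim1 <- simulate_experiment(comm, des, seed = 42)
  sim2 <- simulate_experiment(comm, des, seed = 42)
  expect_identical(sim1, sim2)
  sim3 <- simulate_experiment(comm, des, seed = 43)
  expect_false(identical(sim1$counts, sim3$counts))
  m <- as.matrix(sim1$counts[-1])
  expect_true(all(m >= 0))
  totals <- rowSums(m)[sim1$wells$positive]
  expect_true(all(totals >= des$depth_min & totals <= des$depth_max))
  # negative wells carry no reads
  expect_true(all(rowSums(m)[!sim1$wells$positive] == 0))
})
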