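test_that("single-culture classification follows the screening rules", {
  mono <- classify_culture(c(A = 0.95, B = 0.03, C = 0.02))
  expect_equal(mono$category, "monoculture")
  expect_equal(mono$dominant_asv, "A")
  expect_equal(mono$members[[1]]$asv_id, "A")

  # >= 90% dominant plus a >= 5% companion is mixed, not mono
  mix2 <- classify_culture(c(A = 0.94, B = 0.06))
  expect_equal(mix2$category, "mixed")
  expect_setequal(mix2$members[[1]]$asv_id, c("A", "B"))

  # 50-90% dominant: members are dominant plus all >= 5% others
  mix1 <- classify_culture(c(A = 0.60, B = 0.36, C = 0.04))
  expect_equal(mix1$category, "mixed")
  expect_equal(mix1$members[[1]]$asv_id, c("A", "B"))

  nodom <- classify_culture(c(A = 0.45, B = 0.35, C = 0.20))
  expect_equal(nodom$category, "no_dominant")
  expect_equal(nodom$n_members, 0)

  pure <- classify_culture(c(A = 1.0))
  expect_equal(pure$category, "monoculture")

  zero <- classify_culture(c(A = 0, B = 0))
  expect_equal(zero$category, "no_amplification")

  expect_error(classify_culture(c(A = 0.5, B = 0.3)), "sum to 1")
})

test_that("boundary behaviour: exact thresholds and ties are deterministic", {
  # exactly 0.50 dominant counts as mixed
  tie <- classify_culture(c(B = 0.5, A = 0.5))
  expect_equal(tie$category, "mixed")
  expect_equal(tie$dominant_asv, "A")  # lexicographic tie-break
  # raw counts override lexicographic order when supplied
  tie2 <- classify_culture(c(A = 0.5, B = 0.5), counts = c(A = 10, B = 20))
  expect_equal(tie2$dominant_asv, "B")
  # exactly 5% companion: inclusive by default, excluded when not
  incl <- classify_culture(c(A = 0.95, B = 0.05))
  expect_equal(incl$category, "mixed")
  excl <- classify_culture(c(A = 0.95, B = 0.05), minor_inclusive = FALSE)
  expect_equal(excl$category, "monoculture")
})

test_that("classification agrees with the literal rule restatement on a grid", {
  grid <- proportion_grid(0.05)
  expect_equal(nrow(grid), 231)
  for (i in seq_len(nrow(grid))) {
    p <- stats::setNames(grid[i, ], c("A", "B", "C"))
    if (sum(p) > 0) p <- p / sum(p)
    expect_equal(classify_culture(p)$category, oracle_classify(p),
                 info = paste(p, collapse = "/"))
  }
})

test_that("vectorised experiment classification matches per-culture calls", {
  counts <- make_counts(
    w1 = c(A = 9500, B = 300, C = 200),   # monoculture
    w2 = c(A = 6000, B = 3600, C = 400),  # mixed, members A+B
    w3 = c(A = 4500, B = 3500, C = 2000), # no dominant
    w4 = c(A = 0, B = 0, C = 0),          # no amplification
    ctl = c(A = 0, B = 0, C = 0)
  )
  meta <- tibble::tibble(sample_id = c(paste0("w", 1:4), "ctl"),
                         role = c(rep("culture", 4), "control"),
                         experiment = "E1",
                         cells_per_well = c(rep(5, 4), NA))
  calls <- classify_cultures(counts, meta)
  expect_equal(nrow(calls), 4)  # control excluded
  expect_equal(calls$category,
               c("monoculture", "mixed", "no_dominant", "no_amplification"))
  expect_equal(category_tally(calls)$n, c(1L, 1L, 1L, 1L))
  expect_equal(calls$members[[2]]$asv_id, c("A", "B"))
  # agrees with the scalar classifier on every culture
  prop <- relative_abundance(counts[1:4, ])
  for (i in 1:4) {
    p <- unlist(prop[i, -1])
    expect_equal(calls$category[i], classify_culture(p)$category)
  }
})

test_that("member lists never include ASVs below the minor threshold", {
  set.seed(202)
  for (rep in 1:50) {
    p <- as.vector(stats::rmultinom(1, 1000, runif(4))) / 1000
    names(p) <- c("A", "B", "C", "D")
    call <- classify_culture(p)
    if (call$n_members > 0) {
      expect_true(all(call$members[[1]]$proportion >= 0.05))
    }
  }
})

test_that("all-zero plates classify as no_amplification", {
  counts <- make_counts(w1 = c(A = 0), w2 = c(A = 0))
  calls <- classify_cultures(counts)
  expect_true(all(calls$category == "no_amplification"))
  expect_error(classify_cultures(counts[0, ]), "no culture samples")
})

test_that("noiseless single-founder wells all classify as monocultures", {
  comm <- toy_community(abundance = c(0.6, 0.4), viability = c(0.05, 0.05),
                        ids = c("A", "B"))
  des <- htc_design(400, 1, depth_sd = 0, depth_mean = 20000,
                    depth_min = 679, depth_max = 57557, contamination = 0)
  wells <- simulate_wells(comm, des, seed = 21)
  pure <- rowSums(as.matrix(wells[, c("A", "B")]) > 0) == 1
  reads <- simulate_reads(wells, comm, des, seed = 21)
  calls <- classify_cultures(reads)
  expect_true(all(calls$category[pure] == "monoculture"))
  expect_true(all(calls$category[!wells$positive] == "no_amplification"))
})

test_that("contaminated controls trigger a warning", {
  counts <- make_counts(w1 = c(A = 5000), ctl = c(A = 400))
  meta <- tibble::tibble(sample_id = c("w1", "ctl"),
                         role = c("culture", "control"),
                         experiment = "E1", cells_per_well = c(5, NA))
  expect_warning(classify_cultures(counts, meta), "contamination")
})

test_that("isolate registry numbering is sequential and deterministic", {
  counts <- make_counts(
    w1 = c(A = 9700, B = 150, C = 150),  # mono -> 1 record
    w2 = c(B = 6000, C = 4000)           # mixed -> 2 records
  )
  calls <- classify_cultures(counts)
  calls$experiment <- "E1"
  reg <- assign_isolate_ids(calls, prefix = "HIMB", start = 1)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$isolate_id, c("HIMB0001", "HIMB0002", "HIMB0003"))
  expect_equal(reg$asv_id, c("A", "B", "C"))  # sample order, then proportion
  expect_identical(reg, assign_isolate_ids(calls, prefix = "HIMB", start = 1))
  # every record's ASV is a member of its source call
  for (i in seq_len(nrow(reg))) {
    call <- calls[calls$sample_id == reg$sample_id[i], ]
    expect_true(reg$asv_id[i] %in% call$members[[1]]$asv_id)
  }
  # no mono/mixed calls -> empty registry
  none <- classify_cultures(make_counts(w1 = c(A = 400, B = 300, C = 300)))
  expect_equal(nrow(assign_isolate_ids(none)), 0)
})
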