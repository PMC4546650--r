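# Demographic cells, age strata, exam matching, and the scan.

test_that("sex x generation yields the 6-cell partition of individuals", {
  coh <- simulate_cohort(30, seed = 14)
  cells <- build_cells(coh$phenotypes)
  expect_length(cells, 6)
  members <- unlist(lapply(cells, `[[`, "members"))
  expect_false(any(duplicated(members)))
  expect_setequal(members, unique(coh$phenotypes$individual_id))

  gcells <- build_cells(coh$phenotypes, axes = "generation")
  expect_length(gcells, 3)
  expect_true(all(vapply(gcells, `[[`, "", "sex") == "both"))

  expect_error(build_cells(coh$phenotypes, axes = "postcode"),
               "unknown stratification axis")
  expect_error(build_cells(coh$phenotypes, axes = character(0)),
               "non-empty")
})

test_that("empty cells are retained and scans skip them with a warning", {
  coh <- simulate_cohort(10, seed = 15)
  ph <- coh$phenotypes[coh$phenotypes$generation != 1, ]
  cells <- build_cells(ph)
  expect_length(cells, 6)
  ns <- vapply(cells, `[[`, 0L, "n")
  expect_equal(sum(ns == 0), 2)  # both generation-1 cells empty
  w <- capture_warnings(
    sc <- scan_cells(ph, coh$genotypes, snps = "rs2479409", cells = cells))
  expect_length(w, 2)  # one warning per skipped empty cell
  expect_match(w, "empty cell", all = TRUE)
  expect_equal(sum(sc$error == "empty cell", na.rm = TRUE), 2)
})

test_that("median-age split partitions members at the cutoff", {
  ph <- data.frame(
    individual_id = c("a", "b", "c", "d"),
    family_id = "f", sex = "M", generation = 3L,
    age_at_biospecimen = c(35, 39, 41, 60),
    exam_index = 1L, age_at_exam = 40, tc_mgdl = 190,
    stringsAsFactors = FALSE)
  cell <- new_cell_for_test(ph$individual_id)
  halves <- split_by_median_age(cell, ph, 40)
  expect_setequal(halves$younger$members, c("a", "b"))
  expect_setequal(halves$older$members, c("c", "d"))

  # cutoff below the minimum age: everyone is older
  halves2 <- split_by_median_age(cell, ph, 30)
  expect_length(halves2$younger$members, 0)
  expect_setequal(halves2$older$members, ph$individual_id)

  ph$age_at_biospecimen <- NA_real_
  expect_error(split_by_median_age(cell, ph, 40), "known age")
})

test_that("unknown biospecimen ages are excluded from strata with a note", {
  ph <- data.frame(
    individual_id = c("a", "b", "c"),
    family_id = "f", sex = "M", generation = 3L,
    age_at_biospecimen = c(35, NA, 45),
    exam_index = 1L, age_at_exam = 40, tc_mgdl = 190,
    stringsAsFactors = FALSE)
  cell <- new_cell_for_test(ph$individual_id)
  expect_message(halves <- split_by_median_age(cell, ph, 40), "excluded")
  expect_setequal(c(halves$younger$members, halves$older$members),
                  c("a", "c"))
})

test_that("default generation-3 older stratum spans the 40-60 range", {
  coh <- simulate_cohort(150, seed = 16)
  ph <- coh$phenotypes
  cells <- build_cells(ph, axes = "generation")
  g3 <- cells[[which(vapply(cells, `[[`, 0, "generation") == 3)]]
  halves <- split_by_median_age(g3, ph, 40)
  ages <- ph$age_at_biospecimen[match(halves$older$members,
                                      ph$individual_id)]
  expect_true(all(ages >= 40))
  expect_gt(mean(ages <= 60), 0.95)  # hardly anyone above 60 in gen 3
})

test_that("exam matching ranks by mean-age distance with stable ties", {
  mk <- function(exam, ages) data.frame(
    individual_id = sprintf("i%d_%d", exam, seq_along(ages)),
    exam_index = exam, age_at_exam = ages)
  target <- data.frame(individual_id = "t", exam_index = 1,
                       age_at_exam = 50.1)
  b <- rbind(mk(1, c(48.0, 49.2)),   # mean 48.6
             mk(2, c(51.0, 51.8)),   # mean 51.4
             mk(3, c(54.0, 56.0)))   # mean 55.0
  m <- match_age_cohorts(target, b)
  expect_equal(m$ranking$exam_index, c(2, 1, 3))
  expect_equal(m$selected, 2)
  expect_equal(m$ranking$within_window, c(TRUE, TRUE, FALSE))

  # single exam is selected outright (far from target, hence the warning)
  m1 <- suppressWarnings(match_age_cohorts(target, mk(4, c(60, 62))))
  expect_equal(m1$selected, 4)

  # identical means tie-break toward the lower exam index
  b2 <- rbind(mk(2, c(50, 52)), mk(5, c(49, 53)))
  m2 <- match_age_cohorts(target, b2)
  expect_equal(m2$selected, 2)

  expect_warning(match_age_cohorts(target, mk(1, c(90, 95))),
                 "within")
})

test_that("significance classes are a pure threshold function", {
  p <- c(0.01, 0.05, 0.050001, 0.1, 0.100001, 0.9, NA)
  cls <- classify_significance(p)
  expect_equal(cls, c("significant", "significant", "suggestive",
                      "suggestive", "null", "null", NA))
  expect_identical(classify_significance(p), cls)  # idempotent inputs
  expect_error(classify_significance(0.5, c(significant = 0.2,
                                            suggestive = 0.1)),
               "below")
})

test_that("a scan equals independent per-cell fits", {
  coh <- simulate_cohort(60, model = "generation_clustered", seed = 17)
  cells <- build_cells(coh$phenotypes)
  sc <- scan_cells(coh$phenotypes, coh$genotypes,
                   snps = c("rs2479409", "rs1800562"), cells = cells)
  for (i in sample(nrow(sc), 4)) {
    row <- sc[i, ]
    cell <- cells[[which(vapply(cells, `[[`, "", "label") == row$cell)]]
    sub <- coh$phenotypes[coh$phenotypes$individual_id %in% cell$members, ]
    ref <- fit_additive_baseline(sub, coh$genotypes, row$snp_id,
                                 covariates = c("age", "wga"),
                                 cell = cell$label)
    expect_identical(row$beta, ref$beta)
    expect_identical(row$se, ref$se)
  }
})

test_that("fit failures are recorded per scan entry and the scan continues", {
  coh <- simulate_cohort(40, seed = 18)
  geno <- coh$genotypes
  geno[, "rs1800961"] <- 0L  # monomorphic -> per-entry degenerate error
  cells <- build_cells(coh$phenotypes)
  sc <- scan_cells(coh$phenotypes, geno,
                   snps = c("rs2479409", "rs1800961"), cells = cells)
  bad <- sc[sc$snp_id == "rs1800961", ]
  good <- sc[sc$snp_id == "rs2479409", ]
  expect_true(all(grepl("degenerate", bad$error)))
  expect_true(all(is.na(good$error)))
  expect_true(all(is.finite(good$p_value)))
})
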