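# Synthetic three-generation cohort generator.

test_that("a minimal one-child pedigree has valid structure", {
  ped <- simulate_pedigree(1, offspring = 1, seed = 7)
  expect_equal(sort(table(ped$generation), decreasing = FALSE),
               sort(table(c(1, 1, 2, 2, 3))), ignore_attr = TRUE)
  expect_equal(nrow(ped), 5)  # couple + child + spouse + grandchild
  founders <- is.na(ped$father_id) & is.na(ped$mother_id)
  expect_equal(sum(founders), 3)  # 2 gen-1 founders + 1 married-in spouse
  expect_silent(validate_pedigree(ped))
  kid <- ped[ped$generation == 3, ]
  expect_true(all(c(kid$father_id, kid$mother_id) %in%
                    ped$id[ped$generation == 2]))
})

test_that("birth cohorts match the published generation means", {
  ped <- simulate_pedigree(500, offspring = function(n) 1 + rpois(n, 2),
                           seed = 1)
  g2 <- ped$birth_year[ped$generation == 2]
  expect_gt(mean(g2), 1937 - 2)
  expect_lt(mean(g2), 1937 + 2)
  g1m <- ped$birth_year[ped$generation == 1 & ped$sex == "M"]
  expect_gt(mean(g1m), 1911 - 2)
  expect_lt(mean(g1m), 1911 + 2)
})

test_that("identical seeds give byte-identical cohorts", {
  a <- simulate_cohort(30, model = "antagonistic", seed = 42)
  b <- simulate_cohort(30, model = "antagonistic", seed = 42)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_cohort(30, model = "antagonistic", seed = 43)
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("non-positive n_families and bad MAFs are rejected", {
  expect_error(simulate_pedigree(0), "positive")
  ped <- simulate_pedigree(2, seed = 1)
  expect_error(simulate_genotypes(ped, data.frame(snp_id = "s", maf = 0.6)),
               "maf")
  expect_error(simulate_genotypes(ped, data.frame(snp_id = "s", maf = 0)),
               "maf")
})

test_that("Mendelian transmission forces homozygous-parent offspring", {
  ped <- simulate_pedigree(40, seed = 5)
  geno <- simulate_genotypes(ped, data.frame(snp_id = "s1", maf = 0.5),
                             seed = 9)
  fa <- geno[match(ped$father_id, rownames(geno)), 1]
  mo <- geno[match(ped$mother_id, rownames(geno)), 1]
  child <- geno[ped$id, 1]
  both0 <- which(!is.na(fa) & fa == 0 & mo == 0)
  both2 <- which(!is.na(fa) & fa == 2 & mo == 2)
  expect_true(length(both0) > 0 && all(child[both0] == 0))
  expect_true(length(both2) > 0 && all(child[both2] == 2))
})

test_that("every simulated trio is Mendelian-consistent", {
  coh <- simulate_cohort(100, seed = 11)
  ped <- coh$pedigree
  geno <- coh$genotypes
  has_par <- !is.na(ped$father_id)
  fa <- geno[match(ped$father_id[has_par], rownames(geno)), , drop = FALSE]
  mo <- geno[match(ped$mother_id[has_par], rownames(geno)), , drop = FALSE]
  ch <- geno[ped$id[has_par], , drop = FALSE]
  # child dosage must lie between the minimum and maximum transmissible
  lo <- pmax(fa - 1, 0) / 2 + pmax(mo - 1, 0) / 2  # floor of each parent
  min_tx <- (fa == 2) + (mo == 2)
  max_tx <- (fa >= 1) + (mo >= 1)
  expect_true(all(ch >= min_tx & ch <= max_tx))
})

test_that("founder genotypes are in Hardy-Weinberg equilibrium", {
  ped <- unrelated_pedigree(2000)
  for (seed in 1:3) {
    geno <- simulate_genotypes(ped, data.frame(snp_id = "s", maf = 0.34),
                               seed = seed)
    dos <- geno[, 1]
    maf_hat <- mean(dos) / 2
    expect_gt(maf_hat, 0.32)
    expect_lt(maf_hat, 0.36)
    p <- mean(dos) / 2
    exp_counts <- 2000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(dos + 1, 3)
    chi2 <- sum((obs - exp_counts)^2 / exp_counts)
    expect_gt(pchisq(chi2, df = 1, lower.tail = FALSE), 0.001)
  }
})

test_that("noise-free phenotypes reproduce cell intercepts exactly", {
  coh <- simulate_cohort(10, seed = 2)
  m0 <- scenario_library("homogeneous", beta = 0,
                         varcomp = c(family = 0, subject = 0, residual = 0),
                         age_slope = 0)
  ph <- simulate_phenotypes(coh$pedigree, coh$genotypes, m0, seed = 3)
  ic <- m0$intercepts
  expected <- 10^(ic$intercept[match(paste(ph$generation, ph$sex),
                                     paste(ic$generation, ic$sex))] / 100)
  expect_equal(ph$tc_mgdl, expected, tolerance = 1e-12)
})

test_that("calibrated intercepts reproduce published cohort TC means", {
  # 900 families give ~1800 generation-3 men
  coh <- simulate_cohort(900, model = scenario_library("homogeneous",
                                                       beta = 0),
                         seed = 1,
                         offspring = function(n) 1 + rpois(n, 1))
  ph <- coh$phenotypes
  base <- ph[ph$exam_index == 1 & ph$generation == 3 & ph$sex == "M", ]
  expect_gt(nrow(base), 1500)
  expect_gt(mean(base$tc_mgdl), 192.8 - 2)
  expect_lt(mean(base$tc_mgdl), 192.8 + 2)
})

test_that("family variance induces within-family phenotype correlation", {
  m <- scenario_library("homogeneous", beta = 0,
                        varcomp = c(family = 30, subject = 15,
                                    residual = 27))
  snps <- data.frame(snp_id = "s", maf = 0.3)
  coh <- simulate_cohort(500, model = m, snps = snps, seed = 6)
  ph <- coh$phenotypes
  subj <- aggregate(tc_mgdl ~ individual_id + family_id, ph, mean)
  subj$y <- transform_tc(subj$tc_mgdl)
  # correlation of sibling-style pairs vs randomly permuted pairing
  fams <- split(subj$y, subj$family_id)
  fams <- fams[lengths(fams) >= 2]
  pair <- t(vapply(fams, function(v) v[1:2], numeric(2)))
  r_within <- cor(pair[, 1], pair[, 2])
  set.seed(1)
  r_perm <- cor(pair[, 1], sample(pair[, 2]))
  expect_gt(r_within, 0)
  expect_gt(r_within, r_perm + 0.05)
})

test_that("the scenario library encodes the documented effect patterns", {
  hom <- scenario_library("homogeneous", beta = 1.5)
  expect_true(all(hom$effects$beta == 1.5))
  expect_true(all(hom$effects$sex == "both" & hom$effects$generation == 0))

  gc <- scenario_library("generation_clustered", beta = 2)
  g3 <- gc$effects[gc$effects$generation == 3, ]
  rest <- gc$effects[gc$effects$generation == 0, ]
  expect_true(all(g3$beta == 2) && all(rest$beta == 0))

  ant <- scenario_library("antagonistic", beta = 2)
  young3 <- ant$effects[ant$effects$generation == 3 &
                          ant$effects$age_stratum == "younger", ]
  others <- ant$effects[ant$effects$age_stratum == "all", ]
  expect_true(all(young3$beta == -2) && all(others$beta == 2))

  expect_error(scenario_library("no_such_pattern"), "unknown scenario")
})

test_that("missing effect-model cells raise a configuration error", {
  coh <- simulate_cohort(5, seed = 8)
  m <- scenario_library("homogeneous")
  m$intercepts <- m$intercepts[m$intercepts$generation != 3, ]
  expect_error(simulate_phenotypes(coh$pedigree, coh$genotypes, m,
                                   seed = 1),
               "lacks intercepts")
})
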