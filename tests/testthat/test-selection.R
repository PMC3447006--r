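test_that("truncation keeps the earliest plants, one per maternal family", {
  # singleton families: plain truncation
  set.seed(31)
  cohort <- manual_cohort(phenotype = sample(1:30))
  sel <- truncation_select(cohort, 24)
  expect_equal(sort(sel$info$phenotype), 1:24)
  expect_lte(mean(sel$info$phenotype), mean(cohort$info$phenotype))

  # ranks 1 and 2 are maternal sibs: rank 2 is skipped, rank 25 promoted
  fam <- as.character(seq_len(30))
  fam[2] <- fam[1]
  cohort2 <- manual_cohort(phenotype = 1:30, family = fam)
  sel2 <- truncation_select(cohort2, 24)
  expect_false(2 %in% sel2$info$phenotype)
  expect_true(25 %in% sel2$info$phenotype)
  expect_equal(nrow(sel2$info), 24)

  # sterile plants are never eligible
  cohort3 <- manual_cohort(phenotype = 1:30, fertile = c(FALSE, rep(TRUE, 29)))
  sel3 <- truncation_select(cohort3, 5)
  expect_false(1 %in% sel3$info$phenotype)

  expect_error(truncation_select(manual_cohort(1:10), 11),
    class = "ploidysel_error_insufficient"
  )
  # more fertile plants than M but too few distinct families
  cohort4 <- manual_cohort(phenotype = 1:30, family = rep(c("a", "b"), 15))
  expect_error(truncation_select(cohort4, 3),
    class = "ploidysel_error_insufficient"
  )
})

test_that("selected-set mean never exceeds the fertile cohort mean", {
  set.seed(32)
  for (i in 1:20) {
    cohort <- manual_cohort(
      phenotype = stats::rnorm(60, 45, 4),
      family = sample(letters, 60, replace = TRUE),
      fertile = stats::runif(60) > 0.2
    )
    fert <- cohort$info$fertile
    sel <- try(truncation_select(cohort, 12), silent = TRUE)
    if (inherits(sel, "try-error")) next
    expect_lte(mean(sel$info$phenotype), mean(cohort$info$phenotype[fert]))
  }
})

test_that("crossing designs have the published pair counts and regularity", {
  ids24 <- paste0("p", 1:24)
  set.seed(33)
  d1 <- crossing_design(ids24, k = 3)
  expect_equal(nrow(d1), 36)
  deg <- table(c(d1$a, d1$b))
  expect_true(all(deg == 3))
  expect_true(all(d1$a != d1$b))
  # no duplicated couple
  key <- apply(cbind(pmin(d1$a, d1$b), pmax(d1$a, d1$b)), 1, paste, collapse = "|")
  expect_false(any(duplicated(key)))

  d2 <- crossing_design(paste0("q", 1:20), k = 4)
  expect_equal(nrow(d2), 40)
  expect_true(all(table(c(d2$a, d2$b)) == 4))

  d3 <- crossing_design(c("x", "y"), k = 1)
  expect_equal(nrow(d3), 1)
})

test_that("relatives are never paired and impossible designs error", {
  # two full-sib clusters of 3 within 8 selected parents
  ped <- ped_build(
    id = c("dA", "sA", "dB", "sB", paste0("a", 1:3), paste0("b", 1:3), "u1", "u2"),
    dam = c(rep("0", 4), rep("dA", 3), rep("dB", 3), "0", "0"),
    sire = c(rep("0", 4), rep("sA", 3), rep("sB", 3), "0", "0"),
    generation = c(rep(0, 4), rep(1, 8))
  )
  sel <- c(paste0("a", 1:3), paste0("b", 1:3), "u1", "u2")
  set.seed(34)
  for (i in 1:10) {
    d <- crossing_design(sel, k = 3, ped = ped)
    sib <- function(x) substr(x, 1, 1)
    related <- sib(d$a) == sib(d$b) & sib(d$a) %in% c("a", "b")
    expect_false(any(related))
  }
  # two full sibs alone cannot be paired with non-relatives
  expect_error(
    crossing_design(c("a1", "a2"), k = 1, ped = ped, max_tries = 20),
    class = "ploidysel_error_no_design"
  )
})

test_that("a generation advances with the configured family structure", {
  arch <- calibrate_architecture(0.40, "diploid")
  set.seed(35)
  base <- found_base_population(arch, 113, 2, ploidy = 2)
  sel <- truncation_select(base, 24)
  pairs <- crossing_design(sel, 3)
  g1 <- advance_generation(pairs, sel, arch, generation = 1, line = "D1", mortality = 0)
  expect_equal(nrow(g1$info), 144)
  expect_equal(length(unique(g1$info$maternal_family)), 36)
  expect_true(all(g1$info$dam %in% sel$info$id))
  expect_true(all(g1$info$sire %in% sel$info$id))
  expect_true(all(g1$info$dam != g1$info$sire))

  # total mortality leaves nothing to select from
  g_dead <- advance_generation(pairs, sel, arch, generation = 1, line = "D1", mortality = 1)
  expect_equal(nrow(g_dead$info), 0)
  expect_error(truncation_select(g_dead, 24), class = "ploidysel_error_insufficient")

  # binomial thinning at the default mortality keeps family counts in range
  set.seed(36)
  fams <- replicate(30, {
    g <- advance_generation(pairs, sel, arch, generation = 1, line = "D1", mortality = 0.1)
    length(unique(g$info$maternal_family))
  })
  expect_gte(mean(fams >= 27 & fams <= 36), 0.95)
})
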