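test_that("path-method F reproduces classical closed forms", {
  # founders and outbred individuals
  ped <- ped_build(
    id = c("a", "b", "x"), dam = c("0", "0", "a"), sire = c("0", "0", "b"),
    generation = c(0, 0, 1)
  )
  expect_identical(inbreeding_coefficient(ped, "a"), 0)
  expect_identical(inbreeding_coefficient(ped, "x"), 0)

  # offspring of full sibs: two paths of (1/2)^3
  fs <- ped_build(
    id = c("a", "b", "s1", "s2", "x"),
    dam = c("0", "0", "a", "a", "s1"),
    sire = c("0", "0", "b", "b", "s2"),
    generation = c(0, 0, 1, 1, 2)
  )
  expect_equal(inbreeding_coefficient(fs, "x"), 0.25)

  # offspring of parent-offspring mating: one path, (1/2)^2
  po <- ped_build(
    id = c("a", "b", "c", "x"),
    dam = c("0", "0", "a", "c"), sire = c("0", "0", "b", "a"),
    generation = c(0, 0, 1, 2)
  )
  expect_equal(inbreeding_coefficient(po, "x"), 0.25)

  # inbred common ancestor: offspring of half sibs through an inbred dam
  # F_x = (1/2)^3 * (1 + F_A) with F_A = 0.25
  ia <- ped_build(
    id = c("a", "b", "s1", "s2", "A", "m", "c1", "c2", "x"),
    dam = c("0", "0", "a", "a", "s1", "0", "A", "A", "c1"),
    sire = c("0", "0", "b", "b", "s2", "0", "m", "m", "c2"),
    generation = c(0, 0, 1, 1, 2, 0, 3, 3, 4)
  )
  expect_equal(inbreeding_coefficient(ia, "A"), 0.25)
  # c1 x c2 are full sibs via A and m: 2 paths (1+F_A)/8 and (1+0)/8
  expect_equal(inbreeding_coefficient(ia, "x"), (1 + 0.25) / 8 + 1 / 8)
})

test_that("half-first-cousin offspring match the gene-dropping oracle", {
  # g, h are maternal half sibs (shared dam gm); their children c1, c2 are
  # half first cousins; x is their offspring. Closed form F = 1/32.
  ped <- ped_build(
    id = c("gm", "s1", "s2", "g", "h", "u1", "u2", "c1", "c2", "x"),
    dam = c("0", "0", "0", "gm", "gm", "0", "0", "g", "h", "c1"),
    sire = c("0", "0", "0", "s1", "s2", "0", "0", "u1", "u2", "c2"),
    generation = c(0, 0, 0, 1, 1, 1, 1, 2, 2, 3)
  )
  f_path <- inbreeding_coefficient(ped, "x")
  expect_equal(f_path, 1 / 32)
  set.seed(77)
  n_drops <- 1e5
  f_drop <- gene_drop_F(ped, "x", n_drops = n_drops)
  se <- sqrt(f_path * (1 - f_path) / n_drops)
  expect_lt(abs(f_drop - f_path), 3 * se)
})

test_that("path F agrees with gene dropping across a simulated pedigree", {
  arch <- calibrate_architecture(0.4, "diploid")
  set.seed(402)
  rec <- run_experiment(mini_diploid_design(), arch, seed = 31)
  ped <- rec$pedigree
  expect_lte(nrow(ped), 1000)
  finals <- ped$id[ped$generation == max(ped$generation)]
  set.seed(403)
  for (id in sample(finals, 4)) {
    f_path <- inbreeding_coefficient(ped, id)
    f_drop <- gene_drop_F(ped, id, n_drops = 1e5)
    se <- sqrt(max(f_path * (1 - f_path), 1e-6) / 1e5)
    expect_lt(abs(f_drop - f_path), 3 * se)
  }
})

test_that("F is invariant to record order and id relabeling", {
  ped <- ped_build(
    id = c("a", "b", "s1", "s2", "x"),
    dam = c("0", "0", "a", "a", "s1"),
    sire = c("0", "0", "b", "b", "s2"),
    generation = c(0, 0, 1, 1, 2)
  )
  shuffled <- pedigree(as.data.frame(ped)[c(5, 3, 1, 4, 2), ])
  expect_equal(inbreeding_coefficient(shuffled, "x"), 0.25)

  relabeled <- as.data.frame(ped)
  map <- c(a = "Z9", b = "Q2", s1 = "K1", s2 = "K2", x = "W0")
  for (col in c("id", "dam", "sire")) {
    hit <- relabeled[[col]] %in% names(map)
    relabeled[[col]][hit] <- map[relabeled[[col]][hit]]
  }
  expect_equal(inbreeding_coefficient(pedigree(relabeled), "W0"), 0.25)

  # adding unrelated individuals never changes existing F
  extra <- rbind(as.data.frame(ped), data.frame(
    id = c("u1", "u2", "u3"), dam = c("0", "0", "u1"),
    sire = c("0", "0", "u2"), maternal_family = "U", line = "L",
    generation = c(0, 0, 1), ploidy = 2, fertile = TRUE
  ))
  expect_equal(inbreeding_coefficient(pedigree(extra), "x"), 0.25)
})

test_that("relative queries match ancestor-set intersection", {
  ped <- ped_build(
    id = c("d", "s1", "s2", "k1", "k2", "lone"),
    dam = c("0", "0", "0", "d", "d", "0"),
    sire = c("0", "0", "0", "s1", "s2", "0"),
    generation = c(0, 0, 0, 1, 1, 0)
  )
  expect_false(are_relatives(ped, "d", "lone"))
  expect_true(are_relatives(ped, "d", "k1", max_depth = 1)) # parent-child
  expect_true(are_relatives(ped, "k1", "k2", max_depth = 1)) # maternal half sibs
  expect_false(are_relatives(ped, "k1", "lone"))
  expect_error(are_relatives(ped, "k1", "ghost"), class = "ploidysel_error_unknown_id")
  expect_error(are_relatives(ped, "k1", "k2", max_depth = 0),
    class = "ploidysel_error_bad_argument"
  )
})

test_that("mean line inbreeding averages individual F values", {
  founders <- ped_build(
    id = c("a", "b", "c"), dam = "0", sire = "0", generation = 0,
    line = "D1"
  )
  expect_equal(mean_line_inbreeding(founders, "D1", 0, fertile_only = FALSE), 0)
  expect_error(mean_line_inbreeding(founders, "D9", 0),
    class = "ploidysel_error_empty_selection"
  )

  # line of four: two outbred, two full-sib offspring with F = 0.25
  ped <- ped_build(
    id = c("a", "b", "s1", "s2", "x1", "x2", "y1", "y2"),
    dam = c("0", "0", "a", "a", "s1", "s1", "0", "0"),
    sire = c("0", "0", "b", "b", "s2", "s2", "0", "0"),
    generation = c(0, 0, 1, 1, 2, 2, 2, 2),
    line = c("L", "L", "L", "L", "D1", "D1", "D1", "D1")
  )
  expect_equal(mean_line_inbreeding(ped, "D1", 2, fertile_only = FALSE), 0.125)
})

test_that("the small neotetraploid founder pool accumulates more inbreeding", {
  arch_d <- calibrate_architecture(0.4, "diploid")
  arch_n <- calibrate_architecture(0.4, "neotetraploid")
  set.seed(404)
  f_d <- c()
  f_n <- c()
  for (s in c(21, 22, 23)) {
    rec_d <- run_experiment(design_diploid(), arch_d, seed = s)
    rec_n <- run_experiment(design_neotetraploid(), arch_n, seed = s)
    f_d <- c(f_d, vapply(
      c("D1", "D2", "DC"),
      function(ln) mean_line_inbreeding(rec_d$pedigree, ln, 4), numeric(1)
    ))
    f_n <- c(f_n, vapply(
      c("N1", "N2", "NC"),
      function(ln) mean_line_inbreeding(rec_n$pedigree, ln, 4), numeric(1)
    ))
  }
  expect_gt(mean(f_n), mean(f_d))
})
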