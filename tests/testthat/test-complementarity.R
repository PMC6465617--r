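test_that("module integrity is the matched fraction of required KOs", {
  expect_equal(module_integrity(c("k1", "k2", "k3", "k4"),
                                c("k1", "k2", "k3", "k4")), 1)
  expect_equal(module_integrity(c("k1", "k2"), c("k1", "k2", "k3", "k4")), 0.5)
  expect_equal(module_integrity(c("x1", "x2"), c("k1", "k2")), 0)
  expect_error(module_integrity("k1", character(0)), "empty required")
})

test_that("pair complementarity follows the merged-KO definition", {
  mods <- list(M1 = c("k1", "k2", "k3", "k4"))
  pc <- pair_complementarity(c("k1", "k2"), c("k3", "k4"), mods)
  expect_equal(pc$total_a, 0.5)
  expect_equal(pc$total_merged, 1)
  expect_equal(pc$improvement_ratio, 1)
  # identical KO sets improve nothing
  expect_equal(pair_complementarity(c("k1", "k2"), c("k1", "k2"),
                                    mods)$improvement_ratio, 0)
  # empty-vs-empty is 0, not NaN; one-sided content is flagged infinite
  expect_equal(pair_complementarity(character(0), character(0),
                                    mods)$improvement_ratio, 0)
  inf <- pair_complementarity(character(0), character(0),
                              list(M1 = c("k1")), baseline = "max")
  expect_equal(inf$improvement_ratio, 0)
  inf2 <- pair_complementarity("k1", character(0), list(M1 = "k1"))
  expect_equal(inf2$improvement_ratio, 0)  # merged equals the better genome
})

test_that("complementarity matches the union oracle and is symmetric", {
  set.seed(71)
  for (i in 1:60) {
    n_mod <- sample(1:8, 1)
    universe <- sprintf("K%05d", 1:60)
    mods <- lapply(seq_len(n_mod), function(m)
      sample(universe, sample(2:8, 1)))
    names(mods) <- paste0("M", seq_len(n_mod))
    a <- sample(universe, sample(0:30, 1))
    b <- sample(universe, sample(0:30, 1))
    pc <- pair_complementarity(a, b, mods)
    expect_equal(pc$improvement_ratio, oracle_complementarity(a, b, mods),
                 tolerance = 1e-12, info = paste("instance", i))
    pc_rev <- pair_complementarity(b, a, mods)
    expect_equal(pc$improvement_ratio, pc_rev$improvement_ratio,
                 tolerance = 1e-12)
    # merged integrity dominates both singles (monotone under union)
    expect_gte(pc$total_merged, max(pc$total_a, pc$total_b) - 1e-12)
  }
})

test_that("cross-species pair enumeration matches the count identity", {
  sp <- setNames(c("A", "A", "B", "B", "B"), paste0("g", 1:5))
  pr <- enumerate_cross_species_pairs(sp)
  expect_equal(nrow(pr), 6)
  expect_equal(attr(pr, "n_pairs"), 6)
  expect_true(all(pr$species_a != pr$species_b))
  # single species: no pairs
  one <- enumerate_cross_species_pairs(setNames(rep("A", 4), paste0("g", 1:4)))
  expect_equal(nrow(one), 0)
  # identity C(N,2) - sum C(n_s,2) against an explicit double loop
  set.seed(83)
  for (i in 1:20) {
    sizes <- sample(1:8, sample(2:6, 1), replace = TRUE)
    lab <- rep(paste0("s", seq_along(sizes)), sizes)
    names(lab) <- paste0("g", seq_along(lab))
    pr_i <- enumerate_cross_species_pairs(lab)
    brute <- 0L
    for (a in seq_along(lab)) for (b in seq_along(lab)) {
      if (a < b && lab[a] != lab[b]) brute <- brute + 1L
    }
    expect_equal(nrow(pr_i), brute)
    expect_equal(attr(pr_i, "n_pairs"), brute)
  }
})

test_that("species-pair summary ranks means descending with terciles", {
  set.seed(17)
  species <- setNames(rep(c("A", "B", "C"), each = 2), paste0("g", 1:6))
  kos <- list()
  mods <- list(M1 = c("k1", "k2"), M2 = c("k3", "k4"))
  # construct strain KO sets so that species-pair means differ
  kos[["g1"]] <- c("k1", "k3"); kos[["g2"]] <- c("k1", "k3")
  kos[["g3"]] <- c("k2", "k4"); kos[["g4"]] <- c("k2", "k4")
  kos[["g5"]] <- c("k1", "k2", "k3", "k4"); kos[["g6"]] <- kos[["g5"]]
  tab <- cross_species_complementarity(kos, species, mods)
  summ <- species_pair_summary(tab)
  expect_equal(nrow(summ), 3)  # C(3,2) species pairs
  expect_equal(summ$rank, 1:3)
  expect_true(all(diff(summ$mean_ratio) <= 0))
  # A+B merge disjoint halves -> ratio 1; anything with C -> ratio 0
  expect_equal(summ$pair[1], "A + B")
  expect_equal(summ$mean_ratio[1], 1)
  expect_equal(summ$tercile, c("top", "middle", "last"))
  # direct mean check
  ab <- tab$improvement_ratio[(tab$species_a == "A" & tab$species_b == "B") |
                                (tab$species_a == "B" & tab$species_b == "A")]
  expect_equal(summ$mean_ratio[summ$pair == "A + B"], mean(ab))
})

test_that("planted complementarity ratios are recovered exactly", {
  targets <- c(0, 0.25, 1 / 3, 0.5, 1)
  for (tr in targets) {
    kp <- sim_ko_pair(n_modules = 12, module_size = 4, target_ratio = tr,
                      seed = round(100 * tr) + 1)
    pc <- pair_complementarity(kp$kos_a, kp$kos_b, kp$modules)
    expect_equal(pc$improvement_ratio, tr, tolerance = 1e-12,
                 info = paste("target", tr))
    expect_equal(oracle_complementarity(kp$kos_a, kp$kos_b, kp$modules), tr,
                 tolerance = 1e-12)
  }
  expect_error(sim_ko_pair(2, 4, 0.123, seed = 1), "not achievable")
})

test_that("complementarity-distance correlation has the expected sign", {
  # perfectly anti-monotone linear inputs
  ani <- c(99, 97, 95, 93, 91)
  ratio <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  cc <- complementarity_ani_correlation(ratio, ani)
  expect_equal(cc$cc, -1, tolerance = 1e-12)
  # hand 4-point example equals the closed-form oracle
  x <- c(0.1, 0.35, 0.2, 0.6); y <- c(96, 91, 94, 88)
  cc2 <- complementarity_ani_correlation(x, y)
  expect_equal(cc2$cc, oracle_pearson(x, y), tolerance = 1e-12)
})
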