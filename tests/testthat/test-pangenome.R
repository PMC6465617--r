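test_that("family membership follows the identity and coverage thresholds", {
  set.seed(31)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  base <- paste(sample(aa, 100, replace = TRUE), collapse = "")
  # two identical proteins cluster together
  fam <- cluster_gene_families(list(G1 = c(gA = base), G2 = c(gB = base)))
  expect_equal(length(unique(fam$family_id)), 1)
  # ~80% identity is below the 95% threshold: two families
  v <- strsplit(base, "")[[1]]
  pos <- sample(100, 20)
  for (p in pos) v[p] <- sample(setdiff(aa, v[p]), 1)
  far <- paste(v, collapse = "")
  fam2 <- cluster_gene_families(list(G1 = c(gA = base), G2 = c(gB = far)))
  expect_equal(length(unique(fam2$family_id)), 2)
  # 100-aa protein identical to the first 80 aa of a 200-aa representative:
  # coverage 80% of the shorter sequence < 90% -> new family
  long <- paste(sample(aa, 200, replace = TRUE), collapse = "")
  short <- substr(long, 1, 80)
  short <- paste0(short, paste(sample(aa, 20, replace = TRUE), collapse = ""))
  # ensure the tail does not extend the alignment by chance: make it dissimilar
  fam3 <- cluster_gene_families(list(G1 = c(gA = long), G2 = c(gB = short)))
  expect_equal(length(unique(fam3$family_id)), 2)
  expect_error(cluster_gene_families(list()), "named per-genome list")
})

test_that("greedy clustering matches the brute-force oracle", {
  for (i in 1:25) {
    prot <- random_protein_instance(n_seq = sample(6:30, 1), seed = 100 + i)
    fam <- cluster_gene_families(prot)
    oracle <- oracle_cluster(prot)
    expect_true(partition_equal(family_partition(fam), oracle),
                info = paste("instance", i))
  }
})

test_that("every gene lands in exactly one family", {
  sim <- sim_pangenome(4, 15, 20, 0.4, seed = 55)
  fam <- cluster_gene_families(sim$proteins)
  expect_equal(nrow(fam), sum(lengths(sim$proteins)))
  expect_equal(sum(table(fam$family_id)), sum(lengths(sim$proteins)))
})

test_that("core/accessory/specific partition the families", {
  fam <- data.frame(
    family_id = c("f1", "f1", "f2", "f3"),
    genome_id = c("A", "B", "A", "B"))
  pg <- pan_genome(fam)
  part <- partition_families(pg)
  expect_equal(part$core, "f1")
  expect_equal(sort(part$specific), c("f2", "f3"))
  expect_length(part$accessory, 0)
  # partition is disjoint and exhaustive on random memberships
  set.seed(6)
  for (i in 1:10) {
    n_g <- sample(2:6, 1); n_f <- sample(3:30, 1)
    m <- matrix(runif(n_g * n_f) < 0.5, n_g, n_f)
    m[1, colSums(m) == 0] <- TRUE
    df <- data.frame(
      family_id = sprintf("f%02d", col(m)[m]),
      genome_id = sprintf("G%d", row(m)[m]))
    pgi <- pan_genome(df)
    p <- partition_families(pgi)
    all_f <- sort(c(p$core, p$accessory, p$specific))
    expect_equal(all_f, sort(unique(df$family_id)))
    expect_equal(length(all_f),
                 length(p$core) + length(p$accessory) + length(p$specific))
  }
})

test_that("rarefaction curves are monotone and flat for identical genomes", {
  fam_flat <- data.frame(
    family_id = rep(c("f1", "f2", "f3"), 3),
    genome_id = rep(c("A", "B", "C"), each = 3))
  rc <- rarefaction_curves(pan_genome(fam_flat), n_permutations = 10, seed = 2)
  expect_equal(rc$pan_mean, rep(3, 3))
  expect_equal(rc$core_mean, rep(3, 3))
  # disjoint gene sets: pan(k) = k * g
  fam_dis <- data.frame(
    family_id = paste0("f", 1:8),
    genome_id = rep(c("A", "B"), each = 4))
  rc2 <- rarefaction_curves(pan_genome(fam_dis), n_permutations = 5, seed = 3)
  expect_equal(rc2$pan_mean, c(4, 8))
  expect_equal(rc2$core_mean, c(4, 0))
  # monotone for arbitrary seeded input
  sim <- sim_pangenome(6, 10, 25, 0.5, seed = 19)
  fam3 <- data.frame(
    family_id = colnames(sim$truth$membership)[col(sim$truth$membership)[sim$truth$membership]],
    genome_id = rownames(sim$truth$membership)[row(sim$truth$membership)[sim$truth$membership]])
  rc3 <- rarefaction_curves(pan_genome(fam3), n_permutations = 20, seed = 4)
  expect_true(all(diff(rc3$pan_mean) >= 0))
  expect_true(all(diff(rc3$core_mean) <= 0))
})

test_that("pan-genome index and openness levels follow the definition", {
  fam_id <- data.frame(family_id = rep(c("f1", "f2", "f3"), 2),
                       genome_id = rep(c("A", "B"), each = 3))
  idx <- pan_genome_index(pan_genome(fam_id))
  expect_equal(idx$pi, 1)
  expect_equal(idx$level, "A")
  # A{a,b,c}, B{a,b,d}: pan 4, mean 3 -> 4/3
  fam2 <- data.frame(family_id = c("a", "b", "c", "a", "b", "d"),
                     genome_id = rep(c("A", "B"), each = 3))
  idx2 <- pan_genome_index(pan_genome(fam2))
  expect_equal(idx2$pi, 4 / 3)
  expect_equal(idx2$level, "A")
  # level boundaries at PI = 1.5 (still A), 3 (still B), > 3 (C)
  fam15 <- data.frame(family_id = c("f1", "f2", "f2", "f3"),
                      genome_id = c("A", "A", "B", "B"))
  expect_equal(pan_genome_index(pan_genome(fam15))$pi, 1.5)
  expect_equal(pan_genome_index(pan_genome(fam15))$level, "A")
  fam30 <- data.frame(family_id = c("f1", "f2", "f3"),
                      genome_id = c("A", "B", "C"))
  expect_equal(pan_genome_index(pan_genome(fam30))$pi, 3)
  expect_equal(pan_genome_index(pan_genome(fam30))$level, "B")
  fam40 <- data.frame(family_id = paste0("f", 1:4),
                      genome_id = c("A", "B", "C", "D"))
  expect_equal(pan_genome_index(pan_genome(fam40))$level, "C")
  expect_equal(pan_genome_index(pan_genome(fam2))$mean_genes_per_genome, 3)
})

test_that("planted pan-genomes yield the closed-form PI exactly", {
  grid <- expand.grid(n = c(3, 6, 10), core = c(5, 20),
                      pool = c(0, 10, 40), rate = c(0.2, 0.6))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sim <- sim_pangenome(g$n, g$core, g$pool, g$rate, seed = 500 + i)
    m <- sim$truth$membership
    pan <- sum(colSums(m) > 0)
    expect_equal(sim$truth$pi, pan / mean(rowSums(m)), tolerance = 1e-12)
    if (g$pool == 0) expect_equal(sim$truth$pi, 1)
  }
  # clustering the generated proteins recovers the planted PI
  sim <- sim_pangenome(5, 12, 18, 0.4, seed = 901)
  fam <- cluster_gene_families(sim$proteins)
  idx <- pan_genome_index(pan_genome(fam, genomes = names(sim$proteins)))
  expect_equal(idx$pi, sim$truth$pi, tolerance = 1e-12)
})

test_that("PI only grows when added genomes bring new families", {
  sim <- sim_pangenome(8, 10, 30, 0.35, seed = 77)
  m <- sim$truth$membership
  pi_of <- function(mm) {
    mm <- mm[, colSums(mm) > 0, drop = FALSE]
    ncol(mm) / mean(rowSums(mm))
  }
  # subsets of identical-size repertoires: growing the union only adds pan
  sub <- pi_of(m[1:4, , drop = FALSE])
  full <- pi_of(m)
  # with homogeneous random accessory sampling, more genomes -> larger pan
  expect_gte(full, sub * 0.999)
})

test_that("openness correlates recover a planted linear relation", {
  set.seed(23)
  src <- c(2, 4, 6, 8, 10, 12, 14)
  pi <- 0.3 * src + 1
  res <- suppressWarnings(openness_correlates(pi, src, rnorm(7), rnorm(7)))
  expect_equal(res$per_factor$r_squared[res$per_factor$factor == "source_count"],
               1, tolerance = 1e-10)
  # 5-point hand example equals the squared closed-form Pearson
  x <- c(1, 3, 4, 7, 9); y <- c(2, 3, 7, 6, 11)
  res2 <- ols_correlates(y, list(x = x))
  expect_equal(res2$per_factor$r_squared[1], oracle_pearson(x, y)^2,
               tolerance = 1e-12)
})
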