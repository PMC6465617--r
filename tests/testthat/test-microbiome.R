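test_that("planted abundance shifts are called with the right direction", {
  sim <- sim_abundance(n_case = 50, n_control = 50, n_species = 60,
                       n_enriched = 6, effect_fold = 4, block = NULL,
                       seed = 301)
  calls <- differential_enrichment(sim$abundance, sim$groups)
  truth <- sim$truth$enriched
  got <- calls$direction[match(names(truth), calls$species)]
  expect_true(all(got == truth))
  expect_true(all(calls$q >= calls$p - 1e-15))
})

test_that("identical groups yield no enrichment calls", {
  set.seed(12)
  ab <- matrix(rexp(30 * 40), nrow = 30,
               dimnames = list(paste0("s", 1:30), paste0("S", 1:40)))
  ab <- rbind(ab, zero_sp = 0)
  groups <- setNames(rep(c("case", "control"), 20), colnames(ab))
  # same generating distribution in both groups
  calls <- differential_enrichment(ab, groups)
  expect_true(all(calls$direction == "ns"))
  expect_equal(attr(calls, "skipped"), "zero_sp")
  expect_false("zero_sp" %in% calls$species)
})

test_that("label-permuted null keeps raw positives near 5% and BH near zero", {
  set.seed(99)
  n_sp <- 200
  ab <- matrix(rexp(n_sp * 60), nrow = n_sp,
               dimnames = list(paste0("s", 1:n_sp), paste0("S", 1:60)))
  groups <- setNames(sample(rep(c("case", "control"), 30)), colnames(ab))
  calls <- differential_enrichment(ab, groups)
  raw_rate <- mean(calls$p < 0.05)
  expect_lt(raw_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sp))
  expect_lte(sum(calls$direction != "ns"), 1)
})

test_that("network edges obey the inclusion rule exactly", {
  sim <- sim_abundance(n_case = 60, n_control = 60, n_species = 40,
                       n_enriched = 8, effect_fold = 4,
                       block = list(size = 4, cc = 0.8), seed = 411)
  calls <- differential_enrichment(sim$abundance, sim$groups)
  net <- build_coabundance_network(sim$abundance, calls)
  expect_true(all(net$nodes$species %in%
                    calls$species[calls$direction != "ns"]))
  # recompute every edge from the table: predicate must hold
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    pc <- pearson_cor(sim$abundance[e$a, ], sim$abundance[e$b, ])
    expect_equal(pc$cc, e$cc, tolerance = 1e-12)
    expect_equal(pc$p, e$p, tolerance = 1e-12)
    expect_true(pc$p < 0.05 && (pc$cc > 0.4 || pc$cc < -0.1))
    expect_equal(e$sign, if (e$cc > 0) "positive" else "negative")
  }
  # and no qualifying pair is missing
  sp <- net$nodes$species
  n_edges <- 0L
  for (i in seq_len(length(sp) - 1)) for (j in (i + 1):length(sp)) {
    pc <- pearson_cor(sim$abundance[sp[i], ], sim$abundance[sp[j], ])
    if (!is.na(pc$cc) && pc$p < 0.05 && (pc$cc > 0.4 || pc$cc < -0.1)) {
      n_edges <- n_edges + 1L
    }
  }
  expect_equal(nrow(net$edges), n_edges)
})

test_that("edge width categories bin on |cc| as displayed", {
  sim <- sim_abundance(n_case = 50, n_control = 50, n_species = 30,
                       n_enriched = 6, effect_fold = 4,
                       block = list(size = 3, cc = 0.85), seed = 631)
  calls <- differential_enrichment(sim$abundance, sim$groups)
  net <- build_coabundance_network(sim$abundance, calls)
  for (i in seq_len(nrow(net$edges))) {
    a <- abs(net$edges$cc[i])
    want <- if (a >= 0.7) "thick" else if (a >= 0.4) "medium" else "thin"
    expect_equal(net$edges$width[i], want)
  }
})

test_that("network is invariant to sample and species order", {
  sim <- sim_abundance(n_case = 40, n_control = 40, n_species = 25,
                       n_enriched = 6, effect_fold = 4,
                       block = list(size = 3, cc = 0.8), seed = 55)
  calls <- differential_enrichment(sim$abundance, sim$groups)
  net1 <- build_coabundance_network(sim$abundance, calls)
  set.seed(1)
  perm_s <- sample(ncol(sim$abundance))
  perm_r <- sample(nrow(sim$abundance))
  net2 <- build_coabundance_network(sim$abundance[perm_r, perm_s], calls)
  expect_equal(net1$nodes, net2$nodes)
  expect_equal(net1$edges, net2$edges)
})

test_that("node annotations: decade bins, degree ranks, graphml export", {
  sim <- sim_abundance(n_case = 40, n_control = 40, n_species = 30,
                       n_enriched = 12, effect_fold = 5,
                       block = list(size = 5, cc = 0.85), seed = 77)
  calls <- differential_enrichment(sim$abundance, sim$groups)
  net <- build_coabundance_network(sim$abundance, calls)
  # decade bin consistent with mean abundance
  for (i in seq_len(nrow(net$nodes))) {
    f <- net$nodes$mean_abundance[i] / 100
    if (f >= 0.1) expect_equal(net$nodes$decade_bin[i], "1/10^1")
    if (f < 1e-6) expect_equal(net$nodes$decade_bin[i], "<1/10^6")
  }
  expect_lte(sum(net$nodes$top10_degree), 10)
  expect_lte(sum(net$nodes$top10_abundance), 10)
  # top-10 degree flags pick the stable-sorted head
  ord <- order(-net$nodes$degree, net$nodes$species)
  expect_setequal(net$nodes$species[net$nodes$top10_degree],
                  net$nodes$species[ord[seq_len(min(10, nrow(net$nodes)))]])
  tmp <- tempfile(fileext = ".graphml")
  write_network_graphml(net, tmp)
  expect_true(file.exists(tmp) && file.size(tmp) > 0)
  g <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  unlink(tmp)
})

test_that("metaphlan-style profile parsing keeps species-level rows only", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c(
    "clade_name\tS1\tS2",
    "k__Bacteria\t100\t100",
    "k__Bacteria|p__Firmicutes\t60\t50",
    "k__Bacteria|p__Firmicutes|g__Lactobacillus|s__Lactobacillus_casei\t10\t20",
    "k__Bacteria|p__Firmicutes|g__Lactobacillus|s__Lactobacillus_casei|t__GCF_1\t10\t20",
    "k__Bacteria|p__Actinobacteria|g__Bifidobacterium|s__Bifidobacterium_longum\t5\t2"),
    tmp)
  m <- read_metaphlan_profiles(tmp)
  expect_equal(rownames(m), c("Lactobacillus_casei", "Bifidobacterium_longum"))
  expect_equal(unname(m["Lactobacillus_casei", ]), c(10, 20))
  unlink(tmp)
})

test_that("mapping ratios compare between groups with planted shifts", {
  r05 <- mapping_ratio_compare(c(500, 300), c(1000, 1000),
                               c("case", "control"))
  expect_equal(unname(r05$ratios[1, 1]), 0.5)
  set.seed(9)
  n <- 60
  groups <- rep(c("case", "control"), each = n / 2)
  total <- rep(1e6, n)
  null_m <- cbind(t0 = rbinom(n, 1e6, 0.01))
  shift_m <- cbind(t1 = rbinom(n, 1e6,
                               ifelse(groups == "case", 0.02, 0.01)))
  res <- mapping_ratio_compare(cbind(null_m, shift_m), total, groups)
  expect_gt(res$tests$p[res$tests$target == "t0"], 0.05)
  expect_lt(res$tests$q[res$tests$target == "t1"], 0.01)
  expect_equal(res$tests$direction[res$tests$target == "t1"], "case")
  expect_error(mapping_ratio_compare(10, 5, "case"), "mapped > total")
})
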