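# Seeded generators with planted ground truth for every pipeline input:
# gene repertoires with controlled core/accessory sharing, nucleotide pairs
# at controlled divergence, KO sets with an exactly planted complementarity
# ratio, and abundance tables with planted group effects and a correlated
# species block. Each generator is a pure function of (parameters, seed) and
# returns its realized truth alongside the data.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

random_nt <- function(len) paste(sample(c("A","C","G","T"), len, replace = TRUE),
                                 collapse = "")

# mutate exactly n_mut positions of an amino-acid sequence (to different residues)
mutate_aa <- function(s, n_mut) {
  if (n_mut == 0) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), n_mut)
  for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1)
  paste(v, collapse = "")
}

#' Simulate a pan-genome with planted gene families
#'
#' Every genome carries all `core_size` core families; each of the
#' `accessory_pool` accessory families is included in each genome
#' independently with probability `accessory_rate`. Family ancestor proteins
#' are random amino-acid sequences kept mutually dissimilar (ancestors are
#' resampled until they share no 8-mer with any previous ancestor, keeping
#' inter-family identity far below the 95% clustering threshold); per-genome
#' copies mutate at most 0.5% of residues each, so within-family identity
#' stays at or above 99% and greedy clustering at 95%/90% recovers the
#' planted families exactly.
#'
#' @param n_genomes,core_size,accessory_pool positive integers.
#' @param accessory_rate inclusion probability in \[0, 1\].
#' @param seed RNG seed.
#' @param protein_length_range ancestor length range (residues).
#' @return list with `proteins` (named per-genome character vectors, gene
#'   ids `g<family>` within each genome) and `truth`: generator name, seed,
#'   parameters, `membership` (planted genome-by-family logical matrix),
#'   `pi` (closed-form pan/mean ratio of the planted sets), `family_of_gene`.
#' @export
sim_pangenome <- function(n_genomes, core_size, accessory_pool,
                          accessory_rate, seed = 1L,
                          protein_length_range = c(60L, 120L)) {
  stop_if_not(n_genomes > 0 && core_size > 0 && accessory_pool >= 0,
              "sim_pangenome: sizes must be positive")
  stop_if_not(accessory_rate >= 0 && accessory_rate <= 1,
              "sim_pangenome: rate must be in [0, 1]")
  set.seed(seed)
  n_fam <- core_size + accessory_pool
  fam_ids <- sprintf("fam%04d", seq_len(n_fam))
  # mutually dissimilar ancestors: no shared 8-mer with any previous one
  seen_kmers <- new.env(parent = emptyenv())
  ancestors <- character(n_fam)
  for (i in seq_len(n_fam)) {
    repeat {
      s <- random_aa(sample(protein_length_range[1]:protein_length_range[2], 1))
      ks <- unique(seq_kmers(s, 8L))
      if (!any(vapply(ks, function(k) !is.null(seen_kmers[[k]]), logical(1)))) {
        for (k in ks) seen_kmers[[k]] <- TRUE
        ancestors[i] <- s
        break
      }
    }
  }
  genomes <- sprintf("G%03d", seq_len(n_genomes))
  membership <- matrix(FALSE, n_genomes, n_fam,
                       dimnames = list(genomes, fam_ids))
  membership[, seq_len(core_size)] <- TRUE
  if (accessory_pool > 0) {
    acc <- matrix(stats::runif(n_genomes * accessory_pool) < accessory_rate,
                  n_genomes, accessory_pool)
    membership[, core_size + seq_len(accessory_pool)] <- acc
  }
  proteins <- lapply(genomes, function(g) {
    fams <- which(membership[g, ])
    seqs <- vapply(fams, function(f) {
      len <- nchar(ancestors[f])
      # at most 0.5% of residues per copy: any two copies of one family
      # then stay >= 99% identical
      mutate_aa(ancestors[f], n_mut = floor(0.005 * len))
    }, character(1))
    names(seqs) <- paste0("g", sub("fam", "", fam_ids[fams]))
    seqs
  })
  names(proteins) <- genomes
  per_genome <- rowSums(membership)
  pan_count <- sum(colSums(membership) > 0)
  truth <- list(generator = "sim_pangenome", seed = seed,
                params = list(n_genomes = n_genomes, core_size = core_size,
                              accessory_pool = accessory_pool,
                              accessory_rate = accessory_rate),
                membership = membership,
                pi = pan_count / mean(per_genome),
                mean_families_per_genome = mean(per_genome),
                pan_family_count = pan_count)
  list(proteins = proteins, truth = truth)
}

#' Simulate a diverged nucleotide pair with known true alignment
#'
#' Copies a random sequence and substitutes each site independently with
#' probability `d` (always to a different base); no indels by default, so
#' the true alignment is the identity mapping and the realized per-site
#' difference count is recorded as the oracle.
#'
#' @param length sequence length (bases).
#' @param d per-site substitution rate in \[0, 0.3\].
#' @param seed RNG seed.
#' @return list with `a`, `b` (character sequences) and `truth`: seed,
#'   `d`, `n_diff`, `realized_d`, `true_identity_pct`.
#' @export
sim_divergence_pair <- function(length, d, seed = 1L) {
  stop_if_not(d >= 0 && d <= 0.3, "sim_divergence_pair: d must be in [0, 0.3]")
  set.seed(seed)
  a <- random_nt(length)
  v <- strsplit(a, "")[[1]]
  hit <- which(stats::runif(length) < d)
  for (p in hit) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
  list(a = a, b = paste(v, collapse = ""),
       truth = list(generator = "sim_divergence_pair", seed = seed, d = d,
                    n_diff = length(hit), realized_d = length(hit) / length,
                    true_identity_pct = 100 * (1 - length(hit) / length)))
}

#' Simulate a KO-profile pair with an exactly planted complementarity ratio
#'
#' Builds `n_modules` modules of `module_size` (even) required KOs each.
#' `B` modules are fully present in both genomes and `C` modules are split
#' into disjoint halves, one half per genome; remaining modules are absent
#' from both. With the better-single-genome baseline the improvement ratio
#' is then exactly `C / (2B + C)`; the generator searches integer `(B, C)`
#' realizing `target_ratio` and errors when the target is not representable
#' with the given module count.
#'
#' @param n_modules total module count.
#' @param module_size required KOs per module (even).
#' @param target_ratio desired improvement ratio in \[0, 1\].
#' @param seed RNG seed (shuffles KO identifiers only).
#' @return list with `kos_a`, `kos_b`, `modules` (named list of required-KO
#'   sets) and `truth`: seed, target, `B`, `C`, `expected_ratio`.
#' @export
sim_ko_pair <- function(n_modules, module_size = 4L, target_ratio, seed = 1L) {
  stop_if_not(n_modules >= 1 && module_size >= 2 && module_size %% 2 == 0,
              "sim_ko_pair: module_size must be even, n_modules >= 1")
  stop_if_not(target_ratio >= 0 && target_ratio <= 1,
              "sim_ko_pair: target_ratio must be in [0, 1]")
  set.seed(seed)
  r <- target_ratio
  if (r == 0) {
    B <- n_modules; C <- 0L
  } else {
    sol <- NULL
    for (C in seq_len(n_modules)) {
      B <- C * (1 - r) / (2 * r)
      if (abs(B - round(B)) < 1e-9 && round(B) + C <= n_modules) {
        sol <- c(round(B), C)
        break
      }
    }
    stop_if_not(!is.null(sol),
                sprintf("sim_ko_pair: target ratio %g not achievable with %d modules",
                        r, n_modules))
    B <- sol[1]; C <- sol[2]
  }
  ko_ids <- sprintf("K%05d", sample.int(99999L, n_modules * module_size))
  modules <- split(ko_ids, rep(seq_len(n_modules), each = module_size))
  names(modules) <- sprintf("M%04d", seq_len(n_modules))
  kos_a <- character(0); kos_b <- character(0)
  if (B > 0) {
    shared <- unlist(modules[seq_len(B)], use.names = FALSE)
    kos_a <- c(kos_a, shared); kos_b <- c(kos_b, shared)
  }
  if (C > 0) {
    for (m in modules[B + seq_len(C)]) {
      half <- module_size / 2
      kos_a <- c(kos_a, m[seq_len(half)])
      kos_b <- c(kos_b, m[half + seq_len(half)])
    }
  }
  list(kos_a = kos_a, kos_b = kos_b, modules = modules,
       truth = list(generator = "sim_ko_pair", seed = seed,
                    target_ratio = r, B = B, C = C,
                    expected_ratio = if (B + C == 0) 0 else C / (2 * B + C)))
}

#' Simulate a case/control relative-abundance table with planted truth
#'
#' Species baselines are log-normal (log10 means spread over
#' `mean_decades` decades, per-sample log10 standard deviation
#' `sigma_log10`). The first `n_enriched` species are planted as enriched:
#' the leading half case-enriched, the rest control-enriched, by
#' multiplying their abundance by `effect_fold` in the corresponding group
#' before per-sample renormalization to `scale` (so effects are
#' compositional, as in real profiler output). A block of `block$size`
#' species shares a latent Gaussian factor; the latent loading is chosen by
#' inverting the log-normal correlation formula so that the pairwise
#' Pearson correlation of the observed abundances is approximately
#' `block$cc`. When effects are planted the block occupies the leading
#' case-enriched species (all block species share one direction, since
#' opposite group effects would cancel the planted correlation in the
#' pooled samples); with `n_enriched = 0` the block occupies the first
#' species and the background is independent.
#'
#' @param n_case,n_control sample counts per group.
#' @param n_species number of species.
#' @param n_enriched number of planted enriched species (0 for a null
#'   table; at most `n_species`).
#' @param effect_fold multiplicative group effect (1 = no effect).
#' @param block `list(size =, cc =)` or `NULL` for no correlated block.
#' @param seed RNG seed.
#' @param scale declared per-sample total (100 = percent).
#' @param sigma_log10 per-species log10 standard deviation.
#' @param mean_decades spread of species baseline means (decades).
#' @return list with `abundance` (species-by-samples matrix, columns
#'   renormalized to `scale`), `groups` (named character vector) and
#'   `truth`: enriched species and directions, block species and expected
#'   block edges, latent loading, parameters.
#' @export
sim_abundance <- function(n_case = 100L, n_control = 100L, n_species = 100L,
                          n_enriched = 10L, effect_fold = 4,
                          block = list(size = 5L, cc = 0.8), seed = 1L,
                          scale = 100, sigma_log10 = 0.5, mean_decades = 3) {
  stop_if_not(n_enriched <= n_species, "sim_abundance: n_enriched > n_species")
  stop_if_not(is.null(block) || block$size <= n_species,
              "sim_abundance: block larger than species count")
  set.seed(seed)
  n <- n_case + n_control
  samples <- sprintf("S%04d", seq_len(n))
  groups <- setNames(c(rep("case", n_case), rep("control", n_control)),
                     samples)
  species <- sprintf("sp%03d", seq_len(n_species))
  mu <- stats::runif(n_species, -mean_decades, 0)

  z <- matrix(stats::rnorm(n_species * n), n_species, n)
  rho_latent <- NA_real_
  block_species <- character(0)
  if (!is.null(block) && block$size >= 2) {
    s_nat <- sigma_log10 * log(10)
    rho_latent <- log(1 + block$cc * (exp(s_nat^2) - 1)) / s_nat^2
    stop_if_not(rho_latent <= 1,
                "sim_abundance: block cc not achievable at this sigma")
    f <- stats::rnorm(n)
    bi <- seq_len(block$size)
    z[bi, ] <- sqrt(rho_latent) * matrix(rep(f, each = block$size),
                                         block$size, n) +
      sqrt(1 - rho_latent) * z[bi, , drop = FALSE]
    block_species <- species[bi]
  }
  ab <- 10^(mu + sigma_log10 * z)

  enriched <- character(0); directions <- character(0)
  if (n_enriched > 0) {
    stop_if_not(effect_fold > 0, "sim_abundance: effect_fold must be > 0")
    n_case_enr <- ceiling(n_enriched / 2)
    # keep the correlated block direction-consistent: species sharing the
    # latent factor must not carry opposite group effects
    if (length(block_species) > 0) {
      n_case_enr <- min(n_enriched, max(n_case_enr, length(block_species)))
    }
    ei <- seq_len(n_enriched)
    enriched <- species[ei]
    directions <- c(rep("case_enriched", n_case_enr),
                    rep("control_enriched", n_enriched - n_case_enr))
    case_cols <- groups == "case"
    for (i in ei) {
      if (directions[i] == "case_enriched") {
        ab[i, case_cols] <- ab[i, case_cols] * effect_fold
      } else {
        ab[i, !case_cols] <- ab[i, !case_cols] * effect_fold
      }
    }
  }
  ab <- sweep(ab, 2, colSums(ab), "/") * scale
  dimnames(ab) <- list(species, samples)
  block_edges <- if (length(block_species) >= 2) {
    cmb <- utils::combn(block_species, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0))
  }
  list(abundance = ab, groups = groups,
       truth = list(generator = "sim_abundance", seed = seed,
                    params = list(n_case = n_case, n_control = n_control,
                                  n_species = n_species,
                                  n_enriched = n_enriched,
                                  effect_fold = effect_fold, block = block,
                                  scale = scale, sigma_log10 = sigma_log10,
                                  mean_decades = mean_decades),
                    enriched = setNames(directions, enriched),
                    block_species = block_species,
                    block_edges = block_edges,
                    rho_latent = rho_latent))
}
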