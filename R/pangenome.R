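# Pan-genome construction: greedy incremental protein-family clustering at
# 95% identity over 90% of the shorter sequence, core/accessory/specific
# partition, rarefaction, and the pan-genome index (PI) with openness levels.
#
# PI = pan-genome family count / mean per-genome family count. (The openness
# semantics require the open species to have the larger index, hence this
# orientation; see the methods vignette.)

#' Greedy incremental protein-family clustering
#'
#' Sequences are sorted longest-first (ties broken lexicographically by gene
#' identifier) and processed greedily: each sequence joins the first existing
#' family whose representative it matches at `identity` or more over at least
#' `coverage` of the shorter sequence, otherwise it founds a new family with
#' itself as representative. A shared-8-mer prescreen skips representatives
#' that cannot reach the identity threshold (a >= 95% identical region of
#' length >= 90 residues must contain an exact 8-mer match).
#'
#' @param proteins named list: per-genome character vectors of protein
#'   sequences, each vector named by gene identifier (unique within genome).
#' @param identity family-membership identity threshold, fraction (0.95).
#' @param coverage alignment-length threshold as a fraction of the shorter
#'   sequence (0.90).
#' @return data.frame with columns `family_id`, `representative` (gene key
#'   `genome|gene`), `genome_id`, `gene_id`; one row per gene.
#' @export
cluster_gene_families <- function(proteins, identity = 0.95, coverage = 0.90) {
  stop_if_not(length(proteins) > 0 && !is.null(names(proteins)),
              "cluster_gene_families: need a named per-genome list")
  genes <- data.frame(
    genome_id = rep(names(proteins), lengths(proteins)),
    gene_id = unlist(lapply(proteins, names), use.names = FALSE),
    seq = unlist(proteins, use.names = FALSE),
    stringsAsFactors = FALSE)
  stop_if_not(nrow(genes) > 0, "cluster_gene_families: empty input")
  stop_if_not(!any(is.na(genes$gene_id)),
              "cluster_gene_families: protein vectors must be named by gene id")
  genes$key <- paste(genes$genome_id, genes$gene_id, sep = "|")
  ord <- order(-nchar(genes$seq), genes$key)
  genes <- genes[ord, ]

  k_pre <- 8L
  reps_seq <- character(0)
  reps_key <- character(0)
  reps_kmers <- list()
  assign_fam <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- genes$seq[i]
    fam <- 0L
    if (length(reps_seq)) {
      sk <- unique(seq_kmers(s, k_pre))
      cand <- which(vapply(reps_kmers, function(rk) {
        # sequences too short to carry an 8-mer are never prescreened out
        length(sk) == 0 || length(rk) == 0 || any(sk %in% rk)
      }, logical(1)))
      for (j in cand) {
        ic <- seq_ident_cov(s, reps_seq[j])
        if (ic$identity >= identity * 100 && ic$coverage >= coverage) {
          fam <- j
          break
        }
      }
    }
    if (fam == 0L) {
      reps_seq <- c(reps_seq, s)
      reps_key <- c(reps_key, genes$key[i])
      reps_kmers[[length(reps_seq)]] <- unique(seq_kmers(s, k_pre))
      fam <- length(reps_seq)
    }
    assign_fam[i] <- fam
  }
  data.frame(family_id = sprintf("F%05d", assign_fam),
             representative = reps_key[assign_fam],
             genome_id = genes$genome_id,
             gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Build a pan-genome object from family memberships
#'
#' @param families data.frame as returned by [cluster_gene_families()] (or
#'   any data.frame with columns `family_id`, `genome_id`), covering every
#'   gene of every genome.
#' @param genomes optional character vector of all genome identifiers
#'   (defaults to those present in `families`); genomes with no genes are
#'   rejected.
#' @return object of class `"pan_genome"`: list with `membership` (logical
#'   genome-by-family matrix), `gene_counts` (genes per genome), `families`.
#' @export
pan_genome <- function(families, genomes = NULL) {
  genomes <- genomes %||% sort(unique(families$genome_id))
  stop_if_not(all(families$genome_id %in% genomes),
              "pan_genome: families reference unknown genomes")
  stop_if_not(all(genomes %in% families$genome_id),
              "pan_genome: genome with zero genes")
  fams <- sort(unique(families$family_id))
  membership <- matrix(FALSE, length(genomes), length(fams),
                       dimnames = list(genomes, fams))
  membership[cbind(families$genome_id, families$family_id)] <- TRUE
  gene_counts <- table(factor(families$genome_id, levels = genomes))
  structure(list(membership = membership,
                 gene_counts = as.numeric(gene_counts),
                 families = families),
            class = "pan_genome")
}

#' @export
print.pan_genome <- function(x, ...) {
  p <- partition_families(x)
  cat(sprintf(
    "Pan-genome: %d genomes, %d families (%d core / %d accessory / %d specific)\n",
    nrow(x$membership), ncol(x$membership),
    length(p$core), length(p$accessory), length(p$specific)))
  invisible(x)
}

#' Core / accessory / strain-specific partition
#'
#' Core families are present in all genomes; strain-specific families in
#' exactly one; accessory families in between. The three sets are disjoint
#' and exhaust all families.
#'
#' @param pan a [pan_genome()] object.
#' @return list with character vectors `core`, `accessory`, `specific`.
#' @export
partition_families <- function(pan) {
  m <- pan$membership
  n <- nrow(m)
  cnt <- colSums(m)
  list(core = colnames(m)[cnt == n],
       accessory = colnames(m)[cnt > 1 & cnt < n],
       specific = colnames(m)[cnt == 1])
}

#' Pan- and core-genome rarefaction curves
#'
#' For each genome count k, the mean (over random genome orderings) of the
#' union and intersection sizes of the first k genomes' family sets.
#'
#' @param pan a [pan_genome()] object with at least 2 genomes.
#' @param n_permutations number of random orderings (default 100).
#' @param seed RNG seed.
#' @return data.frame with columns `k`, `pan_mean`, `core_mean`.
#' @export
rarefaction_curves <- function(pan, n_permutations = 100, seed = 1L) {
  m <- pan$membership
  n <- nrow(m)
  stop_if_not(n >= 2, "rarefaction_curves: need >= 2 genomes")
  set.seed(seed)
  pan_acc <- matrix(0, n_permutations, n)
  core_acc <- matrix(0, n_permutations, n)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    un <- rep(FALSE, ncol(m))
    inter <- rep(TRUE, ncol(m))
    for (k in seq_len(n)) {
      un <- un | m[ord[k], ]
      inter <- inter & m[ord[k], ]
      pan_acc[p, k] <- sum(un)
      core_acc[p, k] <- sum(inter)
    }
  }
  data.frame(k = seq_len(n),
             pan_mean = colMeans(pan_acc),
             core_mean = colMeans(core_acc))
}

#' Pan-genome index (PI) and openness level
#'
#' PI is the pan-genome family count divided by the mean per-genome family
#' count; identical genomes give PI = 1 and more open gene repertoires give
#' larger PI. Openness levels: A (relatively conserved) for PI <= 1.5,
#' B (half-open) for 1.5 < PI <= 3, C (relatively open) for PI > 3.
#'
#' @param pan a [pan_genome()] object.
#' @param count `"families"` (default) counts deduplicated families per
#'   genome; `"genes"` counts raw genes per genome in the denominator.
#' @return list with `pi`, `level`, `mean_genes_per_genome`,
#'   `pan_family_count`.
#' @export
pan_genome_index <- function(pan, count = c("families", "genes")) {
  count <- match.arg(count)
  m <- pan$membership
  per_genome <- if (count == "families") rowSums(m) else pan$gene_counts
  stop_if_not(all(per_genome > 0), "pan_genome_index: genome with zero genes")
  pi <- ncol(m) / mean(per_genome)
  level <- if (pi <= 1.5) "A" else if (pi <= 3) "B" else "C"
  list(pi = pi, level = level,
       mean_genes_per_genome = mean(per_genome),
       pan_family_count = ncol(m))
}

#' Correlates of pan-genome openness
#'
#' Per-factor Pearson correlation/R squared of the pan-genome index against
#' candidate species-level factors (isolation-source count, genome count,
#' intra-species AAI standard deviation), plus a combined ordinary
#' least-squares fit with overall-F p-value. Constant factors are flagged
#' and excluded from the combined fit.
#'
#' @param pi_by_species named numeric vector of PI per species.
#' @param source_counts,genome_counts,aai_sds numeric vectors aligned with
#'   `pi_by_species`.
#' @return as [ols_correlates()]: list with `per_factor` and `combined`.
#' @export
openness_correlates <- function(pi_by_species, source_counts, genome_counts,
                                aai_sds) {
  ols_correlates(pi_by_species,
                 list(source_count = source_counts,
                      genome_count = genome_counts,
                      aai_sd = aai_sds))
}

#' Per-species pan-genome summary table
#'
#' @param families family table as from [cluster_gene_families()].
#' @param species named character vector mapping genome id to species.
#' @return data.frame: species, n_genomes, pan, core, accessory, specific,
#'   mean_families, pi, level.
#' @export
pangenome_summary <- function(families, species) {
  sps <- unique(species)
  rows <- lapply(sps, function(sp) {
    g <- names(species)[species == sp]
    fam <- families[families$genome_id %in% g, , drop = FALSE]
    pg <- pan_genome(fam, genomes = g)
    part <- partition_families(pg)
    pidx <- pan_genome_index(pg)
    data.frame(species = sp, n_genomes = length(g),
               pan = pidx$pan_family_count,
               core = length(part$core),
               accessory = length(part$accessory),
               specific = length(part$specific),
               mean_families = pidx$mean_genes_per_genome,
               pi = pidx$pi, level = pidx$level,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
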