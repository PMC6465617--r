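# Independent oracles used across the suite. These deliberately re-derive
# results by enumeration / direct formula, never by calling the code path
# they check.

# Exact two-sided rank-sum p-value by full enumeration of group labelings.
oracle_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  u_obs <- u_of(seq_along(x))
  labelings <- utils::combn(n, length(x))
  us <- apply(labelings, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# BH step-up by the direct formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Pearson correlation by the closed-form covariance/variance formula.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# N50 by brute-force cumulative scan over all candidate lengths.
oracle_n50 <- function(lengths) {
  cands <- sort(unique(lengths), decreasing = TRUE)
  total <- sum(lengths)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
}

# Greedy clustering re-done from its definition (no prescreen): sequences
# longest-first (ties lexicographic by genome|gene key), each joining the
# first representative meeting both thresholds under the same pairwise
# identity/coverage measure.
oracle_cluster <- function(proteins, identity = 0.95, coverage = 0.90) {
  genes <- data.frame(
    genome_id = rep(names(proteins), lengths(proteins)),
    gene_id = unlist(lapply(proteins, names), use.names = FALSE),
    seq = unlist(proteins, use.names = FALSE),
    stringsAsFactors = FALSE)
  genes$key <- paste(genes$genome_id, genes$gene_id, sep = "|")
  genes <- genes[order(-nchar(genes$seq), genes$key), ]
  rep_seq <- character(0)
  fam <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- 0L
    for (j in seq_along(rep_seq)) {
      ic <- panprobio:::seq_ident_cov(genes$seq[i], rep_seq[j])
      if (ic$identity >= identity * 100 && ic$coverage >= coverage) {
        hit <- j; break
      }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, genes$seq[i])
      hit <- length(rep_seq)
    }
    fam[i] <- hit
  }
  split(genes$key, fam)
}

# Pair complementarity by explicit per-module union-and-count.
oracle_complementarity <- function(kos_a, kos_b, modules) {
  integ <- function(kos) {
    vapply(modules, function(req) {
      sum(unique(req) %in% kos) / length(unique(req))
    }, numeric(1))
  }
  ta <- sum(integ(unique(kos_a)))
  tb <- sum(integ(unique(kos_b)))
  tm <- sum(integ(unique(c(kos_a, kos_b))))
  base <- max(ta, tb)
  if (base == 0) {
    if (tm == 0) 0 else Inf
  } else {
    (tm - base) / base
  }
}

# Random protein families for clustering tests: a few ancestors, copies at
# assorted mutation rates so identities land on both sides of the thresholds.
random_protein_instance <- function(n_seq, n_genomes = 3, seed = 1) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  n_anc <- max(2, n_seq %/% 4)
  anc <- vapply(seq_len(n_anc), function(i) {
    paste(sample(aa, sample(40:90, 1), replace = TRUE), collapse = "")
  }, character(1))
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- strsplit(sample(anc, 1), "")[[1]]
    rate <- sample(c(0, 0.02, 0.04, 0.06, 0.1, 0.25), 1)
    nm <- round(rate * length(s))
    if (nm > 0) {
      pos <- sample(length(s), nm)
      for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1)
    }
    paste(s, collapse = "")
  }, character(1))
  gpr <- split(seqs, rep_len(paste0("G", seq_len(n_genomes)), n_seq))
  lapply(gpr, function(v) setNames(v, sprintf("g%03d", seq_along(v))))
}

# single-row annotation hit for boundary tests
mk_hit <- function(db, ident, qlen = 100, slen = 100, alen = 50,
                   query = "q1", subject = "s1", thr = NA) {
  data.frame(query_id = query, subject_id = subject, database = db,
             identity_pct = ident, query_len = qlen, subject_len = slen,
             align_len = alen, subject_threshold_pct = thr,
             stringsAsFactors = FALSE)
}

# family partition (set of member-key sets) for comparing clusterings
family_partition <- function(fam_df) {
  keys <- paste(fam_df$genome_id, fam_df$gene_id, sep = "|")
  unname(lapply(split(keys, fam_df$family_id), function(v) sort(v)))
}

partition_equal <- function(a, b) {
  setequal(vapply(a, paste, character(1), collapse = ";"),
           vapply(b, paste, character(1), collapse = ";"))
}
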