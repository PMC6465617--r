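# Database-specific filtering of homology-search hit tables and the two
# downstream functional comparisons: per-feature species enrichment counts
# (how many other species are significantly weaker) and the friendly vs
# unfriendly risk-gene burden test.
#
# Acceptance rules per database (coverages are fractions of sequence length):
#   KEGG:        query coverage >= 0.5
#   ARDB:        query AND subject coverage >= 0.4, identity > per-gene
#                recommended threshold (subject_threshold_pct column)
#   VFDB, CAZy:  query coverage >= 0.5, identity >= 60

#' Filter annotation hits by database-specific thresholds
#'
#' Applies the per-database acceptance rule, then keeps one best accepted
#' hit per query per database (highest identity; ties broken by subject
#' identifier order).
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `database`
#'   (one of KEGG/ARDB/VFDB/CAZy), `identity_pct`, `query_len`,
#'   `subject_len`, `align_len`, and (for ARDB rows)
#'   `subject_threshold_pct`. Extra columns are carried through.
#' @return accepted hits, one row per (query, database), with added columns
#'   `query_cov` and `subject_cov`.
#' @export
filter_hits <- function(hits) {
  need <- c("query_id", "subject_id", "database", "identity_pct",
            "query_len", "subject_len", "align_len")
  stop_if_not(all(need %in% names(hits)),
              paste("filter_hits: missing columns:",
                    paste(setdiff(need, names(hits)), collapse = ", ")))
  stop_if_not(all(hits$database %in% c("KEGG", "ARDB", "VFDB", "CAZy")),
              "filter_hits: unknown database")
  stop_if_not(all(hits$query_len > 0 & hits$subject_len > 0 & hits$align_len > 0),
              "filter_hits: lengths must be positive")
  stop_if_not(all(hits$identity_pct >= 0 & hits$identity_pct <= 100),
              "filter_hits: identity must be in [0, 100]")
  h <- hits
  h$query_cov <- h$align_len / h$query_len
  h$subject_cov <- h$align_len / h$subject_len
  if (!"subject_threshold_pct" %in% names(h)) h$subject_threshold_pct <- NA_real_
  ardb_missing <- h$database == "ARDB" & is.na(h$subject_threshold_pct)
  if (any(ardb_missing)) {
    warning(sum(ardb_missing),
            " ARDB hit(s) without a recommended identity threshold rejected")
  }
  ok <- rep(FALSE, nrow(h))
  kegg <- h$database == "KEGG"
  ok[kegg] <- h$query_cov[kegg] >= 0.5
  ardb <- h$database == "ARDB" & !ardb_missing
  ok[ardb] <- h$query_cov[ardb] >= 0.4 & h$subject_cov[ardb] >= 0.4 &
    h$identity_pct[ardb] > h$subject_threshold_pct[ardb]
  vc <- h$database %in% c("VFDB", "CAZy")
  ok[vc] <- h$query_cov[vc] >= 0.5 & h$identity_pct[vc] >= 60
  h <- h[ok, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  # best accepted hit per (query, database): highest identity, ties by subject
  h <- h[order(h$query_id, h$database, -h$identity_pct, h$subject_id), ,
         drop = FALSE]
  h[!duplicated(h[, c("query_id", "database")]), , drop = FALSE]
}

#' Genome-by-feature count matrix from accepted annotations
#'
#' @param accepted accepted-hit table from [filter_hits()] with an added
#'   `genome_id` column.
#' @param feature_col column holding the feature identifier (default
#'   `"subject_id"`).
#' @return integer matrix, genomes by features.
#' @export
feature_matrix <- function(accepted, feature_col = "subject_id") {
  stop_if_not(all(c("genome_id", feature_col) %in% names(accepted)),
              "feature_matrix: need genome_id and feature columns")
  tab <- table(accepted$genome_id, accepted[[feature_col]])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m
}

#' Per-species feature enrichment counts
#'
#' For every feature and every ordered species pair (s, t), the strain-level
#' counts of s are compared with those of t by the unpaired rank-sum test;
#' p-values are BH-adjusted jointly across all tests of the call. The cell
#' for (species s, feature f) counts the species t that are significantly
#' weaker than s (q below `q_threshold` and s with the higher mean rank), so
#' each cell lies in 0..(number of species - 1).
#'
#' @param counts genome-by-feature count matrix (rownames = genome ids).
#' @param species named character vector mapping genome id to species.
#' @param q_threshold FDR threshold (default 0.05).
#' @return list with `cells` (species-by-feature integer matrix), `tests`
#'   (long data.frame of all pairwise tests with p, q, direction) and
#'   `low_power_species` (species with a single strain).
#' @export
feature_enrichment_matrix <- function(counts, species, q_threshold = 0.05) {
  stop_if_not(!is.null(rownames(counts)), "counts must have genome rownames")
  species <- species[rownames(counts)]
  stop_if_not(!any(is.na(species)), "species labels missing for some genomes")
  sps <- sort(unique(unname(species)))
  stop_if_not(length(sps) >= 2, "need at least 2 species")
  feats <- colnames(counts)
  tests <- list()
  i <- 0L
  for (f in feats) {
    for (a_i in seq_len(length(sps) - 1)) for (b_i in (a_i + 1):length(sps)) {
      s <- sps[a_i]; t <- sps[b_i]
      xs <- counts[species == s, f]
      ys <- counts[species == t, f]
      rs <- ranksum(xs, ys)
      i <- i + 1L
      tests[[i]] <- data.frame(
        feature = f, species_a = s, species_b = t,
        p = rs$p,
        stronger = if (rs$direction == "x") s else if (rs$direction == "y") t
                   else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$q <- bh_fdr(tests$p)
  cells <- matrix(0L, length(sps), length(feats), dimnames = list(sps, feats))
  sig <- tests[!is.na(tests$stronger) & tests$q < q_threshold, , drop = FALSE]
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      cells[sig$stronger[r], sig$feature[r]] <-
        cells[sig$stronger[r], sig$feature[r]] + 1L
    }
  }
  n_per <- table(unname(species))
  list(cells = cells, tests = tests,
       low_power_species = names(n_per)[n_per < 2])
}

#' Species-specific and shared feature calls
#'
#' Presence/absence summary of accepted annotations: a feature is
#' species-specific when present in at least one strain of exactly one
#' species, shared when present in two or more species.
#'
#' @param counts genome-by-feature count matrix.
#' @param species named character vector mapping genome id to species.
#' @return data.frame: feature, n_species, status (`"specific"`/`"shared"`),
#'   species (comma-joined list of carrier species).
#' @export
feature_specificity <- function(counts, species) {
  species <- species[rownames(counts)]
  rows <- lapply(colnames(counts), function(f) {
    carriers <- sort(unique(unname(species[counts[, f] > 0])))
    data.frame(feature = f, n_species = length(carriers),
               status = if (length(carriers) == 1) "specific" else "shared",
               species = paste(carriers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Risk-gene burden comparison between friendliness groups
#'
#' Compares per-genome accepted virulence + antibiotic-resistance gene
#' counts between the friendly and unfriendly isolation-source groups with
#' the unpaired two-sided rank-sum test. Significance stars: `*` for
#' p < 0.05, `**` for p < 0.01.
#'
#' @param risk_counts numeric vector of per-genome risk-gene counts.
#' @param friendliness character vector aligned with `risk_counts`, values
#'   in `{"friendly", "unfriendly"}` (others dropped).
#' @return list with `p`, `direction` (group with higher mean rank, or
#'   `"none"`), `stars`, `n_friendly`, `n_unfriendly`.
#' @export
risk_burden_compare <- function(risk_counts, friendliness) {
  stop_if_not(length(risk_counts) == length(friendliness),
              "risk_burden_compare: length mismatch")
  fr <- risk_counts[friendliness == "friendly"]
  un <- risk_counts[friendliness == "unfriendly"]
  stop_if_not(length(fr) >= 2 && length(un) >= 2,
              "risk_burden_compare: both groups need >= 2 genomes")
  rs <- ranksum(fr, un)
  direction <- switch(rs$direction, x = "friendly", y = "unfriendly", "none")
  stars <- if (rs$p < 0.01) "**" else if (rs$p < 0.05) "*" else ""
  list(p = rs$p, direction = direction, stars = stars,
       n_friendly = length(fr), n_unfriendly = length(un))
}
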