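# KEGG-module integrity and pairwise complementarity.
#
# Module integrity of a genome = |KO set  intersect  required KOs| / |required
# KOs|. The total integrity T(G) sums integrities over all modules. For a
# genome pair the KO sets are merged (set union) and the complementarity
# improvement ratio is the relative gain of the merged total over the better
# single genome: (T(merged) - max(T_a, T_b)) / max(T_a, T_b).

#' Module definitions from a long table
#'
#' @param df data.frame with columns `module_id`, `ko`.
#' @return named list of character KO vectors (the required/key KO set per
#'   module).
#' @export
module_definitions <- function(df) {
  stop_if_not(all(c("module_id", "ko") %in% names(df)),
              "module_definitions: need module_id and ko columns")
  mods <- split(df$ko, df$module_id)
  lapply(mods, unique)
}

#' KEGG-module integrity
#'
#' Fraction of a module's required (key/essential) KOs present in a KO set.
#'
#' @param kos character vector of KO identifiers carried by a genome.
#' @param required non-empty character vector of the module's required KOs.
#' @return fraction in \[0, 1\].
#' @export
module_integrity <- function(kos, required) {
  stop_if_not(length(required) > 0, "module_integrity: empty required set")
  length(intersect(unique(kos), unique(required))) / length(unique(required))
}

# total integrity: sum of per-module integrities
total_integrity <- function(kos, modules) {
  sum(vapply(modules, function(req) module_integrity(kos, req), numeric(1)))
}

#' Pairwise KEGG-module complementarity
#'
#' Merges the two KO sets and measures the improvement of summed module
#' integrity over the better single genome (`baseline = "max"`, default) or
#' over the mean of the two (`baseline = "mean"`). When both baselines are
#' zero: ratio 0 if the merged total is also zero, otherwise the ratio is
#' `Inf` with `flag = "infinite-improvement"` (reported separately, never
#' averaged into species summaries).
#'
#' @param kos_a,kos_b character vectors of KO identifiers.
#' @param modules named list of required-KO sets (see
#'   [module_definitions()]).
#' @param baseline `"max"` or `"mean"`.
#' @return list with `total_a`, `total_b`, `total_merged`,
#'   `improvement_ratio`, `flag`.
#' @export
pair_complementarity <- function(kos_a, kos_b, modules,
                                 baseline = c("max", "mean")) {
  baseline <- match.arg(baseline)
  stop_if_not(length(modules) > 0, "pair_complementarity: no modules")
  ta <- total_integrity(kos_a, modules)
  tb <- total_integrity(kos_b, modules)
  tm <- total_integrity(union(kos_a, kos_b), modules)
  base <- if (baseline == "max") max(ta, tb) else mean(c(ta, tb))
  if (base == 0) {
    if (tm == 0) {
      ratio <- 0; flag <- NA_character_
    } else {
      ratio <- Inf; flag <- "infinite-improvement"
    }
  } else {
    ratio <- (tm - max(ta, tb)) / base
    flag <- NA_character_
  }
  list(total_a = ta, total_b = tb, total_merged = tm,
       improvement_ratio = ratio, flag = flag)
}

#' Enumerate all cross-species strain pairs
#'
#' All unordered strain pairs whose species labels differ. The count equals
#' C(N, 2) minus the sum of within-species C(n_s, 2).
#'
#' @param species named character vector: strain id -> species label.
#' @return data.frame with columns `a`, `b`, `species_a`, `species_b`; the
#'   attribute `n_pairs` holds the closed-form count.
#' @export
enumerate_cross_species_pairs <- function(species) {
  ids <- names(species)
  stop_if_not(!is.null(ids), "enumerate_cross_species_pairs: species must be named")
  n <- length(ids)
  expected <- choose(n, 2) - sum(choose(table(unname(species)), 2))
  if (n < 2) {
    out <- data.frame(a = character(0), b = character(0),
                      species_a = character(0), species_b = character(0))
    return(structure(out, n_pairs = 0))
  }
  cmb <- utils::combn(n, 2)
  keep <- species[cmb[1, ]] != species[cmb[2, ]]
  out <- data.frame(a = ids[cmb[1, keep]], b = ids[cmb[2, keep]],
                    species_a = unname(species[cmb[1, keep]]),
                    species_b = unname(species[cmb[2, keep]]),
                    stringsAsFactors = FALSE)
  stopifnot(nrow(out) == expected)
  structure(out, n_pairs = expected)
}

#' Complementarity of every cross-species strain pair
#'
#' @param ko_profiles named list: strain id -> character vector of KOs.
#' @param species named character vector: strain id -> species label.
#' @param modules named list of required-KO sets.
#' @param baseline see [pair_complementarity()].
#' @return data.frame: a, b, species_a, species_b, total_a, total_b,
#'   total_merged, improvement_ratio, flag.
#' @export
cross_species_complementarity <- function(ko_profiles, species, modules,
                                          baseline = "max") {
  stop_if_not(all(names(species) %in% names(ko_profiles)),
              "cross_species_complementarity: KO profiles missing for some strains")
  pairs <- enumerate_cross_species_pairs(species)
  if (nrow(pairs) == 0) return(pairs)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pc <- pair_complementarity(ko_profiles[[pairs$a[i]]],
                               ko_profiles[[pairs$b[i]]], modules,
                               baseline = baseline)
    data.frame(total_a = pc$total_a, total_b = pc$total_b,
               total_merged = pc$total_merged,
               improvement_ratio = pc$improvement_ratio,
               flag = pc$flag, stringsAsFactors = FALSE)
  })
  cbind(pairs, do.call(rbind, res))
}

#' Species-level complementarity summary with ranks and terciles
#'
#' Mean improvement ratio per species pair, ranked descending (rank 1 =
#' highest mean), with tercile groups `"top"`, `"middle"`, `"last"` by rank
#' position. Strain pairs flagged as infinite improvement are excluded from
#' the means.
#'
#' @param pair_table output of [cross_species_complementarity()].
#' @return data.frame: species_a, species_b, pair (sorted label), n_pairs,
#'   mean_ratio, rank, tercile.
#' @export
species_pair_summary <- function(pair_table) {
  pt <- pair_table[is.na(pair_table$flag) | pair_table$flag == "", ,
                   drop = FALSE]
  key_a <- pmin(pt$species_a, pt$species_b)
  key_b <- pmax(pt$species_a, pt$species_b)
  key <- paste(key_a, key_b, sep = " + ")
  agg <- aggregate(list(mean_ratio = pt$improvement_ratio),
                   by = list(pair = key, species_a = key_a, species_b = key_b),
                   FUN = mean)
  counts <- as.data.frame(table(pair = key), stringsAsFactors = FALSE)
  agg <- merge(agg, setNames(counts, c("pair", "n_pairs")), by = "pair")
  agg <- agg[order(-agg$mean_ratio, agg$pair), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  third <- nrow(agg) / 3
  agg$tercile <- ifelse(agg$rank <= ceiling(third), "top",
                        ifelse(agg$rank <= ceiling(2 * third), "middle",
                               "last"))
  rownames(agg) <- NULL
  agg[, c("species_a", "species_b", "pair", "n_pairs", "mean_ratio",
          "rank", "tercile")]
}

#' Correlation between species-pair complementarity and ANI
#'
#' Pearson correlation (two-sided p) between per-species-pair mean
#' improvement ratios and the corresponding ANI values; a negative sign
#' indicates that more distant species pairs complement each other more.
#'
#' @param mean_ratios,ani numeric vectors aligned by species pair (n >= 3).
#' @return list with `cc`, `p`, `n`, `flag` (see [pearson_cor()]).
#' @export
complementarity_ani_correlation <- function(mean_ratios, ani) {
  pearson_cor(mean_ratios, ani)
}
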