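# Case/control species enrichment and co-abundance networks.
#
# Enrichment: per species, unpaired two-sided rank-sum test of relative
# abundances between case and control samples, BH-FDR over all tested
# species, direction by higher mean rank at q < 0.05.
#
# Network: nodes are the enriched species only; edges are Pearson
# correlations over ALL samples (groups pooled) with raw p < 0.05 and
# cc > 0.4 if positive or cc < -0.1 if negative. Edge widths bin on |cc|:
# thick >= 0.7, medium in [0.4, 0.7), thin in (0.1, 0.4).

#' Read a merged species-profile table
#'
#' Parses a merged relative-abundance table as produced by MetaPhlAn-style
#' profilers: first column holds rank-prefixed clade names, remaining
#' columns one sample each. Species-level rows are those containing an
#' `s__` label and no strain-level (`t__`) suffix; names are stripped to
#' the plain species label.
#'
#' @param path TSV path.
#' @return numeric matrix, species by samples.
#' @export
read_metaphlan_profiles <- function(path) {
  df <- read_tsv_file(path)
  clade <- df[[1]]
  keep <- grepl("s__", clade) & !grepl("t__", clade)
  m <- as.matrix(df[keep, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- sub(".*s__", "", clade[keep])
  m
}

#' Case/control differential species enrichment
#'
#' @param abundance numeric matrix, species by samples (relative
#'   abundances).
#' @param groups character/factor vector naming each sample's group, values
#'   in `{"case", "control"}`, aligned with (or named by) the columns of
#'   `abundance`.
#' @param q_threshold FDR threshold for calling a direction (default 0.05).
#' @return data.frame of class `"enrichment_calls"`: species, p, q,
#'   direction (`"case_enriched"`, `"control_enriched"`, `"ns"`). Species
#'   that are zero in every sample are skipped and listed in the
#'   `skipped` attribute.
#' @export
differential_enrichment <- function(abundance, groups, q_threshold = 0.05) {
  stop_if_not(is.matrix(abundance), "differential_enrichment: need a matrix")
  if (!is.null(names(groups))) groups <- groups[colnames(abundance)]
  groups <- as.character(groups)
  stop_if_not(length(groups) == ncol(abundance),
              "differential_enrichment: group labels do not match samples")
  stop_if_not(all(groups %in% c("case", "control")),
              "differential_enrichment: groups must be 'case'/'control'")
  stop_if_not(sum(groups == "case") >= 2 && sum(groups == "control") >= 2,
              "differential_enrichment: both groups need >= 2 samples")
  zero <- rowSums(abundance) == 0
  sp <- rownames(abundance)[!zero]
  res <- lapply(sp, function(s) {
    ca <- abundance[s, groups == "case"]
    co <- abundance[s, groups == "control"]
    rs <- ranksum(ca, co)
    data.frame(species = s, p = rs$p,
               raw_direction = switch(rs$direction, x = "case_enriched",
                                      y = "control_enriched", "ns"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p)
  res$direction <- ifelse(res$q < q_threshold & res$raw_direction != "ns",
                          res$raw_direction, "ns")
  res <- res[, c("species", "p", "q", "direction")]
  class(res) <- c("enrichment_calls", "data.frame")
  attr(res, "skipped") <- rownames(abundance)[zero]
  attr(res, "q_threshold") <- q_threshold
  res
}

# |cc| -> edge width category per the display convention
edge_width_category <- function(cc) {
  a <- abs(cc)
  ifelse(a >= 0.7, "thick", ifelse(a >= 0.4, "medium",
                                   ifelse(a > 0.1, "thin", "none")))
}

# mean relative abundance (fraction of scale) -> decade bin label
abundance_decade_bin <- function(mean_abundance, scale = 100) {
  frac <- mean_abundance / scale
  vapply(frac, function(f) {
    if (is.na(f) || f < 1e-6) return("<1/10^6")
    d <- min(6, max(1, ceiling(-log10(f))))
    paste0("1/10^", d)
  }, character(1))
}

#' Build a co-abundance network over enriched species
#'
#' Nodes are the species called enriched (either direction); for every node
#' pair the Pearson correlation of relative abundances is computed over all
#' samples (case and control pooled). An edge is kept iff its raw p-value is
#' below `edge_p` and the coefficient exceeds `pos_cc` (positive edges) or
#' falls below `neg_cc` (negative edges); p-values are deliberately not
#' multiplicity-corrected, matching the stated edge rule. Node attributes:
#' direction, mean abundance with decade bin, degree, and top-10 flags for
#' degree and abundance (ties broken lexicographically by species name).
#'
#' @param abundance species-by-samples matrix (must contain all enriched
#'   species; extra species are ignored).
#' @param enriched an `enrichment_calls` data.frame from
#'   [differential_enrichment()], or a character vector of node species (all
#'   treated as direction `"node"`).
#' @param edge_p raw p-value threshold for edges (default 0.05).
#' @param pos_cc positive-edge coefficient cutoff (default 0.4, strict).
#' @param neg_cc negative-edge coefficient cutoff (default -0.1, strict).
#' @param scale declared per-sample total of the abundance values (100 for
#'   percent tables).
#' @return object of class `"coabundance_network"`: list with `nodes`
#'   (species, direction, mean_abundance, decade_bin, degree, top10_degree,
#'   top10_abundance, flag), `edges` (a, b, cc, p, sign, width) and
#'   `params`.
#' @export
build_coabundance_network <- function(abundance, enriched, edge_p = 0.05,
                                      pos_cc = 0.4, neg_cc = -0.1,
                                      scale = 100) {
  stop_if_not(ncol(abundance) >= 3, "build_coabundance_network: need >= 3 samples")
  if (is.character(enriched)) {
    enriched <- data.frame(species = enriched, direction = "node",
                           stringsAsFactors = FALSE)
  } else {
    enriched <- enriched[enriched$direction != "ns", , drop = FALSE]
  }
  stop_if_not(nrow(enriched) > 0, "build_coabundance_network: no enriched species")
  stop_if_not(all(enriched$species %in% rownames(abundance)),
              "build_coabundance_network: enriched species missing from table")
  sp <- sort(enriched$species)
  sub <- abundance[sp, , drop = FALSE]
  constant <- apply(sub, 1, function(v) stats::sd(v) == 0)
  edges <- list(); k <- 0L
  if (length(sp) >= 2) {
    for (i in 1:(length(sp) - 1)) for (j in (i + 1):length(sp)) {
      if (constant[i] || constant[j]) next
      pc <- pearson_cor(sub[i, ], sub[j, ])
      if (is.na(pc$cc) || is.na(pc$p)) next
      if (pc$p < edge_p && (pc$cc > pos_cc || pc$cc < neg_cc)) {
        k <- k + 1L
        edges[[k]] <- data.frame(
          a = sp[i], b = sp[j], cc = pc$cc, p = pc$p,
          sign = if (pc$cc > 0) "positive" else "negative",
          width = edge_width_category(pc$cc),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (k) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0), cc = numeric(0),
               p = numeric(0), sign = character(0), width = character(0))
  degree <- setNames(integer(length(sp)), sp)
  if (nrow(edges)) {
    dtab <- table(c(edges$a, edges$b))
    degree[names(dtab)] <- as.integer(dtab)
  }
  mean_ab <- rowMeans(sub)
  top_by <- function(v) {
    ord <- order(-v, names(v))  # stable: ties lexicographic
    flags <- setNames(rep(FALSE, length(v)), names(v))
    flags[names(v)[ord[seq_len(min(10, length(v)))]]] <- TRUE
    flags
  }
  nodes <- data.frame(
    species = sp,
    direction = enriched$direction[match(sp, enriched$species)],
    mean_abundance = unname(mean_ab),
    decade_bin = abundance_decade_bin(unname(mean_ab), scale),
    degree = unname(degree),
    top10_degree = unname(top_by(degree)[sp]),
    top10_abundance = unname(top_by(mean_ab)[sp]),
    flag = ifelse(constant, "constant-abundance", NA_character_),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 params = list(edge_p = edge_p, pos_cc = pos_cc,
                               neg_cc = neg_cc, scale = scale)),
            class = "coabundance_network")
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat(sprintf("Co-abundance network: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  cat(sprintf("  edge rule: p < %g and cc > %g or cc < %g\n",
              x$params$edge_p, x$params$pos_cc, x$params$neg_cc))
  invisible(x)
}

#' Export a co-abundance network to GraphML
#'
#' @param net a [build_coabundance_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("a", "b", "cc", "p", "sign", "width"), drop = FALSE],
    directed = FALSE, vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read-mapping ratio comparison between groups
#'
#' The mapping ratio of a sample is mapped reads divided by total reads.
#' Per target (species or strain gene set), ratios are compared between
#' case and control with the unpaired rank-sum test; BH adjustment across
#' targets.
#'
#' @param mapped numeric matrix, samples by targets (or a vector for a
#'   single target), of mapped-read counts.
#' @param total numeric vector of per-sample total reads (> 0).
#' @param groups character vector in `{"case", "control"}` per sample.
#' @return list with `ratios` (samples-by-targets matrix) and `tests`
#'   (data.frame: target, p, q, direction).
#' @export
mapping_ratio_compare <- function(mapped, total, groups) {
  if (is.vector(mapped)) mapped <- matrix(mapped, ncol = 1,
                                          dimnames = list(NULL, "target"))
  stop_if_not(all(total > 0), "mapping_ratio_compare: totals must be > 0")
  stop_if_not(nrow(mapped) == length(total) && length(groups) == length(total),
              "mapping_ratio_compare: dimension mismatch")
  stop_if_not(all(mapped <= total), "mapping_ratio_compare: mapped > total")
  stop_if_not(all(groups %in% c("case", "control")),
              "mapping_ratio_compare: groups must be 'case'/'control'")
  ratios <- sweep(mapped, 1, total, "/")
  tests <- lapply(colnames(ratios), function(tg) {
    rs <- ranksum(ratios[groups == "case", tg], ratios[groups == "control", tg])
    data.frame(target = tg, p = rs$p,
               direction = switch(rs$direction, x = "case", y = "control",
                                  "none"),
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  tests$q <- bh_fdr(tests$p)
  list(ratios = ratios, tests = tests[, c("target", "p", "q", "direction")])
}
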