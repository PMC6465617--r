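# Three-stage genome quality control:
#   1. five high-quality draft criteria (assembly contiguity + core-gene recovery)
#   2. completeness/contamination gate
#   3. intra-species ANI purity filter
# All thresholds are strict inequalities except the contig-fraction criterion,
# which is >= 0.98 ("98% of the assembly must be present in contigs").

#' Assembly N50
#'
#' Smallest length L such that contigs (or scaffolds) of length >= L jointly
#' cover at least half the total assembly.
#'
#' @param lengths positive integer vector of contig/scaffold lengths.
#' @return N50 in bases.
#' @examples
#' n50(c(5, 4, 3, 2))  # 4: total 14, 5 + 4 = 9 >= 7
#' @export
n50 <- function(lengths) {
  stop_if_not(length(lengths) > 0, "no contigs")
  stop_if_not(all(lengths > 0), "n50: lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly statistics record
#'
#' Bundles the quantities evaluated by the five draft-genome quality criteria.
#'
#' @param total_length total assembly length (bases).
#' @param contig_lengths vector of contig lengths (bases).
#' @param scaffold_n50 scaffold N50 (bases).
#' @param contig_n50 contig N50; computed from `contig_lengths` if `NULL`.
#' @param mean_contig_length mean contig length; computed if `NULL`.
#' @param frac_in_long_contigs fraction of the total assembly contained in
#'   contigs longer than 500 bp.
#' @param core_gene_fraction fraction of a reference core-gene set detected
#'   in the assembly (the reference catalogue is supplied by the caller, it
#'   is not shipped with the package).
#' @return object of class `"assembly_stats"`.
#' @export
assembly_stats <- function(total_length, contig_lengths, scaffold_n50,
                           contig_n50 = NULL, mean_contig_length = NULL,
                           frac_in_long_contigs, core_gene_fraction) {
  stop_if_not(total_length > 0 && all(contig_lengths > 0) && scaffold_n50 > 0,
              "assembly_stats: lengths must be positive")
  contig_n50 <- contig_n50 %||% n50(contig_lengths)
  mean_contig_length <- mean_contig_length %||% mean(contig_lengths)
  stop_if_not(contig_n50 <= max(contig_lengths),
              "assembly_stats: contig_n50 exceeds longest contig")
  stop_if_not(frac_in_long_contigs >= 0 && frac_in_long_contigs <= 1 &&
                core_gene_fraction >= 0 && core_gene_fraction <= 1,
              "assembly_stats: fractions must be in [0, 1]")
  structure(list(total_length = total_length,
                 contig_lengths = contig_lengths,
                 scaffold_n50 = scaffold_n50,
                 contig_n50 = contig_n50,
                 mean_contig_length = mean_contig_length,
                 frac_in_long_contigs = frac_in_long_contigs,
                 core_gene_fraction = core_gene_fraction),
            class = "assembly_stats")
}

#' Five draft-genome quality criteria
#'
#' A draft assembly passes when all five hold:
#' (i) at least 98% of the total assembly is in contigs > 500 bp;
#' (ii) scaffold N50 > 20 kb; (iii) contig N50 > 20 kb;
#' (iv) mean contig length > 10 kb; (v) more than 90% of the reference
#' core genes are detected. Criteria (ii)-(v) are strict.
#'
#' @param assembly an [assembly_stats()] object (or compatible list).
#' @return list with `pass` (logical) and `report`, a data.frame with one
#'   row per criterion: value, threshold, verdict.
#' @export
hmp_draft_pass <- function(assembly) {
  a <- assembly
  report <- data.frame(
    criterion = c("frac_in_long_contigs", "scaffold_n50", "contig_n50",
                  "mean_contig_length", "core_gene_fraction"),
    value = c(a$frac_in_long_contigs, a$scaffold_n50, a$contig_n50,
              a$mean_contig_length, a$core_gene_fraction),
    threshold = c(">= 0.98", "> 20000", "> 20000", "> 10000", "> 0.90"),
    pass = c(a$frac_in_long_contigs >= 0.98,
             a$scaffold_n50 > 20000,
             a$contig_n50 > 20000,
             a$mean_contig_length > 10000,
             a$core_gene_fraction > 0.90),
    stringsAsFactors = FALSE
  )
  list(pass = all(report$pass), report = report)
}

#' Completeness/contamination gate
#'
#' Pass iff completeness > 95 and contamination < 5 (both strict), on the
#' percent scale reported by genome quality-assessment tools.
#'
#' @param completeness_pct,contamination_pct percentages in \[0, 100\].
#' @return logical.
#' @export
checkm_gate <- function(completeness_pct, contamination_pct) {
  stop_if_not(all(completeness_pct >= 0 & completeness_pct <= 100) &&
                all(contamination_pct >= 0 & contamination_pct <= 100),
              "checkm_gate: values must be in [0, 100]")
  completeness_pct > 95 & contamination_pct < 5
}

#' Intra-species ANI purity filter
#'
#' Enforces that every within-species genome pair has ANI strictly above
#' `threshold`. Removal is iterative: while any pair fails, the genome with
#' the lowest mean intra-species ANI is dropped and the check repeats on the
#' remainder. The log records the removal order and each removed genome's
#' mean ANI at removal time.
#'
#' @param ani symmetric numeric matrix of pairwise ANI values (percent) with
#'   genome identifiers as dimnames, covering all genomes of one species.
#' @param threshold retained pairs must satisfy ANI > threshold (default 93).
#' @return list with `retained` (character vector of genome ids), `removed`
#'   (data.frame: step, genome_id, mean_intra_ani, reason) and `note`.
#' @export
intra_species_purity_filter <- function(ani, threshold = 93) {
  stop_if_not(is.matrix(ani) && nrow(ani) == ncol(ani),
              "purity filter: ani must be a square matrix")
  stop_if_not(!is.null(rownames(ani)) && identical(rownames(ani), colnames(ani)),
              "purity filter: ani needs matching dimnames")
  stop_if_not(isTRUE(all.equal(ani, t(ani), tolerance = 1e-8)),
              "purity filter: ani must be symmetric")
  ids <- rownames(ani)
  if (length(ids) < 2) {
    return(list(retained = ids,
                removed = data.frame(step = integer(0), genome_id = character(0),
                                     mean_intra_ani = numeric(0),
                                     reason = character(0)),
                note = "fewer than 2 genomes; nothing to check"))
  }
  removed <- list()
  step <- 0L
  repeat {
    sub <- ani[ids, ids, drop = FALSE]
    off <- sub[upper.tri(sub)]
    if (length(ids) < 2 || all(off > threshold)) break
    step <- step + 1L
    mean_ani <- (rowSums(sub) - diag(sub)) / (length(ids) - 1)
    worst <- names(which.min(mean_ani))
    removed[[step]] <- data.frame(
      step = step, genome_id = worst,
      mean_intra_ani = unname(mean_ani[worst]),
      reason = sprintf("pair(s) at ANI <= %g; lowest mean intra-species ANI",
                       threshold),
      stringsAsFactors = FALSE)
    ids <- setdiff(ids, worst)
  }
  list(retained = ids,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(step = integer(0), genome_id = character(0),
                    mean_intra_ani = numeric(0), reason = character(0)),
       note = NA_character_)
}

#' Default isolation-source friendliness keywords
#'
#' Keyword table mapping isolation-source text to a friendliness class.
#' Sources associated with food fermentation or the healthy human gut are
#' "friendly"; clinical or environmental sources are "unfriendly". The table
#' is a plain data.frame and can be extended or replaced by the caller.
#'
#' @return data.frame with columns `keyword`, `class`.
#' @export
friendliness_keywords <- function() {
  path <- system.file("extdata", "friendliness_keywords.tsv",
                      package = "panprobio")
  read_tsv_file(path)
}

#' Classify isolation sources as friendly/unfriendly/unknown
#'
#' Case-insensitive substring match against a keyword table; the first
#' matching keyword (in table order) decides. Unmatched sources are
#' `"unknown"`.
#'
#' @param source character vector of isolation-source descriptions.
#' @param keywords keyword table as from [friendliness_keywords()].
#' @return character vector in `{"friendly", "unfriendly", "unknown"}`.
#' @export
classify_friendliness <- function(source, keywords = friendliness_keywords()) {
  vapply(source, function(s) {
    if (is.na(s) || !nzchar(s)) return("unknown")
    hit <- which(vapply(keywords$keyword,
                        function(k) grepl(tolower(k), tolower(s), fixed = TRUE),
                        logical(1)))
    if (length(hit)) keywords$class[hit[1L]] else "unknown"
  }, character(1), USE.NAMES = FALSE)
}

#' Run the full genome QC gate over a metadata table
#'
#' Applies the draft criteria and the completeness/contamination gate per
#' genome, then the intra-species ANI purity filter per species on the
#' survivors.
#'
#' @param meta data.frame with columns `genome_id`, `species_label`,
#'   `completeness_pct`, `contamination_pct`, and the five assembly columns
#'   `frac_in_long_contigs`, `scaffold_n50`, `contig_n50`,
#'   `mean_contig_length`, `core_gene_fraction`. An optional
#'   `isolation_source` column is classified into a `friendliness` column.
#' @param ani optional full symmetric ANI matrix over `meta$genome_id`; if
#'   supplied, the purity filter runs per species.
#' @param ani_threshold intra-species ANI retention threshold (percent).
#' @return data.frame: `meta` plus logical columns `hmp_pass`, `checkm_pass`,
#'   `ani_pass`, `retained`, and `friendliness` when sources are present.
#' @export
genome_qc_report <- function(meta, ani = NULL, ani_threshold = 93) {
  need <- c("genome_id", "species_label", "completeness_pct",
            "contamination_pct", "frac_in_long_contigs", "scaffold_n50",
            "contig_n50", "mean_contig_length", "core_gene_fraction")
  stop_if_not(all(need %in% names(meta)),
              paste("genome_qc_report: missing columns:",
                    paste(setdiff(need, names(meta)), collapse = ", ")))
  out <- meta
  out$hmp_pass <- vapply(seq_len(nrow(meta)), function(i) {
    hmp_draft_pass(list(
      frac_in_long_contigs = meta$frac_in_long_contigs[i],
      scaffold_n50 = meta$scaffold_n50[i],
      contig_n50 = meta$contig_n50[i],
      mean_contig_length = meta$mean_contig_length[i],
      core_gene_fraction = meta$core_gene_fraction[i]))$pass
  }, logical(1))
  out$checkm_pass <- checkm_gate(meta$completeness_pct, meta$contamination_pct)
  out$ani_pass <- TRUE
  if (!is.null(ani)) {
    for (sp in unique(out$species_label)) {
      ids <- out$genome_id[out$species_label == sp &
                             out$hmp_pass & out$checkm_pass]
      ids <- intersect(ids, rownames(ani))
      if (length(ids) < 2) next
      pf <- intra_species_purity_filter(ani[ids, ids, drop = FALSE],
                                        threshold = ani_threshold)
      out$ani_pass[out$genome_id %in% setdiff(ids, pf$retained)] <- FALSE
    }
  }
  out$retained <- out$hmp_pass & out$checkm_pass & out$ani_pass
  if ("isolation_source" %in% names(meta)) {
    out$friendliness <- classify_friendliness(meta$isolation_source)
  }
  out
}
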