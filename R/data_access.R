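# Bundled reference tables: published per-(sub)species retained-genome tallies
# for the 15 major traditional probiotic (sub)species and the per-cohort fecal
# metagenome sample sizes used in the disease-association analyses. These are
# the inputs for the pair- and sample-bookkeeping computations.

#' Retained genome counts per probiotic (sub)species
#'
#' Published tallies of quality-controlled genomes for the 15 major
#' traditional probiotic (sub)species (444 genomes in total). Used as the
#' species-size input to [cross_species_pairs()].
#'
#' @return data.frame with columns `species`, `n_genomes`.
#' @export
mtps_strain_counts <- function() {
  read_tsv_file(system.file("extdata", "mtps_strain_counts.tsv",
                            package = "panprobio"))
}

#' Case/control sample sizes of the eight gut-metagenome cohorts
#'
#' Published control/case sample counts for the eight disease cohorts
#' (obesity, type 2 diabetes, atherosclerotic cardiovascular disease,
#' Crohn's disease, colorectal cancer, liver cirrhosis, ankylosing
#' spondylitis, rheumatoid arthritis); 1,815 samples in total.
#'
#' @return data.frame with columns `cohort`, `n_control`, `n_case`.
#' @export
mtps_cohort_samples <- function() {
  read_tsv_file(system.file("extdata", "cohort_samples.tsv",
                            package = "panprobio"))
}
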