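# Fragment-based average nucleotide / amino-acid identity.
#
# The one-way identity of a query genome against a reference cuts the query
# into consecutive fragments, places each fragment on the reference by exact
# k-mer seeding with diagonal voting, scores the placement ungapped, and
# averages the identities of fragments passing the conventional acceptance
# rule (>= 30% identity over >= 70% of the fragment). The pairwise value is
# the mean of the two one-way directions, so it is symmetric by construction.

#' Fragment-alignment parameters
#'
#' Defaults follow common fragment-ANI practice: 1,020 bp fragments with
#' 11-mer seeds for nucleotides, 300 aa fragments with 4-mer seeds for
#' proteins; fragments are accepted at >= 30% identity over >= 70% of the
#' fragment.
#'
#' @param kind `"nt"` or `"aa"`.
#' @param fragment_length fragment size (bases or residues).
#' @param seed_k exact-seed k-mer size; must not exceed `fragment_length`.
#' @param min_fragment_identity acceptance identity threshold (percent).
#' @param min_fragment_coverage acceptance coverage threshold (fraction of
#'   the fragment aligned).
#' @return list of class `"fragment_params"`.
#' @export
fragment_params <- function(kind = c("nt", "aa"),
                            fragment_length = NULL, seed_k = NULL,
                            min_fragment_identity = 30,
                            min_fragment_coverage = 0.7) {
  kind <- match.arg(kind)
  fragment_length <- fragment_length %||% if (kind == "nt") 1020L else 300L
  seed_k <- seed_k %||% if (kind == "nt") 11L else 4L
  stop_if_not(fragment_length >= seed_k,
              "fragment_params: fragment_length must be >= seed_k")
  stop_if_not(min_fragment_identity >= 0 && min_fragment_identity <= 100 &&
                min_fragment_coverage > 0 && min_fragment_coverage <= 1,
              "fragment_params: thresholds out of range")
  structure(list(kind = kind, fragment_length = as.integer(fragment_length),
                 seed_k = as.integer(seed_k),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage),
            class = "fragment_params")
}

# coerce FASTA-ish inputs (XStringSet, named character) to character vector
as_seq_chr <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  x <- as.character(x)
  stop_if_not(length(x) > 0 && all(nzchar(x)), "empty sequence set")
  toupper(x)
}

# all k-mers of a string as a character vector (position i -> k-mer at i)
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

#' One-way fragment identity of a query sequence set against a reference
#'
#' The query sequences are cut into consecutive fragments of
#' `params$fragment_length` (a sequence shorter than one fragment is used
#' whole). Each fragment is placed at its best ungapped reference location:
#' exact `seed_k`-mer matches vote for a diagonal offset, the modal offset
#' wins (ties broken by the smallest offset, i.e. first-encountered
#' reference position), and identity is counted over the aligned columns at
#' that offset. Fragments reaching `min_fragment_identity` percent identity
#' over at least `min_fragment_coverage` of their length are accepted; the
#' result is the mean identity of accepted fragments.
#'
#' @param query,reference sequence sets: named character vectors or
#'   `Biostrings::XStringSet`.
#' @param params a [fragment_params()] object.
#' @return percent identity (numeric scalar), or `NA` with attribute
#'   `no_alignment = TRUE` when no fragment is accepted. The attributes
#'   `n_fragments` and `n_accepted` report fragment bookkeeping.
#' @export
one_way_identity <- function(query, reference, params = fragment_params("nt")) {
  q <- as_seq_chr(query); r <- as_seq_chr(reference)
  k <- params$seed_k; L <- params$fragment_length
  sep <- strrep("#", k)
  refcat <- paste(r, collapse = sep)
  ref_kmers <- seq_kmers(refcat, k)
  nref <- nchar(refcat)
  ref_raw <- charToRaw(refcat)

  frags <- character(0)
  for (s in q) {
    len <- nchar(s)
    starts <- seq(1L, max(1L, len - L + 1L), by = L)
    frags <- c(frags, substring(s, starts, pmin(starts + L - 1L, len)))
  }
  frags <- frags[nchar(frags) >= k]
  n_acc <- 0L
  idents <- numeric(0)
  for (f in frags) {
    flen <- nchar(f)
    fk <- seq_kmers(f, k)
    m <- match(ref_kmers, fk)
    idx <- which(!is.na(m))
    if (!length(idx)) next
    offs <- idx - m[idx]           # fragment position j maps to refcat j + off
    tab <- table(offs)
    best <- as.integer(names(tab)[tab == max(tab)])
    off <- min(best)
    a1 <- max(1L, 1L + off); a2 <- min(nref, flen + off)
    if (a2 < a1) next
    ref_win <- ref_raw[a1:a2]
    frag_win <- charToRaw(f)[(a1 - off):(a2 - off)]
    cols <- length(ref_win)
    matches <- sum(ref_win == frag_win)
    ident <- 100 * matches / cols
    cov <- cols / flen
    if (ident >= params$min_fragment_identity &&
        cov >= params$min_fragment_coverage) {
      n_acc <- n_acc + 1L
      idents <- c(idents, ident)
    }
  }
  if (!length(idents)) {
    return(structure(NA_real_, no_alignment = TRUE,
                     n_fragments = length(frags), n_accepted = 0L))
  }
  structure(mean(idents), no_alignment = FALSE,
            n_fragments = length(frags), n_accepted = n_acc)
}

#' Bidirectionally averaged pairwise identity (ANI/AAI)
#'
#' Mean of the two one-way fragment identities (a against b, b against a).
#' If one direction yields no alignment the other direction is reported; if
#' both fail, `NA` with attribute `no_alignment = TRUE`.
#'
#' @inheritParams one_way_identity
#' @param a,b sequence sets.
#' @return percent identity, symmetric in `a` and `b`.
#' @export
symmetric_identity <- function(a, b, params = fragment_params("nt")) {
  ab <- one_way_identity(a, b, params)
  ba <- one_way_identity(b, a, params)
  vals <- c(ab, ba)
  if (all(is.na(vals))) {
    return(structure(NA_real_, no_alignment = TRUE))
  }
  structure(mean(vals, na.rm = TRUE), no_alignment = FALSE)
}

#' Pairwise identity matrix over a set of genomes
#'
#' @param seq_sets named list of sequence sets (one per genome: character
#'   vector or `XStringSet`).
#' @param params a [fragment_params()] object; `params$kind` decides whether
#'   the result is labelled ANI or AAI.
#' @return symmetric numeric matrix (percent), diagonal 100, with attribute
#'   `kind` in `{"ANI", "AAI"}`; cells with no alignment are `NA`.
#' @export
identity_matrix <- function(seq_sets, params = fragment_params("nt")) {
  ids <- names(seq_sets)
  stop_if_not(!is.null(ids) && all(nzchar(ids)),
              "identity_matrix: seq_sets must be named")
  n <- length(seq_sets)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- symmetric_identity(seq_sets[[i]], seq_sets[[j]], params)
      m[i, j] <- m[j, i] <- as.numeric(v)
    }
  }
  structure(m, kind = if (params$kind == "nt") "ANI" else "AAI")
}

# --- protein-pair identity via local alignment (used for RBH and clustering) ---

aa_submat <- function(match = 2, mismatch = -2) {
  letters <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
               "S","T","V","W","Y","X","*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

# local alignment of each sequence in `patterns` against `subject`;
# identity over aligned columns and coverage of the shorter sequence
seq_ident_cov <- function(patterns, subject) {
  ps <- Biostrings::AAStringSet(patterns)
  aln <- Biostrings::pairwiseAlignment(ps, Biostrings::AAString(subject),
                                       type = "local",
                                       substitutionMatrix = aa_submat(),
                                       gapOpening = 4, gapExtension = 2)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  cols <- nm + nmm
  shorter <- pmin(nchar(patterns), nchar(subject))
  ident <- ifelse(cols > 0, 100 * nm / cols, 0)
  cov <- ifelse(cols > 0, cols / shorter, 0)
  data.frame(identity = ident, coverage = cov)
}

# mean identity over reciprocal best hits between two protein sets;
# per-pair identity is counted over the shorter sequence (identity within
# the aligned region times its coverage), so short chance local matches
# between unrelated proteins do not inflate the value
rbh_aai <- function(a, b) {
  ia <- seq_ident_cov_matrix(a, b)
  best_ab <- apply(ia, 1, which.max)     # for each a, best b
  best_ba <- apply(ia, 2, which.max)     # for each b, best a
  rbh <- which(best_ba[best_ab] == seq_along(best_ab))
  if (!length(rbh)) return(structure(NA_real_, no_alignment = TRUE))
  mean(ia[cbind(rbh, best_ab[rbh])])
}

# full identity-over-shorter matrix between two protein sets (rows = a)
seq_ident_cov_matrix <- function(a, b) {
  m <- matrix(0, length(a), length(b))
  for (j in seq_along(b)) {
    ic <- seq_ident_cov(a, b[[j]])
    m[, j] <- ic$identity * ic$coverage
  }
  m
}

#' Species-level AAI matrix and intra-species AAI dispersion
#'
#' Every strain pair's AAI is the mean identity over reciprocal-best-hit
#' pairs of their core-protein sets. The species-level matrix averages the
#' cross-species strain-pair AAIs; the intra-species dispersion is the
#' standard deviation of all within-species strain-pair AAIs (0 when a
#' species has a single pair, `NA` when it has a single strain).
#'
#' @param proteins named list: one character vector of core-protein
#'   sequences per strain.
#' @param species character vector of species labels aligned with
#'   `proteins` (or named by strain).
#' @return list with `species_matrix` (symmetric percent AAI, diagonal 100),
#'   `intra_sd` (named numeric per species), and `strain_pairs` (data.frame
#'   a, b, species_a, species_b, aai).
#' @export
aai_stats <- function(proteins, species) {
  stop_if_not(length(proteins) == length(species),
              "aai_stats: proteins/species length mismatch")
  strains <- names(proteins)
  stop_if_not(!is.null(strains), "aai_stats: proteins must be named by strain")
  n <- length(proteins)
  pairs <- list()
  idx <- 0L
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      idx <- idx + 1L
      pairs[[idx]] <- data.frame(
        a = strains[i], b = strains[j],
        species_a = species[i], species_b = species[j],
        aai = as.numeric(rbh_aai(proteins[[i]], proteins[[j]])),
        stringsAsFactors = FALSE)
    }
  }
  sp_df <- do.call(rbind, pairs)
  sps <- unique(species)
  m <- matrix(NA_real_, length(sps), length(sps), dimnames = list(sps, sps))
  diag(m) <- 100
  if (length(sps) >= 2) {
    for (i in 1:(length(sps) - 1)) for (j in (i + 1):length(sps)) {
      sel <- (sp_df$species_a == sps[i] & sp_df$species_b == sps[j]) |
             (sp_df$species_a == sps[j] & sp_df$species_b == sps[i])
      if (any(sel)) m[i, j] <- m[j, i] <- mean(sp_df$aai[sel], na.rm = TRUE)
    }
  }
  intra_sd <- vapply(sps, function(s) {
    v <- sp_df$aai[sp_df$species_a == s & sp_df$species_b == s]
    if (length(v) == 0) NA_real_ else if (length(v) == 1) 0 else stats::sd(v)
  }, numeric(1))
  list(species_matrix = structure(m, kind = "AAI"),
       intra_sd = intra_sd, strain_pairs = sp_df)
}

#' Single-linkage clusters at an identity cutoff
#'
#' Connected components of the graph with an edge between two labels
#' whenever their identity is at or above `cutoff`.
#'
#' @param mat symmetric identity matrix (percent) with dimnames.
#' @param cutoff edge threshold (percent), default 70.
#' @return named integer vector of cluster memberships (1-based, in order of
#'   first appearance).
#' @export
aai_clusters <- function(mat, cutoff = 70) {
  stop_if_not(is.matrix(mat) && nrow(mat) == ncol(mat),
              "aai_clusters: need a square matrix")
  adj <- !is.na(mat) & mat >= cutoff
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}
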