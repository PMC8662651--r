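# Shared fixtures and independent oracles for the test suite.

toy_aln <- function(match, ids = sprintf("s%d", seq_along(match)), ...) {
  profile_alignment(tibble::tibble(sequence_id = ids, match = match, ...))
}

# Independent all-pairs identity oracle: plain double loop over characters,
# written without reference to the package's vectorised implementation.
brute_identity <- function(aln) {
  ch <- lapply(aln$match, function(s) strsplit(s, "")[[1]])
  n <- length(ch)
  out <- matrix(1, n, n, dimnames = list(aln$sequence_id, aln$sequence_id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (k in seq_along(ch[[i]])) {
      a <- ch[[i]][k]; b <- ch[[j]][k]
      if (a != "-" && b != "-") {
        den <- den + 1
        if (a == b && a != "X") num <- num + 1
      }
    }
    out[i, j] <- if (den == 0) 0 else num / den
  }
  out
}

# Deepest hierarchy node containing each sequence (planted-truth ARI
# comparisons use this as the induced flat partition).
deepest_assignment <- function(h, ids) {
  depth <- vapply(h$id, function(x) length(kinclust::node_ancestors(h, x)),
                  integer(1))
  vapply(ids, function(id) {
    hits <- h$id[vapply(seq_len(nrow(h)),
                        function(i) id %in% h$members[[i]], logical(1))]
    hits[which.max(depth[hits])]
  }, character(1))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Independent intron-phase oracle: lay the coding sequence out nucleotide
# by nucleotide, labelling each with its position within a codon, and read
# the phase of each exon boundary off the label of the following
# nucleotide.
codon_walk_phases <- function(exon_lengths) {
  total <- sum(exon_lengths)
  within_codon <- ((seq_len(total) - 1) %% 3)  # 0,1,2,0,1,2,...
  bounds <- cumsum(exon_lengths)
  bounds <- bounds[-length(bounds)]
  vapply(bounds, function(b) as.integer(within_codon[b + 1]), integer(1))
}

# A deterministic 2-level planted simulation small enough for fast tests.
small_sim <- function(seed = 1, n_per_leaf = 20, n_columns = 120) {
  simulate_kinome(seed = seed, n_per_leaf = n_per_leaf,
                  n_columns = n_columns)
}
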