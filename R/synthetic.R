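#' Built-in toy holozoan taxonomy
#'
#' A small, fixed taxonomy in the shape of the holozoan clades relevant to
#' tyrosine kinase evolution (premetazoan lineages through chordates),
#' with a handful of synthetic species leaves per terminal clade. Used by
#' the synthetic-data generators; round-trips through
#' [write_taxdump()]/[parse_taxdump()].
#'
#' @return A `kc_taxonomy` tibble.
#' @export
make_taxonomy <- function() {
  clades <- tibble(
    tax_id = 1:13,
    parent_id = c(NA, 1L, 2L, 3L, 3L, 3L, 6L, 6L, 8L, 8L, 10L, 10L, 12L),
    rank = c("no rank", rep("clade", 5), "phylum", "clade", "phylum",
             "clade", "clade", "clade", "phylum"),
    name = c("root", "Opisthokonta", "Holozoa", "Choanoflagellata",
             "Filasterea", "Metazoa", "Porifera", "Eumetazoa", "Cnidaria",
             "Bilateria", "Protostomia", "Deuterostomia", "Chordata")
  )
  species <- tibble(
    tax_id = 101:120,
    parent_id = c(4L, 4L, 5L, 5L, 7L, 7L, 7L, 9L, 9L, 9L,
                  11L, 11L, 11L, 11L, 13L, 13L, 13L, 13L, 13L, 13L),
    rank = "species",
    name = c(sprintf("Choanoflagellate sp. %d", 1:2),
             sprintf("Filasterean sp. %d", 1:2),
             sprintf("Sponge sp. %d", 1:3),
             sprintf("Cnidarian sp. %d", 1:3),
             sprintf("Protostome sp. %d", 1:4),
             sprintf("Chordate sp. %d", 1:6))
  )
  new_tibble(bind_rows(clades, species), class = "kc_taxonomy")
}

#' Plant a random constraint hierarchy
#'
#' Builds a two-level tree (root, superclusters, subclusters per
#' supercluster) and plants `constraints_per_node` constraints on every
#' non-root node: columns sampled without replacement across the whole
#' tree (so constrained columns are distinct), residue sets of size 1–2,
#' weights uniform in `[weight_low, weight_high]` nats. The root carries
#' no constraints — universally conserved positions carry no contrast.
#'
#' @param n_supers Number of superclusters. Default 2.
#' @param subs_per_super Subclusters per supercluster. Default 2.
#' @param constraints_per_node Constraints per non-root node. Default 5.
#' @param weight_low,weight_high Weight range in nats. Default 1–4.
#' @param n_columns Alignment width. Default 200.
#' @param seed Integer seed.
#' @return A `kc_hierarchy` (memberships empty until
#'   [make_sequences()]).
#' @export
make_hierarchy <- function(n_supers = 2, subs_per_super = 2,
                           constraints_per_node = 5, weight_low = 1,
                           weight_high = 4, n_columns = 200, seed = 0) {
  n_nodes <- n_supers * (1 + subs_per_super)
  needed <- n_nodes * constraints_per_node
  if (needed > n_columns) {
    abort("not enough columns for the requested constraints")
  }
  set.seed(seed)
  cols <- sample.int(n_columns, needed)
  ids <- c("root",
           unlist(lapply(seq_len(n_supers), function(i) {
             c(sprintf("S%d", i),
               sprintf("S%d.%d", i, seq_len(subs_per_super)))
           })))
  parents <- c(NA_character_,
               unlist(lapply(seq_len(n_supers), function(i) {
                 c("root", rep(sprintf("S%d", i), subs_per_super))
               })))
  k <- 0L
  cons <- lapply(ids, function(id) {
    if (id == "root") {
      return(tibble(column = integer(0), residues = character(0),
                    weight = numeric(0)))
    }
    idx <- (k + 1L):(k + constraints_per_node)
    k <<- k + constraints_per_node
    tibble(
      column = sort(cols[idx]),
      residues = vapply(idx, function(i) {
        paste(sort(sample(kc_alphabet, sample(1:2, 1))), collapse = "")
      }, character(1)),
      weight = runif(constraints_per_node, weight_low, weight_high)
    )
  })
  constraint_hierarchy(
    tibble(id = ids, name = ids, parent_id = parents, constraints = cons),
    n_columns = n_columns)
}

#' Generate sequences from a planted hierarchy
#'
#' Each leaf cluster receives `n_per_leaf` sequences. At every effective
#' constraint column of the leaf (its own plus ancestors'), the residue is
#' drawn from the constraint's residue set with probability `fidelity`,
#' otherwise from the background composition; unconstrained columns are
#' pure background. With `fidelity = 1` every member scores exactly 1
#' against its own leaf.
#'
#' @param h A planted `kc_hierarchy` (e.g. [make_hierarchy()]).
#' @param n_per_leaf Sequences per leaf. Default 50.
#' @param fidelity Probability in (0.5, 1] of drawing from the constraint
#'   set at a constrained column. Default 0.95.
#' @param background `"uniform"` or a 20-vector of residue probabilities.
#' @param seed Integer seed.
#' @return List with `aln` (a `kc_aln`) and `truth` (a `kc_truth` list:
#'   planted `hierarchy` with memberships filled, and `labels` mapping
#'   each sequence to its leaf cluster).
#' @export
make_sequences <- function(h, n_per_leaf = 50, fidelity = 0.95,
                           background = "uniform", seed = 0) {
  if (fidelity <= 0.5 || fidelity > 1) {
    abort("`fidelity` must be in (0.5, 1]")
  }
  bg <- background_probs(background)
  set.seed(seed)
  n_col <- attr(h, "n_columns")
  leaves <- hierarchy_leaves(h)

  recs <- lapply(leaves, function(leaf) {
    eff <- effective_constraints(h, leaf)
    m <- matrix(sample(kc_alphabet, n_per_leaf * n_col, replace = TRUE,
                       prob = bg),
                nrow = n_per_leaf, ncol = n_col)
    if (!is.null(eff) && nrow(eff) > 0) {
      for (j in seq_len(nrow(eff))) {
        set <- strsplit(eff$residues[j], "", fixed = TRUE)[[1]]
        hit <- runif(n_per_leaf) < fidelity
        if (any(hit)) {
          m[hit, eff$column[j]] <- sample(set, sum(hit), replace = TRUE)
        }
      }
    }
    tibble(
      sequence_id = sprintf("%s_seq%02d", leaf, seq_len(n_per_leaf)),
      match = apply(m, 1, paste, collapse = ""),
      label = leaf
    )
  })
  recs <- bind_rows(recs)
  aln <- profile_alignment(recs[, c("sequence_id", "match")])

  h$members <- map(h$id, function(id) {
    sub <- node_subtree(h, id)
    recs$sequence_id[recs$label %in% sub]
  })
  truth <- structure(list(
    hierarchy = h,
    labels = tibble(sequence_id = recs$sequence_id,
                    cluster_id = recs$label)
  ), class = "kc_truth")
  list(aln = aln, truth = truth)
}

background_probs <- function(background) {
  if (identical(background, "uniform")) return(rep(1 / 20, 20))
  if (is.numeric(background) && length(background) == 20) {
    return(background / sum(background))
  }
  abort("`background` must be \"uniform\" or a 20-vector")
}

#' Assign organisms to synthetic sequences
#'
#' Each cluster has an emergence point in the taxonomy; each sequence's
#' organism is drawn uniformly from the species descending from its leaf
#' cluster's emergence node. The organism id is recorded as a UniProt
#' style `OX=` tag in the record description (so it survives an A2M
#' round-trip) and in `truth$taxa`.
#'
#' @param aln A synthetic `kc_aln`.
#' @param truth The matching `kc_truth`.
#' @param tax A `kc_taxonomy`.
#' @param emergence Named integer vector: leaf cluster id → taxon id.
#' @param seed Integer seed.
#' @return List with updated `aln` and `truth`.
#' @export
make_taxa <- function(aln, truth, tax, emergence, seed = 0) {
  if (!all(emergence %in% tax$tax_id)) {
    abort("emergence nodes must exist in the taxonomy")
  }
  set.seed(seed)
  species <- tax$tax_id[tax$rank == "species"]
  labels <- setNames(truth$labels$cluster_id, truth$labels$sequence_id)
  pools <- lapply(emergence, function(node) {
    pool <- intersect(taxon_descendants(tax, node), species)
    if (length(pool) == 0) node else pool
  })
  ox <- vapply(aln$sequence_id, function(id) {
    pool <- pools[[labels[[id]]]]
    if (length(pool) == 1) pool else sample(pool, 1)
  }, integer(1))
  aln$organism_id <- unname(ox)
  aln$description <- sprintf("OX=%d", unname(ox))
  truth$taxa <- tibble(sequence_id = aln$sequence_id,
                       taxon_id = unname(ox))
  truth$emergence <- emergence
  list(aln = aln, truth = truth)
}

#' Plant DE-insert loops with clade-specific length distributions
#'
#' Adds an insert segment between the alphaD-end and alphaE-start anchor
#' columns of every sequence: lengths are Poisson with mean `long_mean`
#' (default 70) for longDE-clade sequences and `short_mean` (default 4)
#' for shortDE, emulating the bimodal loop-length split between receptor
#' and cytoplasmic tyrosine kinase clades.
#'
#' @inheritParams make_taxa
#' @param long_mean,short_mean Poisson means (residues).
#' @param clade_map Named character vector leaf cluster → `"longDE"` /
#'   `"shortDE"`. Default: leaves under the first supercluster are
#'   shortDE, all others longDE.
#' @param d_end,e_start Anchor columns; default from
#'   `column_labels(aln)`.
#' @param seed Integer seed.
#' @return List with updated `aln` and `truth` (gains `clades` and
#'   `loop_model`).
#' @export
make_de_inserts <- function(aln, truth, long_mean = 70, short_mean = 4,
                            clade_map = NULL, d_end = NULL, e_start = NULL,
                            seed = 0) {
  labs <- column_labels(aln)
  d_end <- d_end %||% labs[["alphaD_end"]]
  e_start <- e_start %||% labs[["alphaE_start"]]
  if (is.null(d_end) || is.null(e_start) || d_end >= e_start) {
    abort("valid `d_end` < `e_start` anchors required")
  }
  h <- truth$hierarchy
  if (is.null(clade_map)) {
    supers <- hierarchy_children(h, hierarchy_root(h))
    leaves <- hierarchy_leaves(h)
    clade_map <- setNames(
      ifelse(map_lgl(leaves, function(l)
        supers[1] %in% node_ancestors(h, l) || l == supers[1]),
        "shortDE", "longDE"),
      leaves)
  }
  set.seed(seed)
  labels <- setNames(truth$labels$cluster_id, truth$labels$sequence_id)
  means <- c(longDE = long_mean, shortDE = short_mean)
  lens <- vapply(aln$sequence_id, function(id) {
    rpois(1, means[[clade_map[[labels[[id]]]]]])
  }, integer(1))
  aln$inserts <- map2(aln$inserts, lens, function(ins, len) {
    ins[d_end + 1L] <- paste(sample(kc_alphabet, len, replace = TRUE),
                             collapse = "")
    ins
  })
  truth$clades <- clade_map
  truth$loop_model <- list(long_mean = long_mean, short_mean = short_mean,
                           d_end = d_end, e_start = e_start)
  list(aln = aln, truth = truth)
}

#' Plant gene structures with shared introns
#'
#' Generates a coding exon-length table per sequence such that the planted
#' introns, mapped back through [intron_phases()] and
#' [map_intron_to_alignment()], land at the specified (alignment column,
#' phase) pairs — by default a common phase-2 intron at the alphaH anchor
#' for all longDE-clade sequences. Extra random introns are added at a
#' Poisson(`exon_noise`) rate per sequence.
#'
#' @inheritParams make_taxa
#' @param intron_spec Named list clade → list of `c(column, phase)`
#'   pairs. Default: `longDE` gets phase 2 at the `alphaH` anchor.
#' @param exon_noise Mean number of extra random introns per sequence.
#'   Default 0.5.
#' @param seed Integer seed.
#' @return Tibble with `protein_id`, `exon_index`, `length_nt`.
#' @export
make_gene_structures <- function(aln, truth, intron_spec = NULL,
                                 exon_noise = 0.5, seed = 0) {
  if (is.null(intron_spec)) {
    alpha_h <- column_labels(aln)[["alphaH"]]
    if (is.null(alpha_h)) {
      abort("alphaH anchor required for the default intron placement")
    }
    intron_spec <- list(longDE = list(c(column = alpha_h, phase = 2)))
  }
  set.seed(seed)
  labels <- setNames(truth$labels$cluster_id, truth$labels$sequence_id)
  clades <- truth$clades %||%
    setNames(rep("longDE", length(unique(labels))), unique(labels))

  rows <- lapply(seq_len(nrow(aln)), function(i) {
    id <- aln$sequence_id[i]
    cmap <- residue_column_map(aln$match[i], aln$inserts[[i]])
    total_nt <- 3L * length(cmap)
    clade <- clades[[labels[[id]]]]
    bounds <- integer(0)
    for (sp in intron_spec[[clade]] %||% list()) {
      p1 <- which(cmap == sp[["column"]])
      if (length(p1) == 0) next
      b <- 3L * (p1 - 1L) + as.integer(sp[["phase"]])
      if (b > 0 && b < total_nt) bounds <- c(bounds, b)
    }
    n_extra <- rpois(1, exon_noise)
    if (n_extra > 0) {
      cand <- setdiff(seq_len(total_nt - 1L), bounds)
      bounds <- c(bounds, sample(cand, min(n_extra, length(cand))))
    }
    lens <- diff(c(0L, sort(bounds), total_nt))
    tibble(protein_id = id, exon_index = seq_along(lens),
           length_nt = as.integer(lens))
  })
  bind_rows(rows)
}

#' Default synthetic study preset
#'
#' Orchestrates all generators into the default study conditions used
#' throughout the package's tests: a 2-supercluster x 2-subcluster planted
#' hierarchy over 200 alignment columns, 50 sequences per leaf at
#' constraint fidelity 0.95, 5 constraints per node with weights in
#' \[1, 4\] nats, taxon emergence points spanning Holozoa through
#' Chordata, shortDE/longDE insert lengths Poisson(4)/Poisson(70), and a
#' shared planted phase-2 intron at the alphaH anchor of longDE
#' sequences. Structural anchors are placed at fixed fractions of the
#' alignment width.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_supers,subs_per_super,n_per_leaf,constraints_per_node,fidelity,n_columns,weight_low,weight_high
#'   Passed to [make_hierarchy()] / [make_sequences()].
#' @param long_mean,short_mean,exon_noise Passed to the loop and gene
#'   structure generators.
#' @return A `kc_sim` list: `aln`, `truth`, `taxonomy`, `exons`.
#' @export
simulate_kinome <- function(seed = 0, n_supers = 2, subs_per_super = 2,
                            n_per_leaf = 50, constraints_per_node = 5,
                            fidelity = 0.95, n_columns = 200,
                            weight_low = 1, weight_high = 4,
                            long_mean = 70, short_mean = 4,
                            exon_noise = 0.5) {
  set.seed(seed)
  stage_seeds <- sample.int(2^30, 5)

  h <- make_hierarchy(n_supers = n_supers, subs_per_super = subs_per_super,
                      constraints_per_node = constraints_per_node,
                      weight_low = weight_low, weight_high = weight_high,
                      n_columns = n_columns, seed = stage_seeds[1])
  sq <- make_sequences(h, n_per_leaf = n_per_leaf, fidelity = fidelity,
                       seed = stage_seeds[2])
  aln <- sq$aln
  truth <- sq$truth
  column_labels(aln) <- c(
    beta3_K = max(1L, round(0.10 * n_columns)),
    alphaD_end = round(0.30 * n_columns),
    alphaE_start = round(0.30 * n_columns) + 6L,
    DFG_D = round(0.60 * n_columns),
    alphaH = round(0.78 * n_columns)
  )
  taxonomy <- make_taxonomy()
  leaves <- hierarchy_leaves(truth$hierarchy)
  emergence <- setNames(rep(c(3L, 6L, 8L, 13L), length.out = length(leaves)),
                        leaves)
  tx <- make_taxa(aln, truth, taxonomy, emergence, seed = stage_seeds[3])
  aln <- tx$aln
  truth <- tx$truth
  de <- make_de_inserts(aln, truth, long_mean = long_mean,
                        short_mean = short_mean, seed = stage_seeds[4])
  aln <- de$aln
  truth <- de$truth
  exons <- make_gene_structures(aln, truth, exon_noise = exon_noise,
                                seed = stage_seeds[5])
  structure(list(aln = aln, truth = truth, taxonomy = taxonomy,
                 exons = exons),
            class = "kc_sim")
}
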