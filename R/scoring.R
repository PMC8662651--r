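#' Fit score of one sequence against one cluster
#'
#' The fit score adds the weights of all effective constraints (the node's
#' own plus its ancestors') satisfied by the sequence and divides by the
#' total effective constraint weight, giving a value in \[0, 1\]: a
#' sequence satisfying every constraint scores exactly 1, one satisfying
#' none scores exactly 0. A constraint is satisfied when the sequence's
#' match-column residue lies in the constraint's residue set; gaps (`-`)
#' and unknowns (`X`) never satisfy a constraint.
#'
#' @param aln A `kc_aln` alignment.
#' @param h A `kc_hierarchy`.
#' @param sequence_id Sequence id present in `aln`.
#' @param cluster_id Node id with at least one effective constraint.
#' @return Numeric score in \[0, 1\].
#' @export
score_sequence <- function(aln, h, sequence_id, cluster_id) {
  if (!sequence_id %in% aln$sequence_id) {
    abort(sprintf("unknown sequence '%s'", sequence_id))
  }
  cons <- effective_constraints(h, cluster_id)
  if (is.null(cons) || nrow(cons) == 0) {
    abort(sprintf("cluster '%s' has no effective constraints", cluster_id))
  }
  if (attr(h, "n_columns") != n_columns(aln)) {
    abort("alignment and hierarchy disagree on n_columns")
  }
  m <- aln_matrix(aln)
  row <- match(sequence_id, aln$sequence_id)
  score_rows(m, row, cons)[1]
}

score_rows <- function(m, rows, cons) {
  sets <- strsplit(cons$residues, "", fixed = TRUE)
  sat <- matrix(FALSE, nrow = length(rows), ncol = nrow(cons))
  for (j in seq_len(nrow(cons))) {
    sat[, j] <- m[rows, cons$column[j]] %in% sets[[j]]
  }
  out <- pmin(pmax(as.vector(sat %*% cons$weight) / sum(cons$weight), 0), 1)
  # the bounds are exact by definition: all constraints satisfied scores
  # exactly 1, none satisfied exactly 0, regardless of float summation
  out[rowSums(sat) == ncol(sat)] <- 1
  out[rowSums(sat) == 0] <- 0
  out
}

# Nodes that can be scored / assigned: >= 1 effective constraint.
scoreable_nodes <- function(h) {
  h$id[map_lgl(h$id, function(id) {
    cons <- effective_constraints(h, id)
    !is.null(cons) && nrow(cons) > 0
  })]
}

#' Score every sequence against every cluster
#'
#' Computes the [score_sequence()] fit score for every (sequence, cluster)
#' pair. Clusters without any effective constraint (typically the root)
#' are omitted. Deterministic.
#'
#' @inheritParams score_sequence
#' @return Tibble with `sequence_id`, `cluster_id`, `score`.
#' @export
score_all <- function(aln, h) {
  if (attr(h, "n_columns") != n_columns(aln)) {
    abort("alignment and hierarchy disagree on n_columns")
  }
  m <- aln_matrix(aln)
  rows <- seq_len(nrow(aln))
  nodes <- scoreable_nodes(h)
  bind_rows(lapply(nodes, function(id) {
    cons <- effective_constraints(h, id)
    tibble(sequence_id = aln$sequence_id,
           cluster_id = id,
           score = score_rows(m, rows, cons))
  }))
}

#' Pick a classification cut-off from a score distribution
#'
#' Histograms all sequence-cluster fit scores on \[0, 1\], locates the two
#' tallest modes of the (lightly smoothed) histogram, and returns the
#' midpoint of the lowest-count bin strictly between them — the global
#' minimum of the empirical bimodal score distribution. When the minimum
#' is attained by a plateau of equally low bins, the middle of the plateau
#' is used. The histogram counts as bimodal only when that valley drops
#' below half the smaller mode; otherwise the conventional default of 0.7
#' is returned, with attribute `fallback = TRUE`.
#'
#' @param scores Numeric vector of at least 100 fit scores in \[0, 1\].
#' @param bin_width Histogram bin width in (0, 0.1\]. Default 0.01.
#' @return The cut-off, with attributes `fallback` (logical) and `counts`.
#' @export
select_cutoff <- function(scores, bin_width = 0.01) {
  if (length(scores) < 100) abort("need at least 100 scores")
  if (bin_width <= 0 || bin_width > 0.1) {
    abort("`bin_width` must be in (0, 0.1]")
  }
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- as.vector(table(cut(scores, breaks, include.lowest = TRUE)))
  nb <- length(counts)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2

  # moving-average smoothing so that bin-level raggedness does not spawn
  # spurious modes
  half <- 2L
  smooth <- vapply(seq_len(nb), function(i) {
    win <- max(1, i - half):min(nb, i + half)
    mean(counts[win])
  }, numeric(1))
  is_max <- vapply(seq_len(nb), function(i) {
    left <- if (i > 1) smooth[i - 1] else -Inf
    right <- if (i < nb) smooth[i + 1] else -Inf
    smooth[i] > 0 && smooth[i] >= left && smooth[i] >= right
  }, logical(1))
  # candidate modes: substantial local maxima only, so tail ripples do not
  # masquerade as modes
  peaks <- which(is_max & smooth >= 0.2 * max(smooth))
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > 1 | smooth[peaks[-1]] !=
                smooth[peaks[-length(peaks)]])
    peaks <- peaks[keep]
  }

  # scan every sufficiently separated mode pair for a genuine valley
  # (raw-count minimum below half the smaller mode); among qualifying
  # pairs keep the deepest valley relative to its modes, so the true
  # inter-mode gap beats any ragged dip inside one mode
  fallback <- TRUE
  cutoff <- 0.7
  best <- NULL
  if (length(peaks) >= 2) {
    for (ii in seq_len(length(peaks) - 1)) {
      for (jj in (ii + 1):length(peaks)) {
        lo <- peaks[ii]
        hi <- peaks[jj]
        if (hi - lo < 3) next
        between <- (lo + 1):(hi - 1)
        vmin <- min(counts[between])
        pair_height <- min(smooth[lo], smooth[hi])
        if (vmin >= 0.5 * pair_height) next
        ratio <- vmin / pair_height
        if (is.null(best) || ratio < best$ratio - 1e-12 ||
            (abs(ratio - best$ratio) <= 1e-12 &&
               pair_height > best$height)) {
          low <- between[counts[between] == vmin]
          best <- list(ratio = ratio, height = pair_height,
                       valley = low[ceiling(length(low) / 2)])
        }
      }
    }
  }
  if (!is.null(best)) {
    cutoff <- mids[best$valley]
    fallback <- FALSE
  }
  structure(cutoff, fallback = fallback, counts = counts)
}

#' Named cut-off presets
#'
#' `"optimal"` is the conventional 0.7 cut-off; `"relaxed"` (0.6) is used
#' for taxonomic conservation analysis where weak but genuine family
#' members should still register.
#'
#' @param preset `"optimal"` or `"relaxed"`.
#' @return Numeric cut-off.
#' @export
cutoff_preset <- function(preset = c("optimal", "relaxed")) {
  preset <- match.arg(preset)
  c(optimal = 0.7, relaxed = 0.6)[[preset]]
}

#' Classify sequences against a constraint hierarchy
#'
#' Each sequence is assigned to the deepest node on a root-to-leaf path
#' whose every scoreable node scores at least `cutoff`; among qualifying
#' nodes of equal depth the one with the highest score wins (ties broken
#' by lexicographically smallest cluster id). A sequence qualifying
#' nowhere is assigned to the `"unclassified"` sink.
#'
#' @inheritParams score_all
#' @param cutoff Classification cut-off in (0, 1). Default 0.7.
#' @return A `kc_classification` object: list with `scores` (tibble),
#'   `assignments` (tibble with `sequence_id`, `cluster_id`, `path`,
#'   `score`), and `cutoff`.
#' @export
classify <- function(aln, h, cutoff = 0.7) {
  if (cutoff <= 0 || cutoff >= 1) abort("`cutoff` must be in (0, 1)")
  scores <- score_all(aln, h)
  wide <- pivot_wider(scores, names_from = "cluster_id",
                      values_from = "score")
  node_ids <- setdiff(names(wide), "sequence_id")
  depth <- vapply(node_ids, function(id) length(node_path(h, id)),
                  integer(1))
  parents <- setNames(h$parent_id, h$id)

  assign_one <- function(sc) {
    qual <- vapply(node_ids, function(id) {
      path <- node_path(h, id)
      path <- intersect(path, node_ids)  # unscoreable ancestors qualify
      all(sc[path] >= cutoff)
    }, logical(1))
    if (!any(qual)) {
      return(list(cluster_id = "unclassified", path = "unclassified",
                  score = NA_real_))
    }
    cand <- node_ids[qual]
    d <- depth[cand]
    cand <- cand[d == max(d)]
    cand <- cand[order(-sc[cand], cand)]
    best <- cand[1]
    list(cluster_id = best,
         path = paste(node_path(h, best), collapse = "/"),
         score = unname(sc[best]))
  }

  sc_mat <- as.matrix(wide[, node_ids, drop = FALSE])
  rownames(sc_mat) <- wide$sequence_id
  res <- lapply(seq_len(nrow(sc_mat)), function(i) assign_one(sc_mat[i, ]))
  assignments <- tibble(
    sequence_id = wide$sequence_id,
    cluster_id = map_chr(res, "cluster_id"),
    path = map_chr(res, "path"),
    score = map_dbl(res, "score")
  )
  structure(list(scores = scores, assignments = assignments,
                 cutoff = cutoff, hierarchy = h),
            class = "kc_classification")
}

#' @export
print.kc_classification <- function(x, ...) {
  n <- nrow(x$assignments)
  ncl <- sum(x$assignments$cluster_id != "unclassified")
  cat(sprintf(
    "# Classification: %d sequences, %d classified, %d unclassified (cutoff %.2f)\n",
    n, ncl, n - ncl, x$cutoff))
  print(x$assignments, ...)
  invisible(x)
}

#' Members of a cluster under a classification
#'
#' A sequence belongs to a cluster when the cluster lies on its assigned
#' root-to-deepest path (members of a subcluster are members of its
#' supercluster too).
#'
#' @param result A `kc_classification`.
#' @param cluster_id Node id.
#' @return Character vector of sequence ids.
#' @export
cluster_members <- function(result, cluster_id) {
  sub <- node_subtree(result$hierarchy, cluster_id)
  result$assignments$sequence_id[result$assignments$cluster_id %in% sub]
}

#' @describeIn classify Tidy the per-sequence assignments.
#' @param x A `kc_classification`.
#' @param ... Unused.
#' @method tidy kc_classification
#' @export
tidy.kc_classification <- function(x, ...) x$assignments

#' @describeIn classify One-row summary of the classification.
#' @method glance kc_classification
#' @export
glance.kc_classification <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$assignments),
    n_classified = sum(x$assignments$cluster_id != "unclassified"),
    n_unclassified = sum(x$assignments$cluster_id == "unclassified"),
    n_clusters = length(unique(x$scores$cluster_id)),
    cutoff = x$cutoff
  )
}
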