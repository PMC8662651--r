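#' Inference configuration
#'
#' Tuning parameters for constraint discovery and hierarchy inference.
#'
#' @param minnat Minimum summed constraint weight, in nats *above the
#'   empirical null* (see [sample_partition()]), required to accept a
#'   cluster. Default 5.
#' @param max_constraints_per_node Maximum number of constraints retained
#'   per node. Default 20.
#' @param pseudocount Pseudocount added to foreground/background residue
#'   counts in the contrast statistic. Default 1.
#' @param n_sweeps Maximum number of coordinate-ascent sweeps (pattern
#'   reselection alternated with membership reassignment). Default 50;
#'   sweeps stop early on convergence. `n_sweeps = 0` scores the initial
#'   split once.
#' @param seed Integer seed controlling all randomness in inference.
#' @param min_fg_conservation Minimum fraction of the (non-gap) foreground
#'   that a constraint's residue set must cover: constraints are positions
#'   highly conserved *within* the cluster, not merely contrastive.
#'   Default 0.6.
#' @param min_enrichment A residue may only join a constraint's set when
#'   its pseudocounted foreground frequency is at least this multiple of
#'   its background frequency, so residue sets cannot be padded with
#'   background-typical residues to satisfy the conservation requirement;
#'   genuinely cluster-specific residues sit far above this ratio once the
#'   membership is clean, while background residues sit near 1. Default
#'   1.5.
#' @param final_fg_conservation Stricter conservation threshold applied
#'   when the *final* constraint set of a converged cluster is reported
#'   (the permissive `min_fg_conservation` governs only the search, where
#'   memberships are still noisy). Default 0.75.
#' @param min_cluster_size Minimum number of sequences in an accepted
#'   cluster (shrunk automatically for small inputs). Default 8.
#' @param n_null Number of empirical-null replicates used to calibrate
#'   the minnat acceptance test. Default 3.
#' @param n_restarts During hierarchy inference, how many fresh random
#'   initialisations to try at a node after a rejected extraction before
#'   concluding the node has no further children. Default 3.
#' @return A `kc_config` list.
#' @export
kc_config <- function(minnat = 5, max_constraints_per_node = 20,
                      pseudocount = 1, n_sweeps = 50, seed = 0,
                      min_fg_conservation = 0.6, min_enrichment = 1.5,
                      final_fg_conservation = 0.75, min_cluster_size = 8,
                      n_null = 3, n_restarts = 3) {
  if (minnat <= 0) abort("`minnat` must be positive")
  if (pseudocount <= 0) abort("`pseudocount` must be positive")
  structure(list(minnat = minnat,
                 max_constraints_per_node = as.integer(max_constraints_per_node),
                 pseudocount = pseudocount,
                 n_sweeps = as.integer(n_sweeps),
                 seed = as.integer(seed),
                 min_fg_conservation = min_fg_conservation,
                 min_enrichment = min_enrichment,
                 final_fg_conservation = final_fg_conservation,
                 min_cluster_size = as.integer(min_cluster_size),
                 n_null = as.integer(n_null),
                 n_restarts = as.integer(n_restarts)),
            class = "kc_config")
}

# 20 x L residue count matrix for rows `rows` of the character matrix m.
# Gaps and 'X' are excluded from all counts.
residue_counts <- function(m, rows) {
  L <- ncol(m)
  sub <- m[rows, , drop = FALSE]
  out <- matrix(0, nrow = 20, ncol = L, dimnames = list(kc_alphabet, NULL))
  for (i in seq_along(kc_alphabet)) {
    out[i, ] <- colSums(sub == kc_alphabet[i])
  }
  out
}

# Vectorised binomial log-likelihood-ratio contrast given set counts.
contrast_w <- function(n_fr, n_f, n_br, n_b, a) {
  q_f <- (n_fr + a) / (n_f + 2 * a)
  q_b <- (n_br + a) / (n_b + 2 * a)
  n_fr * log(q_f / q_b) + (n_f - n_fr) * log((1 - q_f) / (1 - q_b))
}

#' Column contrast weight of a residue set
#'
#' Measures, in nats, how strongly a residue set distinguishes a foreground
#' from a background at one alignment column. With foreground total
#' \eqn{n_F}, foreground count in the set \eqn{n_{FR}}, and pseudocounted
#' set frequencies \eqn{q_F = (n_{FR}+\alpha)/(n_F+2\alpha)} (background
#' analogous), the weight is
#' \deqn{w = n_{FR}\,\ln(q_F/q_B) + (n_F-n_{FR})\,\ln((1-q_F)/(1-q_B)),}
#' i.e. the foreground log-likelihood ratio of the set's in/out frequencies
#' under the two (pseudocounted) binomial models. It may be negative.
#'
#' @param fg_counts,bg_counts Numeric vectors of length 20 of residue
#'   counts (ordered as `ACDEFGHIKLMNPQRSTVWY`, or named), gaps excluded.
#' @param residue_set Character vector of amino acids, or a single string
#'   such as `"KR"`.
#' @param pseudocount Positive pseudocount \eqn{\alpha}.
#' @return Weight in nats.
#' @export
column_contrast <- function(fg_counts, bg_counts, residue_set,
                            pseudocount = 1) {
  fg_counts <- align_counts(fg_counts)
  bg_counts <- align_counts(bg_counts)
  if (sum(fg_counts) <= 0 || sum(bg_counts) <= 0) {
    abort("foreground and background totals must be positive")
  }
  set <- residue_set
  if (length(set) == 1 && nchar(set) > 1) {
    set <- strsplit(set, "", fixed = TRUE)[[1]]
  }
  if (length(set) == 0 || !all(set %in% kc_alphabet)) {
    abort("`residue_set` must be a non-empty set of amino acids")
  }
  idx <- match(unique(set), kc_alphabet)
  contrast_w(sum(fg_counts[idx]), sum(fg_counts),
             sum(bg_counts[idx]), sum(bg_counts), pseudocount)
}

align_counts <- function(x) {
  if (length(x) == 20 && is.null(names(x))) return(as.numeric(x))
  if (!is.null(names(x))) {
    out <- setNames(numeric(20), kc_alphabet)
    keep <- intersect(names(x), kc_alphabet)
    out[keep] <- x[keep]
    return(out)
  }
  abort("count vectors must have length 20 or amino-acid names")
}

# Greedy residue-set search at one column: grow the set one residue at a
# time (sizes 1..4), considering only residues enriched in the foreground
# (pseudocounted frequency >= min_enrich x background), and keeping the
# best weight among sets that also cover at least `min_cov` of the
# non-gap foreground.
greedy_column_set <- function(f, b, a, min_cov, min_enrich) {
  n_f <- sum(f)
  n_b <- sum(b)
  if (n_f == 0 || n_b == 0) return(NULL)
  enriched <- (f + a) / (n_f + 2 * a) >= min_enrich * (b + a) / (n_b + 2 * a)
  set_idx <- integer(0)
  best <- NULL
  for (step in 1:4) {
    cand <- setdiff(which(enriched), set_idx)
    if (length(cand) == 0) break
    n_fr0 <- sum(f[set_idx])
    n_br0 <- sum(b[set_idx])
    w <- contrast_w(n_fr0 + f[cand], n_f, n_br0 + b[cand], n_b, a)
    j <- cand[which.max(w)]
    wj <- max(w)
    set_idx <- c(set_idx, j)
    cov <- (n_fr0 + f[j]) / n_f
    if (cov >= min_cov && (is.null(best) || wj > best$w)) {
      best <- list(set = set_idx, w = wj, coverage = cov)
    }
  }
  best
}

# Vectorised greedy search over all columns at once; equivalent to running
# greedy_column_set() per column (asserted in the test suite) but runs the
# 4 growth steps as 20 x L matrix operations.
select_pattern_rows <- function(m, fg_rows, bg_rows, cfg,
                                exclude_cols = integer(0)) {
  empty <- tibble(column = integer(0), residues = character(0),
                  weight = numeric(0))
  fg_counts <- residue_counts(m, fg_rows)
  bg_counts <- residue_counts(m, bg_rows)
  L <- ncol(m)
  a <- cfg$pseudocount
  n_f <- colSums(fg_counts)
  n_b <- colSums(bg_counts)
  valid <- n_f > 0 & n_b > 0
  valid[exclude_cols] <- FALSE
  if (!any(valid)) return(empty)

  nf_mat <- matrix(n_f, 20, L, byrow = TRUE)
  nb_mat <- matrix(n_b, 20, L, byrow = TRUE)
  enr <- (fg_counts + a) / (nf_mat + 2 * a) >=
    cfg$min_enrichment * (bg_counts + a) / (nb_mat + 2 * a)

  in_set <- matrix(FALSE, 20, L)
  best_mask <- matrix(FALSE, 20, L)
  nfr <- numeric(L)
  nbr <- numeric(L)
  best_w <- rep(-Inf, L)
  for (step in 1:4) {
    cand <- enr & !in_set
    cand[, !valid] <- FALSE
    if (!any(cand)) break
    nfr_m <- matrix(nfr, 20, L, byrow = TRUE) + fg_counts
    nbr_m <- matrix(nbr, 20, L, byrow = TRUE) + bg_counts
    qf <- (nfr_m + a) / (nf_mat + 2 * a)
    qb <- (nbr_m + a) / (nb_mat + 2 * a)
    # entries for residues already in the set double-count and are masked
    # below; clamp them so the logs stay defined
    qf[!cand] <- 0.5
    qb[!cand] <- 0.5
    w <- nfr_m * log(qf / qb) + (nf_mat - nfr_m) * log((1 - qf) / (1 - qb))
    w[!cand] <- -Inf
    j <- max.col(t(w), ties.method = "first")
    wj <- w[cbind(j, seq_len(L))]
    upd <- is.finite(wj)
    if (!any(upd)) break
    sel <- cbind(j[upd], which(upd))
    in_set[sel] <- TRUE
    nfr[upd] <- nfr[upd] + fg_counts[sel]
    nbr[upd] <- nbr[upd] + bg_counts[sel]
    cov <- nfr / pmax(n_f, 1)
    improve <- upd & cov >= cfg$min_fg_conservation & wj > best_w
    if (any(improve)) {
      best_w[improve] <- wj[improve]
      best_mask[, improve] <- in_set[, improve]
    }
  }
  keep <- which(is.finite(best_w) & best_w > 0)
  if (length(keep) == 0) return(empty)
  out <- tibble(
    column = keep,
    residues = vapply(keep, function(cl)
      paste(kc_alphabet[best_mask[, cl]], collapse = ""), character(1)),
    weight = best_w[keep]
  )
  out <- arrange(out, desc(.data$weight), .data$column)
  head(out, cfg$max_constraints_per_node)
}

#' Select cluster-specific constraints for a foreground set
#'
#' For every alignment column, greedily grows a residue set (sizes 1–4)
#' maximizing [column_contrast()] of the foreground against the remaining
#' sequences; keeps columns whose best set has positive weight and covers
#' at least `min_fg_conservation` of the non-gap foreground; returns them
#' sorted by decreasing weight, truncated at `max_constraints_per_node`.
#'
#' @param aln A `kc_aln` alignment.
#' @param fg_ids Non-empty proper subset of the alignment's sequence ids.
#' @param cfg A [kc_config()].
#' @param exclude_cols Columns to skip (e.g. already constrained by
#'   ancestor clusters).
#' @return Tibble with `column`, `residues`, `weight`.
#' @export
select_pattern <- function(aln, fg_ids, cfg = kc_config(),
                           exclude_cols = integer(0)) {
  fg_ids <- unique(fg_ids)
  if (length(fg_ids) == 0 || !all(fg_ids %in% aln$sequence_id) ||
      length(fg_ids) >= nrow(aln)) {
    abort("`fg_ids` must be a non-empty proper subset of sequence ids")
  }
  m <- aln_matrix(aln)
  fg <- match(fg_ids, aln$sequence_id)
  bg <- setdiff(seq_len(nrow(aln)), fg)
  select_pattern_rows(m, fg, bg, cfg, exclude_cols)
}

# Fraction of total constraint weight matched by each of rows `rows`.
matched_fraction <- function(m, rows, cons) {
  k <- nrow(cons)
  sat <- matrix(FALSE, nrow = length(rows), ncol = k)
  sets <- strsplit(cons$residues, "", fixed = TRUE)
  for (j in seq_len(k)) {
    sat[, j] <- m[rows, cons$column[j]] %in% sets[[j]]
  }
  as.vector(sat %*% cons$weight) / sum(cons$weight)
}

effective_min_size <- function(cfg, n_members) {
  min(cfg$min_cluster_size, max(2L, floor(n_members / 4)))
}

# Null summed weights for a *fixed* membership of the given size: random
# same-size foregrounds, pattern selected once each.
null_weights_fixed <- function(m, member_rows, size, cfg, exclude_cols) {
  if (cfg$n_null <= 0) return(0)
  vapply(seq_len(cfg$n_null), function(i) {
    fg <- sample(member_rows, size)
    cons <- select_pattern_rows(m, fg, setdiff(member_rows, fg), cfg,
                                exclude_cols)
    sum(cons$weight)
  }, numeric(1))
}

# Gap-statistic style acceptance: the observed summed weight must exceed
# the empirical null by minnat with a margin absorbing the null's spread
# (twice its sd, and half its maximum again), so that the selection
# variance of the ascent statistic cannot manufacture clusters.
passes_minnat <- function(w_obs, w_nulls, cfg) {
  spread <- if (length(w_nulls) > 1) stats::sd(w_nulls) else 0
  bar <- max(mean(w_nulls) + 2 * spread, 1.5 * max(w_nulls))
  w_obs >= bar + cfg$minnat
}

# Two k-means-style refinement rounds on the initial foreground: rank the
# pool by log-likelihood under the foreground residue profile relative to
# the pool profile and keep the top k. Pairwise identity to a single seed
# sequence is a noisy guide when groups differ at few columns; profile
# affinity aggregates the weak per-column signal across the whole set.
refine_init <- function(m, fg, pool_rows, k, cfg) {
  a <- cfg$pseudocount
  pool_counts <- residue_counts(m, pool_rows)
  lq <- log(sweep(pool_counts + a, 2, colSums(pool_counts) + 20 * a, "/"))
  msub <- m[pool_rows, , drop = FALSE]
  ridx <- matrix(match(msub, kc_alphabet), nrow = nrow(msub))
  for (round in 1:2) {
    fg_counts <- residue_counts(m, fg)
    lp <- log(sweep(fg_counts + a, 2, colSums(fg_counts) + 20 * a, "/"))
    d <- lp - lq
    aff <- vapply(seq_len(nrow(msub)), function(i) {
      ok <- !is.na(ridx[i, ])
      sum(d[cbind(ridx[i, ok], which(ok))])
    }, numeric(1))
    fg <- pool_rows[order(-aff, pool_rows)[seq_len(k)]]
  }
  fg
}

empty_extraction <- function() {
  list(accepted = FALSE, fg_rows = integer(0),
       constraints = tibble(column = integer(0), residues = character(0),
                            weight = numeric(0)),
       weight = 0, null = 0)
}

# One coordinate-ascent run: seeded nearest-neighbour init, then alternate
# pattern reselection and membership reassignment until convergence.
# Returns the converged foreground and constraints without any acceptance
# decision. Deterministic given the RNG state.
ascend_cluster <- function(m, member_rows, pool_rows, cfg,
                           exclude_cols = integer(0), k_frac = 0.5) {
  eff_min <- effective_min_size(cfg, length(member_rows))
  frozen <- setdiff(member_rows, pool_rows)

  # init: a random seed sequence and its nearest neighbours by identity
  seed_row <- if (length(pool_rows) == 1) pool_rows else
    sample(pool_rows, 1)
  ident <- pairwise_identity_rows(m, pool_rows, m[seed_row, ])
  k <- max(eff_min, floor(length(pool_rows) * k_frac))
  if (length(frozen) == 0) k <- min(k, length(pool_rows) - 2L)
  k <- max(1L, min(k, length(pool_rows)))
  ord <- order(-ident, pool_rows)
  fg <- pool_rows[ord[seq_len(k)]]
  fg <- refine_init(m, fg, pool_rows, k, cfg)

  sweeps <- max(cfg$n_sweeps, 0L)
  for (s in seq_len(sweeps)) {
    cons <- select_pattern_rows(m, fg, setdiff(member_rows, fg), cfg,
                                exclude_cols)
    if (nrow(cons) == 0) return(NULL)
    frac <- matched_fraction(m, pool_rows, cons)
    new_fg <- pool_rows[frac > 0.5 |
                          (abs(frac - 0.5) < 1e-12 & pool_rows %in% fg)]
    if (length(new_fg) == 0) return(NULL)
    if (length(new_fg) == length(member_rows) && length(frozen) == 0) {
      return(NULL)  # foreground swallowed everything: no contrast left
    }
    if (setequal(new_fg, fg)) break
    fg <- new_fg
  }
  cons <- select_pattern_rows(m, fg, setdiff(member_rows, fg),
                              final_cfg(cfg), exclude_cols)
  if (nrow(cons) == 0) return(NULL)
  list(fg_rows = sort(fg), constraints = cons,
       weight = sum(cons$weight))
}

final_cfg <- function(cfg) {
  cfg$min_fg_conservation <- max(cfg$min_fg_conservation,
                                 cfg$final_fg_conservation %||%
                                   cfg$min_fg_conservation)
  cfg
}

# Empirical null for the ascent statistic: shuffle every column of the
# node's submatrix independently across its members (destroying
# co-occurrence structure while preserving column compositions) and run
# the same ascent. The summed weight it reaches is what pure noise chasing
# can achieve on data with these column compositions.
# The observed weight is only ever tested when the real ascent survived
# (converged to a proper split), so each null replicate is conditioned on
# survival too: failed shuffled ascents are redrawn a few times.
ascent_null_weights <- function(m, member_rows, pool_rows, cfg,
                                exclude_cols, k_frac = 0.5) {
  if (cfg$n_null <= 0) return(0)
  n <- length(member_rows)
  pool_rel <- match(pool_rows, member_rows)
  vapply(seq_len(cfg$n_null), function(i) {
    for (try in 1:4) {
      msub <- m[member_rows, , drop = FALSE]
      for (cl in seq_len(ncol(msub))) {
        msub[, cl] <- msub[sample.int(n), cl]
      }
      res <- ascend_cluster(msub, seq_len(n), pool_rel, cfg, exclude_cols,
                            k_frac = k_frac)
      if (!is.null(res)) return(res$weight)
    }
    0
  }, numeric(1))
}

# Extract one cluster from `pool_rows`, contrasted against all of
# `member_rows` minus the current foreground. Sequences in member_rows but
# not pool_rows are frozen in the background (they belong to previously
# extracted siblings). The converged split is accepted only if its summed
# weight beats the column-shuffled ascent null by at least minnat.
extract_cluster <- function(m, member_rows, pool_rows, cfg,
                            exclude_cols = integer(0), k_frac = 0.5) {
  rejected <- empty_extraction()
  eff_min <- effective_min_size(cfg, length(member_rows))
  res <- ascend_cluster(m, member_rows, pool_rows, cfg, exclude_cols,
                        k_frac = k_frac)
  if (is.null(res) || length(res$fg_rows) < eff_min) return(rejected)
  w_nulls <- ascent_null_weights(m, member_rows, pool_rows, cfg,
                                 exclude_cols, k_frac = k_frac)
  if (!passes_minnat(res$weight, w_nulls, cfg)) return(rejected)
  list(accepted = TRUE, fg_rows = res$fg_rows,
       constraints = res$constraints, weight = res$weight,
       null = mean(w_nulls))
}

#' Sample a single foreground/background partition
#'
#' One run of the pattern-partition sampler: starting from a seeded initial
#' split (a random seed sequence plus its nearest neighbours by pairwise
#' identity, half the alignment), alternates (i) constraint reselection
#' given the membership ([select_pattern()]) and (ii) membership
#' reassignment given the constraints — a sequence joins the foreground
#' when its matched-weight fraction exceeds 0.5, ties resolved toward its
#' current side — until convergence or `n_sweeps`. The final split is
#' accepted only if its summed constraint weight exceeds the mean summed
#' weight of `n_null` random same-size memberships by at least `minnat`
#' nats; otherwise an empty result is returned.
#'
#' @param aln A `kc_aln` alignment with at least 4 records.
#' @param cfg A [kc_config()]; `cfg$seed` makes the run deterministic.
#' @return List with `fg_ids` (character, empty if rejected),
#'   `constraints` (tibble), `weight`, and `accepted`.
#' @export
sample_partition <- function(aln, cfg = kc_config()) {
  if (nrow(aln) < 4) abort("need at least 4 records")
  set.seed(cfg$seed)
  m <- aln_matrix(aln)
  rows <- seq_len(nrow(aln))
  res <- extract_cluster(m, rows, rows, cfg)
  list(fg_ids = aln$sequence_id[res$fg_rows],
       constraints = res$constraints,
       weight = res$weight,
       accepted = res$accepted)
}

#' Infer a constraint hierarchy from an alignment
#'
#' Recursive splitting: the root holds all sequences; at each node the
#' sampler repeatedly extracts accepted foreground clusters from the pool
#' of not-yet-assigned members (each extraction contrasts the candidate
#' against all other node members, including previously extracted
#' siblings). Before each sampler run the remaining pool as a whole is
#' tested as a candidate child, so that the complement of an extracted
#' cluster (e.g. the second of two superclusters) can form at the correct
#' level rather than fragmenting. Recursion continues into each child
#' until `max_depth` or until no split passes the minnat test. Child
#' constraints exclude columns already constrained by ancestors.
#'
#' @inheritParams sample_partition
#' @param max_depth Maximum tree depth below the root (0 = single node).
#' @return A `kc_hierarchy` with memberships and `total_lpr` set.
#' @export
infer_hierarchy <- function(aln, cfg = kc_config(), max_depth = 4) {
  if (nrow(aln) < 4) abort("need at least 4 records")
  set.seed(cfg$seed)
  m <- aln_matrix(aln)
  ids <- aln$sequence_id

  nodes <- new.env(parent = emptyenv())
  nodes$tbl <- list(list(id = "root", name = "root",
                         parent_id = NA_character_,
                         constraints = tibble(column = integer(0),
                                              residues = character(0),
                                              weight = numeric(0)),
                         members = ids))

  recurse <- function(node_id, member_rows, depth, exclude_cols) {
    if (depth >= max_depth || length(member_rows) < 4) return(invisible())
    pool <- member_rows
    child_n <- 0L
    fails <- 0L
    children <- list()
    repeat {
      if (length(pool) == 0) break
      extracted <- FALSE
      eff_min <- effective_min_size(cfg, length(member_rows))
      if (length(pool) < length(member_rows) && length(pool) >= eff_min) {
        # try the remainder as a coherent cluster in its own right
        cons <- select_pattern_rows(m, pool, setdiff(member_rows, pool),
                                    final_cfg(cfg), exclude_cols)
        if (nrow(cons) > 0) {
          w_obs <- sum(cons$weight)
          w_nulls <- null_weights_fixed(m, member_rows, length(pool),
                                        final_cfg(cfg), exclude_cols)
          if (passes_minnat(w_obs, w_nulls, cfg)) {
            child_n <- child_n + 1L
            children[[child_n]] <- list(rows = pool, constraints = cons)
            pool <- integer(0)
            extracted <- TRUE
          }
        }
      }
      if (!extracted) {
        if (length(pool) < 4) break
        res <- extract_cluster(m, member_rows, pool, cfg, exclude_cols)
        if (!res$accepted) {
          fails <- fails + 1L
          if (fails > cfg$n_restarts) break
          next
        }
        fails <- 0L
        child_n <- child_n + 1L
        children[[child_n]] <- list(rows = res$fg_rows,
                                    constraints = res$constraints)
        pool <- setdiff(pool, res$fg_rows)
      }
    }
    for (i in seq_along(children)) {
      ch <- children[[i]]
      child_id <- if (node_id == "root") sprintf("C%d", i) else
        sprintf("%s.%d", node_id, i)
      nodes$tbl[[length(nodes$tbl) + 1L]] <-
        list(id = child_id, name = child_id, parent_id = node_id,
             constraints = ch$constraints, members = ids[ch$rows])
      recurse(child_id, ch$rows, depth + 1L,
              union(exclude_cols, ch$constraints$column))
    }
    invisible()
  }

  recurse("root", seq_len(nrow(aln)), 0L, integer(0))

  tbl <- tibble(
    id = map_chr(nodes$tbl, "id"),
    name = map_chr(nodes$tbl, "name"),
    parent_id = map_chr(nodes$tbl, "parent_id"),
    constraints = map(nodes$tbl, "constraints"),
    members = map(nodes$tbl, "members")
  )
  h <- constraint_hierarchy(tbl, n_columns = n_columns(aln))
  attr(h, "total_lpr") <- total_lpr(h, aln)
  h
}

#' Total log-probability ratio of a hierarchy on an alignment
#'
#' Sums, over all nodes, the constraint weights recomputed from the node's
#' members (foreground) against all non-members (background). Negative
#' recomputed column weights are dropped, so the total is nonnegative;
#' nodes with empty membership or empty background (e.g. the root)
#' contribute 0. Units: nats.
#'
#' @param h A `kc_hierarchy` with memberships.
#' @param aln The alignment the memberships refer to.
#' @return Nonnegative total LPR in nats.
#' @export
total_lpr <- function(h, aln) {
  m <- aln_matrix(aln)
  total <- 0
  for (i in seq_len(nrow(h))) {
    cons <- h$constraints[[i]]
    memb <- intersect(h$members[[i]], aln$sequence_id)
    if (nrow(cons) == 0 || length(memb) == 0) next
    fg <- match(memb, aln$sequence_id)
    bg <- setdiff(seq_len(nrow(aln)), fg)
    if (length(bg) == 0) next
    fc <- residue_counts(m, fg)
    bc <- residue_counts(m, bg)
    for (j in seq_len(nrow(cons))) {
      cl <- cons$column[j]
      if (sum(fc[, cl]) == 0 || sum(bc[, cl]) == 0) next
      w <- column_contrast(fc[, cl], bc[, cl], cons$residues[j],
                           pseudocount = 1)
      if (w > 0) total <- total + w
    }
  }
  total
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Consensus hierarchy across multiple inference runs
#'
#' Clusters are matched across runs by membership Jaccard similarity
#' (>= 0.5); matched groups present in at least `min_support` of the runs
#' are kept, with the union of the matched memberships. The kept clusters
#' are re-nested by membership containment and their constraints
#' re-estimated on the union membership via [select_pattern()] (excluding
#' ancestor columns).
#'
#' @param runs List of at least two `kc_hierarchy` objects inferred on the
#'   same set of sequence ids.
#' @param aln The alignment the runs refer to.
#' @param cfg A [kc_config()] used for constraint re-estimation.
#' @param min_support Minimum fraction of runs in which a cluster must
#'   appear. Default 0.5.
#' @return A `kc_hierarchy`.
#' @export
consensus_hierarchy <- function(runs, aln, cfg = kc_config(),
                                min_support = 0.5) {
  if (length(runs) < 2) abort("need at least 2 runs")
  id_sets <- lapply(runs, function(h) sort(node_members(h,
                                                        hierarchy_root(h))))
  if (!all(map_lgl(id_sets[-1], function(s) identical(s, id_sets[[1]])))) {
    abort("runs cover different sequence id sets")
  }

  clusters <- bind_rows(lapply(seq_along(runs), function(r) {
    h <- runs[[r]]
    keep <- h$id != hierarchy_root(h)
    tibble(run = r, node = h$id[keep], members = h$members[keep])
  }))
  if (nrow(clusters) == 0) {
    return(constraint_hierarchy(
      tibble(id = "root", name = "root", parent_id = NA_character_,
             constraints = list(tibble(column = integer(0),
                                       residues = character(0),
                                       weight = numeric(0))),
             members = list(id_sets[[1]])),
      n_columns = n_columns(aln)))
  }
  clusters <- clusters %>%
    mutate(size = map_int(.data$members, length)) %>%
    arrange(desc(.data$size), .data$run, .data$node)

  grouped <- logical(nrow(clusters))
  groups <- list()
  for (i in seq_len(nrow(clusters))) {
    if (grouped[i]) next
    grouped[i] <- TRUE
    grp_rows <- i
    for (r in setdiff(seq_along(runs), clusters$run[i])) {
      cand <- which(!grouped & clusters$run == r)
      if (length(cand) == 0) next
      jac <- vapply(cand, function(j)
        jaccard(clusters$members[[i]], clusters$members[[j]]), numeric(1))
      if (max(jac) >= 0.5) {
        j <- cand[which.max(jac)]
        grouped[j] <- TRUE
        grp_rows <- c(grp_rows, j)
      }
    }
    groups[[length(groups) + 1L]] <- grp_rows
  }

  support <- map_dbl(groups, function(g)
    length(unique(clusters$run[g])) / length(runs))
  kept <- groups[support >= min_support]
  unions <- lapply(kept, function(g)
    sort(unique(unlist(clusters$members[g]))))
  ord <- order(-map_int(unions, length))
  unions <- unions[ord]

  # nest by containment: parent = smallest placed cluster holding >= 80%
  all_ids <- id_sets[[1]]
  placed <- list(root = all_ids)
  parent_of <- character(0)
  for (i in seq_along(unions)) {
    u <- unions[[i]]
    best <- "root"
    best_size <- length(all_ids)
    for (pid in names(placed)) {
      if (pid == "root") next
      p <- placed[[pid]]
      if (length(p) <= length(u)) next
      if (length(intersect(u, p)) / length(u) >= 0.8 &&
          length(p) < best_size) {
        best <- pid
        best_size <- length(p)
      }
    }
    nid <- sprintf("K%d", i)
    placed[[nid]] <- intersect(u, placed[[best]])
    parent_of[nid] <- best
  }

  m <- aln_matrix(aln)
  node_ids <- names(placed)
  tbl <- tibble(id = node_ids, name = node_ids,
                parent_id = c(NA_character_,
                              parent_of[node_ids[-1]])[seq_along(node_ids)],
                constraints = rep(list(tibble(column = integer(0),
                                              residues = character(0),
                                              weight = numeric(0))),
                                  length(node_ids)),
                members = unname(placed[node_ids]))
  # re-estimate constraints top-down, excluding ancestor columns
  for (i in order(map_int(tbl$members, length), decreasing = TRUE)) {
    if (is.na(tbl$parent_id[i])) next
    anc_cols <- integer(0)
    p <- tbl$parent_id[i]
    while (!is.na(p)) {
      anc_cols <- union(anc_cols, tbl$constraints[[which(tbl$id == p)]]$column)
      p <- tbl$parent_id[which(tbl$id == p)]
    }
    parent_members <- tbl$members[[which(tbl$id == tbl$parent_id[i])]]
    fg <- match(tbl$members[[i]], aln$sequence_id)
    bg <- match(setdiff(parent_members, tbl$members[[i]]), aln$sequence_id)
    if (length(bg) == 0) bg <- setdiff(seq_len(nrow(aln)), fg)
    if (length(bg) == 0) next
    tbl$constraints[[i]] <- select_pattern_rows(m, fg, bg, cfg, anc_cols)
  }

  h <- constraint_hierarchy(tbl, n_columns = n_columns(aln))
  attr(h, "total_lpr") <- total_lpr(h, aln)
  h
}
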