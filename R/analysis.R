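#' All-versus-all cluster similarity matrix
#'
#' For every ordered cluster pair (A, B), the entry is the mean fit score
#' of the sequences classified into A (path membership, see
#' [cluster_members()]) against B's effective constraints. The metric is
#' non-symmetric: members of a subcluster score highly against their
#' supercluster's constraints (which they share), but supercluster members
#' at large do not carry the subcluster's extra constraints, so the
#' converse mean is lower. Every diagonal entry is at least the
#' classification cut-off, since each member scored at least the cut-off
#' against every node on its assigned path.
#'
#' @param result A `kc_classification`.
#' @param h The `kc_hierarchy` used for classification.
#' @param aln The classified alignment.
#' @return A `kc_similarity` object wrapping the source x target matrix
#'   (rows = A, columns = B; `NA` rows for memberless clusters).
#' @export
similarity_matrix <- function(result, h, aln) {
  nodes <- scoreable_nodes(h)
  wide <- pivot_wider(result$scores, names_from = "cluster_id",
                      values_from = "score")
  sc <- as.matrix(wide[, nodes, drop = FALSE])
  rownames(sc) <- wide$sequence_id
  out <- matrix(NA_real_, length(nodes), length(nodes),
                dimnames = list(source = nodes, target = nodes))
  n_members <- setNames(integer(length(nodes)), nodes)
  for (a in nodes) {
    memb <- cluster_members(result, a)
    n_members[a] <- length(memb)
    if (length(memb) == 0) next
    out[a, ] <- colMeans(sc[memb, , drop = FALSE])
  }
  structure(list(matrix = out, n_members = n_members,
                 cutoff = result$cutoff),
            class = "kc_similarity")
}

#' @export
print.kc_similarity <- function(x, ...) {
  cat(sprintf("# Cluster similarity matrix (%d clusters, cutoff %.2f)\n",
              nrow(x$matrix), x$cutoff))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @describeIn similarity_matrix Tidy to one row per (source, target) pair.
#' @param x A `kc_similarity`.
#' @param ... Unused.
#' @method tidy kc_similarity
#' @export
tidy.kc_similarity <- function(x, ...) {
  m <- x$matrix
  tibble(
    source = rep(rownames(m), times = ncol(m)),
    target = rep(colnames(m), each = nrow(m)),
    similarity = as.vector(m),
    n_source = rep(unname(x$n_members[rownames(m)]), times = ncol(m))
  )
}

#' Comparative sequence logo data
#'
#' Pseudocounted per-column residue frequencies for a foreground set and
#' the remaining background, with a per-column divergence equal to the
#' relative entropy (Kullback-Leibler divergence, in nats) of the
#' foreground distribution from the background distribution — the
#' histogram height of a comparative logo. Gaps are excluded from counts;
#' a column that is all-gap in the foreground gets divergence 0 and is
#' flagged.
#'
#' @param aln A `kc_aln` alignment.
#' @param fg_ids Non-empty proper subset of sequence ids.
#' @param columns 1-based alignment columns to include.
#' @param pseudocount Pseudocount per residue. Default 1.
#' @return A `kc_logo` object: list with `freq` (tibble: `column`,
#'   `residue`, `fg_freq`, `bg_freq`) and `divergence` (tibble: `column`,
#'   `divergence`, `flagged`).
#' @export
comparative_logo <- function(aln, fg_ids, columns, pseudocount = 1) {
  fg_ids <- unique(fg_ids)
  if (length(fg_ids) == 0 || length(fg_ids) >= nrow(aln) ||
      !all(fg_ids %in% aln$sequence_id)) {
    abort("`fg_ids` must be a non-empty proper subset of sequence ids")
  }
  if (any(columns < 1 | columns > n_columns(aln))) {
    abort("columns out of range")
  }
  m <- aln_matrix(aln)
  fg <- match(fg_ids, aln$sequence_id)
  bg <- setdiff(seq_len(nrow(aln)), fg)
  fc <- residue_counts(m, fg)[, columns, drop = FALSE]
  bc <- residue_counts(m, bg)[, columns, drop = FALSE]

  a <- pseudocount
  ff <- sweep(fc + a, 2, colSums(fc) + 20 * a, "/")
  bf <- sweep(bc + a, 2, colSums(bc) + 20 * a, "/")
  kl <- colSums(ff * log(ff / bf))
  flagged <- colSums(fc) == 0
  kl[flagged] <- 0

  freq <- tibble(
    column = rep(as.integer(columns), each = 20),
    residue = rep(kc_alphabet, times = length(columns)),
    fg_freq = as.vector(ff),
    bg_freq = as.vector(bf)
  )
  divergence <- tibble(column = as.integer(columns),
                       divergence = unname(kl),
                       flagged = unname(flagged))
  if (any(flagged)) {
    warn(sprintf("%d column(s) are all-gap in the foreground", sum(flagged)))
  }
  structure(list(freq = freq, divergence = divergence),
            class = "kc_logo")
}

#' @export
print.kc_logo <- function(x, ...) {
  cat(sprintf("# Comparative logo data: %d columns\n",
              nrow(x$divergence)))
  print(x$divergence, ...)
  invisible(x)
}

#' @describeIn comparative_logo Tidy to per-(column, residue) rows with
#'   divergence attached.
#' @param x A `kc_logo`.
#' @param ... Unused.
#' @method tidy kc_logo
#' @export
tidy.kc_logo <- function(x, ...) {
  left_join(x$freq, x$divergence, by = "column")
}

#' Per-sequence and per-family alphaD-alphaE loop lengths
#'
#' The DE insert (kinase insert domain) sits between the alphaD and alphaE
#' helices. Its length for a sequence is the number of non-gap match
#' residues strictly between the anchor columns plus all insert residues
#' attached between them. Families with long inserts (longDE clade,
#' predominantly receptor tyrosine kinases) separate sharply from shortDE
#' families.
#'
#' @param aln A `kc_aln` alignment; if `d_end`/`e_start` are missing they
#'   are taken from `column_labels(aln)` entries `alphaD_end` and
#'   `alphaE_start`.
#' @param family_map Data frame with `sequence_id` and `family`, or a
#'   named character vector. Sequences without a family are grouped as
#'   `"unclassified"`.
#' @param d_end,e_start 1-based anchor columns, `d_end < e_start`.
#' @return A `kc_loops` object: per-family tibble with `family`, `n`,
#'   `lengths` (list), `median_length` and `clade` (initially
#'   `"unassigned"`); the per-sequence table is in attribute
#'   `"per_sequence"`.
#' @export
de_loop_lengths <- function(aln, family_map, d_end = NULL, e_start = NULL) {
  labs <- column_labels(aln)
  d_end <- d_end %||% labs[["alphaD_end"]]
  e_start <- e_start %||% labs[["alphaE_start"]]
  if (is.null(d_end) || is.null(e_start)) abort("anchor columns required")
  if (d_end >= e_start) abort("`d_end` must be < `e_start`")
  if (d_end < 1 || e_start > n_columns(aln)) abort("anchors out of range")

  fam <- normalize_family_map(family_map)
  m <- aln_matrix(aln)
  inner <- if (e_start - d_end > 1) (d_end + 1):(e_start - 1) else integer(0)
  match_len <- if (length(inner) > 0) {
    rowSums(m[, inner, drop = FALSE] != "-")
  } else rep(0L, nrow(aln))
  ins_len <- map_int(aln$inserts, function(ins) {
    sum(nchar(ins[(d_end + 1):e_start]))
  })
  per_seq <- tibble(sequence_id = aln$sequence_id,
                    family = fam[aln$sequence_id] %|NA|% "unclassified",
                    loop_length = as.integer(match_len + ins_len))
  stats <- per_seq %>%
    group_by(.data$family) %>%
    summarise(n = n(),
              lengths = list(.data$loop_length),
              median_length = median(.data$loop_length),
              .groups = "drop") %>%
    mutate(clade = "unassigned")
  structure(stats, class = c("kc_loops", class(stats)),
            per_sequence = per_seq)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

normalize_family_map <- function(family_map) {
  if (is.data.frame(family_map)) {
    setNames(as.character(family_map$family), family_map$sequence_id)
  } else {
    fm <- as.character(family_map)
    names(fm) <- names(family_map)
    fm
  }
}

#' Label families as longDE or shortDE
#'
#' Clade labels come from a user-supplied (typically phylogeny-derived)
#' map when given; otherwise a heuristic threshold on the median loop
#' length is applied (`median > threshold` → longDE). Exactly one of
#' `clade_map` and `threshold` must be provided.
#'
#' @param stats A `kc_loops` table from [de_loop_lengths()].
#' @param clade_map Named character vector family → `"longDE"`/`"shortDE"`.
#' @param threshold Numeric median-length threshold (e.g. 10).
#' @return `stats` with the `clade` column filled.
#' @export
label_clades <- function(stats, clade_map = NULL, threshold = NULL) {
  if (is.null(clade_map) == is.null(threshold)) {
    abort("provide exactly one of `clade_map` or `threshold`")
  }
  if (!is.null(clade_map)) {
    stats$clade <- unname(clade_map[stats$family]) %|NA|% "unassigned"
  } else {
    stats$clade <- ifelse(stats$median_length > threshold,
                          "longDE", "shortDE")
  }
  stats
}

#' Display table of loop statistics with a length cap
#'
#' @param stats A `kc_loops` table.
#' @param display_cap Lengths above this are reported as `">cap"` in the
#'   `median_display` column. Default 30.
#' @return Tibble with `family`, `n`, `median_length`, `median_display`,
#'   `clade`.
#' @export
loop_display <- function(stats, display_cap = 30) {
  mutate(as_tibble(stats)[, c("family", "n", "median_length", "clade")],
         median_display = ifelse(.data$median_length > display_cap,
                                 paste0(">", display_cap),
                                 format(.data$median_length, trim = TRUE)),
         .after = "median_length")
}
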