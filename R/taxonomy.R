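#' Parse NCBI-taxdump-dialect nodes and names files
#'
#' The taxdump dialect separates fields with `\t|\t` and terminates lines
#' with `\t|`. From `nodes.dmp` the node id, parent id and rank are used;
#' from `names.dmp` only rows of class `"scientific name"`. The NCBI
#' convention that the root is its own parent is normalised to a `NA`
#' parent.
#'
#' @param nodes_path,names_path Paths to the dump files.
#' @return A `kc_taxonomy` tibble with `tax_id`, `parent_id`, `rank`,
#'   `name`.
#' @export
parse_taxdump <- function(nodes_path, names_path) {
  nodes_fields <- read_dmp(nodes_path, min_fields = 3)
  nodes <- tibble(
    tax_id = as.integer(map_chr(nodes_fields, 1)),
    parent_id = as.integer(map_chr(nodes_fields, 2)),
    rank = map_chr(nodes_fields, 3)
  )
  nodes$parent_id[nodes$parent_id == nodes$tax_id] <- NA_integer_

  names_fields <- read_dmp(names_path, min_fields = 4)
  name_tbl <- tibble(
    tax_id = as.integer(map_chr(names_fields, 1)),
    name = map_chr(names_fields, 2),
    class = map_chr(names_fields, 4)
  ) %>%
    filter(.data$class == "scientific name") %>%
    distinct(.data$tax_id, .keep_all = TRUE)

  out <- left_join(nodes, name_tbl[, c("tax_id", "name")], by = "tax_id")
  if (any(is.na(out$name))) {
    warn(sprintf("%d node(s) without a scientific name",
                 sum(is.na(out$name))))
  }
  new_tibble(out, class = "kc_taxonomy")
}

read_dmp <- function(path, min_fields) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  bad <- which(map_int(fields, length) < min_fields)
  if (length(bad) > 0) {
    abort(sprintf("malformed taxdump line %d in '%s'", bad[1], path))
  }
  fields
}

#' Write a taxonomy as taxdump-dialect nodes/names files
#'
#' Inverse of [parse_taxdump()] (up to rank/name fields used); handy for
#' synthetic data and round-trip tests.
#'
#' @param tax A `kc_taxonomy`.
#' @param dir Output directory; `nodes.dmp` and `names.dmp` are written
#'   inside it.
#' @return `dir`, invisibly.
#' @export
write_taxdump <- function(tax, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parent <- ifelse(is.na(tax$parent_id), tax$tax_id, tax$parent_id)
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", tax$tax_id, parent, tax$rank)
  names_l <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     tax$tax_id, tax$name)
  readr::write_lines(nodes, file.path(dir, "nodes.dmp"))
  readr::write_lines(names_l, file.path(dir, "names.dmp"))
  invisible(dir)
}

#' Lineage of a taxon, root first
#'
#' Follows parent pointers from the given organism identifier up to the
#' root. Cycle-safe: revisiting a node raises a data error.
#'
#' @param tax A `kc_taxonomy`.
#' @param ox Integer taxon id present in `tax`.
#' @return Integer vector of node ids ordered root → `ox`.
#' @export
lineage <- function(tax, ox) {
  parent <- setNames(tax$parent_id, tax$tax_id)
  if (!as.character(ox) %in% names(parent)) {
    abort(sprintf("unknown taxon id %s", ox))
  }
  out <- integer(0)
  cur <- as.integer(ox)
  seen <- integer(0)
  repeat {
    if (cur %in% seen) abort("cycle in taxonomy parent pointers")
    seen <- c(seen, cur)
    out <- c(cur, out)
    p <- parent[[as.character(cur)]]
    if (is.na(p)) break
    cur <- p
  }
  out
}

#' All descendant taxa of a node (including itself)
#' @inheritParams lineage
#' @param node Integer taxon id.
#' @return Integer vector of taxon ids.
#' @export
taxon_descendants <- function(tax, node) {
  out <- node
  frontier <- node
  while (length(frontier) > 0) {
    kids <- tax$tax_id[!is.na(tax$parent_id) & tax$parent_id %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Cluster-by-taxon conservation matrix
#'
#' An entry (cluster, taxon) is `TRUE` when at least one sequence scoring
#' at least `cutoff` against the cluster descends from the taxon (i.e. the
#' taxon appears in the lineage of the sequence's organism). Entries are
#' monotone in the cut-off: relaxing it can only add detections.
#' Sequences without an organism id are ignored (with a message).
#'
#' @param result A `kc_classification` (its score table is used).
#' @param aln The classified alignment (provides organism ids).
#' @param tax A `kc_taxonomy`.
#' @param target_taxa Integer taxon ids to report (must exist in `tax`).
#' @param cutoff Score cut-off; defaults to the classification's.
#' @return A `kc_conservation` object: long tibble `cluster_id`,
#'   `taxon_id`, `taxon_name`, `detected`, with the cut-off as attribute.
#' @export
conservation_matrix <- function(result, aln, tax, target_taxa,
                                cutoff = NULL) {
  cutoff <- cutoff %||% result$cutoff
  if (!all(target_taxa %in% tax$tax_id)) {
    abort("all target taxa must exist in the taxonomy")
  }
  no_ox <- is.na(aln$organism_id)
  if (any(no_ox)) {
    inform(sprintf("%d sequence(s) without organism id ignored",
                   sum(no_ox)))
  }
  ox_of <- setNames(aln$organism_id, aln$sequence_id)
  lineages <- lapply(unique(aln$organism_id[!no_ox]),
                     function(o) lineage(tax, o))
  names(lineages) <- as.character(unique(aln$organism_id[!no_ox]))

  clusters <- sort(unique(result$scores$cluster_id))
  hits <- result$scores %>%
    filter(.data$score >= cutoff) %>%
    mutate(organism_id = ox_of[.data$sequence_id]) %>%
    filter(!is.na(.data$organism_id))

  name_of <- setNames(tax$name, tax$tax_id)
  grid <- expand.grid(cluster_id = clusters, taxon_id = target_taxa,
                      stringsAsFactors = FALSE)
  detected <- map_lgl(seq_len(nrow(grid)), function(i) {
    cl <- grid$cluster_id[i]
    tx <- grid$taxon_id[i]
    org <- unique(hits$organism_id[hits$cluster_id == cl])
    any(map_lgl(as.character(org),
                function(o) tx %in% lineages[[o]]))
  })
  out <- as_tibble(grid) %>%
    mutate(taxon_name = unname(name_of[as.character(.data$taxon_id)]),
           detected = detected)
  out <- new_tibble(out, class = "kc_conservation")
  attr(out, "cutoff") <- cutoff
  out
}

#' @export
print.kc_conservation <- function(x, ...) {
  cat(sprintf("# Conservation matrix (cutoff %.2f): %d clusters x %d taxa\n",
              attr(x, "cutoff"), length(unique(x$cluster_id)),
              length(unique(x$taxon_id))))
  NextMethod()
}

#' Wide view of a conservation matrix
#' @param x A `kc_conservation`.
#' @return Logical matrix, clusters x taxa (named by scientific name).
#' @export
conservation_wide <- function(x) {
  wide <- pivot_wider(as_tibble(x)[, c("cluster_id", "taxon_name",
                                       "detected")],
                      names_from = "taxon_name", values_from = "detected")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$cluster_id
  m
}

#' Per-cluster protein domain frequency table
#'
#' Given per-sequence domain annotations (e.g. precomputed CDD output),
#' reports for each cluster the fraction of member sequences containing
#' each domain. Consecutive repeats of the same domain within a protein
#' are compressed to a single occurrence before counting; a user-supplied
#' synonym map is applied first. Domains below `min_fraction` are retained
#' in the table but flagged `displayed = FALSE` (display convention:
#' domains in at least 3% of sequences are shown).
#'
#' @param annotations Data frame with `sequence_id`, `domain`, and
#'   optionally `start` (used to order domains within a protein).
#' @param result A `kc_classification`.
#' @param min_fraction Display threshold. Default 0.03.
#' @param synonyms Optional named character vector mapping domain names to
#'   canonical names.
#' @return Tibble with `cluster_id`, `domain`, `n_with`, `n_members`,
#'   `frequency`, `displayed`.
#' @export
domain_frequency <- function(annotations, result, min_fraction = 0.03,
                             synonyms = NULL) {
  ann <- as_tibble(annotations)
  if (!is.null(synonyms)) {
    hit <- ann$domain %in% names(synonyms)
    ann$domain[hit] <- unname(synonyms[ann$domain[hit]])
  }
  if (!is.null(ann$start)) {
    ann <- arrange(ann, .data$sequence_id, .data$start)
  }
  # compress consecutive repeats within each protein
  ann <- ann %>%
    group_by(.data$sequence_id) %>%
    filter(is.na(dplyr::lag(.data$domain)) |
             .data$domain != dplyr::lag(.data$domain)) %>%
    ungroup() %>%
    distinct(.data$sequence_id, .data$domain,
             .keep_all = FALSE)

  clusters <- sort(unique(result$scores$cluster_id))
  bind_rows(lapply(clusters, function(cl) {
    memb <- cluster_members(result, cl)
    if (length(memb) == 0) return(NULL)
    sub <- filter(ann, .data$sequence_id %in% memb)
    if (nrow(sub) == 0) return(NULL)
    sub %>%
      count(.data$domain, name = "n_with") %>%
      mutate(cluster_id = cl, n_members = length(memb),
             frequency = .data$n_with / .data$n_members,
             displayed = .data$frequency >= min_fraction,
             .before = 1) %>%
      select("cluster_id", "domain", "n_with", "n_members",
             "frequency", "displayed")
  })) %>%
    arrange(.data$cluster_id, desc(.data$frequency), .data$domain)
}
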