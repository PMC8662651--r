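#' Intron phases from coding exon lengths
#'
#' The phase of an intron is the cumulative coding length (nt) of the
#' exons preceding it, modulo 3 (the codon size): phase 0 lies between two
#' codons, phase 1 between the first and second nucleotide of a codon,
#' phase 2 between the second and third. `codon_position` is the number of
#' complete codons before the intron (floor of the cumulative length over
#' 3); a phase-1/2 intron "belongs to" the codon it interrupts, so
#' `codon_position` is also the 0-based index of the interrupted (or, for
#' phase 0, the immediately following) residue.
#'
#' @param exons Either a numeric vector of exon lengths (nt, ORF order)
#'   for a single gene, or a data frame with `protein_id` and `length_nt`
#'   (optionally `exon_index` for ordering).
#' @return Tibble with `protein_id` (absent for vector input),
#'   `intron_index` (intron i follows exon i), `phase`, `codon_position`.
#'   A gene whose total length is not divisible by 3 is flagged in the
#'   `partial` column.
#' @export
intron_phases <- function(exons) {
  if (is.numeric(exons)) {
    return(intron_phases_one(exons))
  }
  exons <- as_tibble(exons)
  if (!all(c("protein_id", "length_nt") %in% names(exons))) {
    abort("`exons` needs `protein_id` and `length_nt` columns")
  }
  if (!is.null(exons$exon_index)) {
    exons <- arrange(exons, .data$protein_id, .data$exon_index)
  }
  exons %>%
    group_by(.data$protein_id) %>%
    summarise(res = list(intron_phases_one(.data$length_nt)),
              .groups = "drop") %>%
    unnest("res")
}

intron_phases_one <- function(lengths) {
  if (length(lengths) < 1 || any(lengths <= 0) ||
      any(lengths != round(lengths))) {
    abort("exon lengths must be positive integers")
  }
  partial <- (sum(lengths) %% 3) != 0
  if (length(lengths) == 1) {
    return(tibble(intron_index = integer(0), phase = integer(0),
                  codon_position = integer(0), partial = logical(0)))
  }
  cum <- cumsum(lengths)[-length(lengths)]
  tibble(intron_index = seq_along(cum),
         phase = as.integer(cum %% 3),
         codon_position = as.integer(cum %/% 3),
         partial = partial)
}

#' Map intron positions onto alignment columns
#'
#' For each intron, walks the protein's residues in order (insert and
#' match residues interleaved as in the A2M record) to locate the residue
#' at the intron's `codon_position`: if it falls on a profile match column
#' the intron gets that `alignment_column`; if it falls in an insert
#' segment or beyond the aligned domain the column is `NA` and the
#' `region` column says why. An intron is never mapped to a column where
#' the record has a gap.
#'
#' @param introns Tibble from [intron_phases()] with `protein_id`.
#' @param aln A `kc_aln` alignment; `protein_id` values are matched
#'   against `sequence_id`.
#' @return `introns` with `alignment_column` (integer or `NA`) and
#'   `region` (`"match"`, `"insert"`, `"outside"`) columns added.
#' @export
map_intron_to_alignment <- function(introns, aln) {
  maps <- lapply(seq_len(nrow(aln)), function(i) {
    residue_column_map(aln$match[i], aln$inserts[[i]])
  })
  names(maps) <- aln$sequence_id

  out <- introns
  out$alignment_column <- NA_integer_
  out$region <- "outside"
  for (i in seq_len(nrow(out))) {
    pid <- out$protein_id[i]
    cmap <- maps[[pid]]
    if (is.null(cmap)) next
    p <- out$codon_position[i] + 1L  # 1-based residue index
    if (p < 1 || p > length(cmap)) next
    if (is.na(cmap[p])) {
      out$region[i] <- "insert"
    } else {
      out$alignment_column[i] <- cmap[p]
      out$region[i] <- "match"
    }
  }
  out
}

# For one record: vector over the protein's residues (in order), giving
# the match column of each residue or NA for insert residues.
residue_column_map <- function(match, inserts) {
  mch <- strsplit(match, "", fixed = TRUE)[[1]]
  n <- length(mch)
  out <- integer(0)
  for (k in seq_len(n + 1L)) {
    out <- c(out, rep(NA_integer_, nchar(inserts[k])))
    if (k <= n && mch[k] != "-") out <- c(out, k)
  }
  out
}

#' Group introns shared across sequences and families
#'
#' Introns mapping to the same (alignment column, phase) in different
#' sequences are evidence of common descent. Introns that did not map to
#' a match column are excluded. Groups are sorted by the number of
#' distinct supporting families, descending.
#'
#' @param mapped Tibble from [map_intron_to_alignment()].
#' @param family_map Data frame with `sequence_id`/`family` or a named
#'   character vector mapping protein ids to families.
#' @return Tibble with `alignment_column`, `phase`, `n_families`,
#'   `families` (list column), `n_seqs`.
#' @export
shared_introns <- function(mapped, family_map) {
  fam <- normalize_family_map(family_map)
  mapped %>%
    filter(!is.na(.data$alignment_column)) %>%
    mutate(family = fam[.data$protein_id] %|NA|% "unclassified") %>%
    group_by(.data$alignment_column, .data$phase) %>%
    summarise(n_families = length(unique(.data$family)),
              families = list(sort(unique(.data$family))),
              n_seqs = length(unique(.data$protein_id)),
              .groups = "drop") %>%
    arrange(desc(.data$n_families), desc(.data$n_seqs),
            .data$alignment_column)
}

#' Extract coding exon lengths from a GFF3 file
#'
#' Convenience reader for the exon-length table: takes CDS features
#' (1-based inclusive coordinates per the GFF3 standard), groups them by
#' their `Parent` (or `ID`) attribute, orders them along the ORF
#' (reversing segment order on the minus strand), and returns their
#' lengths. Requires the rtracklayer package.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `protein_id`, `exon_index`, `length_nt`.
#' @export
read_cds_lengths <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_cds_lengths() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) {
    return(tibble(protein_id = character(0), exon_index = integer(0),
                  length_nt = integer(0)))
  }
  grd <- as.data.frame(gr)
  parent <- if (!is.null(grd$Parent) && any(lengths(grd$Parent) > 0)) {
    vapply(as.list(grd$Parent), function(p)
      if (length(p) > 0) p[[1]] else NA_character_, character(1))
  } else as.character(grd$ID)
  df <- tibble(protein_id = parent,
               start = grd$start,
               width = grd$width,
               strand = as.character(grd$strand))
  df %>%
    group_by(.data$protein_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(ord = if (dplyr::first(.data$strand) == "-")
      rev(row_number()) else row_number()) %>%
    arrange(.data$ord, .by_group = TRUE) %>%
    mutate(exon_index = row_number(), length_nt = .data$width) %>%
    ungroup() %>%
    select("protein_id", "exon_index", "length_nt")
}
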