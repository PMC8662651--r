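#' Profile alignments
#'
#' A profile alignment is the substrate of every analysis in kinclust. It is
#' stored as a tibble with one row per sequence and columns:
#'
#' * `sequence_id` — unique identifier (first whitespace-delimited token of
#'   the FASTA header),
#' * `description` — remainder of the header (may carry a UniProt-style
#'   `OX=<taxid>` tag),
#' * `organism_id` — integer NCBI taxon identifier parsed from `OX=`, or `NA`,
#' * `match` — string of fixed length (the number of profile match columns)
#'   over the 20 amino acids, `-` (deletion) and `X` (unknown),
#' * `inserts` — list column; each element is a character vector of
#'   `n_columns(aln) + 1` insert segments (element `i` sits immediately
#'   before match column `i`; the last element follows the final column).
#'
#' The number of match columns is carried as an attribute, as is an optional
#' named vector of `column_labels` mapping structural anchors (e.g.
#' `beta3_K`, `DFG_D`, `alphaD_end`, `alphaE_start`, `alphaH`) to 1-based
#' column indices.
#'
#' @param records A data frame with at least `sequence_id` and `match`
#'   columns; `organism_id`, `description` and `inserts` are filled with
#'   defaults when absent.
#' @param column_labels Optional named integer vector of anchor columns.
#' @return A `kc_aln` tibble.
#' @export
profile_alignment <- function(records, column_labels = NULL) {
  records <- as_tibble(records)
  if (!all(c("sequence_id", "match") %in% names(records))) {
    abort("`records` must have `sequence_id` and `match` columns.")
  }
  widths <- nchar(records$match)
  if (length(unique(widths)) > 1) {
    bad <- records$sequence_id[widths != widths[1]][1]
    abort(sprintf("inconsistent match-column counts (record '%s')", bad))
  }
  n_col <- if (nrow(records) > 0) widths[1] else 0L
  if (anyDuplicated(records$sequence_id)) {
    abort("duplicated sequence ids in alignment")
  }
  if (!"description" %in% names(records)) records$description <- NA_character_
  if (!"organism_id" %in% names(records)) records$organism_id <- NA_integer_
  records$organism_id <- as.integer(records$organism_id)
  if (!"inserts" %in% names(records)) {
    records$inserts <- rep(list(character(n_col + 1L)), nrow(records))
    records$inserts <- map(records$inserts, function(x) {
      x[] <- ""
      x
    })
  }
  ok_ins <- map_lgl(records$inserts, function(x) length(x) == n_col + 1L)
  if (nrow(records) > 0 && !all(ok_ins)) {
    abort("each `inserts` element must have n_columns + 1 segments")
  }
  records <- records[, c("sequence_id", "description", "organism_id",
                         "match", "inserts")]
  out <- new_tibble(records, class = "kc_aln")
  attr(out, "n_columns") <- as.integer(n_col)
  attr(out, "column_labels") <- column_labels
  out
}

#' Number of match columns of a profile alignment
#' @param aln A `kc_aln` alignment.
#' @return Integer scalar.
#' @export
n_columns <- function(aln) attr(aln, "n_columns")

#' Anchor column labels of a profile alignment
#' @inheritParams n_columns
#' @return Named integer vector (possibly `NULL`).
#' @export
column_labels <- function(aln) attr(aln, "column_labels")

#' @export
`column_labels<-` <- function(aln, value) {
  attr(aln, "column_labels") <- value
  aln
}

# Rebuild a kc_aln around a plain-tibble subset, keeping alignment attributes.
aln_replace <- function(aln, records) {
  out <- new_tibble(as_tibble(records), class = "kc_aln")
  attr(out, "n_columns") <- attr(aln, "n_columns")
  attr(out, "column_labels") <- attr(aln, "column_labels")
  out
}

# Character matrix of match states (rows = sequences, columns = profile
# columns). This is the workhorse representation for counting.
aln_matrix <- function(aln) {
  if (nrow(aln) == 0) {
    return(matrix(character(0), nrow = 0, ncol = n_columns(aln)))
  }
  m <- matrix(unlist(strsplit(aln$match, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(aln), ncol = n_columns(aln), byrow = TRUE)
  rownames(m) <- aln$sequence_id
  m
}

#' @export
print.kc_aln <- function(x, ...) {
  cat(sprintf("# Profile alignment: %d sequences x %d match columns\n",
              nrow(x), n_columns(x)))
  labs <- column_labels(x)
  if (!is.null(labs)) {
    cat("# Anchors:", paste(names(labs), labs, sep = "=", collapse = ", "),
        "\n")
  }
  NextMethod()
}

#' Read an A2M-style aligned FASTA file
#'
#' A2M encodes profile states by letter case: uppercase letters and `-` are
#' match-column states, lowercase letters are insertions relative to the
#' profile, and `.` is alignment padding (ignored). Every record must carry
#' the same number of match states. A UniProt-style `OX=<taxid>` tag in the
#' header, when present, populates `organism_id`.
#'
#' Uppercase letters outside the 20-residue alphabet (e.g. `B`, `Z`) are
#' recoded as the unknown residue `X`, which never satisfies a constraint
#' and never counts toward sequence identity.
#'
#' @param path Path to the A2M FASTA file.
#' @return A [profile_alignment()] tibble.
#' @export
read_a2m <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  ox <- suppressWarnings(as.integer(str_match(headers, "\\bOX=(\\d+)")[, 2]))

  parsed <- map(unname(as.character(seqs)), parse_a2m_states)
  n_match <- map_int(parsed, function(p) nchar(p$match))
  if (length(unique(n_match)) > 1) {
    ref <- as.integer(names(sort(table(n_match), decreasing = TRUE))[1])
    bad <- ids[n_match != ref][1]
    abort(sprintf(
      "inconsistent match-column counts: record '%s' has %d, expected %d",
      bad, n_match[n_match != ref][1], ref))
  }
  profile_alignment(tibble(
    sequence_id = ids,
    description = desc,
    organism_id = ox,
    match = map_chr(parsed, "match"),
    inserts = map(parsed, "inserts")
  ))
}

parse_a2m_states <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  is_upper <- ch %in% LETTERS
  is_dash <- ch == "-"
  is_lower <- ch %in% letters
  is_dot <- ch == "."
  if (!all(is_upper | is_dash | is_lower | is_dot)) {
    abort(sprintf("invalid A2M character '%s'",
                  ch[!(is_upper | is_dash | is_lower | is_dot)][1]))
  }
  is_match <- is_upper | is_dash
  mch <- ch[is_match]
  mch[!(mch %in% c(kc_alphabet, "-"))] <- "X"
  n <- sum(is_match)
  inserts <- character(n + 1L)
  inserts[] <- ""
  if (any(is_lower)) {
    slot <- cumsum(is_match)[is_lower] + 1L
    ins_ch <- toupper(ch[is_lower])
    ins_ch[!(ins_ch %in% kc_alphabet)] <- "X"
    for (k in unique(slot)) {
      inserts[k] <- paste(ins_ch[slot == k], collapse = "")
    }
  }
  list(match = paste(mch, collapse = ""), inserts = inserts)
}

#' Write a profile alignment as A2M
#'
#' Inverse of [read_a2m()]: match states are written uppercase (or `-`),
#' insert segments lowercase. `read_a2m(write_a2m(aln))` is the identity on
#' the alignment data model.
#'
#' @param aln A `kc_aln` alignment.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_a2m <- function(aln, path) {
  n <- n_columns(aln)
  strings <- pmap(list(aln$match, aln$inserts), function(m, ins) {
    mch <- strsplit(m, "", fixed = TRUE)[[1]]
    pieces <- character(2L * n + 1L)
    pieces[seq(1L, 2L * n + 1L, by = 2L)] <- tolower(ins)
    pieces[seq(2L, 2L * n, by = 2L)] <- mch
    paste(pieces, collapse = "")
  })
  headers <- ifelse(is.na(aln$description), aln$sequence_id,
                    paste(aln$sequence_id, aln$description))
  set <- Biostrings::BStringSet(unlist(strings))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 20000L)
  invisible(path)
}

#' Remove fragmentary sequences from an alignment
#'
#' A sequence is deemed fragmentary, and removed, unless it has a residue
#' (non-gap match state) at or before `first_required` and at or after
#' `last_required`. In kinase-domain profiles these anchors are typically
#' the beta3 lysine and the DFG aspartate columns.
#'
#' @param aln A `kc_aln` alignment.
#' @param first_required,last_required 1-based anchor column indices with
#'   `first_required <= last_required`.
#' @return The filtered alignment; surviving records are unaltered.
#' @export
filter_fragments <- function(aln, first_required, last_required) {
  n <- n_columns(aln)
  if (first_required < 1 || last_required > n ||
      first_required > last_required) {
    abort("anchor columns out of range")
  }
  m <- aln_matrix(aln)
  keep <- vapply(seq_len(nrow(aln)), function(i) {
    any(m[i, seq_len(first_required)] != "-") &&
      any(m[i, last_required:n] != "-")
  }, logical(1))
  aln_replace(aln, aln[keep, ])
}

#' Purge an alignment at a sequence-identity threshold
#'
#' Greedy single-pass clustering in input order: each record is compared to
#' all previously retained records and dropped if its match-column identity
#' to any of them is `>= threshold`. Identity is the fraction of identical
#' residues over columns where both records are non-gap; `X` never counts
#' as identical; a pair with no mutually non-gap columns has identity 0.
#' Input order therefore defines the retained representatives.
#'
#' @param aln A `kc_aln` alignment.
#' @param threshold Identity fraction in (0, 1], e.g. `0.98`.
#' @return The purged alignment.
#' @export
purge_identity <- function(aln, threshold = 0.98) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  if (nrow(aln) == 0) return(aln)
  m <- aln_matrix(aln)
  keep <- logical(nrow(aln))
  keep[1] <- TRUE
  for (i in seq_len(nrow(aln))[-1]) {
    ri <- m[i, ]
    prev <- which(keep)
    ids <- pairwise_identity_rows(m, prev, ri)
    keep[i] <- all(ids < threshold)
  }
  aln_replace(aln, aln[keep, ])
}

# Identity of row vector `ri` against each row of m[rows, ], as defined for
# purge_identity().
pairwise_identity_rows <- function(m, rows, ri) {
  sub <- m[rows, , drop = FALSE]
  valid_i <- ri != "-"
  both <- sweep(sub != "-", 2, valid_i, "&")
  eq <- sweep(sub, 2, ri, "==") & both
  eq <- eq & sweep(eq, 2, ri != "X", "&") & (sub != "X")
  num <- rowSums(eq)
  den <- rowSums(both)
  ifelse(den == 0, 0, num / den)
}

#' All-pairs match-column identity
#'
#' Convenience used in tests and diagnostics; same identity definition as
#' [purge_identity()].
#'
#' @param aln A `kc_aln` alignment.
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
identity_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  out <- matrix(1, n, n, dimnames = list(aln$sequence_id, aln$sequence_id))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    ids <- pairwise_identity_rows(m, (i + 1):n, m[i, ])
    out[i, (i + 1):n] <- ids
    out[(i + 1):n, i] <- ids
  }
  diag(out) <- 1
  out
}
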