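counts_of <- function(...) {
  x <- setNames(numeric(20), c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                               "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                               "W", "Y"))
  args <- list(...)
  for (r in names(args)) x[r] <- args[[r]]
  x
}

test_that("column_contrast matches the plug-in arithmetic oracle", {
  # n_F = 10 all in the set, n_B = 10 none, alpha = 1:
  # q_F = 11/12, q_B = 1/12, w = 10 * ln((11/12)/(1/12)) + 0 = 10 ln 11
  w <- column_contrast(counts_of(M = 10), counts_of(A = 10), "M",
                       pseudocount = 1)
  expect_equal(w, 10 * log(11))

  # hand-computed mixed case: n_FR = 7 of 10, n_BR = 2 of 20, alpha = 0.5
  # q_F = 7.5/11, q_B = 2.5/21
  q_f <- 7.5 / 11
  q_b <- 2.5 / 21
  w2 <- column_contrast(counts_of(K = 7, A = 3), counts_of(K = 2, A = 18),
                        "K", pseudocount = 0.5)
  expect_equal(w2, 7 * log(q_f / q_b) + 3 * log((1 - q_f) / (1 - q_b)))
})

test_that("column_contrast vanishes for identical profiles and full sets", {
  fg <- counts_of(A = 5, C = 5, D = 5, E = 5)
  expect_equal(column_contrast(fg, fg, "A"), 0)
  # proportional profiles are also contrast-free
  expect_equal(column_contrast(fg, 2 * fg, "AC"), 0)
  # the degenerate all-residue set carries no information
  all20 <- paste(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 collapse = "")
  expect_lt(abs(column_contrast(counts_of(M = 10), counts_of(A = 10),
                                all20)), 0.5)
  expect_error(column_contrast(numeric(20), counts_of(A = 1), "A"),
               "positive")
})

test_that("select_pattern finds a planted column with the top weight", {
  set.seed(7)
  n <- 20
  bg_cols <- replicate(20, sample(kinclust:::kc_alphabet, 2 * n,
                                  replace = TRUE))
  m <- apply(bg_cols, 2, identity)
  m[1:n, 7] <- "M"  # foreground fully conserved at column 7
  aln <- toy_aln(apply(m, 1, paste, collapse = ""),
                 ids = sprintf("q%02d", 1:(2 * n)))
  cons <- select_pattern(aln, aln$sequence_id[1:n], kc_config())
  expect_equal(cons$column[1], 7L)
  expect_true(grepl("M", cons$residues[1]))
  expect_true(all(cons$weight > 0))
})

test_that("columns that are all-gap in the foreground are never selected", {
  set.seed(8)
  m <- matrix(sample(kinclust:::kc_alphabet, 40 * 10, replace = TRUE),
              40, 10)
  m[1:20, 3] <- "-"
  aln <- toy_aln(apply(m, 1, paste, collapse = ""),
                 ids = sprintf("g%02d", 1:40))
  cons <- select_pattern(aln, aln$sequence_id[1:20], kc_config())
  expect_false(3L %in% cons$column)
})

test_that("vectorised pattern search equals the per-column greedy oracle", {
  set.seed(11)
  cfg <- kc_config()
  for (rep in 1:10) {
    m <- matrix(sample(c(kinclust:::kc_alphabet, "-"), 30 * 25,
                       replace = TRUE), 30, 25)
    fg <- sample(30, sample(5:15, 1))
    bg <- setdiff(1:30, fg)
    fast <- kinclust:::select_pattern_rows(m, fg, bg, cfg)
    fgc <- kinclust:::residue_counts(m, fg)
    bgc <- kinclust:::residue_counts(m, bg)
    slow <- list()
    for (cl in 1:25) {
      best <- kinclust:::greedy_column_set(fgc[, cl], bgc[, cl],
                                           cfg$pseudocount,
                                           cfg$min_fg_conservation,
                                           cfg$min_enrichment)
      if (!is.null(best) && best$w > 0) {
        slow[[length(slow) + 1]] <- tibble::tibble(
          column = cl,
          residues = paste(sort(kinclust:::kc_alphabet[best$set]),
                           collapse = ""),
          weight = best$w)
      }
    }
    slow <- dplyr::bind_rows(slow)
    slow <- head(dplyr::arrange(slow, dplyr::desc(weight), column),
                 cfg$max_constraints_per_node)
    expect_equal(as.data.frame(fast), as.data.frame(slow))
  }
})

test_that("sample_partition recovers two planted groups", {
  h <- make_hierarchy(n_supers = 2, subs_per_super = 0,
                      constraints_per_node = 5, n_columns = 200, seed = 3)
  sq <- make_sequences(h, n_per_leaf = 50, fidelity = 0.95, seed = 4)
  res <- sample_partition(sq$aln, kc_config(seed = 1))
  expect_true(res$accepted)
  truth_fg <- sq$truth$labels$sequence_id[sq$truth$labels$cluster_id == "S1"]
  in_fg <- sq$aln$sequence_id %in% res$fg_ids
  in_truth <- sq$aln$sequence_id %in% truth_fg
  expect_gte(ari(in_fg, in_truth), 0.9)
  expect_true(all(res$constraints$weight > 0))
  expect_gte(res$weight, kc_config()$minnat)
})

test_that("a homogeneous alignment is rejected in most seeds", {
  set.seed(20)
  m <- matrix(sample(kinclust:::kc_alphabet, 40 * 100, replace = TRUE),
              40, 100)
  aln <- toy_aln(apply(m, 1, paste, collapse = ""),
                 ids = sprintf("h%02d", 1:40))
  empty <- vapply(1:20, function(s) {
    res <- sample_partition(aln, kc_config(seed = s, minnat = 5))
    !res$accepted
  }, logical(1))
  expect_gte(mean(empty), 0.8)
})

test_that("sample_partition contracts: n_sweeps = 0 and small inputs", {
  aln <- toy_aln(c("AAA", "AAA", "CCC"))
  expect_error(sample_partition(aln, kc_config()), "at least 4")

  h <- make_hierarchy(2, 0, 5, n_columns = 100, seed = 5)
  sq <- make_sequences(h, n_per_leaf = 10, fidelity = 1, seed = 6)
  r1 <- sample_partition(sq$aln, kc_config(seed = 9, n_sweeps = 0))
  r2 <- sample_partition(sq$aln, kc_config(seed = 9, n_sweeps = 0))
  expect_identical(r1, r2)  # the scored initial split is deterministic
})

test_that("infer_hierarchy handles degenerate inputs", {
  h <- make_hierarchy(2, 0, 5, n_columns = 100, seed = 5)
  sq <- make_sequences(h, n_per_leaf = 10, fidelity = 1, seed = 6)
  h0 <- infer_hierarchy(sq$aln, kc_config(seed = 0), max_depth = 0)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$id, "root")

  same <- toy_aln(rep("ACDEFGHIKL", 10), ids = sprintf("i%02d", 1:10))
  h1 <- infer_hierarchy(same, kc_config(seed = 0), max_depth = 3)
  expect_equal(nrow(h1), 1L)
})

test_that("accepted nodes carry positive weights above minnat", {
  sim <- small_sim(seed = 2)
  cfg <- kc_config(seed = 2)
  h <- infer_hierarchy(sim$aln, cfg, max_depth = 3)
  for (i in seq_len(nrow(h))) {
    cons <- h$constraints[[i]]
    if (h$id[i] == "root") next
    expect_true(all(cons$weight > 0))
    expect_gte(sum(cons$weight), cfg$minnat)
  }
})

test_that("total_lpr behaves as an evidence measure", {
  h <- make_hierarchy(2, 0, 5, n_columns = 100, seed = 13)
  sq <- make_sequences(h, n_per_leaf = 25, fidelity = 0.95, seed = 14)
  ht <- sq$truth$hierarchy

  single <- constraint_hierarchy(
    tibble::tibble(id = "root", name = "root", parent_id = NA_character_,
                   constraints = list(tibble::tibble(column = integer(0),
                                                     residues = character(0),
                                                     weight = numeric(0))),
                   members = list(sq$aln$sequence_id)),
    n_columns = 100)
  expect_equal(total_lpr(single, sq$aln), 0)

  lpr_true <- total_lpr(ht, sq$aln)
  set.seed(99)
  for (i in 1:20) {
    hr <- ht
    perm <- sample(sq$aln$sequence_id)
    n1 <- length(hr$members[[which(hr$id == "S1")]])
    hr$members[[which(hr$id == "S1")]] <- perm[1:n1]
    hr$members[[which(hr$id == "S2")]] <- perm[(n1 + 1):length(perm)]
    expect_gte(lpr_true, total_lpr(hr, sq$aln))
  }

  # duplicating every sequence approximately doubles the total LPR
  dup <- sq$aln
  dup2 <- dplyr::mutate(tibble::as_tibble(dup),
                        sequence_id = paste0(sequence_id, "_dup"))
  both <- profile_alignment(dplyr::bind_rows(tibble::as_tibble(dup), dup2))
  hd <- ht
  hd$members <- lapply(ht$members, function(mm) c(mm, paste0(mm, "_dup")))
  ratio <- total_lpr(hd, both) / lpr_true
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("total_lpr is invariant under consistent column permutation", {
  h <- make_hierarchy(2, 0, 4, n_columns = 60, seed = 21)
  sq <- make_sequences(h, n_per_leaf = 15, fidelity = 0.95, seed = 22)
  ht <- sq$truth$hierarchy
  set.seed(23)
  perm <- sample(60)
  m <- kinclust:::aln_matrix(sq$aln)
  aln2 <- toy_aln(apply(m[, perm, drop = FALSE], 1, paste, collapse = ""),
                  ids = sq$aln$sequence_id)
  ht2 <- ht
  ht2$constraints <- lapply(ht$constraints, function(cons) {
    cons$column <- match(cons$column, perm)
    cons
  })
  ht2 <- constraint_hierarchy(ht2, n_columns = 60)
  ht2$members <- ht$members
  expect_equal(total_lpr(ht2, aln2), total_lpr(ht, sq$aln))
})

test_that("planted members satisfy ancestor constraints at the fidelity rate", {
  sim <- small_sim(seed = 6, n_per_leaf = 30)
  ht <- sim$truth$hierarchy
  m <- kinclust:::aln_matrix(sim$aln)
  for (leaf in c("S1.1", "S2.2")) {
    memb <- match(kinclust:::node_members(ht, leaf), sim$aln$sequence_id)
    anc <- setdiff(kinclust::node_ancestors(ht, leaf), "root")
    for (a in anc) {
      cons <- ht$constraints[[which(ht$id == a)]]
      sat <- vapply(seq_len(nrow(cons)), function(j) {
        set <- strsplit(cons$residues[j], "")[[1]]
        mean(m[memb, cons$column[j]] %in% set)
      }, numeric(1))
      expect_gte(mean(sat), 0.9)  # fidelity 0.95 minus sampling noise
    }
  }
})

test_that("consensus keeps reproducible clusters and drops spurious ones", {
  sim <- small_sim(seed = 3, n_per_leaf = 20, n_columns = 120)
  ht <- sim$truth$hierarchy
  cfg <- kc_config(seed = 0)

  runs <- list(ht, ht, ht)
  cons <- consensus_hierarchy(runs, sim$aln, cfg, min_support = 0.5)
  expect_equal(nrow(cons), nrow(ht))
  for (id in setdiff(ht$id, "root")) {
    memb <- sort(kinclust:::node_members(ht, id))
    hit <- any(vapply(seq_len(nrow(cons)), function(i)
      identical(sort(cons$members[[i]]), memb), logical(1)))
    expect_true(hit)
  }

  spurious <- ht[1, ]
  extra <- ht
  set.seed(31)
  extra <- dplyr::bind_rows(
    tibble::as_tibble(ht),
    tibble::tibble(id = "junk", name = "junk", parent_id = "root",
                   constraints = list(ht$constraints[[2]]),
                   members = list(sample(sim$aln$sequence_id, 10))))
  extra <- constraint_hierarchy(extra, n_columns = n_columns(sim$aln))
  runs2 <- list(ht, ht, extra)
  cons2 <- consensus_hierarchy(runs2, sim$aln, cfg, min_support = 0.5)
  junk_members <- sort(extra$members[[which(extra$id == "junk")]])
  hit <- any(vapply(seq_len(nrow(cons2)), function(i)
    length(intersect(cons2$members[[i]], junk_members)) /
      length(union(cons2$members[[i]], junk_members)) > 0.5, logical(1)))
  expect_false(hit)

  expect_error(consensus_hierarchy(list(ht), sim$aln, cfg), "at least 2")
})
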