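mini_hierarchy <- function(cons_list, n_columns = 10) {
  nodes <- tibble::tibble(
    id = c("root", names(cons_list)),
    name = c("root", names(cons_list)),
    parent_id = c(NA_character_,
                  vapply(cons_list, function(x)
                    attr(x, "parent") %||% "root", character(1))),
    constraints = c(list(tibble::tibble(column = integer(0),
                                        residues = character(0),
                                        weight = numeric(0))),
                    lapply(cons_list, tibble::as_tibble))
  )
  constraint_hierarchy(nodes, n_columns = n_columns)
}

`%||%` <- rlang::`%||%`

test_that("fit scores are the satisfied-weight fraction", {
  h <- mini_hierarchy(list(
    A = tibble::tibble(column = c(1L, 2L), residues = c("M", "K"),
                       weight = c(2, 2)),
    B = tibble::tibble(column = c(3L, 4L), residues = c("W", "F"),
                       weight = c(3, 1))
  ))
  aln <- toy_aln(c("MAAAAAAAAA",   # satisfies only column 1 of A
                   "AAWAAAAAAA",   # satisfies only the weight-3 constraint
                   "MKAAAAAAAA",   # satisfies all of A
                   "AAAAAAAAAA"))  # satisfies nothing
  expect_equal(score_sequence(aln, h, "s1", "A"), 0.5)
  expect_equal(score_sequence(aln, h, "s2", "B"), 0.75)
  expect_equal(score_sequence(aln, h, "s3", "A"), 1)
  expect_equal(score_sequence(aln, h, "s4", "A"), 0)
  expect_error(score_sequence(aln, h, "s1", "root"), "no effective")
})

test_that("gaps and unknown residues never satisfy a constraint", {
  h <- mini_hierarchy(list(
    A = tibble::tibble(column = 1:2, residues = c("M", "K"),
                       weight = c(1, 1))))
  aln <- toy_aln(c("----------", "XXXXXXXXXX"))
  expect_equal(score_sequence(aln, h, "s1", "A"), 0)
  expect_equal(score_sequence(aln, h, "s2", "A"), 0)
  sc <- score_all(aln, h)
  expect_true(all(sc$score == 0))
})

test_that("scoring matches a brute-force recomputation on random instances", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    cols <- sample(10, k)
    cons <- tibble::tibble(
      column = as.integer(cols),
      residues = vapply(seq_len(k), function(i)
        paste(sort(sample(kinclust:::kc_alphabet, sample(1:3, 1))),
              collapse = ""), character(1)),
      weight = runif(k, 0.5, 5))
    h <- mini_hierarchy(list(A = cons))
    s <- paste(sample(c(kinclust:::kc_alphabet, "-"), 10, replace = TRUE),
               collapse = "")
    aln <- toy_aln(s, ids = "q")
    got <- score_sequence(aln, h, "q", "A")
    ch <- strsplit(s, "")[[1]]
    num <- 0
    for (i in seq_len(k)) {
      if (ch[cons$column[i]] %in% strsplit(cons$residues[i], "")[[1]]) {
        num <- num + cons$weight[i]
      }
    }
    expect_equal(got, num / sum(cons$weight))
  }
})

test_that("adding constraints moves scores monotonically", {
  base <- tibble::tibble(column = 1:2, residues = c("M", "K"),
                         weight = c(1, 2))
  aln <- toy_aln("MKWAAAAAAA", ids = "q")
  h0 <- mini_hierarchy(list(A = base))
  s0 <- score_sequence(aln, h0, "q", "A")
  # adding a satisfied constraint cannot decrease the score
  h1 <- mini_hierarchy(list(A = dplyr::bind_rows(
    base, tibble::tibble(column = 3L, residues = "W", weight = 1))))
  expect_gte(score_sequence(aln, h1, "q", "A"), s0)
  # adding an unsatisfied constraint cannot increase it
  h2 <- mini_hierarchy(list(A = dplyr::bind_rows(
    base, tibble::tibble(column = 4L, residues = "W", weight = 1))))
  expect_lte(score_sequence(aln, h2, "q", "A"), s0)
})

test_that("select_cutoff finds the valley of a bimodal score distribution", {
  # mixture with a planted empty valley centred at 0.55: the global
  # minimum of the histogram is known by construction
  for (s in 7:9) {
    set.seed(s)
    scores <- c(runif(600, 0.05, 0.45), runif(400, 0.65, 0.95))
    cut <- select_cutoff(scores, bin_width = 0.01)
    expect_false(attr(cut, "fallback"))
    expect_lte(abs(as.numeric(cut) - 0.55), 0.015)
  }

  # overlapping Gaussian modes: the valley sits between them
  set.seed(5)
  scores2 <- c(pmax(0, pmin(1, rnorm(600, 0.25, 0.09))),
               pmax(0, pmin(1, rnorm(400, 0.9, 0.04))))
  cut2 <- select_cutoff(scores2, bin_width = 0.02)
  expect_false(attr(cut2, "fallback"))
  expect_gt(as.numeric(cut2), 0.4)
  expect_lt(as.numeric(cut2), 0.85)
})

test_that("select_cutoff falls back to 0.7 for unimodal scores", {
  set.seed(6)
  cut <- select_cutoff(pmin(1, pmax(0, rnorm(500, 0.5, 0.05))))
  expect_equal(as.numeric(cut), 0.7)
  expect_true(attr(cut, "fallback"))
  expect_error(select_cutoff(runif(50)), "at least 100")
  expect_equal(cutoff_preset("optimal"), 0.7)
  expect_equal(cutoff_preset("relaxed"), 0.6)
})

test_that("classification picks the deepest qualifying path", {
  # supercluster A with 10 unit constraints; subclusters B and C add 10 more
  cols_a <- 1:10
  cols_b <- 11:20
  cols_c <- 21:30
  mk <- function(cols, res) tibble::tibble(column = as.integer(cols),
                                           residues = res, weight = 1)
  b <- mk(cols_b, "K"); attr(b, "parent") <- "A"
  c_ <- mk(cols_c, "K"); attr(c_, "parent") <- "A"
  h <- mini_hierarchy(list(A = mk(cols_a, "M"), B = b, C = c_),
                      n_columns = 30)
  # sequence: 9/10 of A, 7/10 of B, 0/10 of C -> A: 0.9, B: 0.8, C: 0.45
  s <- paste(c(rep("M", 9), "A", rep("K", 7), rep("A", 3), rep("A", 10)),
             collapse = "")
  aln <- toy_aln(s, ids = "q")
  expect_equal(score_sequence(aln, h, "q", "A"), 0.9)
  expect_equal(score_sequence(aln, h, "q", "B"), 0.8)
  expect_equal(score_sequence(aln, h, "q", "C"), 0.45)
  res <- classify(aln, h, cutoff = 0.7)
  expect_equal(res$assignments$cluster_id, "B")
  expect_equal(res$assignments$path, "root/A/B")

  # below the cutoff everywhere -> unclassified sink
  aln2 <- toy_aln(paste(rep("A", 30), collapse = ""), ids = "q2")
  res2 <- classify(aln2, h, cutoff = 0.7)
  expect_equal(res2$assignments$cluster_id, "unclassified")

  # deterministic and idempotent
  expect_identical(classify(aln, h, 0.7)$assignments, res$assignments)
})

test_that("random background sequences fall into the unclassified sink", {
  sim <- small_sim(seed = 4, n_per_leaf = 25)
  ht <- sim$truth$hierarchy
  set.seed(44)
  rand <- toy_aln(replicate(40, paste(sample(kinclust:::kc_alphabet,
                                             n_columns(sim$aln),
                                             replace = TRUE),
                                      collapse = "")),
                  ids = sprintf("r%02d", 1:40))
  res <- classify(rand, ht, cutoff = 0.7)
  expect_gte(mean(res$assignments$cluster_id == "unclassified"), 0.95)
})

test_that("members score higher on their own cluster than unrelated ones", {
  sim <- small_sim(seed = 5, n_per_leaf = 25)
  ht <- sim$truth$hierarchy
  sc <- score_all(sim$aln, ht)
  lab <- setNames(sim$truth$labels$cluster_id,
                  sim$truth$labels$sequence_id)
  own <- sc$score[sc$cluster_id == lab[sc$sequence_id]]
  other_leaf <- sc$score[sc$cluster_id != lab[sc$sequence_id] &
                           sc$cluster_id %in% c("S1.1", "S1.2", "S2.1",
                                                "S2.2")]
  expect_gt(mean(own), mean(other_leaf))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_equal(nrow(sc), nrow(sim$aln) * 6)  # 6 scoreable nodes
})

test_that("tidy and glance summarise classifications", {
  sim <- small_sim(seed = 5, n_per_leaf = 10)
  res <- classify(sim$aln, sim$truth$hierarchy, 0.7)
  td <- tidy(res)
  expect_true(all(c("sequence_id", "cluster_id", "path", "score") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(gl$n_sequences, nrow(sim$aln))
  expect_equal(gl$n_classified + gl$n_unclassified, gl$n_sequences)
})
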