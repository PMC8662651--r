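write_toy_taxdump <- function(dir) {
  writeLines(c(
    "1\t|\t1\t|\tno rank\t|",
    "33208\t|\t1\t|\tkingdom\t|",
    "7711\t|\t33208\t|\tphylum\t|"
  ), file.path(dir, "nodes.dmp"))
  writeLines(c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "33208\t|\tMetazoa\t|\t\t|\tscientific name\t|",
    "33208\t|\tmetazoans\t|\t\t|\tblast name\t|",
    "7711\t|\tChordata\t|\t\t|\tscientific name\t|"
  ), file.path(dir, "names.dmp"))
  dir
}

test_that("parse_taxdump reads the dialect and keeps scientific names", {
  dir <- withr::local_tempdir()
  write_toy_taxdump(dir)
  tax <- parse_taxdump(file.path(dir, "nodes.dmp"),
                       file.path(dir, "names.dmp"))
  expect_equal(nrow(tax), 3L)
  expect_true(is.na(tax$parent_id[tax$tax_id == 1]))  # root self-parent
  expect_equal(tax$parent_id[tax$tax_id == 7711], 33208L)
  expect_equal(tax$name[tax$tax_id == 33208], "Metazoa")  # not "metazoans"
})

test_that("parse_taxdump flags missing names and malformed lines", {
  dir <- withr::local_tempdir()
  write_toy_taxdump(dir)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  expect_warning(tax <- parse_taxdump(file.path(dir, "nodes.dmp"),
                                      file.path(dir, "names.dmp")),
                 "without a scientific name")
  expect_true(is.na(tax$name[tax$tax_id == 7711]))

  writeLines(c("1\t|\t1\t|\tno rank\t|", "garbage line"),
             file.path(dir, "nodes.dmp"))
  expect_error(parse_taxdump(file.path(dir, "nodes.dmp"),
                             file.path(dir, "names.dmp")),
               "line 2")
})

test_that("the built-in taxonomy round-trips through taxdump files", {
  tax <- make_taxonomy()
  dir <- withr::local_tempdir()
  write_taxdump(tax, dir)
  back <- parse_taxdump(file.path(dir, "nodes.dmp"),
                        file.path(dir, "names.dmp"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tax))
})

test_that("lineage traces parent pointers root-first", {
  dir <- withr::local_tempdir()
  write_toy_taxdump(dir)
  tax <- parse_taxdump(file.path(dir, "nodes.dmp"),
                       file.path(dir, "names.dmp"))
  expect_equal(lineage(tax, 7711), c(1L, 33208L, 7711L))
  expect_equal(lineage(tax, 1), 1L)
  expect_error(lineage(tax, 999), "unknown")
})

test_that("lineage equals a brute-force descent oracle on random trees", {
  set.seed(55)
  n <- 50
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  tax <- tibble::new_tibble(
    tibble::tibble(tax_id = 1:n, parent_id = as.integer(parent),
                   rank = "no rank", name = sprintf("n%d", 1:n)),
    class = "kc_taxonomy")
  # oracle: recursive descent from the root, accumulating paths
  paths <- vector("list", n)
  paths[[1]] <- 1L
  descend <- function(node) {
    for (child in which(!is.na(parent) & parent == node)) {
      paths[[child]] <<- c(paths[[node]], child)
      descend(child)
    }
  }
  descend(1L)
  for (i in seq_len(n)) {
    expect_equal(lineage(tax, i), paths[[i]])
  }
})

test_that("lineage detects parent-pointer cycles", {
  tax <- tibble::new_tibble(
    tibble::tibble(tax_id = 1:3, parent_id = c(3L, 1L, 2L),
                   rank = "no rank", name = c("a", "b", "c")),
    class = "kc_taxonomy")
  expect_error(lineage(tax, 1), "cycle")
})

test_that("conservation reflects planted emergence points", {
  sim <- small_sim(seed = 8, n_per_leaf = 25)
  ht <- sim$truth$hierarchy
  res <- classify(sim$aln, ht, 0.7)
  targets <- c(3L, 4L, 7L, 9L, 11L, 13L)  # Holozoa .. Chordata clades
  cons <- conservation_matrix(res, sim$aln, sim$taxonomy, targets,
                              cutoff = 0.7)
  wide <- conservation_wide(cons)
  # S2.2 emerges at Chordata: detected there, absent from clades outside
  # the chordate lineage
  expect_true(wide["S2.2", "Chordata"])
  expect_false(wide["S2.2", "Porifera"])
  expect_false(wide["S2.2", "Cnidaria"])
  expect_false(wide["S2.2", "Protostomia"])
  expect_false(wide["S2.2", "Choanoflagellata"])
  # S1.1 emerges at Holozoa: its sequences span the whole tree
  expect_true(wide["S1.1", "Holozoa"])
})

test_that("relaxing the cut-off can only add detections", {
  sim <- small_sim(seed = 9, n_per_leaf = 20)
  res <- classify(sim$aln, sim$truth$hierarchy, 0.7)
  targets <- c(3L, 6L, 8L, 13L)
  strict <- conservation_wide(conservation_matrix(
    res, sim$aln, sim$taxonomy, targets, cutoff = 0.7))
  relaxed <- conservation_wide(conservation_matrix(
    res, sim$aln, sim$taxonomy, targets, cutoff = 0.6))
  expect_true(all(relaxed >= strict))
})

test_that("clusters without qualifying members give all-false rows", {
  fake <- structure(list(
    scores = tibble::tibble(sequence_id = c("a", "b"),
                            cluster_id = "C1", score = c(0.2, 0.3)),
    assignments = tibble::tibble(sequence_id = c("a", "b"),
                                 cluster_id = "unclassified",
                                 path = "unclassified", score = NA_real_),
    cutoff = 0.7), class = "kc_classification")
  aln <- toy_aln(c("AAAA", "CCCC"), ids = c("a", "b"))
  aln$organism_id <- c(115L, 116L)
  cons <- conservation_matrix(fake, aln, make_taxonomy(),
                              c(3L, 13L), cutoff = 0.7)
  expect_false(any(cons$detected))
})

test_that("sequences without organism ids are ignored with a message", {
  sim <- small_sim(seed = 9, n_per_leaf = 10)
  sim$aln$organism_id[1:5] <- NA
  res <- classify(sim$aln, sim$truth$hierarchy, 0.7)
  expect_message(conservation_matrix(res, sim$aln, sim$taxonomy, 3L),
                 "without organism id")
})

test_that("domain frequencies compress repeats and apply display cutoffs", {
  sim <- small_sim(seed = 10, n_per_leaf = 20)
  res <- classify(sim$aln, sim$truth$hierarchy, 0.7)
  memb <- cluster_members(res, "S1.1")
  ann <- dplyr::bind_rows(
    tibble::tibble(sequence_id = memb[1],
                   domain = c("IG", "IG", "IG", "KINASE"),
                   start = c(1L, 100L, 200L, 300L)),
    tibble::tibble(sequence_id = memb, domain = "KINASE", start = 300L),
    tibble::tibble(sequence_id = memb[1], domain = "RARE", start = 500L))
  freq <- domain_frequency(ann, res, min_fraction = 0.5)
  s11 <- freq[freq$cluster_id == "S1.1", ]
  # consecutive IG repeats collapse: one protein carries IG
  expect_equal(s11$n_with[s11$domain == "IG"], 1L)
  expect_equal(s11$frequency[s11$domain == "KINASE"], 1)
  expect_true(s11$displayed[s11$domain == "KINASE"])
  expect_false(s11$displayed[s11$domain == "IG"])
  # invariant to annotation row order
  freq2 <- domain_frequency(ann[sample(nrow(ann)), ], res,
                            min_fraction = 0.5)
  expect_equal(dplyr::arrange(freq, cluster_id, domain),
               dplyr::arrange(freq2, cluster_id, domain))
})

test_that("domain synonyms merge before counting", {
  sim <- small_sim(seed = 10, n_per_leaf = 10)
  res <- classify(sim$aln, sim$truth$hierarchy, 0.7)
  memb <- cluster_members(res, "S1.1")
  ann <- tibble::tibble(sequence_id = memb[1:2],
                        domain = c("SH3-like", "SH3"),
                        start = 1L)
  freq <- domain_frequency(ann, res, min_fraction = 0,
                           synonyms = c("SH3-like" = "SH3"))
  s11 <- freq[freq$cluster_id == "S1.1", ]
  expect_equal(s11$n_with[s11$domain == "SH3"], 2L)
  expect_false("SH3-like" %in% s11$domain)
})
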