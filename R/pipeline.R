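#' Sample representative sequences per cluster-taxon pair
#'
#' For phylogenetic follow-up, a taxonomically balanced representative set
#' is drawn: one member, uniformly at random, from every (cluster, target
#' taxon) pair that has members; occupied pairs only. User-supplied
#' special sets (e.g. all sequences of a reference organism, outgroup
#' sequences) are appended verbatim.
#'
#' @param result A `kc_classification`.
#' @param aln The classified alignment (provides organism ids).
#' @param tax A `kc_taxonomy`.
#' @param target_taxa Integer taxon ids.
#' @param special_ids Character vector of sequence ids appended verbatim.
#' @param seed Integer seed.
#' @return Tibble with `cluster_id`, `taxon_id`, `sequence_id`; appended
#'   special rows carry `cluster_id = "special"`.
#' @export
sample_representatives <- function(result, aln, tax, target_taxa,
                                   special_ids = character(0), seed = 0) {
  set.seed(seed)
  ox_of <- setNames(aln$organism_id, aln$sequence_id)
  descendants <- lapply(target_taxa, function(tx)
    taxon_descendants(tax, tx))
  names(descendants) <- as.character(target_taxa)
  clusters <- sort(unique(result$scores$cluster_id))

  rows <- list()
  for (cl in clusters) {
    memb <- cluster_members(result, cl)
    if (length(memb) == 0) next
    org <- ox_of[memb]
    for (tx in target_taxa) {
      pool <- memb[!is.na(org) & org %in% descendants[[as.character(tx)]]]
      if (length(pool) == 0) next
      pick <- if (length(pool) == 1) pool else sample(pool, 1)
      rows[[length(rows) + 1L]] <- tibble(cluster_id = cl,
                                          taxon_id = tx,
                                          sequence_id = pick)
    }
  }
  out <- bind_rows(rows)
  if (length(special_ids) > 0) {
    out <- bind_rows(out, tibble(cluster_id = "special",
                                 taxon_id = NA_integer_,
                                 sequence_id = special_ids))
  }
  out
}

#' Run the full analysis pipeline on the synthetic preset
#'
#' Simulate → infer → classify → similarity → conservation (at the
#' optimal and relaxed cut-offs) → introns → loops, writing every result
#' table to `out_dir`. All randomness derives from `seed`; rerunning with
#' the same configuration produces byte-identical data outputs (only
#' `run.log` carries a timestamp). Every TSV opens with a header comment
#' carrying a hash of the configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for simulation and inference.
#' @param sim_args Named list of overrides passed to [simulate_kinome()].
#' @param cfg A [kc_config()]; its seed is replaced by `seed`.
#' @param cutoff Classification cut-off. Default `cutoff_preset("optimal")`.
#' @param relaxed_cutoff Relaxed cut-off used for the second conservation
#'   matrix. Default `cutoff_preset("relaxed")`.
#' @param max_depth Hierarchy depth for inference.
#' @param target_taxa Taxa for the conservation matrix; defaults to all
#'   internal clades of the built-in taxonomy.
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(out_dir, seed = 0, sim_args = list(),
                         cfg = kc_config(), cutoff = cutoff_preset(),
                         relaxed_cutoff = cutoff_preset("relaxed"),
                         max_depth = 4, target_taxa = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg$seed <- as.integer(seed)
  config <- list(seed = seed, sim_args = sim_args,
                 cfg = unclass(cfg), cutoff = cutoff,
                 relaxed_cutoff = relaxed_cutoff, max_depth = max_depth)
  chash <- rlang::hash(config)
  log_lines <- c(sprintf("kinclust %s",
                         as.character(utils::packageVersion("kinclust"))),
                 sprintf("started: %s", format(Sys.time(), usetz = TRUE)),
                 sprintf("seed: %d", seed),
                 sprintf("config hash: %s", chash))

  sim <- do.call(simulate_kinome, c(list(seed = seed), sim_args))
  log_lines <- c(log_lines,
                 sprintf("simulate: %d sequences x %d columns",
                         nrow(sim$aln), n_columns(sim$aln)))

  h <- infer_hierarchy(sim$aln, cfg, max_depth = max_depth)
  write_model(h, file.path(out_dir, "model.json"))
  log_lines <- c(log_lines,
                 sprintf("infer: %d nodes, total LPR %.2f nats",
                         nrow(h), attr(h, "total_lpr")))

  res <- classify(sim$aln, h, cutoff = cutoff)
  write_result_tsv(res$scores, file.path(out_dir, "scores.tsv"), chash)
  write_result_tsv(res$assignments, file.path(out_dir, "assignments.tsv"),
                   chash)
  log_lines <- c(log_lines,
                 sprintf("classify: %d/%d classified at cutoff %.2f",
                         sum(res$assignments$cluster_id != "unclassified"),
                         nrow(res$assignments), cutoff))

  sim_mat <- similarity_matrix(res, h, sim$aln)
  write_result_tsv(tidy(sim_mat), file.path(out_dir, "similarity.tsv"),
                   chash)

  if (is.null(target_taxa)) {
    target_taxa <- sim$taxonomy$tax_id[sim$taxonomy$rank != "species" &
                                         sim$taxonomy$tax_id != 1L]
  }
  cons <- bind_rows(
    mutate(as_tibble(conservation_matrix(res, sim$aln, sim$taxonomy,
                                         target_taxa, cutoff = cutoff)),
           cutoff = cutoff),
    mutate(as_tibble(conservation_matrix(res, sim$aln, sim$taxonomy,
                                         target_taxa,
                                         cutoff = relaxed_cutoff)),
           cutoff = relaxed_cutoff)
  )
  write_result_tsv(cons, file.path(out_dir, "conservation.tsv"), chash)

  fam <- setNames(res$assignments$cluster_id, res$assignments$sequence_id)
  phases <- intron_phases(sim$exons)
  mapped <- map_intron_to_alignment(phases, sim$aln)
  shared <- shared_introns(mapped, fam)
  shared_out <- mutate(shared,
                       families = map_chr(.data$families, paste,
                                          collapse = ","))
  write_result_tsv(shared_out, file.path(out_dir, "introns.tsv"), chash)

  loops <- de_loop_lengths(sim$aln, fam)
  loops <- label_clades(loops, threshold = 10)
  write_result_tsv(loop_display(loops), file.path(out_dir, "loops.tsv"),
                   chash)
  log_lines <- c(log_lines,
                 sprintf("introns: %d shared groups; loops: %d families",
                         nrow(shared), nrow(loops)),
                 sprintf("finished: %s", format(Sys.time(), usetz = TRUE)))
  readr::write_lines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(sim = sim, hierarchy = h, classification = res,
                 similarity = sim_mat, conservation = cons,
                 shared_introns = shared, loops = loops,
                 out_dir = out_dir, config_hash = chash))
}

write_result_tsv <- function(df, path, chash) {
  readr::write_lines(sprintf("# kinclust config %s", chash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline result TSV (skipping the config header)
#' @param path Path written by [run_pipeline()].
#' @return A tibble.
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
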