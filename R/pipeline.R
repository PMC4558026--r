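#' Read a study configuration
#'
#' YAML with the sections used by [run_study()]: `inputs` (paths to
#' `freqs`, `meta`, `ibd_segments`, `genetic_map`, `individuals`,
#' `wordlists`), `groups` (named lists of population ids, plus `focal`,
#' `comparator_1`, `comparator_2`), and scalar settings (`amova_by`,
#' `permutations`, `mds_k`, `mds_restarts`, `collapse_years`, `lambda`,
#' `law`, `seed`, `outdir`).
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$inputs)) stop_input("config lacks an 'inputs' section")
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_input("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the six stages of the study graph on the configured inputs --
#' genetic and geographic distances, MDS, AMOVA, Mantel tests, IBD sharing,
#' and lexicostatistics -- writing one TSV (or Newick) per result plus a
#' JSON manifest recording seeds and parameters. Stages communicate only
#' through their declared files; a rerun with the same configuration and
#' seed is bit-identical for every deterministic stage.
#'
#' @param config a configuration list or a YAML path
#'   (see [read_study_config()]).
#' @return invisibly, a named list of the in-memory stage results; the
#'   manifest is written to `<outdir>/manifest.json`.
#' @export
run_study <- function(config) {
  cfg <- if (is.character(config)) read_study_config(config) else config
  inputs <- cfg$inputs
  outdir <- cfg$outdir %||% "study-results"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  perms <- cfg$permutations %||% 999
  seed <- cfg$seed %||% 1
  need_file <- function(stage, key) {
    p <- inputs[[key]]
    if (is.null(p) || !file.exists(p)) {
      stop_input("stage '%s' failed: missing input '%s' (%s)", stage, key,
                 if (is.null(p)) "not configured" else p)
    }
    p
  }
  results <- list()
  stages <- character()

  # -- distances ------------------------------------------------------
  stage <- "distances"
  tbl <- run_stage(stage, read_haplogroup_table(need_file(stage, "freqs"),
                                                need_file(stage, "meta")))
  d_gen <- run_stage(stage, nei_distance_matrix(tbl))
  d_geo <- run_stage(stage, haversine_matrix(tbl$meta))
  write_distance_matrix(d_gen, file.path(outdir, "nei_distances.tsv"))
  write_distance_matrix(d_geo, file.path(outdir, "geo_distances.tsv"))
  results$distances <- list(genetic = d_gen, geographic = d_geo)
  stages <- c(stages, stage)

  # -- mds ------------------------------------------------------------
  stage <- "mds"
  m <- run_stage(stage, mds_embed(d_gen, k = cfg$mds_k %||% 2,
                                  restarts = cfg$mds_restarts %||% 8,
                                  seed = derive_seed(seed, 11)))
  readr::write_tsv(m$coordinates, file.path(outdir, "mds_coordinates.tsv"))
  results$mds <- m
  stages <- c(stages, stage)

  # -- amova ----------------------------------------------------------
  stage <- "amova"
  by <- cfg$amova_by %||% "branch"
  am <- run_stage(stage, amova(tbl, groups = by, permutations = perms,
                               seed = derive_seed(seed, 23)))
  readr::write_tsv(tidy(am), file.path(outdir, "amova.tsv"))
  results$amova <- am
  stages <- c(stages, stage)

  # -- mantel ---------------------------------------------------------
  stage <- "mantel"
  mt <- run_stage(stage, mantel_test(d_gen, d_geo, permutations = perms,
                                     seed = derive_seed(seed, 31)))
  man_tbl <- tidy(mt)
  man_tbl$comparison <- "genetic~geographic"
  if (!is.null(inputs$lex_distances)) {
    d_lex <- run_stage(stage, read_distance_matrix(need_file(stage, "lex_distances")))
    mt2 <- run_stage(stage, mantel_test(d_gen, d_lex, permutations = perms,
                                        seed = derive_seed(seed, 32)))
    t2 <- tidy(mt2); t2$comparison <- "genetic~linguistic"
    pm <- run_stage(stage, partial_mantel_test(d_gen, d_lex, d_geo,
                                               permutations = perms,
                                               seed = derive_seed(seed, 33)))
    t3 <- tidy(pm); t3$comparison <- "genetic~linguistic|geographic"
    man_tbl <- dplyr::bind_rows(man_tbl, t2, t3)
  }
  readr::write_tsv(man_tbl, file.path(outdir, "mantel.tsv"))
  results$mantel <- man_tbl
  stages <- c(stages, stage)

  # -- ibd -------------------------------------------------------------
  stage <- "ibd"
  segs <- run_stage(stage, read_ibd_segments(
    need_file(stage, "ibd_segments"), need_file(stage, "genetic_map"),
    individuals_path = need_file(stage, "individuals"),
    min_cM = cfg$min_cM %||% 1
  ))
  groups <- lapply(cfg$groups$comparators, unlist)
  focal <- unlist(cfg$groups$focal)
  prof <- run_stage(stage, sharing_profile_table(segs, groups, focal,
                                                 focal_name = "focal"))
  readr::write_tsv(prof, file.path(outdir, "ibd_profiles.tsv"))
  results$ibd <- prof
  if (!is.null(cfg$groups$comparator_1) && !is.null(cfg$groups$comparator_2)) {
    cmpr <- run_stage(stage, compare_sharing(
      segs, focal, unlist(cfg$groups$comparator_1), unlist(cfg$groups$comparator_2),
      permutations = perms, seed = derive_seed(seed, 41)
    ))
    readr::write_tsv(glance(cmpr), file.path(outdir, "ibd_comparison.tsv"))
    results$ibd_comparison <- cmpr
  }
  stages <- c(stages, stage)

  # -- lex -------------------------------------------------------------
  stage <- "lex"
  w <- run_stage(stage, read_wordlist(need_file(stage, "wordlists")))
  d_lx <- run_stage(stage, lex_distance_matrix(w))
  write_distance_matrix(d_lx, file.path(outdir, "lex_distances.tsv"))
  tr <- run_stage(stage, starling_nj(w, lambda = cfg$lambda %||% 0.05,
                                     law = cfg$law %||% "starostin",
                                     exclude = unlist(cfg$lex_exclude)))
  tr <- run_stage(stage, collapse_consensus(tr, cfg$collapse_years %||% 300))
  write_newick(tr, file.path(outdir, "lex_tree.nwk"))
  results$lex <- tr
  stages <- c(stages, stage)

  manifest <- list(
    package = "slavstrata",
    version = as.character(utils::packageVersion("slavstrata")),
    stages = stages,
    seed = seed,
    permutations = perms,
    parameters = list(
      amova_by = by, mds_k = cfg$mds_k %||% 2,
      mds_restarts = cfg$mds_restarts %||% 8, min_cM = cfg$min_cM %||% 1,
      lambda = cfg$lambda %||% 0.05, law = cfg$law %||% "starostin",
      collapse_years = cfg$collapse_years %||% 300
    ),
    inputs = inputs
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Stages of the study pipeline
#'
#' The pipeline covers exactly the haplogroup-frequency, ordination, AMOVA,
#' matrix-correlation, IBD-sharing and lexicostatistics stages. Raw-genotype
#' analyses (autosomal PCA, ADMIXTURE ancestry modelling, F_ST from SNP
#' genotypes) and IBD segment *detection* are out of scope by design: the
#' package consumes detector output, it does not re-detect.
#'
#' @return character vector of stage names, in execution order.
#' @export
study_stages <- function() {
  c("distances", "mds", "amova", "mantel", "ibd", "lex")
}
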