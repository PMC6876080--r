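# End-to-end orchestration: ontologies -> similarity -> retention ->
# feature matrix -> bagged LR/GD ensemble -> vote report, with a
# manifest sufficient to reproduce any run bit for bit.

#' Run the full disease-related-protein identification pipeline
#'
#' Stages: load and filter the disease-protein associations; parse the
#' disease and gene ontologies and compute information content; score
#' every disease against the target with the five similarity measures;
#' retain diseases at or above the similarity threshold; build the binary
#' feature matrix labelled with normalized similarities; run the bagged
#' logistic-regression / gradient-descent ensemble; select proteins by
#' vote threshold and report the known-versus-novel split.
#'
#' @param associations Path to the disease-protein TSV
#'   (`disease_id`, `protein_accession`).
#' @param do_obo,go_obo Paths to the disease- and gene-ontology OBO files.
#' @param go_annotations Path to the gene-to-GO-term annotation TSV.
#' @param target_id Target disease id (must appear in the associations).
#' @param seed_proteins Character vector of known target-related protein
#'   accessions, or the path of a one-per-line file.
#' @param out_dir Output directory.
#' @param funnet_path Optional functional-association TSV for the
#'   SemFunSim surrogate.
#' @param do_annotations Optional entity-to-disease-term TSV used for
#'   disease-ontology information content; when absent the association
#'   table itself is used as the corpus.
#' @param sim_threshold Similarity retention threshold (default 3.5).
#' @param vote_threshold Vote-count selection threshold (default 7).
#' @param n_rounds Ensemble rounds (default 400).
#' @param bag_size Features per bag (default `round(sqrt(p))`).
#' @param ridge Ridge penalty of the per-bag fits (default 1).
#' @param gd_step,gd_tol,gd_max_iter Gradient-descent controls.
#' @param rng_seed Master seed (default 1).
#' @param min_proteins,max_proteins,drop_ids Disease exclusion rules
#'   (defaults 1, 2000, none).
#' @param include_target Keep the target as a training row with its own
#'   normalized self-similarity label (default `TRUE`).
#' @return Invisibly, a list with the similarity table, retained disease
#'   ids, the `feature_matrix`, the `vote_tally`, the selected
#'   accessions, the known/novel split and all output paths.
#' @export
run_pipeline <- function(associations, do_obo, go_obo, go_annotations,
                         target_id, seed_proteins, out_dir,
                         funnet_path = NULL, do_annotations = NULL,
                         sim_threshold = 3.5, vote_threshold = 7,
                         n_rounds = 400, bag_size = NULL, ridge = 1,
                         gd_step = 0.1, gd_tol = 1e-3, gd_max_iter = 10000,
                         rng_seed = 1, min_proteins = 1,
                         max_proteins = 2000, drop_ids = character(),
                         include_target = TRUE) {
  t0 <- Sys.time()
  stage <- function(...) message(sprintf("[%5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (length(seed_proteins) == 1 && file.exists(seed_proteins))
    seed_proteins <- readLines(seed_proteins, warn = FALSE)
  seed_proteins <- seed_proteins[nzchar(seed_proteins)]

  stage("loading associations")
  tab <- load_associations(associations)
  tab <- exclude_diseases(tab, min_proteins = min_proteins,
                          max_proteins = max_proteins, drop_ids = drop_ids)
  if (!target_id %in% tab$diseases)
    stop("stage associations: target disease ", target_id,
         " absent after exclusion filtering")

  stage("parsing ontologies")
  dag_do <- parse_obo(do_obo)
  dag_go <- parse_obo(go_obo)
  go_ann <- read_annotations(go_annotations, dag = dag_go)
  do_ann <- if (!is.null(do_annotations)) {
    read_annotations(do_annotations, dag = dag_do)
  } else {
    annotation_corpus(tab$rows$protein_accession, tab$rows$disease_id,
                      dag = dag_do)
  }
  ic_go <- information_content(dag_go, go_ann)
  ic_do <- information_content(dag_do, do_ann)
  fn <- if (!is.null(funnet_path)) read_funnet(funnet_path) else NULL
  resources <- list(dag_do = dag_do, ic_do = ic_do, dag_go = dag_go,
                    ic_go = ic_go, funnet = fn)

  stage("computing disease similarities")
  genes_of <- split(tab$rows$protein_accession, tab$rows$disease_id)
  profiles <- lapply(tab$diseases, function(d)
    disease_profile(d, genes_of[[d]], go_annotations = go_ann))
  names(profiles) <- tab$diseases
  target_profile <- profiles[[target_id]]
  sim <- similarity_table(target_profile, profiles, resources)
  sim_path <- file.path(out_dir, "similarity.tsv")
  utils::write.table(sim, sim_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  retained <- filter_by_threshold(sim, sim_threshold)
  if (include_target) retained <- union(retained, target_id)
  others <- setdiff(retained, target_id)
  if (!length(others))
    stop("stage similarity: no diseases retained at threshold ",
         sim_threshold)
  writeLines(retained, file.path(out_dir, "retained_diseases.txt"))
  stage(length(retained), " diseases retained")

  stage("building feature matrix")
  keep <- tab$rows$disease_id %in% retained
  sub <- association_table(tab$rows$disease_id[keep],
                           tab$rows$protein_accession[keep])
  labels <- stats::setNames(sim$normalized, sim$disease_id)
  fm <- build_feature_matrix(sub, labels)
  fm_path <- file.path(out_dir, "feature_matrix.tsv")
  write_feature_matrix(fm, fm_path, file.path(out_dir, "labels.tsv"))

  stage("running ensemble (", n_rounds, " rounds)")
  tally <- run_ensemble(fm, target_id, seed_proteins = seed_proteins,
                        n_rounds = n_rounds, bag_size = bag_size,
                        rng_seed = rng_seed, ridge = ridge,
                        gd_step = gd_step, gd_tol = gd_tol,
                        gd_max_iter = gd_max_iter)
  selected <- select_related(tally, vote_threshold)
  known <- intersect(selected, seed_proteins)
  novel <- setdiff(selected, seed_proteins)

  votes <- data.frame(
    protein_accession = tally$protein_accession,
    times_selected = tally$times_selected,
    times_called_related = tally$times_called_related,
    called_fraction = ifelse(tally$times_selected > 0,
                             tally$times_called_related /
                               tally$times_selected, 0),
    is_seed = tally$protein_accession %in% seed_proteins,
    selected_flag = tally$protein_accession %in% selected,
    stringsAsFactors = FALSE)
  votes_path <- file.path(out_dir, "votes.tsv")
  utils::write.table(votes, votes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(selected, file.path(out_dir, "selected_proteins.txt"))

  report <- pipeline_report(votes_path, seed_proteins)
  writeLines(report, file.path(out_dir, "report.txt"))

  manifest <- list(
    target_id = target_id, rng_seed = rng_seed, n_rounds = n_rounds,
    bag_size = attr(tally, "bag_size"), ridge = ridge,
    gd_step = gd_step, gd_tol = gd_tol, gd_max_iter = gd_max_iter,
    sim_threshold = sim_threshold, vote_threshold = vote_threshold,
    min_proteins = min_proteins, max_proteins = max_proteins,
    drop_ids = drop_ids, include_target = include_target,
    n_diseases_retained = length(retained),
    n_proteins = length(fm$protein_index),
    n_selected = length(selected), n_known = length(known),
    n_novel = length(novel),
    failed_rounds = attr(tally, "failed_rounds"),
    inputs = list(associations = associations, do_obo = do_obo,
                  go_obo = go_obo, go_annotations = go_annotations,
                  funnet = funnet_path, do_annotations = do_annotations))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage("done: ", length(selected), " proteins selected (",
        length(novel), " novel)")

  invisible(list(similarity = sim, retained = retained,
                 feature_matrix = fm, tally = tally, selected = selected,
                 known = known, novel = novel, out_dir = out_dir,
                 paths = list(similarity = sim_path, votes = votes_path,
                              manifest = file.path(out_dir,
                                                   "manifest.json"))))
}

#' Summarize a votes table
#'
#' Prints the number of proteins selected, the known-versus-novel split
#' among them (relative to a known/seed protein list) and a text
#' histogram of vote counts over all proteins selected at least once.
#'
#' @param votes A votes TSV path (as written by [run_pipeline()]) or a
#'   `vote_tally`.
#' @param known_proteins Character vector (or one-per-line file path) of
#'   known related proteins.
#' @param vote_threshold Selection threshold used for the summary
#'   (default 7).
#' @return Character vector of report lines (invisibly; also printed).
#' @export
pipeline_report <- function(votes, known_proteins = character(),
                            vote_threshold = 7) {
  if (is.character(votes)) votes <- utils::read.delim(votes,
                                                      stringsAsFactors = FALSE)
  if (length(known_proteins) == 1 && file.exists(known_proteins))
    known_proteins <- readLines(known_proteins, warn = FALSE)

  if ("selected_flag" %in% names(votes)) {
    selected <- votes$protein_accession[votes$selected_flag]
  } else {
    selected <- select_related(votes, vote_threshold)
  }
  n_sel <- length(selected)
  n_known <- length(intersect(selected, known_proteins))
  n_novel <- n_sel - n_known
  pct_known <- if (n_sel > 0) round(known_fraction(n_sel, n_novel)) else 0

  ever <- votes[votes$times_selected > 0, , drop = FALSE]
  lines <- c(
    sprintf("proteins selected at least once : %d", nrow(ever)),
    sprintf("proteins called related (>= threshold): %d", n_sel),
    sprintf("known among selected            : %d (%d%%)", n_known,
            pct_known),
    sprintf("novel among selected            : %d", n_novel),
    "vote-count histogram (calls: proteins):")
  if (nrow(ever)) {
    counts <- base::table(ever$times_called_related)
    bar <- vapply(as.integer(counts), function(n)
      paste(rep("#", min(n, 60)), collapse = ""), character(1))
    lines <- c(lines, sprintf("  %3s : %4d %s", names(counts),
                              as.integer(counts), bar))
  } else {
    lines <- c(lines, "  (no proteins were ever selected)")
  }
  writeLines(lines)
  invisible(lines)
}
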