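# Seeded synthetic fixtures: toy ontologies, annotations, functional
# association weights and disease-protein tables with a planted set of
# truly related proteins shared preferentially by diseases designed to be
# similar to the target. Everything is a pure function of the spec and
# its seed, so every pipeline stage is testable without downloads.

#' Specification of a synthetic fixture
#'
#' @param n_diseases Number of diseases including the target (default 30).
#' @param n_proteins Protein pool size (default 300).
#' @param planted_proteins Number of truly target-related proteins
#'   (default 10).
#' @param overlap_decay Geometric decay of designed closeness with a
#'   disease's similarity rank: the rank-r disease includes each planted
#'   protein with probability `overlap_decay^r` (default 0.85, a graded
#'   spectrum with a few close and many distant diseases).
#' @param background_rate Inclusion probability of any background protein
#'   in any disease (default 0.05, keeping the association table sparse).
#' @param n_go_terms Size of the toy gene-ontology DAG (default 40).
#' @param seed_fraction Fraction of the planted set exposed as "known"
#'   seed proteins (default 0.4; a strict subset so recovery is
#'   nontrivial).
#' @param rng_seed Master seed (default 42).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_diseases = 30, n_proteins = 300,
                         planted_proteins = 10, overlap_decay = 0.85,
                         background_rate = 0.05, n_go_terms = 40,
                         seed_fraction = 0.4, rng_seed = 42) {
  if (planted_proteins > n_proteins)
    stop("planted_proteins cannot exceed n_proteins")
  if (min(n_diseases, n_proteins, planted_proteins, n_go_terms) < 1)
    stop("all counts must be >= 1")
  if (overlap_decay <= 0 || overlap_decay > 1)
    stop("overlap_decay must lie in (0, 1]")
  structure(list(n_diseases = n_diseases, n_proteins = n_proteins,
                 planted_proteins = planted_proteins,
                 overlap_decay = overlap_decay,
                 background_rate = background_rate,
                 n_go_terms = n_go_terms, seed_fraction = seed_fraction,
                 rng_seed = rng_seed),
            class = "fixture_spec")
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate a random rooted DAG as OBO 1.2 text
#'
#' Term 1 is the single root; every later term gets one `is_a` parent
#' among earlier terms and, with probability `p_second_parent`, a second
#' parent (`is_a` or `part_of`). Byte-identical output per seed.
#'
#' @param n_terms Number of terms (>= 2).
#' @param rng_seed Seed.
#' @param prefix Accession prefix (default "SYNGO").
#' @param namespace Namespace string written for every term.
#' @param p_second_parent Probability of a second parent (default 0.25).
#' @param chain If `TRUE`, emit a simple root-to-leaf chain instead of a
#'   random DAG (used for the disease ontology ladder).
#' @return Character scalar of OBO text.
#' @export
generate_ontology <- function(n_terms, rng_seed = 42, prefix = "SYNGO",
                              namespace = "biological_process",
                              p_second_parent = 0.25, chain = FALSE) {
  if (n_terms < 2) stop("n_terms must be >= 2")
  .with_seed(rng_seed, {
    tid <- function(i) sprintf("%s:%07d", prefix, i)
    out <- c("format-version: 1.2", "")
    for (i in seq_len(n_terms)) {
      stanza <- c("[Term]",
                  paste0("id: ", tid(i)),
                  paste0("name: synthetic term ", i),
                  paste0("namespace: ", namespace))
      if (i > 1) {
        p1 <- if (chain) i - 1L else sample.int(i - 1L, 1L)
        stanza <- c(stanza, paste0("is_a: ", tid(p1)))
        if (!chain && i > 2 && stats::runif(1) < p_second_parent) {
          p2 <- sample(setdiff(seq_len(i - 1L), p1), 1L)
          if (stats::runif(1) < 0.7) {
            stanza <- c(stanza, paste0("is_a: ", tid(p2)))
          } else {
            stanza <- c(stanza, paste0("relationship: part_of ", tid(p2)))
          }
        }
      }
      out <- c(out, stanza, "")
    }
    paste(out, collapse = "\n")
  })
}

# Disease identifiers: the target sits at the bottom of a disease-ontology
# chain; the rank-r disease sits r steps above it, so ontology depth and
# designed closeness agree.
.fixture_disease_ids <- function(spec) {
  n <- spec$n_diseases
  ids <- sprintf("SYNDO:%07d", seq_len(n + 1L))  # ids[1] is the root
  list(root = ids[[1]],
       # rank 0 (target) is the deepest term, rank r is r steps up
       by_rank = rev(ids[-1]))
}

.fixture_proteins <- function(spec) sprintf("P%05d", seq_len(spec$n_proteins))

#' Generate the disease-protein association table with planted signal
#'
#' The target disease's row is exactly the planted set (a disease's
#' curated association row is its known related-protein list, so the
#' target's row defines the ground truth); the rank-r disease includes
#' each planted protein with probability `overlap_decay^r` and each
#' background protein at the base rate. The heavy cross-disease sharing
#' this produces mirrors the redundancy regime of curated
#' disease-protein tables.
#'
#' @param spec A `fixture_spec`.
#' @return List with `associations` (a `disease_protein_table`),
#'   `planted` (ground-truth accessions), `ranking` (data.frame
#'   `disease_id`, `rank`, `closeness`, target first) and `target_id`.
#' @export
generate_disease_protein_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$rng_seed + 1L, {
    ids <- .fixture_disease_ids(spec)
    proteins <- .fixture_proteins(spec)
    planted <- sort(sample(proteins, spec$planted_proteins))
    background <- setdiff(proteins, planted)
    target <- ids$by_rank[[1]]

    rows_d <- character(); rows_p <- character()
    add <- function(d, ps) {
      if (length(ps)) {
        rows_d <<- c(rows_d, rep(d, length(ps)))
        rows_p <<- c(rows_p, ps)
      }
    }
    closeness <- numeric(spec$n_diseases)
    closeness[[1]] <- 1
    add(target, planted)
    for (r in seq_len(spec$n_diseases - 1L)) {
      d <- ids$by_rank[[r + 1L]]
      c_d <- spec$overlap_decay^r
      closeness[[r + 1L]] <- c_d
      add(d, planted[stats::runif(length(planted)) < c_d])
      add(d, background[stats::runif(length(background)) <
                          spec$background_rate])
      if (!any(rows_d == d)) add(d, sample(background, 1L))
    }
    list(associations = association_table(rows_d, rows_p),
         planted = planted,
         ranking = data.frame(disease_id = ids$by_rank,
                              rank = seq_len(spec$n_diseases) - 1L,
                              closeness = closeness,
                              stringsAsFactors = FALSE),
         target_id = target)
  })
}

#' Generate the fixture's ontologies, annotations and functional network
#'
#' Builds the disease-ontology chain and a random GO-like DAG, annotates
#' proteins to GO terms (planted proteins share a small module of terms
#' so closely designed diseases also share annotation signal), derives
#' the disease-ontology annotation corpus from the association table, and
#' assigns functional-association weights that are high inside the
#' planted neighbourhood and low elsewhere.
#'
#' @param spec A `fixture_spec`.
#' @param table Output of [generate_disease_protein_table()] for `spec`.
#' @return List with `do_obo`, `go_obo` (OBO text), `go_annotations`,
#'   `do_annotations` (`annotation_corpus`), `funnet` (a `funnet`).
#' @export
generate_annotations_and_funnet <- function(spec, table) {
  stopifnot(inherits(spec, "fixture_spec"))
  do_obo <- generate_ontology(spec$n_diseases + 1L,
                              rng_seed = spec$rng_seed + 2L,
                              prefix = "SYNDO", namespace = "disease",
                              chain = TRUE)
  go_obo <- generate_ontology(spec$n_go_terms,
                              rng_seed = spec$rng_seed + 3L,
                              prefix = "SYNGO",
                              namespace = "biological_process")
  .with_seed(spec$rng_seed + 4L, {
    proteins <- .fixture_proteins(spec)
    planted <- table$planted
    go_ids <- sprintf("SYNGO:%07d", seq_len(spec$n_go_terms))
    # later-generated terms sit deeper on average; use the last quarter
    # as the planted module's annotation targets
    module_terms <- utils::tail(go_ids, max(3L, spec$n_go_terms %/% 8L))
    ann_e <- character(); ann_t <- character()
    for (p in proteins) {
      k <- sample(1:3, 1L)
      pool <- if (p %in% planted) module_terms else go_ids[-1]
      ts <- sample(pool, min(k, length(pool)))
      ann_e <- c(ann_e, rep(p, length(ts)))
      ann_t <- c(ann_t, ts)
    }
    go_ann <- annotation_corpus(ann_e, ann_t)
    do_ann <- annotation_corpus(table$associations$rows$protein_accession,
                                table$associations$rows$disease_id)
    # funnet: strong ties inside the planted neighbourhood, weak random
    # background ties
    fa <- character(); fb <- character(); fw <- numeric()
    if (length(planted) > 1) {
      pairs <- utils::combn(planted, 2)
      fa <- pairs[1, ]; fb <- pairs[2, ]
      fw <- stats::runif(ncol(pairs), 0.6, 0.9)
    }
    n_bg <- 2L * spec$n_proteins
    ba <- sample(proteins, n_bg, replace = TRUE)
    bb <- sample(proteins, n_bg, replace = TRUE)
    ok <- ba != bb
    fa <- c(fa, ba[ok]); fb <- c(fb, bb[ok])
    fw <- c(fw, stats::runif(sum(ok), 0, 0.3))
    list(do_obo = do_obo, go_obo = go_obo, go_annotations = go_ann,
         do_annotations = do_ann, funnet = funnet(fa, fb, fw))
  })
}

.write_corpus <- function(corpus, path) {
  utils::write.table(
    data.frame(entity_id = corpus$pairs$entity_id,
               term_id = corpus$pairs$term_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete runnable fixture directory
#'
#' Emits the disease and gene ontologies (OBO), the annotation tables,
#' the functional-association weights, the disease-protein association
#' table, the ground-truth planted set, the designed similarity ranking,
#' and a seed-protein list that is a strict subset of the planted set
#' (emulating partially known disease proteins).
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A `fixture_spec`; `rng_seed` may be overridden.
#' @param rng_seed Optional seed override.
#' @return Invisibly, a `fixture_bundle`: list with `paths` (named file
#'   paths), `target_id`, `planted` (ground truth), `seed_proteins`,
#'   `ranking` (designed closeness) and `spec`.
#' @export
end_to_end_fixture <- function(out_dir, spec = fixture_spec(),
                               rng_seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(rng_seed)) spec$rng_seed <- rng_seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- generate_disease_protein_table(spec)
  res <- generate_annotations_and_funnet(spec, table)

  paths <- list(
    do_obo = file.path(out_dir, "do.obo"),
    go_obo = file.path(out_dir, "go.obo"),
    go_annotations = file.path(out_dir, "go_annotations.tsv"),
    do_annotations = file.path(out_dir, "do_annotations.tsv"),
    funnet = file.path(out_dir, "funnet.tsv"),
    associations = file.path(out_dir, "associations.tsv"),
    seed_proteins = file.path(out_dir, "seed_proteins.txt"),
    planted = file.path(out_dir, "truth_planted.txt"),
    ranking = file.path(out_dir, "designed_ranking.tsv"))

  writeLines(res$do_obo, paths$do_obo)
  writeLines(res$go_obo, paths$go_obo)
  .write_corpus(res$go_annotations, paths$go_annotations)
  .write_corpus(res$do_annotations, paths$do_annotations)

  env <- res$funnet$env
  keys <- sort(ls(env))
  kk <- strsplit(keys, "\r", fixed = TRUE)
  utils::write.table(
    data.frame(gene_a = vapply(kk, `[[`, "", 1),
               gene_b = vapply(kk, `[[`, "", 2),
               weight = vapply(keys, function(k) get(k, envir = env),
                               numeric(1))),
    paths$funnet, sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(table$associations$rows, paths$associations,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  n_seed <- max(1L, floor(spec$seed_fraction * length(table$planted)))
  n_seed <- min(n_seed, length(table$planted) - 1L)  # strict subset
  seeds <- .with_seed(spec$rng_seed + 5L,
                      sort(sample(table$planted, max(n_seed, 1L))))
  writeLines(seeds, paths$seed_proteins)
  writeLines(table$planted, paths$planted)
  utils::write.table(table$ranking, paths$ranking, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(structure(list(paths = paths,
                           target_id = table$target_id,
                           planted = table$planted,
                           seed_proteins = seeds,
                           ranking = table$ranking, spec = spec,
                           out_dir = out_dir),
                      class = "fixture_bundle"))
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("fixture_bundle in", x$out_dir, "- target", x$target_id, "with",
      length(x$planted), "planted proteins\n")
  invisible(x)
}
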