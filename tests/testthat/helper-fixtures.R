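# Shared fixtures and independent oracles built in code.

# Write OBO text to a temp file and return the path.
write_obo <- function(text) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

obo_stanza <- function(id, name = id, namespace = "test",
                       is_a = character(), relationship = character(),
                       obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("namespace: ", namespace),
    if (length(is_a)) paste0("is_a: ", is_a),
    if (length(relationship)) paste0("relationship: ", relationship),
    if (obsolete) "is_obsolete: true",
    "")
}

# Three-term chain root <- A <- B with 4/2/1 annotated entities:
# IC(root)=0, IC(A)=ln 2, IC(B)=ln 4.
chain_fixture <- function(envir = parent.frame()) {
  txt <- c("format-version: 1.2", "",
           obo_stanza("T:root"),
           obo_stanza("T:A", is_a = "T:root"),
           obo_stanza("T:B", is_a = "T:A"))
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = envir)
  writeLines(txt, path)
  dag <- parse_obo(path)
  corpus <- annotation_corpus(
    entity_id = c("g1", "g2", "g3", "g4", "g2", "g3", "g3"),
    term_id = c("T:root", "T:root", "T:root", "T:root",
                "T:A", "T:A", "T:B"))
  list(dag = dag, corpus = corpus,
       ic = information_content(dag, corpus))
}

# A random annotated DAG built from the package generator (round-trips
# the generator) with a dense random annotation corpus.
random_annotated_dag <- function(n_terms = 50, n_entities = 40,
                                 seed = 1, envir = parent.frame()) {
  txt <- generate_ontology(n_terms, rng_seed = seed, prefix = "R",
                           namespace = "test")
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = envir)
  writeLines(txt, path)
  dag <- parse_obo(path)
  set.seed(seed + 1000)
  ids <- names(dag$terms)
  ent <- sprintf("e%03d", seq_len(n_entities))
  corpus <- annotation_corpus(
    entity_id = sample(ent, 3 * n_entities, replace = TRUE),
    term_id = sample(ids, 3 * n_entities, replace = TRUE))
  list(dag = dag, corpus = corpus,
       ic = information_content(dag, corpus))
}

# Independent oracle: ancestor closure by iterative BFS over raw parent
# links (is_a / part_of only), no recursion, no memoization.
brute_ancestors <- function(dag, term) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- character()
    for (t in frontier) {
      p <- dag$terms[[t]]$parents
      nxt <- c(nxt, p$parent[p$relation %in% c("is_a", "part_of")])
    }
    frontier <- setdiff(unique(nxt), seen)
  }
  seen
}

# Independent oracle: MICA by exhaustive enumeration of common
# ancestors, lexicographic tie-break, common-root fallback.
brute_mica <- function(dag, ic, t1, t2) {
  common <- intersect(brute_ancestors(dag, t1), brute_ancestors(dag, t2))
  vals <- vapply(common, function(t) {
    v <- ic$ic[[t]]
    if (is.null(v) || is.na(v)) 0 else v
  }, numeric(1))
  if (!length(common)) return(list(term = NA_character_, ic = 0))
  if (max(vals) <= 0) {
    roots <- intersect(common, dag$roots)
    pick <- if (length(roots)) sort(roots)[[1]] else sort(common)[[1]]
    return(list(term = pick, ic = 0))
  }
  best <- common[vals == max(vals)]
  list(term = sort(best)[[1]], ic = max(vals))
}

# Independent oracle: Wang S-values by naive unmemoized recursion over
# parent links.
naive_wang_svalue <- function(dag, a, t, decay) {
  if (identical(t, a)) return(1)
  anc <- brute_ancestors(dag, a)
  ch <- dag$children[[t]]
  ch <- ch[ch$child %in% anc, , drop = FALSE]
  if (!nrow(ch)) return(NA_real_)
  max(vapply(seq_len(nrow(ch)), function(k)
    decay[[ch$relation[[k]]]] *
      naive_wang_svalue(dag, a, ch$child[[k]], decay), numeric(1)))
}

naive_wang <- function(dag, t1, t2, decay = c(is_a = 0.8, part_of = 0.6)) {
  a1 <- brute_ancestors(dag, t1)
  a2 <- brute_ancestors(dag, t2)
  s1 <- vapply(a1, function(t) naive_wang_svalue(dag, t1, t, decay),
               numeric(1))
  s2 <- vapply(a2, function(t) naive_wang_svalue(dag, t2, t, decay),
               numeric(1))
  shared <- intersect(a1, a2)
  if (!length(shared)) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

# A pair of resources/profiles where every one of the five measures
# attains its maximum on the self pair: one informative DO term and one
# informative BP GO term, each with IC equal to its ontology's maximum.
maximal_similarity_fixture <- function(envir = parent.frame()) {
  do_txt <- c("format-version: 1.2", "",
              obo_stanza("D:root", namespace = "disease"),
              obo_stanza("D:1", namespace = "disease", is_a = "D:root"))
  go_txt <- c("format-version: 1.2", "",
              obo_stanza("G:root", namespace = "biological_process"),
              obo_stanza("G:1", namespace = "biological_process",
                         is_a = "G:root"))
  do_path <- withr::local_tempfile(fileext = ".obo", .local_envir = envir)
  go_path <- withr::local_tempfile(fileext = ".obo", .local_envir = envir)
  writeLines(do_txt, do_path)
  writeLines(go_txt, go_path)
  dag_do <- parse_obo(do_path)
  dag_go <- parse_obo(go_path)
  ic_do <- information_content(dag_do, annotation_corpus(
    c("g1", "g2"), c("D:1", "D:root")))
  go_ann <- annotation_corpus(c("g1", "g2"), c("G:1", "G:root"))
  ic_go <- information_content(dag_go, go_ann)
  prof <- disease_profile("D:1", genes = "g1", go_annotations = go_ann)
  list(resources = list(dag_do = dag_do, ic_do = ic_do,
                        dag_go = dag_go, ic_go = ic_go, funnet = NULL),
       profile = prof)
}

# Cached default fixture bundle (generated once per test run).
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- end_to_end_fixture(tempfile("fixture"), fixture_spec())
    }
    cache
  }
})

# Cached full pipeline run on the default fixture at the study
# conditions: 400 rounds, retention threshold 1.5 (the cut separating
# the designed closeness ladder from the flat tail of this fixture's
# similarity distribution), vote threshold 7. Computed once, reused by
# the ensemble property tests and the acceptance suite.
default_pipeline_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- default_bundle()
      cache <<- suppressWarnings(suppressMessages(run_pipeline(
        associations = b$paths$associations,
        do_obo = b$paths$do_obo, go_obo = b$paths$go_obo,
        go_annotations = b$paths$go_annotations,
        do_annotations = b$paths$do_annotations,
        funnet_path = b$paths$funnet,
        target_id = b$target_id,
        seed_proteins = b$paths$seed_proteins,
        out_dir = tempfile("run"), rng_seed = 1, n_rounds = 400,
        sim_threshold = 1.5, vote_threshold = 7)))
    }
    cache
  }
})
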