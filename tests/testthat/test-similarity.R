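test_that("Resnik scaling and Lin ratio follow the IC of the MICA", {
  fx <- chain_fixture()  # IC: root 0, A ln2, B ln4 (= ic_max)
  expect_equal(sim_resnik(fx$dag, fx$ic, "T:B", "T:B"), 4)
  # MICA(A, B) = A with IC exactly half of ic_max
  expect_equal(sim_resnik(fx$dag, fx$ic, "T:A", "T:B"), 2)
  expect_equal(sim_lin(fx$dag, fx$ic, "T:A", "T:A"), 1)
  expect_equal(sim_lin(fx$dag, fx$ic, "T:A", "T:B"),
               2 * log(2) / (log(2) + log(4)))
  expect_equal(sim_lin(fx$dag, fx$ic, "T:A", "T:B"), 2 / 3)

  sib <- write_obo(c("format-version: 1.2", "",
                     obo_stanza("T:r"),
                     obo_stanza("T:a", is_a = "T:r"),
                     obo_stanza("T:b", is_a = "T:r")))
  dag <- parse_obo(sib)
  ic <- information_content(dag, annotation_corpus(
    c("g1", "g2"), c("T:a", "T:b")))
  expect_equal(sim_resnik(dag, ic, "T:a", "T:b"), 0)
  expect_equal(sim_lin(dag, ic, "T:a", "T:b"), 0)
})

test_that("Wang similarity matches hand computation and the naive oracle", {
  sib <- write_obo(c("format-version: 1.2", "",
                     obo_stanza("T:r"),
                     obo_stanza("T:a", is_a = "T:r"),
                     obo_stanza("T:b", is_a = "T:r")))
  dag <- parse_obo(sib)
  expect_equal(sim_wang(dag, "T:a", "T:a"), 1)
  # SV = 1 + 0.8 each; shared = {root}: (0.8 + 0.8) / 3.6
  expect_equal(sim_wang(dag, "T:a", "T:b"), 1.6 / 3.6)
  expect_error(sim_wang(dag, "T:a", "T:b", decay = c(is_a = 1.2)),
               "decay")

  rnd <- random_annotated_dag(n_terms = 30, seed = 7)
  ids <- names(rnd$dag$terms)
  set.seed(21)
  for (k in 1:40) {
    t1 <- sample(ids, 1); t2 <- sample(ids, 1)
    expect_equal(sim_wang(rnd$dag, t1, t2), naive_wang(rnd$dag, t1, t2),
                 tolerance = 1e-12)
  }
})

test_that("best-match average equals the brute-force double loop", {
  set.seed(5)
  s1 <- letters[1:3]; s2 <- LETTERS[1:4]
  m <- matrix(runif(12), 3, 4, dimnames = list(s1, s2))
  score <- function(a, b) m[a, b]
  brute <- (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
  expect_equal(bma(score, s1, s2), brute)
  expect_equal(bma(score, "a", "B"), m["a", "B"])
  expect_error(bma(score, character(), s2), "nonempty")
})

test_that("PSB surrogate spans [0, 1] and matches a hand-rolled BMA", {
  mx <- maximal_similarity_fixture()
  expect_equal(sim_psb(mx$profile, mx$profile, mx$resources$dag_go,
                       mx$resources$ic_go), 1)

  # disjoint subtrees sharing only the root
  go <- write_obo(c("format-version: 1.2", "",
                    obo_stanza("G:r", namespace = "biological_process"),
                    obo_stanza("G:a", namespace = "biological_process",
                               is_a = "G:r"),
                    obo_stanza("G:b", namespace = "biological_process",
                               is_a = "G:r")))
  dag <- parse_obo(go)
  ann <- annotation_corpus(c("g1", "g2"), c("G:a", "G:b"))
  ic <- information_content(dag, ann)
  p1 <- disease_profile("d1", "g1", ann)
  p2 <- disease_profile("d2", "g2", ann)
  expect_equal(sim_psb(p1, p2, dag, ic), 0)

  # overlapping 3-term sets against a brute-force pair-score matrix
  rnd <- random_annotated_dag(n_terms = 25, seed = 13)
  ids <- names(rnd$dag$terms)
  set.seed(31)
  b1 <- sample(ids, 3); b2 <- c(b1[1], sample(setdiff(ids, b1), 2))
  ann2 <- annotation_corpus(
    c(rep("gA", 3), rep("gB", 3)), c(b1, b2))
  pa <- disease_profile("dA", "gA", ann2)
  pb <- disease_profile("dB", "gB", ann2)
  icmax <- rnd$ic$ic_max
  sc <- outer(b1, b2, Vectorize(function(a, b)
    mica(rnd$dag, rnd$ic, a, b)$ic / icmax))
  brute <- (mean(apply(sc, 1, max)) + mean(apply(sc, 2, max))) / 2
  expect_equal(sim_psb(pa, pb, rnd$dag, rnd$ic, bp_namespace = "test"),
               brute)
})

test_that("SemFunSim surrogate blends identity with funnet weights", {
  p1 <- disease_profile("d1", c("a", "b"))
  p2 <- disease_profile("d2", c("a", "c"))
  same <- disease_profile("d3", c("a", "b"))
  expect_equal(sim_semfunsim(p1, same), 1)
  expect_equal(sim_semfunsim(disease_profile("x", "u"),
                             disease_profile("y", "v")), 0)
  fn <- funnet(gene_a = "b", gene_b = "c", weight = 0.5)
  expect_equal(sim_semfunsim(p1, p2, fn), 0.75)
  expect_error(funnet("a", "b", 1.5), "\\[0, 1\\]")
})

test_that("combined similarity reproduces published totals and bounds", {
  # self-comparison row of the published table
  self <- method_scores(semfunsim = 1.00, wang = 0.87, lin = 1.00,
                        psb = 0.00, resnik = 3.60)
  expect_equal(self$total, 6.47)
  # first row: printed total 3.52, components sum to 3.51
  first <- method_scores(0.02, 0.48, 0.40, 0.06, 2.55)
  expect_lt(abs(first$total - 3.52), 0.011)

  # a pair constructed so every component attains its maximum sums to 8
  mx <- maximal_similarity_fixture()
  s <- combined_similarity(mx$profile, mx$profile, mx$resources)
  expect_equal(s$semfunsim, 1)
  expect_equal(s$wang, 1)
  expect_equal(s$lin, 1)
  expect_equal(s$psb, 1)
  expect_equal(s$resnik, 4)
  expect_equal(s$total, 8)

  expect_error(method_scores(1.2, 0, 0, 0, 0), "\\[0, 1\\]")
  expect_error(method_scores(0, 0, 0, 0, 4.2), "\\[0, 4\\]")
})

test_that("normalization divides by the theoretical maximum of 8", {
  expect_equal(normalize_similarity(8), 1)
  expect_equal(normalize_similarity(0), 0)
  expect_equal(normalize_similarity(6.47), 0.80875)
  expect_error(normalize_similarity(8.5), "\\[0, 8\\]")
})

test_that("threshold filter is inclusive and keeps the published set", {
  sc <- data.frame(disease_id = c("d1", "d2", "d3"),
                   total = c(3.52, 3.40, 4.98))
  expect_identical(filter_by_threshold(sc, 3.5), c("d1", "d3"))
  expect_identical(filter_by_threshold(sc[0, ], 3.5), character())
  ref <- ad_similarity_reference()
  expect_length(filter_by_threshold(ref, 3.5), 34)
})

test_that("all five measures are symmetric on fixture disease pairs", {
  b <- default_bundle()
  tab <- load_associations(b$paths$associations)
  dag_do <- parse_obo(b$paths$do_obo)
  dag_go <- parse_obo(b$paths$go_obo)
  go_ann <- read_annotations(b$paths$go_annotations, dag_go)
  do_ann <- read_annotations(b$paths$do_annotations, dag_do)
  res <- list(dag_do = dag_do, ic_do = information_content(dag_do, do_ann),
              dag_go = dag_go, ic_go = information_content(dag_go, go_ann),
              funnet = read_funnet(b$paths$funnet))
  genes_of <- split(tab$rows$protein_accession, tab$rows$disease_id)
  set.seed(17)
  for (k in 1:8) {
    ids <- sample(tab$diseases, 2)
    pa <- disease_profile(ids[1], genes_of[[ids[1]]], go_ann)
    pb <- disease_profile(ids[2], genes_of[[ids[2]]], go_ann)
    ab <- suppressWarnings(combined_similarity(pa, pb, res))
    ba <- suppressWarnings(combined_similarity(pb, pa, res))
    expect_equal(unclass(ab), unclass(ba), tolerance = 1e-12)
    expect_gte(ab$total, 0)
    expect_lte(ab$total, 8)
  }
})
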