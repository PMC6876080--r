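# Disease-pair similarity: term-level Resnik, Lin and Wang measures,
# best-match-average set lifting, the PSB and SemFunSim surrogates, the
# five-way combined score, its normalization, and the retention filter.

#' Construct a disease profile
#'
#' The unit compared by all five similarity measures: a disease's gene
#' (protein) set, the GO terms annotating those genes (recomputed from the
#' corpus, never stored stale), and the disease's own ontology term(s).
#'
#' @param disease_id Disease accession (opaque string).
#' @param genes Character vector of gene/protein identifiers (nonempty).
#' @param go_annotations Optional `annotation_corpus` mapping genes to GO
#'   terms; the profile's `terms` are the union over `genes`.
#' @param do_terms The disease's own ontology term ids; defaults to the
#'   singleton `disease_id`.
#' @return A `disease_profile` object.
#' @export
disease_profile <- function(disease_id, genes, go_annotations = NULL,
                            do_terms = disease_id) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("disease ", disease_id, " has an empty gene set")
  terms <- character()
  if (!is.null(go_annotations)) {
    stopifnot(inherits(go_annotations, "annotation_corpus"))
    p <- go_annotations$pairs
    terms <- unique(p$term_id[p$entity_id %in% genes])
  }
  structure(list(disease_id = disease_id, genes = genes, terms = terms,
                 do_terms = unique(as.character(do_terms))),
            class = "disease_profile")
}

#' @export
print.disease_profile <- function(x, ...) {
  cat("disease_profile", x$disease_id, "-", length(x$genes), "genes,",
      length(x$terms), "GO terms\n")
  invisible(x)
}

#' Resnik term similarity scaled to [0, 4]
#'
#' `4 * IC(MICA(t1, t2)) / ic_max`; the raw MICA information content is
#' rescaled so the measure's maximum is 4 and the five-way combined score
#' is bounded by 8. Returns 0 when `ic_max` is 0.
#'
#' @param dag An `ontology_dag`.
#' @param ic An `ic_table` for `dag`.
#' @param t1,t2 Term ids.
#' @return Similarity in `[0, 4]`.
#' @export
sim_resnik <- function(dag, ic, t1, t2) {
  if (ic$ic_max <= 0) return(0)
  m <- mica(dag, ic, t1, t2)
  4 * m$ic / ic$ic_max
}

#' Lin term similarity
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))`; 0 when the denominator is 0.
#'
#' @inheritParams sim_resnik
#' @return Similarity in `[0, 1]`.
#' @export
sim_lin <- function(dag, ic, t1, t2) {
  m <- mica(dag, ic, t1, t2)
  denom <- .ic_of(ic, t1) + .ic_of(ic, t2)
  if (denom <= 0) return(0)
  2 * m$ic / denom
}

# S-values of Wang's measure for one term: the decayed semantic
# contribution of each ancestor, S_A(A) = 1 and
# S_A(t) = max over child edges (c -> t) with c in anc(A) of decay * S_A(c).
.wang_svalues <- function(dag, term_id, decay) {
  anc <- term_ancestors(dag, term_id)
  memo <- new.env(parent = emptyenv())
  assign(term_id, 1, envir = memo)
  sval <- function(t) {
    hit <- get0(t, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    ch <- dag$children[[t]]
    ch <- ch[ch$child %in% anc, , drop = FALSE]
    v <- max(vapply(seq_len(nrow(ch)), function(k)
      decay[[ch$relation[[k]]]] * sval(ch$child[[k]]), numeric(1)))
    assign(t, v, envir = memo)
    v
  }
  stats::setNames(vapply(anc, sval, numeric(1)), anc)
}

#' Wang term similarity from decayed semantic contributions
#'
#' For each term the S-value of every ancestor is the maximal product of
#' relation decay factors along a path down to the term; similarity is the
#' summed S-values over shared ancestors, normalized by the two terms'
#' total semantic values.
#'
#' @param dag An `ontology_dag`.
#' @param t1,t2 Term ids.
#' @param decay Named decay factors in `(0, 1)` per relation type;
#'   defaults `is_a = 0.8`, `part_of = 0.6` (Wang's original weights).
#' @return Similarity in `(0, 1]`.
#' @export
sim_wang <- function(dag, t1, t2, decay = c(is_a = 0.8, part_of = 0.6)) {
  .assert_term(dag, t1)
  .assert_term(dag, t2)
  if (any(decay <= 0) || any(decay >= 1))
    stop("decay factors must lie strictly in (0, 1)")
  s1 <- .wang_svalues(dag, t1, decay)
  s2 <- .wang_svalues(dag, t2, decay)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

#' Best-match average of a pairwise score over two sets
#'
#' Symmetrized: the mean over `set1` of each element's best match in
#' `set2`, averaged with the converse.
#'
#' @param pair_score Function of two elements returning a numeric score.
#' @param set1,set2 Nonempty vectors.
#' @return The best-match-average score.
#' @export
bma <- function(pair_score, set1, set2) {
  if (!length(set1) || !length(set2))
    stop("bma requires two nonempty sets")
  m <- matrix(NA_real_, length(set1), length(set2))
  for (i in seq_along(set1))
    for (j in seq_along(set2))
      m[i, j] <- pair_score(set1[[i]], set2[[j]])
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

#' Process-similarity (PSB) surrogate over biological-process GO terms
#'
#' A documented surrogate for the cited process-similarity-based measure:
#' the best-match average over the two diseases' biological-process GO
#' terms with pair score `IC(MICA) / ic_max`, `ic_max` taken over the BP
#' namespace. Returns 0 with a warning when either disease has no BP
#' terms (the published tables likewise show 0 for such pairs).
#'
#' @param p1,p2 `disease_profile` objects.
#' @param dag_go GO `ontology_dag`.
#' @param ic_go `ic_table` for the GO DAG.
#' @param bp_namespace Namespace string marking biological-process terms.
#' @return Similarity in `[0, 1]`.
#' @export
sim_psb <- function(p1, p2, dag_go, ic_go,
                    bp_namespace = "biological_process") {
  bp_terms <- function(p) {
    keep <- vapply(p$terms, function(t) {
      ns <- dag_go$terms[[t]]$namespace
      is.null(ns) || identical(ns, bp_namespace)
    }, logical(1))
    p$terms[keep]
  }
  b1 <- bp_terms(p1)
  b2 <- bp_terms(p2)
  if (!length(b1) || !length(b2)) {
    warning("empty biological-process term set for ",
            if (!length(b1)) p1$disease_id else p2$disease_id,
            "; PSB surrogate set to 0")
    return(0)
  }
  all_bp <- unique(c(b1, b2))
  ns_terms <- Filter(function(t) {
    ns <- dag_go$terms[[t]]$namespace
    is.null(ns) || identical(ns, bp_namespace)
  }, names(ic_go$ic))
  ic_max_bp <- if (length(ns_terms)) max(ic_go$ic[ns_terms]) else ic_go$ic_max
  if (ic_max_bp <= 0) return(0)
  bma(function(a, b) mica(dag_go, ic_go, a, b)$ic / ic_max_bp, b1, b2)
}

#' Read a gene functional-association weight table
#'
#' TSV with header columns `gene_a`, `gene_b`, `weight` (weights in
#' `[0, 1]`); pairs are stored symmetrically.
#'
#' @param path Path to the TSV.
#' @return A `funnet` object (environment-backed symmetric lookup).
#' @export
read_funnet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(df)))
    stop("funnet table must have columns gene_a, gene_b, weight")
  funnet(df$gene_a, df$gene_b, df$weight)
}

#' Build a functional-association network from vectors
#'
#' @param gene_a,gene_b Parallel gene id vectors.
#' @param weight Numeric weights in `[0, 1]`.
#' @return A `funnet` object.
#' @export
funnet <- function(gene_a = character(), gene_b = character(),
                   weight = numeric()) {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(weight))
  if (length(weight) && (any(weight < 0) || any(weight > 1)))
    stop("funnet weights must lie in [0, 1]")
  env <- new.env(parent = emptyenv())
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (length(gene_a)) {
    k <- key(as.character(gene_a), as.character(gene_b))
    for (i in seq_along(k)) assign(k[[i]], weight[[i]], envir = env)
  }
  structure(list(env = env, key = key, n_pairs = length(weight)),
            class = "funnet")
}

#' @export
print.funnet <- function(x, ...) {
  cat("funnet:", length(ls(x$env)), "weighted gene pairs\n")
  invisible(x)
}

.funnet_weight <- function(fn, a, b) {
  v <- get0(fn$key(a, b), envir = fn$env, inherits = FALSE)
  if (is.null(v)) 0 else v
}

#' SemFunSim surrogate over gene sets
#'
#' A documented surrogate for the cited measure integrating semantic and
#' functional association: the best-match average over the two diseases'
#' gene sets with pair score 1 for identical genes and otherwise the
#' functional-association weight (0 when the pair is absent).
#'
#' @param p1,p2 `disease_profile` objects with nonempty gene sets.
#' @param fn A `funnet`; `NULL` means no functional associations.
#' @return Similarity in `[0, 1]`.
#' @export
sim_semfunsim <- function(p1, p2, fn = NULL) {
  if (!length(p1$genes) || !length(p2$genes))
    stop("SemFunSim surrogate requires nonempty gene sets")
  score <- function(a, b) {
    if (identical(a, b)) return(1)
    if (is.null(fn)) return(0)
    .funnet_weight(fn, a, b)
  }
  bma(score, p1$genes, p2$genes)
}

.lift_term_measure <- function(pair_score, terms1, terms2) {
  if (!length(terms1) || !length(terms2)) return(0)
  bma(pair_score, terms1, terms2)
}

#' Combined five-way disease similarity
#'
#' Computes the SemFunSim surrogate, Wang, Lin, the PSB surrogate and the
#' `[0, 4]`-scaled Resnik score for a disease pair and their sum (bounded
#' by 8). Resnik, Lin and Wang are term-pair measures lifted to diseases
#' by best-match average over the diseases' own ontology terms when a
#' disease-ontology DAG with an IC table is supplied (`dag_do`/`ic_do` in
#' `resources`), else over the GO-term profiles of their gene sets.
#'
#' @param target,other `disease_profile` objects.
#' @param resources List with elements `dag_go`, `ic_go` (required),
#'   `dag_do`, `ic_do` (optional; enables the disease-ontology route),
#'   `funnet` (optional) and `wang_decay` (optional named decays).
#' @return A `method_scores` object: list with `semfunsim`, `wang`,
#'   `lin`, `psb`, `resnik`, `total`.
#' @export
combined_similarity <- function(target, other, resources) {
  stopifnot(inherits(target, "disease_profile"),
            inherits(other, "disease_profile"))
  decay <- resources$wang_decay
  if (is.null(decay)) decay <- c(is_a = 0.8, part_of = 0.6)

  do_route <- !is.null(resources$dag_do) && !is.null(resources$ic_do) &&
    length(target$do_terms) && length(other$do_terms) &&
    all(c(target$do_terms, other$do_terms) %in% names(resources$dag_do$terms))
  if (do_route) {
    dag <- resources$dag_do; ict <- resources$ic_do
    t1 <- target$do_terms;   t2 <- other$do_terms
  } else {
    dag <- resources$dag_go; ict <- resources$ic_go
    t1 <- target$terms;      t2 <- other$terms
  }

  resnik <- .lift_term_measure(function(a, b) sim_resnik(dag, ict, a, b), t1, t2)
  lin    <- .lift_term_measure(function(a, b) sim_lin(dag, ict, a, b), t1, t2)
  wang   <- .lift_term_measure(function(a, b) sim_wang(dag, a, b, decay), t1, t2)
  psb    <- sim_psb(target, other, resources$dag_go, resources$ic_go)
  semfun <- sim_semfunsim(target, other, resources$funnet)

  method_scores(semfunsim = semfun, wang = wang, lin = lin,
                psb = psb, resnik = resnik)
}

#' Bundle the five per-method scores and their total
#'
#' @param semfunsim,wang,lin,psb Scores in `[0, 1]`.
#' @param resnik Score in `[0, 4]`.
#' @return A `method_scores` object with `total` equal to the sum.
#' @export
method_scores <- function(semfunsim, wang, lin, psb, resnik) {
  in01 <- c(semfunsim = semfunsim, wang = wang, lin = lin, psb = psb)
  if (any(in01 < -1e-9) || any(in01 > 1 + 1e-9))
    stop("semfunsim, wang, lin and psb must lie in [0, 1]")
  if (resnik < -1e-9 || resnik > 4 + 1e-9)
    stop("resnik must lie in [0, 4]")
  structure(list(semfunsim = semfunsim, wang = wang, lin = lin,
                 psb = psb, resnik = resnik,
                 total = semfunsim + wang + lin + psb + resnik),
            class = "method_scores")
}

#' @export
print.method_scores <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s=%.2f", names(v), v), collapse = " "), "\n")
  invisible(x)
}

#' Normalize a combined similarity to [0, 1]
#'
#' Divides by 8, the theoretical maximum of the combined score (four
#' measures bounded by 1 plus Resnik bounded by 4).
#'
#' @param total Combined similarity in `[0, 8]`.
#' @return `total / 8`.
#' @export
normalize_similarity <- function(total) {
  if (any(total < -1e-9) || any(total > 8 + 1e-9))
    stop("combined similarity must lie in [0, 8]")
  total / 8
}

#' Retain diseases at or above a similarity threshold
#'
#' @param scores data.frame with columns `disease_id` and `total`.
#' @param threshold Retention cutoff (inclusive), default 3.5.
#' @return Disease ids with `total >= threshold`, sorted by total
#'   ascending then id.
#' @export
filter_by_threshold <- function(scores, threshold = 3.5) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (!nrow(scores)) return(character())
  keep <- scores[scores$total >= threshold, , drop = FALSE]
  keep <- keep[order(keep$total, keep$disease_id), , drop = FALSE]
  keep$disease_id
}

#' Similarity of every candidate disease to the target
#'
#' @param target A `disease_profile`.
#' @param profiles List of candidate `disease_profile`s (may include the
#'   target itself).
#' @param resources Resource bundle as for [combined_similarity()].
#' @return data.frame with one row per candidate: `disease_id`, the five
#'   per-method scores, `total` and `normalized`.
#' @export
similarity_table <- function(target, profiles, resources) {
  rows <- lapply(profiles, function(p) {
    s <- combined_similarity(target, p, resources)
    data.frame(disease_id = p$disease_id, semfunsim = s$semfunsim,
               wang = s$wang, lin = s$lin, psb = s$psb, resnik = s$resnik,
               total = s$total, normalized = normalize_similarity(s$total),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference similarity table for Alzheimer's disease
#'
#' The published five-method similarity scores between Alzheimer's
#' disease and the 34 candidate diseases retained at the 3.5 threshold,
#' as computed from 2019 snapshots of the Disease Ontology, Gene Ontology
#' and UniProt. Components and totals are printed to two decimals; the
#' final row (`680`) is the disease compared with itself.
#'
#' @return data.frame with columns `disease_id`, `semfunsim`, `wang`,
#'   `lin`, `psb`, `resnik`, `total`.
#' @export
ad_similarity_reference <- function() {
  tab <- c(
    "0050784", 0.02, 0.48, 0.40, 0.06, 2.55, 3.52,
    "0060368", 0.01, 0.48, 0.42, 0.06, 2.55, 3.52,
    "0050765", 0.00, 0.63, 0.33, 0.00, 2.55, 3.52,
    "14784",   0.00, 0.63, 0.33, 0.00, 2.55, 3.52,
    "1440",    0.02, 0.48, 0.40, 0.08, 2.55, 3.52,
    "12705",   0.01, 0.48, 0.39, 0.10, 2.55, 3.53,
    "936",     0.23, 0.53, 0.62, 0.09, 2.09, 3.56,
    "13548",   0.00, 0.63, 0.35, 0.02, 2.55, 3.57,
    "3981",    0.00, 0.63, 0.35, 0.03, 2.55, 3.57,
    "4873",    0.01, 0.48, 0.39, 0.14, 2.55, 3.57,
    "9277",    0.01, 0.63, 0.38, 0.00, 2.55, 3.58,
    "0060264", 0.01, 0.63, 0.39, 0.00, 2.55, 3.59,
    "12704",   0.03, 0.48, 0.44, 0.08, 2.55, 3.59,
    "1441",    0.04, 0.54, 0.48, 0.00, 2.55, 3.63,
    "12377",   0.04, 0.54, 0.47, 0.02, 2.55, 3.63,
    "0050950", 0.05, 0.54, 0.48, 0.00, 2.55, 3.63,
    "14332",   0.00, 0.54, 0.30, 0.28, 2.55, 3.68,
    "4752",    0.03, 0.54, 0.44, 0.12, 2.55, 3.69,
    "2378",    0.04, 0.48, 0.45, 0.22, 2.55, 3.75,
    "0050968", 0.00, 0.48, 0.30, 0.44, 2.55, 3.77,
    "0050951", 0.08, 0.63, 0.53, 0.00, 2.55, 3.80,
    "12217",   0.06, 0.44, 0.47, 0.31, 2.55, 3.84,
    "230",     0.11, 0.54, 0.55, 0.15, 2.55, 3.91,
    "12858",   0.09, 0.63, 0.52, 0.12, 2.55, 3.91,
    "331",     0.46, 0.65, 0.73, 0.02, 2.09, 3.95,
    "332",     0.14, 0.54, 0.58, 0.13, 2.55, 3.95,
    "11870",   0.03, 0.63, 0.41, 0.38, 2.55, 4.00,
    "0050890", 0.21, 0.63, 0.63, 0.00, 2.55, 4.03,
    "3213",    0.19, 0.63, 0.65, 0.10, 2.55, 4.12,
    "2377",    0.19, 0.54, 0.64, 0.19, 2.55, 4.12,
    "231",     0.15, 0.63, 0.60, 0.19, 2.55, 4.13,
    "14330",   0.19, 0.54, 0.62, 0.24, 2.55, 4.16,
    "1289",    0.57, 0.75, 0.83, 0.27, 2.55, 4.98,
    "680",     1.00, 0.87, 1.00, 0.00, 3.60, 6.47)
  m <- matrix(tab, ncol = 7, byrow = TRUE)
  data.frame(disease_id = m[, 1],
             semfunsim = as.numeric(m[, 2]), wang = as.numeric(m[, 3]),
             lin = as.numeric(m[, 4]), psb = as.numeric(m[, 5]),
             resnik = as.numeric(m[, 6]), total = as.numeric(m[, 7]),
             stringsAsFactors = FALSE)
}
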