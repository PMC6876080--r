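# Ontology handling: OBO 1.2 parsing into a DAG, ancestor closure,
# annotation-derived information content, and the most informative
# common ancestor (MICA) used by the Resnik and Lin measures.

# Relation types followed when walking ancestry; other OBO relations are
# kept in the term records but never traversed.
.traversed_relations <- c("is_a", "part_of")

#' Parse an OBO 1.2 ontology file into a DAG
#'
#' Reads `[Term]` stanzas (fields `id`, `name`, `namespace`, `is_a`,
#' `relationship`, `is_obsolete`), drops obsolete terms, and verifies that
#' the `is_a`/`part_of` graph is acyclic. Parent links pointing at terms
#' absent from the file (e.g. parents of dropped obsolete terms) are
#' discarded with a warning.
#'
#' @param path Path to an OBO 1.2 flat file.
#' @return An object of class `ontology_dag`: a list with elements
#'   `terms` (named list of term records with `term_id`, `name`,
#'   `namespace`, `parents` data.frame of `parent`/`relation`), `children`
#'   (reverse index), and `roots` (term ids with no traversable parents).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  terms <- list()
  cur <- NULL
  in_term <- FALSE

  flush_term <- function(cur) {
    if (is.null(cur) || is.null(cur$term_id)) return(terms)
    if (isTRUE(cur$obsolete)) return(terms)  # obsolete terms are dropped
    cur$parents <- if (length(cur$parent_ids)) {
      data.frame(parent = cur$parent_ids, relation = cur$parent_rels,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(parent = character(), relation = character(),
                 stringsAsFactors = FALSE)
    }
    cur$parent_ids <- NULL
    cur$parent_rels <- NULL
    if (!is.null(terms[[cur$term_id]]))
      stop("duplicate term id in OBO file: ", cur$term_id)
    terms[[cur$term_id]] <- cur
    terms
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      terms <- flush_term(cur)
      cur <- NULL
      in_term <- identical(line, "[Term]")
      next
    }
    if (!in_term) next
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0)
      stop("malformed OBO stanza line ", i, ": ", line)
    key <- substr(line, 1L, colon - 1L)
    val <- trimws(substr(line, colon + 1L, nchar(line)))
    # strip trailing '! name' comments
    bang <- regexpr(" ! ", val, fixed = TRUE)
    if (bang > 0) val <- trimws(substr(val, 1L, bang - 1L))
    if (is.null(cur)) cur <- list(parent_ids = character(),
                                  parent_rels = character(),
                                  obsolete = FALSE)
    if (key == "id") {
      cur$term_id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "namespace") {
      cur$namespace <- val
    } else if (key == "is_a") {
      cur$parent_ids <- c(cur$parent_ids, val)
      cur$parent_rels <- c(cur$parent_rels, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(parts) < 2)
        stop("malformed relationship on OBO line ", i, ": ", line)
      cur$parent_ids <- c(cur$parent_ids, parts[[2]])
      cur$parent_rels <- c(cur$parent_rels, parts[[1]])
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
    # other keys (def, xref, synonym, ...) are ignored
  }
  terms <- flush_term(cur)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  ids <- names(terms)
  # drop parent links to unknown terms (e.g. parents that were obsolete)
  dangling <- character()
  for (id in ids) {
    p <- terms[[id]]$parents
    keep <- p$parent %in% ids
    if (any(!keep)) {
      dangling <- c(dangling, p$parent[!keep])
      terms[[id]]$parents <- p[keep, , drop = FALSE]
    }
  }
  if (length(dangling))
    warning("dropped parent links to unknown terms: ",
            paste(unique(dangling), collapse = ", "))

  dag <- .build_dag(terms)
  .check_acyclic(dag)
  dag
}

.build_dag <- function(terms) {
  ids <- names(terms)
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    p <- terms[[id]]$parents
    p <- p[p$relation %in% .traversed_relations, , drop = FALSE]
    for (k in seq_len(nrow(p))) {
      pid <- p$parent[[k]]
      children[[pid]] <- rbind(children[[pid]],
                               data.frame(child = id,
                                          relation = p$relation[[k]],
                                          stringsAsFactors = FALSE))
    }
  }
  roots <- ids[vapply(ids, function(id) {
    p <- terms[[id]]$parents
    !any(p$relation %in% .traversed_relations)
  }, logical(1))]
  structure(list(terms = terms, children = children, roots = sort(roots),
                 anc_cache = new.env(parent = emptyenv())),
            class = "ontology_dag")
}

.check_acyclic <- function(dag) {
  edges <- .edge_frame(dag)
  if (!nrow(edges)) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = names(dag$terms))
  if (igraph::is_dag(g)) return(invisible(TRUE))
  comp <- igraph::components(g, mode = "strong")
  bad <- names(comp$membership)[comp$membership %in%
                                  which(comp$csize > 1)]
  if (!length(bad)) {  # self-loop
    loops <- igraph::which_loop(g)
    bad <- igraph::as_ids(igraph::head_of(g, igraph::E(g)[loops]))
  }
  stop("ontology contains a cycle involving term ", sort(bad)[[1]])
}

.edge_frame <- function(dag) {
  rows <- lapply(names(dag$terms), function(id) {
    p <- dag$terms[[id]]$parents
    p <- p[p$relation %in% .traversed_relations, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    data.frame(from = id, to = p$parent, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(from = character(),
                                         to = character()))))
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

.assert_term <- function(dag, term_id) {
  if (!term_id %in% names(dag$terms))
    stop("unknown term: ", term_id)
}

#' Reflexive transitive ancestor closure of a term
#'
#' Walks `is_a`/`part_of` parent links; the term itself is included.
#'
#' @param dag An `ontology_dag`.
#' @param term_id A term identifier present in `dag`.
#' @return Character vector of ancestor term ids (including `term_id`).
#' @export
term_ancestors <- function(dag, term_id) {
  .assert_term(dag, term_id)
  cache <- dag$anc_cache
  memo <- function(id) {
    hit <- get0(id, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    p <- dag$terms[[id]]$parents
    p <- p$parent[p$relation %in% .traversed_relations]
    out <- id
    for (pid in unique(p)) out <- c(out, memo(pid))
    out <- unique(out)
    assign(id, out, envir = cache)
    out
  }
  memo(term_id)
}

#' Read a GAF-like annotation table
#'
#' Two-column tab-separated file mapping entities (genes/proteins) to
#' ontology terms. Lines starting with `!` are comments; an optional
#' header row `entity_id<TAB>term_id` is recognised and skipped.
#' Pairs are deduplicated.
#'
#' @param path Path to the TSV file.
#' @param dag Optional `ontology_dag`; if supplied, annotations to terms
#'   absent from the DAG are dropped with a warning.
#' @return An `annotation_corpus`: list with `pairs` (data.frame
#'   `entity_id`, `term_id`) and `entities` (unique entity ids).
#' @export
read_annotations <- function(path, dag = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(lines)) stop("no annotation rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) stop("annotation line ", bad[[1]], " has fewer than 2 columns")
  df <- data.frame(entity_id = vapply(parts, `[[`, "", 1),
                   term_id = vapply(parts, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  if (identical(tolower(df$entity_id[[1]]), "entity_id"))
    df <- df[-1, , drop = FALSE]
  annotation_corpus(df$entity_id, df$term_id, dag = dag)
}

#' Build an annotation corpus from vectors
#'
#' @param entity_id,term_id Parallel character vectors.
#' @param dag Optional `ontology_dag` used to drop annotations to
#'   unknown terms.
#' @return An `annotation_corpus` object.
#' @export
annotation_corpus <- function(entity_id, term_id, dag = NULL) {
  stopifnot(length(entity_id) == length(term_id))
  df <- unique(data.frame(entity_id = as.character(entity_id),
                          term_id = as.character(term_id),
                          stringsAsFactors = FALSE))
  if (!is.null(dag)) {
    known <- df$term_id %in% names(dag$terms)
    if (any(!known)) {
      warning("dropped ", sum(!known),
              " annotation(s) to terms absent from the ontology")
      df <- df[known, , drop = FALSE]
    }
  }
  if (!nrow(df)) stop("annotation corpus is empty")
  structure(list(pairs = df, entities = unique(df$entity_id)),
            class = "annotation_corpus")
}

#' Information content from up-propagated annotation counts
#'
#' Each entity annotated to a term counts once for that term and for
#' every ancestor of it. `IC(t) = -ln(count(t) / count(root))`, where the
#' root is the reachable root with the largest propagated count (so roots
#' always have IC 0). Terms with zero propagated count carry no IC entry.
#'
#' @param dag An `ontology_dag`.
#' @param annotations An `annotation_corpus` whose terms live in `dag`.
#' @return An `ic_table`: list with `ic` (named numeric, non-negative),
#'   `ic_max` (max IC over annotated terms) and `total_annotations`
#'   (distinct annotated entities).
#' @export
information_content <- function(dag, annotations) {
  stopifnot(inherits(annotations, "annotation_corpus"))
  pairs <- annotations$pairs
  unknown <- setdiff(unique(pairs$term_id), names(dag$terms))
  if (length(unknown))
    stop("annotations reference terms absent from the ontology: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  if (!nrow(pairs)) stop("annotation corpus is empty")

  # propagate: entity annotated to t counts for every ancestor of t
  ent_sets <- new.env(parent = emptyenv())
  by_term <- split(pairs$entity_id, pairs$term_id)
  for (tid in names(by_term)) {
    ents <- unique(by_term[[tid]])
    for (anc in term_ancestors(dag, tid)) {
      assign(anc, c(get0(anc, envir = ent_sets, inherits = FALSE), ents),
             envir = ent_sets)
    }
  }
  counted <- ls(ent_sets)
  counts <- vapply(counted, function(id)
    length(unique(get(id, envir = ent_sets))), numeric(1))

  root_count <- function(tid) {
    rts <- intersect(term_ancestors(dag, tid), dag$roots)
    rc <- counts[rts]
    rc <- rc[!is.na(rc)]
    if (!length(rc)) return(NA_real_)
    max(rc)
  }
  ic <- vapply(counted, function(tid) {
    denom <- root_count(tid)
    if (is.na(denom) || denom <= 0) return(NA_real_)
    -log(counts[[tid]] / denom)
  }, numeric(1))
  ic <- ic[!is.na(ic)]
  structure(list(ic = ic,
                 ic_max = if (length(ic)) max(ic) else 0,
                 total_annotations = length(annotations$entities)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table:", length(x$ic), "annotated terms, ic_max =",
      format(x$ic_max, digits = 4), "\n")
  invisible(x)
}

.ic_of <- function(ic, term_id) {
  v <- unname(ic$ic[term_id])
  v[is.na(v)] <- 0
  v
}

#' Most informative common ancestor of two terms
#'
#' Common ancestors are reflexive (a term is its own ancestor). Returns
#' the common ancestor with maximal IC; ties are broken by the
#' lexicographically smallest term id. When no common ancestor carries a
#' positive IC, the lexicographically smallest common root is returned
#' with IC 0.
#'
#' @param dag An `ontology_dag`.
#' @param ic An `ic_table` for `dag`.
#' @param t1,t2 Term identifiers.
#' @return List with `term` (the MICA id, `NA` if the terms share no
#'   ancestor) and `ic` (its information content).
#' @export
mica <- function(dag, ic, t1, t2) {
  .assert_term(dag, t1)
  .assert_term(dag, t2)
  common <- intersect(term_ancestors(dag, t1), term_ancestors(dag, t2))
  if (!length(common)) return(list(term = NA_character_, ic = 0))
  vals <- .ic_of(ic, common)
  if (max(vals) <= 0) {
    common_roots <- intersect(common, dag$roots)
    pick <- if (length(common_roots)) sort(common_roots)[[1]]
            else sort(common)[[1]]
    return(list(term = pick, ic = 0))
  }
  best <- common[vals == max(vals)]
  list(term = sort(best)[[1]], ic = max(vals))
}
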