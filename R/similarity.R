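#' ATC code level prefixes
#'
#' The WHO Anatomical Therapeutic Chemical (ATC) classification assigns a
#' 7-character code with five cumulative levels: anatomical main group
#' (1 character), therapeutic subgroup (+2 digits), pharmacological
#' subgroup (+1 character), chemical subgroup (+1 character) and chemical
#' substance (+2 digits).  `atc_level_prefixes()` truncates a set of codes
#' to their level-k prefixes.
#'
#' @param codes character vector of 7-character ATC codes.
#' @param k level, 1 to 5.
#' @return character vector of unique level-k prefixes.
#' @export
atc_level_prefixes <- function(codes, k) {
  stopifnot(k %in% 1:5)
  codes <- validate_atc_codes(codes)
  unique(substr(codes, 1L, c(1L, 3L, 4L, 5L, 7L)[k]))
}

validate_atc_codes <- function(codes) {
  codes <- toupper(as.character(codes))
  ok <- grepl("^[A-Z][0-9]{2}[A-Z][A-Z][0-9]{2}$", codes)
  if (!all(ok))
    stop_domain("invalid ATC code(s): %s (expected letter, 2 digits, 2 letters, 2 digits)",
                paste(codes[!ok], collapse = ", "))
  codes
}

#' Level-k ATC similarity between two drugs
#'
#' Jaccard index of the two drugs' level-k ATC prefix sets.  A drug may
#' carry several ATC codes; all are truncated to level k before the set
#' comparison.
#'
#' @param a,b character vectors of ATC codes (non-empty).
#' @param k level, 1 to 5.
#' @return similarity in `[0, 1]`.
#' @export
atc_level_similarity <- function(a, b, k) {
  if (length(a) == 0L || length(b) == 0L)
    stop_domain("ATC code sets must be non-empty")
  pa <- atc_level_prefixes(a, k)
  pb <- atc_level_prefixes(b, k)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

#' Multi-level ATC similarity between two drugs
#'
#' The mean of the level-wise Jaccard similarities over the five ATC
#' levels.  Symmetric and bounded in `[0, 1]`; identical code sets score 1.
#'
#' @inheritParams atc_level_similarity
#' @export
atc_similarity <- function(a, b) {
  mean(vapply(1:5, function(k) atc_level_similarity(a, b, k), numeric(1)))
}

#' Directed acyclic ontology
#'
#' A set of terms and child-to-parent (`is_a`) edges forming a DAG, with
#' precomputed ancestor sets.  A term's ancestor set includes the term
#' itself, so that a term is maximally similar to itself.
#'
#' @param terms character vector of term ids.
#' @param parents data frame (or 2-column matrix) of child, parent edges.
#' @return An object of class `ontology` with fields `terms`, `parents`
#'   (named list child -> parent ids) and `ancestors` (named list,
#'   self-inclusive).
#' @export
ontology <- function(terms, parents) {
  terms <- unique(as.character(terms))
  parents <- as.data.frame(parents, stringsAsFactors = FALSE)
  if (nrow(parents) && ncol(parents) != 2L)
    stop_domain("parent edges must have 2 columns (child, parent)")
  if (nrow(parents)) {
    parents[] <- lapply(parents, as.character)
    unknown <- setdiff(unique(unlist(parents)), terms)
    if (length(unknown))
      stop_domain("edges reference unknown terms: %s", paste(unknown, collapse = ", "))
  }
  plist <- if (nrow(parents)) split(parents[[2]], parents[[1]]) else list()

  anc <- new.env(parent = emptyenv())
  onstack <- new.env(parent = emptyenv())
  ancestors_of <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (!is.null(onstack[[t]])) stop_domain("ontology contains a cycle through term '%s'", t)
    onstack[[t]] <- TRUE
    out <- t
    for (p in plist[[t]]) out <- union(out, ancestors_of(p))
    rm(list = t, envir = onstack)
    anc[[t]] <- out
    out
  }
  ancestors <- stats::setNames(lapply(terms, ancestors_of), terms)
  structure(list(terms = terms, parents = plist, ancestors = ancestors),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d is_a edges\n",
              length(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

#' Terms in the subtree rooted at `roots` (descendants, self-inclusive)
#'
#' @param onto an [ontology()].
#' @param roots character vector of sub-ontology root term ids.
#' @export
ontology_descendants <- function(onto, roots) {
  names(Filter(function(a) any(roots %in% a), onto$ancestors))
}

#' Read a minimal OBO file
#'
#' Parses `[Term]` stanzas for `id:` and `is_a:` tags, skipping obsolete
#' terms.  This covers the subset of OBO needed to compute ancestor-based
#' semantic similarity.
#'
#' @param path OBO file path.
#' @return An [ontology()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character()
  edges <- list()
  cur <- NULL
  obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) terms[[length(terms) + 1L]] <<- cur
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur <- NULL; obsolete <- FALSE; in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      parent <- trimws(sub("^is_a:", "", ln))
      edges[[length(edges) + 1L]] <- c(cur, parent)
    } else if (in_term && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  edges <- if (length(edges)) do.call(rbind, edges) else matrix(character(), ncol = 2)
  # drop edges from obsolete children / to terms outside the kept set
  keep <- edges[, 1] %in% terms & edges[, 2] %in% terms
  ontology(terms, edges[keep, , drop = FALSE])
}

#' Write an ontology in minimal OBO format
#'
#' @param onto an [ontology()].
#' @param path output path.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in onto$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    for (p in onto$parents[[t]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Annotation corpus with information content
#'
#' Maps entities (genes or diseases) to ontology terms, propagates each
#' annotation to all ancestors, and computes per-term probabilities
#' P(C) = fraction of annotated entities whose propagated annotation set
#' contains C, and information content IC(C) = -log P(C).  The root of
#' the ontology is carried by every entity, so IC(root) = 0.
#'
#' @param onto an [ontology()].
#' @param annotations data frame with columns entity, term, and optional
#'   evidence and qualifier columns.
#' @param drop_iea drop annotations with evidence code `IEA` (on by
#'   default when an evidence column is present).
#' @param drop_not drop annotations whose qualifier contains `NOT`.
#' @param roots optional sub-ontology root whitelist: only terms that
#'   descend from one of these roots (self-inclusive) contribute.
#' @return An object of class `annotation_corpus` with fields `onto`,
#'   `terms` (entity -> direct annotated terms), `propagated`
#'   (entity -> ancestral closure of its terms), `p` and `ic`
#'   (named numeric vectors over annotated terms).
#' @export
annotation_corpus <- function(onto, annotations, drop_iea = TRUE,
                              drop_not = TRUE, roots = NULL) {
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) stop_domain("annotations need at least entity and term columns")
  names(ann)[1:2] <- c("entity", "term")
  if (drop_iea && ncol(ann) >= 3L) {
    ev <- toupper(trimws(as.character(ann[[3]])))
    ann <- ann[is.na(ev) | ev == "" | ev != "IEA", , drop = FALSE]
  }
  if (drop_not && ncol(ann) >= 4L) {
    qu <- toupper(as.character(ann[[4]]))
    ann <- ann[is.na(qu) | !grepl("NOT", qu), , drop = FALSE]
  }
  known <- ann$term %in% onto$terms
  if (any(!known)) {
    tt_log("dropped %d annotations to unknown terms", sum(!known))
    ann <- ann[known, , drop = FALSE]
  }
  if (!is.null(roots)) {
    allowed <- ontology_descendants(onto, roots)
    ann <- ann[ann$term %in% allowed, , drop = FALSE]
  }
  term_sets <- lapply(split(ann$term, ann$entity), unique)
  propagated <- lapply(term_sets, function(ts) {
    anc <- unique(unlist(onto$ancestors[ts], use.names = FALSE))
    if (!is.null(roots)) anc <- intersect(anc, ontology_descendants(onto, roots))
    anc
  })
  n_entities <- length(propagated)
  counts <- table(unlist(propagated, use.names = FALSE))
  p <- as.numeric(counts) / max(n_entities, 1L)
  names(p) <- names(counts)
  structure(
    list(onto = onto, terms = term_sets, propagated = propagated,
         p = p, ic = -log(p), roots = roots),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> %d entities, %d annotated terms\n",
              length(x$terms), length(x$p)))
  invisible(x)
}

#' Read an annotation table
#'
#' TSV with columns: entity id, term id, optional evidence code, optional
#' qualifier.  Filtering defaults follow [annotation_corpus()].
#'
#' @inheritParams annotation_corpus
#' @param path TSV path.
#' @export
read_annotation_table <- function(path, onto, drop_iea = TRUE, drop_not = TRUE,
                                  roots = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  annotation_corpus(onto, tab, drop_iea = drop_iea, drop_not = drop_not,
                    roots = roots)
}

#' Read an ATC code table
#'
#' TSV with columns drug id, ATC code; multiple rows per drug.
#'
#' @param path TSV path.
#' @return named list of character vectors (drug id -> codes).
#' @export
read_atc_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop_domain("ATC table needs drug and code columns")
  lapply(split(tab[[2]], tab[[1]]), function(x) validate_atc_codes(unique(x)))
}

#' Write an ATC code table
#'
#' @param codes named list of ATC code vectors.
#' @param path output path.
#' @export
write_atc_table <- function(codes, path) {
  tab <- data.frame(drug = rep(names(codes), lengths(codes)),
                    code = unlist(codes, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation table
#'
#' @param annotations data frame (entity, term, ...).
#' @param path output path.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Information-content semantic similarity of two ontology terms
#'
#' The ratio of summed information content over the terms' shared
#' ancestors to that over the union of their ancestors (ancestor sets are
#' self-inclusive).  Terms whose ancestors all have zero information
#' content (e.g. the root alone) score 0.
#'
#' @param corpus an [annotation_corpus()].
#' @param c1,c2 term ids.
#' @return similarity in `[0, 1]`.
#' @export
term_semantic_similarity <- function(corpus, c1, c2) {
  onto <- corpus$onto
  if (!c1 %in% onto$terms || !c2 %in% onto$terms)
    stop_domain("unknown ontology term(s): %s",
                paste(setdiff(c(c1, c2), onto$terms), collapse = ", "))
  a1 <- onto$ancestors[[c1]]
  a2 <- onto$ancestors[[c2]]
  if (!is.null(corpus$roots)) {
    allowed <- ontology_descendants(onto, corpus$roots)
    a1 <- intersect(a1, allowed)
    a2 <- intersect(a2, allowed)
  }
  ic <- function(ts) {
    v <- corpus$ic[ts]
    sum(v[is.finite(v)], na.rm = TRUE)
  }
  denom <- ic(union(a1, a2))
  if (denom == 0) return(0)
  ic(intersect(a1, a2)) / denom
}

#' Best-match-average entity similarity
#'
#' Entity-level semantic similarity: each term annotated to one entity is
#' matched with its most similar term on the other entity, and the two
#' directed sums are averaged over the total number of terms.
#'
#' @param corpus an [annotation_corpus()].
#' @param e1,e2 entity ids.
#' @return similarity in `[0, 1]`; 0 with a message if either entity has
#'   no annotations.
#' @export
bma_similarity <- function(corpus, e1, e2) {
  t1 <- corpus$terms[[e1]]
  t2 <- corpus$terms[[e2]]
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) {
    tt_log("entity '%s' has no annotations; similarity undefined, using 0",
           if (length(t1)) e2 else e1)
    return(0)
  }
  simt <- outer(t1, t2, Vectorize(function(x, y) term_semantic_similarity(corpus, x, y)))
  (sum(apply(simt, 1, max)) + sum(apply(simt, 2, max))) / (length(t1) + length(t2))
}

#' Combine similarity matrices across sub-ontologies
#'
#' Gene similarity is typically computed on two Gene Ontology
#' sub-ontologies (biological process and molecular function).  For each
#' entity pair the sub-ontology scores are averaged over the corpora in
#' which both entities carry annotations; when only one sub-ontology
#' defines the pair, that score is used; otherwise the pair scores 0.
#'
#' @param idx an [entity_index()].
#' @param corpora list of [annotation_corpus()] objects (one per
#'   sub-ontology).
#' @param ... passed to [build_similarity_matrix()].
#' @return a [similarity_matrix()].
#' @export
combine_subontology_similarities <- function(idx, corpora, ...) {
  stopifnot(length(corpora) >= 1L)
  mats <- lapply(corpora, function(cp) unclass(build_similarity_matrix(idx, cp, ...)))
  defined <- lapply(corpora, function(cp) {
    as.numeric(idx$ids %in% names(cp$terms) & lengths(cp$terms[idx$ids]) > 0)
  })
  acc <- matrix(0, idx$size, idx$size)
  wt <- matrix(0, idx$size, idx$size)
  for (s in seq_along(mats)) {
    d <- outer(defined[[s]], defined[[s]])  # 1 where both entities annotated
    acc <- acc + mats[[s]] * d
    wt <- wt + d
  }
  out <- ifelse(wt > 0, acc / pmax(wt, 1), 0)
  dimnames(out) <- list(idx$ids, idx$ids)
  diag(out) <- 1
  similarity_matrix(out, idx$role)
}

#' Build a full entity similarity matrix
#'
#' Applies the applicable pairwise kernel — multi-level ATC similarity
#' when `source` is a named list of ATC code sets, best-match-average
#' semantic similarity when `source` is an [annotation_corpus()] — to
#' every entity pair of `idx`.  Entities lacking features get a zero row
#' with diagonal 1.
#'
#' @param idx an [entity_index()].
#' @param source named list of ATC code vectors, or an
#'   [annotation_corpus()].
#' @param pair_whitelist optional data frame of id pairs; when given,
#'   only listed pairs are computed and all other off-diagonal entries
#'   are 0.
#' @return a [similarity_matrix()].
#' @export
build_similarity_matrix <- function(idx, source, pair_whitelist = NULL) {
  n <- idx$size
  m <- matrix(0, n, n, dimnames = list(idx$ids, idx$ids))
  diag(m) <- 1

  if (inherits(source, "annotation_corpus")) {
    has <- idx$ids %in% names(source$terms) & lengths(source$terms[idx$ids]) > 0
    kernel <- function(a, b) bma_similarity(source, a, b)
  } else {
    has <- idx$ids %in% names(source) & lengths(source[idx$ids]) > 0
    kernel <- function(a, b) atc_similarity(source[[a]], source[[b]])
  }
  if (!any(has)) {
    tt_log("no entity of role '%s' has features; similarity is the identity", idx$role)
    return(similarity_matrix(m, idx$role))
  }

  if (!is.null(pair_whitelist)) {
    wl <- as.data.frame(pair_whitelist, stringsAsFactors = FALSE)
    pairs <- cbind(match(wl[[1]], idx$ids), match(wl[[2]], idx$ids))
    pairs <- pairs[stats::complete.cases(pairs) & pairs[, 1] != pairs[, 2], , drop = FALSE]
  } else {
    pairs <- which(upper.tri(m), arr.ind = TRUE)
  }
  for (row in seq_len(nrow(pairs))) {
    ia <- pairs[row, 1]; ib <- pairs[row, 2]
    if (!has[ia] || !has[ib]) next
    s <- tryCatch(kernel(idx$ids[ia], idx$ids[ib]), error = function(e) {
      tt_log("similarity(%s, %s) failed: %s", idx$ids[ia], idx$ids[ib],
             conditionMessage(e))
      0
    })
    m[ia, ib] <- s
    m[ib, ia] <- s
  }
  similarity_matrix(m, idx$role)
}
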