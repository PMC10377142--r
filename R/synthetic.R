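# Self-contained synthetic benchmark generators: planted low-rank
# tensors with factor-derived similarity side information, toy ontology
# DAGs with annotations, and toy five-level ATC code sets.  Every module
# of the package can be exercised on these fixtures without downloads.

#' Generate a planted low-rank binary tensor with similarity side
#' information
#'
#' Draws non-negative CP factor matrices per role, scores every tensor
#' cell by the rank-R CP sum, and marks the top `n_positives` cells as
#' positive (ties broken in lexicographic (i, j, k) order).  Optional
#' label noise replaces a fraction of planted positives with uniformly
#' random free cells.  Per-role similarity matrices are the cosine
#' similarities of the ground-truth factor rows, so side information is
#' genuinely informative about the planted structure; with
#' `informative_sims = FALSE` they are random symmetric matrices instead
#' (an ablation control).
#'
#' @param shape integer `c(I, J, K)`.
#' @param rank planted CP rank.
#' @param n_positives number of positive cells.
#' @param factor_sparsity probability that a factor entry is zeroed.
#' @param noise fraction of planted positives replaced by random cells
#'   (label flip rate, in `[0, 0.5)`).
#' @param informative_sims derive similarities from the planted factors
#'   (default) or draw them at random.
#' @param seed RNG seed; all outputs are reproducible under it.
#' @return list with `tensor` ([triple_tensor()]), `factors` (list of
#'   the three ground-truth factor matrices), `sims` (list of three
#'   [similarity_matrix()]s), and `scores` (the dense CP score array).
#' @export
generate_planted_tensor <- function(shape, rank, n_positives,
                                    factor_sparsity = 0.3, noise = 0,
                                    informative_sims = TRUE, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, rank >= 1L, n_positives >= 1L,
            n_positives <= prod(as.numeric(shape)),
            noise >= 0, noise < 0.5, factor_sparsity >= 0, factor_sparsity < 1)
  with_seed(seed, {
    factors <- lapply(shape, function(n) {
      f <- matrix(stats::runif(n * rank), n, rank)
      f * (matrix(stats::runif(n * rank), n, rank) >= factor_sparsity)
    })
    names(factors) <- c("dr", "ge", "di")

    scores <- array(0, shape)
    for (r in seq_len(rank))
      scores <- scores + outer(outer(factors$dr[, r], factors$ge[, r]), factors$di[, r])

    idx <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                       k = seq_len(shape[3]))
    lex <- ((idx$i - 1) * shape[2] + (idx$j - 1)) * shape[3] + (idx$k - 1)
    ord <- order(-as.vector(scores[cbind(idx$i, idx$j, idx$k)]), lex)
    pos <- as.matrix(idx[ord[seq_len(n_positives)], ])

    if (noise > 0) {
      flip <- stats::runif(n_positives) < noise
      if (any(flip)) {
        keep <- pos[!flip, , drop = FALSE]
        free <- as.matrix(idx[-ord[seq_len(n_positives)], ])
        repl <- free[sample.int(nrow(free), sum(flip)), , drop = FALSE]
        pos <- rbind(keep, repl)
      }
    }

    sims <- lapply(c("dr", "ge", "di"), function(rl) {
      n <- nrow(factors[[rl]])
      if (informative_sims) {
        f <- factors[[rl]]
        nrm <- sqrt(rowSums(f^2))
        s <- tcrossprod(f) / pmax(outer(nrm, nrm), .Machine$double.eps)
        s[nrm == 0, ] <- 0
        s[, nrm == 0] <- 0
        diag(s) <- 1
      } else {
        r <- matrix(stats::runif(n * n), n, n)
        s <- (r + t(r)) / 2
        diag(s) <- 1
      }
      similarity_matrix(s, c(dr = "drug", ge = "gene", di = "disease")[[rl]])
    })
    names(sims) <- c("dr", "ge", "di")

    list(tensor = triple_tensor(shape, pos), factors = factors,
         sims = sims, scores = scores)
  })
}

#' Generate a toy ontology DAG with entity annotations
#'
#' Builds a complete tree of the given depth and branching factor
#' (depth 1 is the bare root), optionally adds extra cross edges to
#' deeper-to-shallower terms so the graph is a proper DAG, annotates
#' entities to random leaf terms, and computes the propagated annotation
#' corpus.
#'
#' @param depth number of levels including the root.
#' @param branching children per internal term.
#' @param n_entities number of annotated entities.
#' @param terms_per_entity leaf terms annotated to each entity.
#' @param extra_edges number of additional random DAG edges.
#' @param seed RNG seed.
#' @return list with `onto` ([ontology()]), `corpus`
#'   ([annotation_corpus()]) and `annotations` (the entity/term data
#'   frame).
#' @export
generate_toy_ontology <- function(depth = 4L, branching = 2L, n_entities = 10L,
                                  terms_per_entity = 2L, extra_edges = 0L,
                                  seed = 1L) {
  stopifnot(depth >= 1L, branching >= 1L, n_entities >= 1L,
            terms_per_entity >= 1L)
  with_seed(seed, {
    terms <- character()
    level <- integer()
    edges <- list()
    counter <- 0L
    new_term <- function() {
      counter <<- counter + 1L
      sprintf("T:%07d", counter)
    }
    root <- new_term()
    terms <- root; level <- 0L
    frontier <- root
    for (d in seq_len(depth - 1L)) {
      nxt <- character()
      for (parent in frontier) {
        for (b in seq_len(branching)) {
          ch <- new_term()
          terms <- c(terms, ch)
          level <- c(level, d)
          edges[[length(edges) + 1L]] <- c(ch, parent)
          nxt <- c(nxt, ch)
        }
      }
      frontier <- nxt
    }
    if (extra_edges > 0L && depth > 2L) {
      deep <- terms[level >= 2L]
      for (x in seq_len(extra_edges)) {
        ch <- sample(deep, 1L)
        shallower <- terms[level < level[match(ch, terms)]]
        edges[[length(edges) + 1L]] <- c(ch, sample(shallower, 1L))
      }
    }
    edges <- unique(do.call(rbind, edges) %||% matrix(character(), ncol = 2))
    onto <- ontology(terms, edges)

    leaves <- terms[level == max(level)]
    ann <- do.call(rbind, lapply(seq_len(n_entities), function(e) {
      data.frame(entity = sprintf("E%03d", e),
                 term = sample(leaves, min(terms_per_entity, length(leaves))))
    }))
    list(onto = onto, corpus = annotation_corpus(onto, ann), annotations = ann)
  })
}

#' Generate toy ATC code sets
#'
#' Synthesizes valid 7-character ATC-style codes arranged in families:
#' drugs within a family share their code prefixes through
#' `shared_level`, and families are disjoint at level 1.
#'
#' @param n_drugs number of drugs (assigned to families round-robin).
#' @param n_families number of families (at most 26).
#' @param codes_per_drug ATC codes per drug.
#' @param shared_level level (1-5) through which family members share
#'   prefixes; 5 makes all codes within a family identical.
#' @param seed RNG seed.
#' @return named list: drug id -> character vector of codes, with a
#'   `family` attribute mapping drugs to families.
#' @export
generate_toy_atc <- function(n_drugs = 10L, n_families = 3L,
                             codes_per_drug = 1L, shared_level = 5L,
                             seed = 1L) {
  stopifnot(n_families >= 1L, n_families <= 26L, shared_level %in% 1:5,
            n_drugs >= 1L, codes_per_drug >= 1L)
  with_seed(seed, {
    fam_prefix <- lapply(seq_len(n_families), function(f) {
      c(LETTERS[f], sprintf("%02d", sample.int(99, 1)),
        sample(LETTERS, 1), sample(LETTERS, 1), sprintf("%02d", sample.int(99, 1)))
    })
    fam_of <- rep(seq_len(n_families), length.out = n_drugs)
    piece_pool <- list(LETTERS, sprintf("%02d", 1:99), LETTERS, LETTERS,
                       sprintf("%02d", 1:99))
    codes <- lapply(seq_len(n_drugs), function(d) {
      f <- fam_of[d]
      vapply(seq_len(codes_per_drug), function(cidx) {
        pieces <- fam_prefix[[f]]
        if (shared_level < 5L) {
          for (lv in (shared_level + 1L):5L) {
            # diverge beyond the shared level, unique-ish per drug/code
            pool <- setdiff(piece_pool[[lv]], pieces[lv])
            pieces[lv] <- sample(pool, 1L)
          }
        }
        paste(pieces, collapse = "")
      }, character(1))
    })
    names(codes) <- sprintf("D%03d", seq_len(n_drugs))
    codes <- lapply(codes, unique)
    attr(codes, "family") <- stats::setNames(fam_of, names(codes))
    codes
  })
}
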