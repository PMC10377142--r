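# Independent brute-force oracles and small fixture builders shared by
# the module and acceptance tests.  These deliberately use naive loops
# and explicit enumerations, not the package's own code paths.

# Exhaustive pairwise-comparison AUC: every (positive, negative) pair,
# ties counting one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Direct evaluation of the DCG/IDCG ratio on a relevance list.
oracle_ndcg <- function(rel, n) {
  dcg <- 0; idcg <- 0
  ideal <- sort(rel, decreasing = TRUE)
  for (i in seq_len(min(n, length(rel)))) {
    dcg <- dcg + rel[i] / log2(i + 1)
    idcg <- idcg + ideal[i] / log2(i + 1)
  }
  if (idcg == 0) 0 else dcg / idcg
}

# CP model scores by an explicit loop over ranks (sum-of-rank-one form:
# x_ijk = sum_r a_ir b_jr c_kr).
oracle_cp_cell <- function(A, B, C, i, j, k) {
  s <- 0
  for (r in seq_len(ncol(A))) s <- s + A[i, r] * B[j, r] * C[k, r]
  s
}

# Triangle closure by exhaustive scan over every (i, j, k) cell.
oracle_triple_intersection <- function(dd, dg, sg, I, J, K) {
  has <- function(m, a, b) any(m[, 1] == a & m[, 2] == b)
  out <- NULL
  for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K)) {
    if (has(dd, i, k) && has(dg, i, j) && has(sg, k, j))
      out <- rbind(out, c(i, j, k))
  }
  if (is.null(out)) matrix(integer(), ncol = 3) else out
}

# Level-k ATC Jaccard from first principles (explicit prefix sets).
oracle_atc_level <- function(a, b, k) {
  cut <- c(1, 3, 4, 5, 7)[k]
  pa <- unique(substr(a, 1, cut))
  pb <- unique(substr(b, 1, cut))
  length(intersect(pa, pb)) / length(union(pa, pb))
}

oracle_atc <- function(a, b) mean(sapply(1:5, function(k) oracle_atc_level(a, b, k)))

# Ancestor closure by repeated expansion over an explicit edge matrix
# (child in column 1, parent in column 2); self-inclusive.
oracle_ancestors <- function(term, edges) {
  anc <- term
  repeat {
    more <- edges[edges[, 1] %in% anc, 2]
    new <- setdiff(more, anc)
    if (!length(new)) return(anc)
    anc <- c(anc, new)
  }
}

# Term IC-ratio similarity from explicit ancestor sets and a named IC
# vector (unannotated ancestors contribute 0).
oracle_term_sim <- function(c1, c2, edges, ic) {
  a1 <- oracle_ancestors(c1, edges)
  a2 <- oracle_ancestors(c2, edges)
  val <- function(ts) sum(ic[intersect(ts, names(ic))])
  denom <- val(union(a1, a2))
  if (denom == 0) 0 else val(intersect(a1, a2)) / denom
}

# Best-match average by an explicit double loop with row/column maxima.
oracle_bma <- function(t1, t2, term_sim_fun) {
  m <- matrix(0, length(t1), length(t2))
  for (x in seq_along(t1)) for (y in seq_along(t2))
    m[x, y] <- term_sim_fun(t1[x], t2[y])
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (length(t1) + length(t2))
}

# Random symmetric similarity matrices for model fixtures.
random_sims <- function(dims, seed = 1) {
  set.seed(seed)
  out <- lapply(dims, function(n) {
    r <- matrix(runif(n * n), n, n)
    s <- (r + t(r)) / 2
    diag(s) <- 1
    s
  })
  names(out) <- c("dr", "ge", "di")
  out
}

random_triples <- function(dims, n, seed = 1) {
  set.seed(seed)
  data.frame(i = sample(dims[1], n, TRUE), j = sample(dims[2], n, TRUE),
             k = sample(dims[3], n, TRUE))
}

# A six-term hand-laid-out DAG:   R <- A <- C ; R <- B ; A,B <- D ; A <- E
# (D has two parents).  Used wherever a fully enumerable ontology is
# needed.
toy_dag <- function() {
  edges <- rbind(c("A", "R"), c("B", "R"), c("C", "A"),
                 c("D", "A"), c("D", "B"), c("E", "A"))
  list(terms = c("R", "A", "B", "C", "D", "E"), edges = edges)
}
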