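#' Entity index
#'
#' An ordered, unique set of external identifiers for one entity role
#' (drug, gene or disease).  Positions in the index are the integer
#' coordinates used everywhere inside the package; external identifier
#' strings appear only at I/O boundaries.
#'
#' @param ids character vector of external identifiers.
#' @param role one of `"drug"`, `"gene"`, `"disease"`.
#' @return An object of class `entity_index` with fields `role`, `ids`
#'   and `size`.
#' @export
entity_index <- function(ids, role = c("drug", "gene", "disease")) {
  role <- match.arg(role)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_domain("entity ids must be unique (role '%s')", role)
  structure(
    list(role = role, ids = ids, size = length(ids),
         lookup = stats::setNames(seq_along(ids), ids)),
    class = "entity_index"
  )
}

#' @export
print.entity_index <- function(x, ...) {
  cat(sprintf("<entity_index> role=%s size=%d\n", x$role, x$size))
  invisible(x)
}

# Map external ids to integer positions; unresolvable ids become NA.
resolve_ids <- function(idx, ids) unname(idx$lookup[as.character(ids)])

#' Association list
#'
#' A deduplicated set of bipartite identifier pairs of a given kind.
#'
#' @param pairs data frame (or matrix) with two character columns.
#' @param kind one of `"drug-disease"`, `"drug-gene"`, `"disease-gene"`.
#' @export
association_list <- function(pairs, kind = c("drug-disease", "drug-gene", "disease-gene")) {
  kind <- match.arg(kind)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) != 2L) stop_domain("association pairs must have exactly 2 columns")
  pairs[] <- lapply(pairs, as.character)
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  structure(list(kind = kind, pairs = pairs), class = "association_list")
}

#' @export
print.association_list <- function(x, ...) {
  cat(sprintf("<association_list> kind=%s n=%d\n", x$kind, nrow(x$pairs)))
  invisible(x)
}

#' Read a pairwise association table
#'
#' Reads a tab-delimited edge list with a header row naming the two
#' identifier columns, deduplicates it and reports the row count.
#'
#' @param path path to a TSV file.
#' @param kind association kind, see [association_list()].
#' @return An [association_list()].
#' @export
read_association_table <- function(path, kind = c("drug-disease", "drug-gene", "disease-gene")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L)
    stop_domain("malformed association table '%s': expected 2 identifier columns, found %d",
                path, ncol(tab))
  if (ncol(tab) > 2L) tab <- tab[, 1:2]
  if (nrow(tab) == 0L) warning(sprintf("association table '%s' is empty", path))
  out <- association_list(tab, kind)
  tt_log("read %d rows (%d unique pairs) from %s", nrow(tab), nrow(out$pairs), path)
  out
}

#' Write a pairwise association table
#'
#' @param x an [association_list()].
#' @param path output TSV path.
#' @param col_names header names for the two identifier columns; defaults
#'   are derived from `x$kind`.
#' @export
write_association_table <- function(x, path, col_names = NULL) {
  stopifnot(inherits(x, "association_list"))
  if (is.null(col_names)) col_names <- strsplit(x$kind, "-", fixed = TRUE)[[1]]
  tab <- x$pairs
  names(tab) <- col_names
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sparse binary drug-gene-disease tensor
#'
#' The three-way association tensor is stored as its positive cells only:
#' an n-by-3 integer matrix of (drug, gene, disease) coordinates into the
#' three entity indexes.  All other cells are implicitly zero.
#'
#' @param shape integer vector `c(I, J, K)`: numbers of drugs, genes and
#'   diseases.
#' @param positives n-by-3 matrix of integer coordinates (columns i, j, k).
#' @export
triple_tensor <- function(shape, positives) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 0L))
  positives <- matrix(as.integer(positives), ncol = 3L,
                      dimnames = list(NULL, c("i", "j", "k")))
  if (nrow(positives)) {
    ok <- positives[, 1] >= 1L & positives[, 1] <= shape[1] &
          positives[, 2] >= 1L & positives[, 2] <= shape[2] &
          positives[, 3] >= 1L & positives[, 3] <= shape[3]
    if (!all(ok)) stop_domain("tensor positives contain out-of-range indices")
    positives <- positives[!duplicated(positives), , drop = FALSE]
    positives <- positives[order(positives[, 1], positives[, 2], positives[, 3]), , drop = FALSE]
  }
  structure(list(shape = shape, positives = positives), class = "triple_tensor")
}

#' @export
print.triple_tensor <- function(x, ...) {
  cat(sprintf("<triple_tensor> %dx%dx%d, %d positives (density %.3g)\n",
              x$shape[1], x$shape[2], x$shape[3], nrow(x$positives),
              tensor_density(x)))
  invisible(x)
}

#' @rdname triple_tensor
#' @param x a `triple_tensor`.
#' @export
tensor_density <- function(x) {
  cells <- prod(as.numeric(x$shape))
  if (cells == 0) return(0)
  nrow(x$positives) / cells
}

# Linearize (i,j,k) to a scalar cell id (double precision; supports
# tensors up to ~2^53 cells).
cell_id <- function(ijk, shape) {
  (as.numeric(ijk[, 1]) - 1) +
    as.numeric(shape[1]) * ((as.numeric(ijk[, 2]) - 1) +
    as.numeric(shape[2]) * (as.numeric(ijk[, 3]) - 1))
}

cell_coords <- function(id, shape) {
  i <- id %% shape[1]
  rest <- (id - i) / shape[1]
  j <- rest %% shape[2]
  k <- (rest - j) / shape[2]
  cbind(i = as.integer(i) + 1L, j = as.integer(j) + 1L, k = as.integer(k) + 1L)
}

#' Build the drug-gene-disease tensor from pairwise associations
#'
#' A cell (i, j, k) is set to 1 exactly when all three pairwise links
#' exist: drug i treats disease k, drug i binds gene j, and disease k is
#' caused by gene j (a closed triangle in the three bipartite graphs).
#'
#' @param dd drug-disease [association_list()] (columns: drug, disease).
#' @param dg drug-gene [association_list()] (columns: drug, gene).
#' @param sg disease-gene [association_list()] (columns: disease, gene).
#' @param idx_d,idx_g,idx_s entity indexes for drugs, genes and diseases.
#' @param min_gene_degree optional preprocessing filter: genes with fewer
#'   than this many drug-gene or disease-gene associations are dropped
#'   before triangle closure.  Default 0 (off).
#' @return A [triple_tensor()] of shape (drugs, genes, diseases).
#' @export
build_triple_tensor <- function(dd, dg, sg, idx_d, idx_g, idx_s,
                                min_gene_degree = 0L) {
  stopifnot(dd$kind == "drug-disease", dg$kind == "drug-gene", sg$kind == "disease-gene")

  resolve_pairs <- function(al, idx_a, idx_b, label) {
    a <- resolve_ids(idx_a, al$pairs[[1]])
    b <- resolve_ids(idx_b, al$pairs[[2]])
    drop <- is.na(a) | is.na(b)
    if (any(drop)) tt_log("dropped %d %s pairs with unresolvable ids", sum(drop), label)
    cbind(a[!drop], b[!drop])
  }

  dd_ik <- resolve_pairs(dd, idx_d, idx_s, "drug-disease")
  dg_ij <- resolve_pairs(dg, idx_d, idx_g, "drug-gene")
  sg_kj <- resolve_pairs(sg, idx_s, idx_g, "disease-gene")

  if (min_gene_degree > 0L) {
    deg <- tabulate(c(dg_ij[, 2], sg_kj[, 2]), nbins = idx_g$size)
    keep <- deg >= min_gene_degree
    dg_ij <- dg_ij[keep[dg_ij[, 2]], , drop = FALSE]
    sg_kj <- sg_kj[keep[sg_kj[, 2]], , drop = FALSE]
    tt_log("gene degree filter (< %d): kept %d of %d genes", min_gene_degree,
           sum(keep), idx_g$size)
  }

  genes_of_drug <- split(dg_ij[, 2], dg_ij[, 1])
  genes_of_disease <- split(sg_kj[, 2], sg_kj[, 1])

  pos <- vector("list", nrow(dd_ik))
  for (row in seq_len(nrow(dd_ik))) {
    i <- dd_ik[row, 1]; k <- dd_ik[row, 2]
    js <- intersect(genes_of_drug[[as.character(i)]],
                    genes_of_disease[[as.character(k)]])
    if (length(js)) pos[[row]] <- cbind(i, js, k)
  }
  pos <- do.call(rbind, pos)
  if (is.null(pos)) pos <- matrix(integer(), ncol = 3L)
  out <- triple_tensor(c(idx_d$size, idx_g$size, idx_s$size), pos)
  if (nrow(out$positives) == 0L)
    warning("triangle closure produced an empty tensor (no triple associations)")
  out
}

#' Similarity matrix constructor
#'
#' Validates and normalizes a square entity-similarity matrix: the matrix
#' is symmetrized by averaging (with a warning when the asymmetry exceeds
#' `1e-8`), min-max rescaled over the off-diagonal entries when any value
#' falls outside `[0, 1]`, and its diagonal is forced to 1.
#'
#' @param values square numeric matrix; dimnames, if present, must agree
#'   between rows and columns.
#' @param role entity role of both axes.
#' @return The normalized matrix with class `similarity_matrix` and a
#'   `role` attribute.
#' @export
similarity_matrix <- function(values, role = c("drug", "gene", "disease")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_domain("similarity matrix must be square")
  if (!is.null(rownames(values)) && !is.null(colnames(values)) &&
      !identical(rownames(values), colnames(values)))
    stop_domain("similarity matrix row/column identifiers disagree")
  if (nrow(values)) {
    asym <- max(abs(values - t(values)))
    if (asym > 1e-8)
      warning(sprintf("similarity matrix asymmetric (max dev %.3g); symmetrized by averaging", asym))
    values <- (values + t(values)) / 2
    off <- values[row(values) != col(values)]
    if (length(off) && (min(values) < 0 || max(values) > 1)) {
      rng <- range(off)
      if (diff(rng) > 0) {
        values <- (values - rng[1]) / diff(rng)
      } else {
        values[] <- pmin(pmax(values, 0), 1)
      }
    }
    values[values < 0] <- 0
    values[values > 1] <- 1
    diag(values) <- 1
  }
  structure(values, class = c("similarity_matrix", "matrix"), role = role)
}

#' Read an entity similarity matrix
#'
#' Reads a TSV with row and column identifier headers, reindexes it to the
#' order of `idx`, and normalizes it via [similarity_matrix()].
#' Identifiers absent from the file get a zero row/column with diagonal 1.
#'
#' @param path TSV path (first column holds row identifiers).
#' @param idx target [entity_index()].
#' @export
read_similarity_matrix <- function(path, idx) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1L)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop_domain("similarity matrix '%s' contains non-numeric values", path)
  out <- matrix(0, idx$size, idx$size, dimnames = list(idx$ids, idx$ids))
  have <- intersect(idx$ids, intersect(rownames(m), colnames(m)))
  missing <- setdiff(idx$ids, have)
  if (length(missing))
    tt_log("%d of %d %s ids absent from %s; rows filled with zeros",
           length(missing), idx$size, idx$role, path)
  out[have, have] <- m[have, have]
  diag(out) <- 1
  similarity_matrix(out, idx$role)
}

#' Write a similarity matrix as TSV
#'
#' @param x a `similarity_matrix` (or plain matrix with dimnames).
#' @param path output path.
#' @export
write_similarity_matrix <- function(x, path) {
  m <- unclass(x)
  utils::write.table(
    data.frame(id = rownames(m) %||% seq_len(nrow(m)), m, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
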