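#' Read a rooted phylogenetic tree
#'
#' Thin wrapper over `ape::read.tree` that enforces the requirements of the
#' Brownian covariance construction: a rooted tree, unique tip labels and a
#' branch length on every edge (missing lengths are rejected rather than
#' defaulted, since they would silently change the covariance).
#'
#' @param text newick string, or `NULL` to read from `file`.
#' @param file path to a newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  ## ape warns and returns NULL on bad input; we turn that into an error
  tree <- suppressWarnings(
    if (!is.null(text)) ape::read.tree(text = text)
    else ape::read.tree(file = file))
  if (is.null(tree)) stop("malformed newick input", call. = FALSE)
  .validate_tree(tree)
  tree
}

.validate_tree <- function(tree) {
  .assert(inherits(tree, "phylo"), "not a phylogenetic tree")
  .assert(!is.null(tree$edge.length) &&
            length(tree$edge.length) == nrow(tree$edge) &&
            all(is.finite(tree$edge.length)),
          "tree must carry a branch length on every edge")
  .assert(all(tree$edge.length >= 0), "negative branch length")
  .unique_labels(tree$tip.label, "tip")
  ## the basal node of the newick string serves as the root; a basal
  ## polytomy (e.g. a star tree) is acceptable for the Brownian rule
  invisible(tree)
}

#' Brownian-motion species covariance
#'
#' Under a Brownian trait-evolution model on a rooted tree, the covariance of
#' two taxa equals the shared branch length from the root down to their most
#' recent common ancestor; the variance of a taxon is its root-to-tip path
#' length. Non-ultrametric trees are accepted (the diagonal need not be
#' constant).
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param taxa_order character vector of tip labels selecting and ordering the
#'   rows/columns; defaults to the tree's tip order.
#' @param normalize_height if `TRUE`, rescale branch lengths so the maximum
#'   root-to-tip distance is 1 (useful to compare trees on a common scale);
#'   default `FALSE`, raw branch lengths.
#' @return a symmetric S x S matrix with `taxa_order` dimnames.
#' @export
brownian_covariance <- function(tree, taxa_order = tree$tip.label,
                                normalize_height = FALSE) {
  .validate_tree(tree)
  .assert(all(taxa_order %in% tree$tip.label),
          "taxa not in tree: %s",
          paste(setdiff(taxa_order, tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)     # root-to-node path length
  if (normalize_height) depth <- depth / max(depth[seq_len(ntip)])
  idx <- match(taxa_order, tree$tip.label)
  if (length(idx) == 1L) {
    V <- matrix(depth[idx], 1L, 1L)
  } else {
    anc <- ape::mrca(tree)                      # tip x tip MRCA node ids
    V <- matrix(depth[anc[idx, idx]], length(idx), length(idx))
    diag(V) <- depth[idx]
  }
  dimnames(V) <- list(taxa_order, taxa_order)
  V
}

#' Model covariance for the log-ratio likelihood
#'
#' Builds the (S-1) x (S-1) covariance entering the multivariate-Gaussian
#' log-ratio likelihood: the full-species Brownian covariance with the
#' reference taxon's row and column dropped, scaled by `scale_c`. When no
#' tree is available, the identity is used. A small ridge
#' (1e-8 x mean diagonal) guards against exactly singular matrices from
#' zero-length branches.
#'
#' @param full S x S covariance with taxon dimnames (from
#'   [brownian_covariance]), or `NULL` for the no-tree identity case.
#' @param reference_taxon label of the reference taxon to drop. Required with
#'   a tree; ignored when `full` is `NULL`.
#' @param scale_c positive scaling constant c multiplying the covariance;
#'   c = 1 is the default and fit the benchmark datasets well.
#' @param taxon_ids for the `full = NULL` case: the S-1 non-reference labels.
#' @return an object of class `species_covariance` with fields `values`,
#'   `taxon_ids`, `scale_c`.
#' @export
model_covariance <- function(full = NULL, reference_taxon = NULL, scale_c = 1,
                             taxon_ids = NULL) {
  .assert(is.numeric(scale_c) && length(scale_c) == 1L && scale_c > 0,
          "scale_c must be a positive scalar")
  if (is.null(full)) {
    .assert(!is.null(taxon_ids), "taxon_ids required when no tree is supplied")
    V <- diag(length(taxon_ids))
    dimnames(V) <- list(taxon_ids, taxon_ids)
  } else {
    .assert(is.matrix(full) && !is.null(rownames(full)),
            "full covariance must be a labeled matrix")
    .assert(max(abs(full - t(full))) < 1e-10, "covariance must be symmetric")
    .assert(reference_taxon %in% rownames(full),
            "reference taxon '%s' not among covariance labels", reference_taxon)
    keep <- setdiff(rownames(full), reference_taxon)
    .assert(is.null(taxon_ids) || identical(taxon_ids, keep),
            "taxon_ids disagree with covariance labels")
    V <- full[keep, keep, drop = FALSE]
  }
  species_covariance(scale_c * V, rownames(V), scale_c)
}

#' @rdname model_covariance
#' @param values the (S-1) x (S-1) covariance matrix (already scaled).
#' @export
species_covariance <- function(values, taxon_ids = rownames(values),
                               scale_c = 1) {
  values <- as.matrix(values)
  .assert(max(abs(values - t(values))) < 1e-10, "covariance must be symmetric")
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  .assert(min(ev) >= -1e-8 * max(abs(ev)), "covariance is not PSD")
  taxon_ids <- as.character(taxon_ids %||% paste0("taxon", seq_len(ncol(values))))
  dimnames(values) <- list(taxon_ids, taxon_ids)
  structure(list(values = values, taxon_ids = taxon_ids, scale_c = scale_c),
            class = "species_covariance")
}

## Ridge-stabilised Cholesky pieces cached for repeated MVN evaluations.
.cov_factor <- function(cov) {
  V <- cov$values
  ridge <- 1e-8 * mean(diag(V))
  Vr <- V + diag(ridge, nrow(V))
  U <- chol(Vr)
  list(U = U, omega = chol2inv(U), logdet = 2 * sum(log(diag(U))))
}

#' @rdname model_covariance
#' @param x a `species_covariance`.
#' @param path output TSV path (labeled matrix).
#' @export
write_covariance <- function(x, path) {
  .write_labeled_matrix(x$values, path, "taxon")
}
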