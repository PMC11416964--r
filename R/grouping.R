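# Germplasm grouping: p-distances, neighbor-joining tree, cluster-based
# or user-supplied group labels.

#' Pairwise p-distance matrix between lines
#'
#' `d_ij = mean(|d_i - d_j| / 2)` over the markers where both lines are
#' observed - the complement of IBS similarity. For fully inbred lines
#' this is the proportion of markers at which the two lines carry
#' different alleles.
#'
#' @param g genotype matrix, missing allowed (pairwise-complete markers).
#' @return symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
p_distance_matrix <- function(g) {
  d <- 1 - compute_ibs(g)
  diag(d) <- 0
  attr(d, "kind") <- NULL
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj()`). On an additive (tree
#' metric) input the true topology and branch lengths are recovered
#' exactly. Negative branch lengths can arise on non-additive inputs and
#' are kept as computed, flagged in the `negative_branch_lengths`
#' attribute rather than clamped.
#'
#' @param d symmetric distance matrix (>= 3 taxa) with ids as dimnames.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3) abort("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(d < -1e-12)) abort("distances must be non-negative")
  tree <- ape::nj(as.dist(d))
  attr(tree, "negative_branch_lengths") <- any(tree$edge.length < 0)
  tree
}

#' Write / read a tree as Newick
#'
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Assign lines to germplasm groups by clustering
#'
#' Average-linkage hierarchical clustering on the distance matrix, cut
#' into `k` clusters; labels `group_1..group_k` are ordered by cluster
#' size descending (ties by first line id), so the assignment is
#' deterministic.
#'
#' @param d distance matrix.
#' @param k number of groups (1..n).
#' @return a `group_assignment` tibble `(line_id, group)` with attributes
#'   `k` and `source = "clustering"`.
#' @export
assign_groups <- function(d, k) {
  n <- nrow(d)
  if (k < 1 || k > n) abort("k must be between 1 and the number of lines")
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, k = k)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(paste0("group_", seq_along(sizes)), names(sizes))
  out <- tibble::tibble(line_id = rownames(d),
                        group = unname(relabel[as.character(cl)]))
  attr(out, "k") <- k
  attr(out, "source") <- "clustering"
  class(out) <- c("group_assignment", class(out))
  out
}

#' Load (or save) germplasm group labels
#'
#' Two-column tab-separated file: line id, group label.
#'
#' @param path file path.
#' @param line_ids optional full set of line ids; the file must label each
#'   of them.
#' @return a `group_assignment` tibble with `source = "user"`.
#' @export
load_groups <- function(path, line_ids = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("line_id", "group")
  if (anyDuplicated(tab$line_id)) abort("duplicate line id in group file")
  if (!is.null(line_ids)) {
    miss <- setdiff(line_ids, tab$line_id)
    if (length(miss)) {
      abort(paste0("group file missing line(s): ", paste(head(miss, 5), collapse = ", ")))
    }
    unknown <- setdiff(tab$line_id, line_ids)
    if (length(unknown)) {
      abort(paste0("group file has unknown line(s): ", paste(head(unknown, 5), collapse = ", ")))
    }
  }
  out <- tibble::as_tibble(tab[, c("line_id", "group")])
  attr(out, "k") <- length(unique(out$group))
  attr(out, "source") <- "user"
  class(out) <- c("group_assignment", class(out))
  out
}

#' @rdname load_groups
#' @param groups a `group_assignment` tibble.
#' @export
write_groups <- function(groups, path) {
  write.table(groups[, c("line_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Agreement between two group assignments
#'
#' Adjusted Rand index between two labelings of the same lines; 1 means
#' identical partitions (up to label permutation), 0 is chance level.
#'
#' @param a,b group assignments (tibbles or named vectors).
#' @return numeric scalar.
#' @export
group_agreement <- function(a, b) {
  if (is.data.frame(a)) a <- setNames(a$group, a$line_id)
  if (is.data.frame(b)) b <- setNames(b$group, b$line_id)
  ids <- intersect(names(a), names(b))
  if (!length(ids)) abort("no shared line ids")
  x <- as.integer(factor(a[ids]))
  y <- as.integer(factor(b[ids]))
  tab <- table(x, y)
  n <- length(ids)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  expected <- sum_i * sum_j / (n * (n - 1) / 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
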