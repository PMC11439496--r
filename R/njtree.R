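#' Neighbour-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbour joining with deterministic behaviour: ties
#' in the Q criterion are broken by the lexicographically smallest label pair
#' (each cluster is labelled by the smallest tip label it contains), and
#' negative branch-length estimates are clamped to zero with the deficit
#' transferred to the sibling branch (their sum is preserved).  On an
#' additive distance matrix the true tree and its branch lengths are
#' recovered exactly.
#'
#' @param D symmetric numeric matrix with zero diagonal, non-negative finite
#'   entries and at least 3 labelled rows.
#' @return An unrooted \code{phylo} tree (\pkg{ape}).
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stopf("D must be a square matrix")
  if (is.null(rownames(D))) stopf("D must have row labels")
  if (max(abs(D - t(D))) > 1e-9) stopf("distance matrix is not symmetric")
  if (any(!is.finite(D)) || any(D < 0)) stopf("distances must be finite and >= 0")
  n0 <- nrow(D)
  if (n0 < 3) stopf("need at least 3 taxa")

  labs <- rownames(D)
  nodes <- paste0("t", seq_len(n0))          # newick fragments (placeholders)
  minlab <- labs                              # smallest true label per cluster
  d <- unname(D)

  fmt <- function(x) sprintf("%.12g", x)
  while (length(nodes) > 3) {
    n <- length(nodes)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(minlab[ij[1]], minlab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    others <- setdiff(seq_len(n), c(i, j))
    dnew <- (d[i, others] + d[j, others] - d[i, j]) / 2
    dnew <- pmax(dnew, 0)
    d <- rbind(cbind(d[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    nodes <- c(nodes[others], new_node)
    minlab <- c(minlab[others], min(minlab[c(i, j)]))
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[1], fmt(max(la, 0)), nodes[2], fmt(max(lb, 0)),
                 nodes[3], fmt(max(lc, 0)))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labs[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

# tips descending from the child node of every edge
edge_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2]]])
}

# canonical keys for the non-trivial bipartitions of an unrooted tree
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  sets <- edge_tip_sets(tree)
  keys <- vapply(sets, function(s) {
    if (length(s) < 2 || length(s) > ntip - 2) return(NA_character_)
    if (ref %in% s) s <- setdiff(tree$tip.label, s)
    paste(sort(s), collapse = "\r")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Terminal branch lengths of a tree
#'
#' @param tree a \code{phylo}.
#' @return Named numeric vector, one entry per tip.
#' @export
terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= ntip
  setNames(tree$edge.length[term], tree$tip.label[tree$edge[term, 2]])
}

#' Tips whose terminal branch exceeds a threshold
#'
#' Implements the long-branch rule of the curation screen: a tip is
#' divergent when its terminal branch length is strictly greater than the
#' threshold (a branch of exactly the threshold is retained).
#'
#' @param tree a \code{phylo} with branch lengths in substitutions per site.
#' @param threshold branch-length threshold (default 1.0).
#' @return Named numeric vector of offending terminal branch lengths, sorted
#'   decreasing.
#' @export
long_terminal_branches <- function(tree, threshold = 1.0) {
  tb <- terminal_branch_lengths(tree)
  sort(tb[tb > threshold], decreasing = TRUE)
}

#' Bootstrap support for a neighbour-joining screening tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance neighbour-joining tree per replicate, and reports for
#' each internal bipartition of the point-estimate tree the fraction of
#' replicate trees containing it.  Deterministic for a given seed.
#'
#' @param msa a \code{b12_msa}.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed.
#' @param p_cap saturation cap passed to [poisson_distance()].
#' @return The point-estimate \code{phylo} with an added \code{split_support}
#'   data.frame attribute (\code{tips}, \code{support}) and node labels set
#'   to support values.
#' @export
bootstrap_support <- function(msa, n_reps = 100, seed = 1, p_cap = 0.95) {
  stopifnot(n_reps >= 1)
  point <- nj_tree(suppressWarnings(poisson_distance(msa, p_cap)))
  keys <- tree_splits(point)
  counts <- setNames(numeric(length(keys)), keys)
  m <- msa_matrix(msa)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_msa <- matrix_msa(m[, cols, drop = FALSE])
    rep_tree <- try(nj_tree(suppressWarnings(poisson_distance(rep_msa, p_cap))),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    hit <- intersect(keys, tree_splits(rep_tree))
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_reps
  # node labels: support of the edge subtending each internal node
  ntip <- length(point$tip.label)
  ref <- min(point$tip.label)
  sets <- edge_tip_sets(point)
  point$node.label <- rep(NA_character_, point$Nnode)
  for (e in seq_len(nrow(point$edge))) {
    ch <- point$edge[e, 2]
    if (ch <= ntip) next
    s <- sets[[e]]
    if (length(s) < 2 || length(s) > ntip - 2) next
    if (ref %in% s) s <- setdiff(point$tip.label, s)
    key <- paste(sort(s), collapse = "\r")
    point$node.label[ch - ntip] <- format(support[[key]], digits = 3)
  }
  attr(point, "split_support") <-
    data.frame(tips = gsub("\r", ",", names(support)),
               support = unname(support), stringsAsFactors = FALSE)
  point
}
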