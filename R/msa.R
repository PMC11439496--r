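#' Multiple alignment container
#'
#' Alignments are named character vectors of equal-length gapped rows
#' (gap character \code{-}).  \code{as_msa()} validates: at least two rows,
#' equal lengths, no all-gap row.
#'
#' @param rows named character vector of aligned rows.
#' @return The validated alignment, classed \code{b12_msa}.
#' @export
as_msa <- function(rows) {
  if (length(rows) < 2) stopf("an alignment needs at least 2 rows")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stopf("alignment rows must be named")
  if (length(unique(nchar(rows))) != 1) stopf("alignment rows differ in length")
  if (any(gsub("-", "", rows) == "")) stopf("alignment contains an all-gap row")
  structure(rows, class = "b12_msa")
}

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(m) <- names(msa)
  m
}

matrix_msa <- function(m) {
  as_msa(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

# mean substitution score of each profile column against each alphabet letter
profile_column_scores <- function(prof_mat, scheme) {
  ab <- aa_alphabet()
  counts <- vapply(ab, function(r) colSums(prof_mat == r),
                   numeric(ncol(prof_mat)))
  if (ncol(prof_mat) == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, ab))
  nz <- pmax(rowSums(counts), 1)
  (counts %*% scheme$matrix) / nz
}

#' Centre-star progressive multiple alignment
#'
#' The default in-package aligner: the centre sequence is the one maximising
#' the summed pairwise global alignment scores; the remaining sequences are
#' merged in input order by global dynamic programming against the growing
#' profile (column scores are the mean substitution score over ungapped
#' residues), with new gap columns propagated to all rows.  Ungapping any
#' output row reproduces its input sequence.  An external aligner may be
#' substituted upstream; every downstream stage consumes only the
#' \code{b12_msa} contract.
#'
#' @param seqs named character vector of at least two protein sequences.
#' @param scheme a [scoring_scheme()].
#' @return A \code{b12_msa} with rows in input order.
#' @export
profile_align <- function(seqs, scheme = scoring_scheme()) {
  if (length(seqs) < 2) stopf("profile_align needs at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  enc <- lapply(seqs, encode_seq)
  if (n == 2) {
    g <- align_global(seqs[[1]], seqs[[2]], scheme)
    return(as_msa(setNames(c(g$aligned_a, g$aligned_b), names(seqs))))
  }
  ps <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S <- scheme$matrix[enc[[i]], enc[[j]], drop = FALSE]
    sc <- align_dp_cpp(S, scheme$gap_open, scheme$gap_extend, FALSE, FALSE)$score
    ps[i, j] <- sc; ps[j, i] <- sc
  }
  centre <- which.max(rowSums(ps))
  prof <- matrix(strsplit(seqs[[centre]], "")[[1]], nrow = 1,
                 dimnames = list(names(seqs)[centre], NULL))
  for (i in setdiff(seq_len(n), centre)) {
    cs <- profile_column_scores(prof, scheme)   # ncol x 21
    S <- cs[, enc[[i]], drop = FALSE]
    if (nrow(prof) == 0) stopf("internal: empty profile")
    res <- align_dp_cpp(as.matrix(S), scheme$gap_open, scheme$gap_extend,
                        FALSE, TRUE)
    ai <- res$a_idx; bi <- res$b_idx
    sq <- strsplit(seqs[[i]], "")[[1]]
    newprof <- matrix("-", nrow(prof) + 1, length(ai),
                      dimnames = list(c(rownames(prof), names(seqs)[i]), NULL))
    for (k in seq_along(ai)) {
      if (ai[k] > 0) newprof[seq_len(nrow(prof)), k] <- prof[, ai[k]]
      if (bi[k] > 0) newprof[nrow(prof) + 1, k] <- sq[bi[k]]
    }
    prof <- newprof
  }
  matrix_msa(prof[names(seqs), , drop = FALSE])
}

#' Trim gappy alignment columns
#'
#' Keeps a column if and only if the fraction of rows without a gap in it is
#' at least \code{config$gap_threshold} (columns at exactly the threshold are
#' kept, matching the documented behaviour of the classical \code{-gt}
#' trimmer).  Rows rendered all-gap are dropped with a warning; a result with
#' zero columns is an error flagging the alignment as untrimmable.
#'
#' @param msa a \code{b12_msa}.
#' @param config a [pipeline_config()].
#' @return The trimmed \code{b12_msa}.
#' @export
trim_columns <- function(msa, config = pipeline_config()) {
  m <- msa_matrix(msa)
  keep <- colMeans(m != "-") >= config$gap_threshold
  if (!any(keep)) stopf("trimming removed every column")
  m <- m[, keep, drop = FALSE]
  allgap <- rowSums(m != "-") == 0
  if (any(allgap)) {
    warnf("dropping %d all-gap row(s) after trimming: %s", sum(allgap),
          paste(rownames(m)[allgap], collapse = ", "))
    m <- m[!allgap, , drop = FALSE]
  }
  if (nrow(m) < 2) stopf("fewer than 2 rows remain after trimming")
  matrix_msa(m)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' For each pair of rows, \code{p} is the mismatch fraction over columns
#' where both rows are ungapped and \code{d = -ln(1 - p)} substitutions per
#' site.  Saturated pairs (\code{p >= p_cap}, default 0.95) are capped at
#' \code{-ln(1 - p_cap)} (about 3.0) so distances stay finite; pairs with no
#' mutually ungapped column get the cap with a warning.  The Poisson
#' correction keeps the units of the long-branch threshold meaningful
#' (expected substitutions per site).
#'
#' @param msa a \code{b12_msa}.
#' @param p_cap saturation cap on the observed mismatch fraction.
#' @return Symmetric numeric matrix with zero diagonal and row labels.
#' @export
poisson_distance <- function(msa, p_cap = 0.95) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  d_cap <- -log(1 - p_cap)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  ung <- m != "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ung[i, ] & ung[j, ]
    if (!any(both)) {
      warnf("no mutually ungapped columns for %s vs %s; distance capped",
            rownames(m)[i], rownames(m)[j])
      d <- d_cap
    } else {
      p <- mean(m[i, both] != m[j, both])
      d <- if (p >= p_cap) d_cap else -log(1 - p)
    }
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Pairwise identity matrix from an alignment
#'
#' Identity is the fraction of identical residues over columns where both
#' rows are ungapped (used by the contaminant identity rule).
#'
#' @param msa a \code{b12_msa}.
#' @return Symmetric numeric matrix in \code{[0, 1]} (diagonal 1); pairs with
#'   no overlap are \code{NA}.
#' @export
pairwise_identity <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  ID <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  ung <- m != "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ung[i, ] & ung[j, ]
    v <- if (any(both)) mean(m[i, both] == m[j, both]) else NA_real_
    ID[i, j] <- v; ID[j, i] <- v
  }
  ID
}
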