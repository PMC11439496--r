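#' Iteratively remove divergent tips from a sequence set
#'
#' Repeats the screening cycle — centre-star alignment, Poisson distances,
#' neighbour joining — and removes, one per iteration, the tip with the
#' longest terminal branch strictly greater than
#' \code{config$branch_length_threshold} (1.0 substitutions per site by
#' default).  Removing a single worst offender and recomputing avoids
#' overshooting when one rogue sequence inflates its neighbours' branches.
#' Iteration stops when no terminal branch exceeds the threshold or when a
#' removal would leave fewer than four sequences, in which case the set is
#' flagged unalignable.  Long internal branches are logged but never trigger
#' removal.
#'
#' @param seqs named character vector of at least 4 sequences.
#' @param config a [pipeline_config()].
#' @param scheme a [scoring_scheme()].
#' @return list with \code{retained} (named character vector),
#'   \code{removed_log} (data.frame: id, branch_length, iteration),
#'   \code{unalignable} (logical), and \code{tree}/\code{msa} for the final
#'   retained set.
#' @export
prune_divergent <- function(seqs, config = pipeline_config(),
                            scheme = scoring_scheme()) {
  if (length(seqs) < 4) stopf("prune_divergent needs at least 4 sequences")
  removed <- data.frame(id = character(), branch_length = numeric(),
                        iteration = integer(), stringsAsFactors = FALSE)
  unalignable <- FALSE
  iter <- 0L
  msa <- NULL; tree <- NULL
  repeat {
    iter <- iter + 1L
    msa <- profile_align(seqs, scheme)
    D <- suppressWarnings(poisson_distance(msa))
    tree <- nj_tree(D)
    off <- long_terminal_branches(tree, config$branch_length_threshold)
    if (length(off) == 0) break
    if (length(seqs) - 1 < 4) { unalignable <- TRUE; break }
    worst <- names(off)[1]
    removed <- rbind(removed,
                     data.frame(id = worst, branch_length = unname(off[1]),
                                iteration = iter, stringsAsFactors = FALSE))
    seqs <- seqs[names(seqs) != worst]
  }
  list(retained = seqs, removed_log = removed, unalignable = unalignable,
       msa = msa, tree = tree)
}

#' Flag contaminant and horizontally transferred tips
#'
#' Discriminates bacterial contamination from genuine horizontal gene
#' transfer on a curated tree containing both library sequences and a
#' prokaryotic reference panel.  A eukaryotic tip is a \emph{contaminant}
#' when (a) its pairwise identity to any prokaryotic tip reaches
#' \code{config$contaminant_identity_threshold} (99% by default), or (b)
#' the smallest clade containing it and at least two other tips (smallest
#' bipartition side of three or more tips) consists otherwise entirely of
#' prokaryotic tips and it is the only strain of its lineage group there.
#' When condition (b) holds but two or more distinct strains of the same
#' lineage group sit in that clade, the acquisition is shared and all such
#' tips are flagged \emph{hgt} instead.  Tips nested among eukaryotes of
#' other lineage groups are \emph{clean}.
#'
#' @param tree a \code{phylo} whose tips are all annotated.
#' @param annotations data.frame with columns \code{tip}, \code{domain}
#'   (\code{bacteria}, \code{archaea} or \code{eukaryote}),
#'   \code{lineage_group}, \code{strain} (or \code{library_id}).
#' @param identities optional symmetric pairwise identity matrix over tips
#'   (from [pairwise_identity()]); rule (a) is skipped when absent.
#' @param config a [pipeline_config()].
#' @return data.frame: \code{tip}, \code{flag} in
#'   \code{\{clean, contaminant, hgt\}} (prokaryotic reference tips are
#'   flagged \code{reference}).
#' @export
flag_contaminants <- function(tree, annotations, identities = NULL,
                              config = pipeline_config()) {
  tips <- tree$tip.label
  if (is.null(annotations$strain)) annotations$strain <- annotations$library_id
  miss <- setdiff(tips, annotations$tip)
  if (length(miss)) stopf("unannotated tips: %s", paste(miss, collapse = ", "))
  ann <- annotations[match(tips, annotations$tip), , drop = FALSE]
  prok <- ann$domain %in% c("bacteria", "archaea")
  names(prok) <- tips
  group <- setNames(ann$lineage_group, tips)
  strain <- setNames(ann$strain, tips)

  sides <- c(edge_tip_sets(tree),
             lapply(edge_tip_sets(tree), function(s) setdiff(tips, s)))
  flag <- setNames(ifelse(prok, "reference", "clean"), tips)

  for (t in tips[!prok]) {
    if (!is.null(identities)) {
      ids <- identities[t, tips[prok]]
      if (length(ids) && any(!is.na(ids) & ids >= config$contaminant_identity_threshold)) {
        flag[t] <- "contaminant"
        next
      }
    }
    mine <- vapply(sides, function(s) t %in% s, TRUE)
    cand <- sides[mine]
    sizes <- vapply(cand, length, 0L)
    ok <- sizes >= 3
    if (!any(ok)) next
    smallest <- cand[ok][sizes[ok] == min(sizes[ok])]
    for (S in smallest) {
      others <- setdiff(S, t)
      euk_others <- others[!prok[others]]
      if (!any(prok[others])) break             # local clade is eukaryotic
      if (any(group[euk_others] != group[t])) break  # other lineages present
      same_group <- c(t, euk_others)
      if (length(unique(strain[same_group])) >= 2) {
        flag[same_group] <- "hgt"
      } else {
        flag[t] <- "contaminant"
      }
      break
    }
  }
  data.frame(tip = tips, flag = unname(flag[tips]), stringsAsFactors = FALSE)
}

#' Assign tips to anchored isoform clades
#'
#' Used to separate methionine synthase isoform clades: given anchor tips
#' for each clade label (e.g. the three characterised Arabidopsis methionine
#' synthases anchoring Clade I), each tip is labelled \code{L} when it lies
#' inside the maximal clade (bipartition side) containing every anchor of
#' \code{L} and no anchor of any other label.  Tips outside every anchored
#' clade are \code{unassigned}.  If the anchor sets of two labels cannot be
#' separated by any edge the anchors conflict and an error is raised.
#'
#' @param tree a \code{phylo}.
#' @param anchors named list: clade label -> character vector of anchor tip
#'   ids (each present in the tree; sets disjoint).
#' @return data.frame: \code{tip}, \code{clade} (label or
#'   \code{"unassigned"}).
#' @export
assign_isoform_clade <- function(tree, anchors) {
  tips <- tree$tip.label
  allanch <- unlist(anchors)
  if (anyDuplicated(allanch)) stopf("anchor sets must be mutually exclusive")
  miss <- setdiff(allanch, tips)
  if (length(miss)) stopf("anchor tip(s) not in tree: %s", paste(miss, collapse = ", "))
  sides <- edge_tip_sets(tree)
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)))
  clade_side <- list()
  for (L in names(anchors)) {
    own <- anchors[[L]]
    other <- setdiff(allanch, own)
    ok <- vapply(sides, function(s)
      all(own %in% s) && !any(other %in% s), TRUE)
    if (!any(ok))
      stopf("anchor sets conflict: no edge separates clade '%s' from the other anchors", L)
    sel <- sides[ok]
    clade_side[[L]] <- sel[[which.max(vapply(sel, length, 0L))]]
  }
  # a tip belongs to a clade only if it lies inside exactly one anchored
  # clade; tips claimed by several (e.g. outgroups between two maximal
  # sides) stay unassigned
  lab <- setNames(rep("unassigned", length(tips)), tips)
  claims <- setNames(rep(0L, length(tips)), tips)
  for (L in names(clade_side)) {
    inL <- clade_side[[L]]
    claims[inL] <- claims[inL] + 1L
    lab[inL] <- L
  }
  lab[claims != 1L] <- "unassigned"
  data.frame(tip = tips, clade = unname(lab[tips]), stringsAsFactors = FALSE)
}
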