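presence_rank <- c(absent = 0, contaminant_only = 1, present_partial = 2,
                   present_split = 3, present = 4)

#' Build the strain-by-family presence matrix
#'
#' Aggregates per-record calls (after reciprocal validation, tree curation
#' and completeness assessment) to one cell per unique strain and family,
#' keeping the strongest value across the strain's libraries in the order
#' \code{present > present_split > present_partial > contaminant_only >
#' absent}.  Contaminant-flagged records can never yield presence;
#' hgt-flagged records count as genuine presence (shared acquisitions are
#' transfers, not contamination).  Strains with no sequenced record at all
#' are flagged low-coverage.
#'
#' @param calls data.frame with one row per record-level call: \code{strain},
#'   \code{family}, \code{record_id}, \code{status} (\code{complete},
#'   \code{complete_split}, \code{partial}, \code{absent}), \code{flag}
#'   (\code{clean}/\code{contaminant}/\code{hgt}).
#' @param strains strain table from [dedupe_strains()].
#' @param registry a \code{b12_registry} supplying the column order.
#' @return A \code{presence_matrix}: data.frame with one row per strain,
#'   columns \code{strain}, \code{has_genome}, \code{low_coverage}, then one
#'   column per family; cell audit trails in
#'   \code{attr(, "audit")}.
#' @export
build_presence_matrix <- function(calls, strains, registry) {
  fams <- names(registry$families)
  unknown <- setdiff(calls$strain, strains$strain)
  if (length(unknown))
    stopf("call(s) reference unknown strain(s): %s", paste(unknown, collapse = ", "))
  mat <- data.frame(strain = strains$strain, has_genome = strains$has_genome,
                    low_coverage = FALSE, stringsAsFactors = FALSE)
  for (f in fams) mat[[f]] <- "absent"
  audit <- list()
  if (NROW(calls) > 0) {
    for (k in seq_len(nrow(calls))) {
      cl <- calls[k, ]
      cell <- if (cl$flag == "contaminant") "contaminant_only"
      else switch(cl$status,
                  complete = "present",
                  complete_split = "present_split",
                  partial = "present_partial",
                  "absent")
      i <- match(cl$strain, mat$strain)
      if (presence_rank[[cell]] > presence_rank[[mat[[cl$family]][i]]])
        mat[[cl$family]][i] <- cell
      key <- paste(cl$strain, cl$family, sep = "\r")
      audit[[key]] <- c(audit[[key]],
                        sprintf("%s:%s:%s", cl$record_id, cl$status, cl$flag))
    }
  }
  covered <- unique(calls$strain)
  mat$low_coverage <- !mat$strain %in% covered & !mat$has_genome
  attr(mat, "audit") <- audit
  class(mat) <- c("presence_matrix", "data.frame")
  mat
}

cell_present <- function(x) x %in% c("present", "present_split")

#' Classify the B12 metabolic status of one strain
#'
#' Methionine synthase logic: both METH and METE present means the strain
#' can use B12 but does not depend on it (\code{facultative}); METH without
#' METE means B12 dependence (\code{dependent_only}); METE without METH
#' means B12-independent methionine synthesis (\code{independent_only});
#' neither means \code{unknown}.  Because transcriptomes under-report METE
#' (it is repressed in B12-replete cultures), a METH-only call without any
#' sequenced genome is recorded as \code{dependent_only} with a
#' low-confidence flag rather than a firm absence call.  Partial presences
#' count as absent for status (but stay visible in the matrix).
#'
#' A strain has lost all known B12-associated metabolism
#' (\code{lost_known_b12}) when it retains METE but lacks METH, MTRR, MCM
#' and RNR-II — assessable only with a genome (\code{NA} otherwise).
#' Families absent from the matrix columns are treated as not detected.
#'
#' @param row one row of a [build_presence_matrix()] result (data.frame).
#' @param has_genome does the strain have at least one genome library?
#' @return A \code{b12_status}: list with \code{strain},
#'   \code{methionine_status}, \code{low_confidence}, \code{adenosyl_users},
#'   \code{accessory_present}, \code{lost_known_b12}.
#' @export
classify_b12_status <- function(row, has_genome = row$has_genome) {
  g <- function(f) if (!is.null(row[[f]])) cell_present(row[[f]]) else FALSE
  meth <- g("METH"); mete <- g("METE"); mtrr <- g("MTRR")
  mcm <- g("MCM"); rnr <- g("RNR-II")
  status <- if (meth && mete) "facultative"
  else if (meth) "dependent_only"
  else if (mete) "independent_only"
  else "unknown"
  low_conf <- meth && !mete && !has_genome
  aden <- c("MCM", "RNR-II")[c(mcm, rnr)]
  core <- c("strain", "has_genome", "low_coverage")
  fams <- setdiff(names(row), core)
  accessory <- fams[vapply(fams, g, TRUE)]
  accessory <- setdiff(accessory, c("METH", "METE"))
  lost <- if (!has_genome) NA else (mete && !meth && !mtrr && !mcm && !rnr)
  structure(list(strain = row$strain %||% NA_character_,
                 methionine_status = status,
                 low_confidence = low_conf,
                 adenosyl_users = aden,
                 accessory_present = accessory,
                 lost_known_b12 = lost),
            class = "b12_status")
}

#' Classify every strain of a presence matrix
#'
#' @param mat a [build_presence_matrix()] result.
#' @return data.frame: \code{strain}, \code{methionine_status},
#'   \code{low_confidence}, \code{adenosyl_users} (comma-separated),
#'   \code{accessory_present}, \code{lost_known_b12}.
#' @export
classify_all <- function(mat) {
  out <- lapply(seq_len(nrow(mat)), function(i) {
    st <- classify_b12_status(mat[i, , drop = FALSE])
    data.frame(strain = st$strain,
               methionine_status = st$methionine_status,
               low_confidence = st$low_confidence,
               adenosyl_users = paste(st$adenosyl_users, collapse = ","),
               accessory_present = paste(st$accessory_present, collapse = ","),
               lost_known_b12 = st$lost_known_b12,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Consensus of per-tool targeting predictions
#'
#' Subcellular-targeting calls from several predictors are combined by
#' strict majority; with fewer than three predictions, or no strict
#' majority, the consensus is \code{ambiguous}.
#'
#' @param per_tool named character vector or list: tool -> compartment, each
#'   in \code{secretory}, \code{mitochondrion}, \code{plastid},
#'   \code{endomembrane}, \code{other}, \code{none}.
#' @return list with \code{predictions}, \code{consensus}, \code{note}.
#' @export
targeting_consensus <- function(per_tool) {
  per_tool <- unlist(per_tool)
  if (length(per_tool) == 0) stopf("need at least one tool prediction")
  vocab <- c("secretory", "mitochondrion", "plastid", "endomembrane",
             "other", "none")
  bad <- setdiff(per_tool, vocab)
  if (length(bad))
    stopf("unknown compartment(s) %s; accepted terms: %s",
          paste(bad, collapse = ", "), paste(vocab, collapse = ", "))
  if (length(per_tool) < 3)
    return(list(predictions = per_tool, consensus = "ambiguous",
                note = "fewer than 3 predictions"))
  tab <- sort(table(per_tool), decreasing = TRUE)
  cons <- if (tab[1] * 2 > length(per_tool)) names(tab)[1] else "ambiguous"
  list(predictions = per_tool, consensus = cons, note = "")
}

#' Per-lineage occurrence counts
#'
#' For each lineage group: the number of unique strains carrying METH only,
#' METE only, or both; the total number of assessable strains; and, among
#' strains with at least one of the two methionine synthases, occurrence
#' counts for every other family.  Counts are over strains, never libraries.
#'
#' @param mat a [build_presence_matrix()] result.
#' @param strains strain table from [dedupe_strains()].
#' @return list with \code{synthase} (data.frame of METH/METE counts per
#'   group) and \code{occurrence} (group x family counts among strains with
#'   at least one B12 enzyme).
#' @export
tabulate_groups <- function(mat, strains) {
  lg <- strains$lineage_group[match(mat$strain, strains$strain)]
  if (any(is.na(lg))) stopf("strain(s) without lineage_group")
  meth <- cell_present(mat$METH %||% rep("absent", nrow(mat)))
  mete <- cell_present(mat$METE %||% rep("absent", nrow(mat)))
  groups <- sort(unique(strains$lineage_group))
  syn <- do.call(rbind, lapply(groups, function(g) {
    i <- which(lg == g)
    data.frame(lineage_group = g,
               meth_only = sum(meth[i] & !mete[i]),
               mete_only = sum(mete[i] & !meth[i]),
               both = sum(meth[i] & mete[i]),
               total_assessable = length(i),
               stringsAsFactors = FALSE)
  }))
  fams <- setdiff(names(mat), c("strain", "has_genome", "low_coverage"))
  occ <- sapply(fams, function(f) {
    p <- cell_present(mat[[f]])
    sapply(groups, function(g) sum(p & lg == g & (meth | mete)))
  })
  occ <- matrix(occ, nrow = length(groups),
                dimnames = list(groups, fams))
  list(synthase = syn, occurrence = occ)
}

#' Habitat by B12-loss contingency table
#'
#' Cross-tabulates the habitat class of each strain's collection site
#' against the loss of known B12-associated metabolism.  Strains without a
#' habitat tag or with indeterminate loss status are excluded and counted.
#'
#' @param statuses data.frame from [classify_all()].
#' @param strains strain table from [dedupe_strains()] (supplies
#'   \code{habitat}).
#' @return list with \code{table} (habitat x lost_known_b12 counts) and
#'   \code{excluded} (strains without usable habitat or status).
#' @export
habitat_crosstab <- function(statuses, strains) {
  hab <- strains$habitat[match(statuses$strain, strains$strain)]
  classes <- c("marine", "freshwater", "terrestrial", "symbiotic", "other")
  hab[!is.na(hab) & !hab %in% classes] <- "other"
  usable <- !is.na(hab) & !is.na(statuses$lost_known_b12)
  tab <- table(factor(hab[usable], levels = classes),
               factor(statuses$lost_known_b12[usable], levels = c(TRUE, FALSE)))
  names(dimnames(tab)) <- c("habitat", "lost_known_b12")
  list(table = tab, excluded = sum(!usable))
}
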