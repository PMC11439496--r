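#' Assess domain-architecture completeness of one record
#'
#' A record is \code{complete} when every required domain of the family has
#' at least one hit, \code{partial} when some but not all do, and
#' \code{absent} when none do.  Missing domains are listed in registry
#' (architecture) order; hit order is recorded but not enforced.  For
#' consensus-validated families (no required domains) a single consensus-
#' profile hit makes the record complete.
#'
#' @param hits data.frame of domain hits for one record (from
#'   [scan_domains()]).
#' @param family a [query_family()].
#' @param record_id id of the scanned record.
#' @return A \code{completeness_call}: list with \code{family},
#'   \code{record_id}, \code{status} (\code{complete}/\code{partial}/
#'   \code{absent}/\code{complete_split}), \code{missing_domains},
#'   \code{domains_present}, \code{contributing_records}, \code{note}.
#' @export
assess_completeness <- function(hits, family, record_id = NA_character_) {
  req <- family$required_domains
  if (length(req) == 0) req <- paste0(family$name, "_consensus")
  present <- intersect(req, unique(hits$profile))
  missing <- setdiff(req, present)
  status <- if (length(missing) == 0) "complete"
            else if (length(present) > 0) "partial"
            else "absent"
  structure(list(family = family$name, record_id = record_id,
                 status = status, missing_domains = missing,
                 domains_present = present,
                 contributing_records = if (status == "absent") character()
                                        else record_id,
                 note = ""),
            class = "completeness_call")
}

#' Rescue split gene models within a genome library
#'
#' Genome annotations sometimes split one gene across neighbouring gene
#' models.  When no single record of a family in a genome library is
#' complete, but the union of domains over records sharing a scaffold covers
#' every required domain, the family is called \code{complete_split} with
#' the contributing records listed.  A union spread over different scaffolds
#' is not rescued: the best partial call is returned with the note
#' \code{"possible split (multi-scaffold)"}.  Transcriptome libraries are
#' never rescued, and a record already complete takes precedence over any
#' rescue.
#'
#' @param calls list of \code{completeness_call}s for one family within one
#'   library.
#' @param records data.frame of the corresponding records with
#'   \code{id} and \code{scaffold_id} columns.
#' @param family the [query_family()].
#' @param library_type \code{"genome"} or \code{"transcriptome"}.
#' @return A single library-level \code{completeness_call}.
#' @export
rescue_split_models <- function(calls, records, family,
                                library_type = "genome") {
  stopifnot(length(calls) >= 1)
  rank <- c(absent = 0, partial = 1, complete_split = 2, complete = 3)
  best <- calls[[order(-vapply(calls, function(c) rank[[c$status]], 0))[1]]]
  if (best$status == "complete" || library_type != "genome") return(best)
  req <- family$required_domains
  if (length(req) == 0) return(best)

  ids <- vapply(calls, `[[`, "", "record_id")
  scaff <- records$scaffold_id[match(ids, records$id)]
  has_scaff <- !is.na(scaff) & nzchar(scaff)
  if (any(!has_scaff))
    warnf("family %s: %d record(s) lack scaffold_id; skipped from rescue",
          family$name, sum(!has_scaff))
  dom_union <- function(sel) unique(unlist(lapply(calls[sel], `[[`,
                                                  "domains_present")))
  for (sc in unique(scaff[has_scaff])) {
    sel <- which(has_scaff & scaff == sc)
    if (length(setdiff(req, dom_union(sel))) == 0) {
      return(structure(list(family = family$name, record_id = NA_character_,
                            status = "complete_split",
                            missing_domains = character(),
                            domains_present = req,
                            contributing_records = ids[sel],
                            note = sprintf("split gene models on scaffold %s", sc)),
                       class = "completeness_call"))
    }
  }
  if (length(setdiff(req, dom_union(seq_along(calls)))) == 0 &&
      best$status != "complete_split") {
    best$note <- "possible split (multi-scaffold)"
  }
  best
}
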