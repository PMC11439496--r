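#' Forward homologue search of a library against a family's seeds
#'
#' Every library sequence is aligned locally against each seed of the family;
#' the best seed is the one giving the highest score (ties broken by seed
#' order in the registry).  Records whose best E-value is at or below
#' \code{config$forward_evalue_threshold} are returned as candidates.  The
#' database size used in the E-value is the total residue count of the
#' library searched.
#'
#' @param family a [query_family()].
#' @param library data.frame of sequence records (as from [read_fasta()]).
#' @param config a [pipeline_config()].
#' @param scheme a [scoring_scheme()].
#' @return data.frame of candidate hits: record id, library, family, best
#'   seed, score, E-value, identity, status (\code{"candidate"}).
#' @export
find_candidates <- function(family, library, config = pipeline_config(),
                            scheme = scoring_scheme()) {
  empty <- data.frame(id = character(), library_id = character(),
                      family = character(), seed_id = character(),
                      score = numeric(), evalue = numeric(),
                      identity = numeric(), status = character(),
                      stringsAsFactors = FALSE)
  if (NROW(library) == 0) return(empty)
  n_db <- sum(nchar(library$sequence))
  seeds <- family$seed_sequences
  rows <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    best_score <- -Inf; best_seed <- NA_integer_
    for (s in seq_len(nrow(seeds))) {
      sc <- align_local_score(seeds$sequence[s], library$sequence[i], scheme)
      if (sc > best_score) { best_score <- sc; best_seed <- s }
    }
    ev <- estimate_evalue(best_score, nchar(seeds$sequence[best_seed]), n_db, scheme)
    if (ev <= config$forward_evalue_threshold) {
      al <- align_local(seeds$sequence[best_seed], library$sequence[i], scheme)
      rows[[i]] <- data.frame(id = library$id[i],
                              library_id = library$library_id[i],
                              family = family$name,
                              seed_id = seeds$id[best_seed],
                              score = best_score, evalue = ev,
                              identity = al$identity,
                              status = "candidate",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) empty else out
}

#' Build a reciprocal-validation database
#'
#' The validation database holds a decoy proteome (a complete non-target
#' proteome; in the original design a plant genome that uniquely encodes
#' METE) supplemented with all registry seed queries, and, for the METE
#' special rule, the characterised Arabidopsis methionine synthases.  Roles
#' are carried in a sidecar table.
#'
#' @param sequences data.frame of records (\code{id}, \code{sequence}).
#' @param roles data.frame with columns \code{id}, \code{role} (one of
#'   \code{decoy_proteome}, \code{registry_query},
#'   \code{arabidopsis_met_synthase}) and \code{family} (NA for decoys).
#' @return data.frame of class \code{validation_db} joining sequences and roles.
#' @export
validation_db <- function(sequences, roles) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)),
            all(c("id", "role") %in% names(roles)))
  bad <- setdiff(roles$role,
                 c("decoy_proteome", "registry_query", "arabidopsis_met_synthase"))
  if (length(bad)) stopf("unknown validation roles: %s", paste(bad, collapse = ", "))
  if (is.null(roles$family)) roles$family <- rep(NA_character_, nrow(roles))
  db <- merge(sequences[, c("id", "sequence")], roles, by = "id", all.x = TRUE)
  db$role[is.na(db$role)] <- "decoy_proteome"
  structure(db[order(db$id), , drop = FALSE], class = c("validation_db", "data.frame"))
}

#' Reciprocal best-hit validation of a candidate
#'
#' The candidate sequence is aligned against every entry of the validation
#' database; it is validated when its best-scoring match (score ties resolved
#' in favour of registry queries over decoys, then by database id order) is a
#' registry query of the same family — or, when the family carries the METE
#' special rule, an Arabidopsis methionine synthase.  No E-value threshold is
#' applied: the criterion is best-hit identity of origin, after which the
#' tree-based filters act.
#'
#' @param sequence candidate protein sequence.
#' @param family_name family the candidate was retrieved for.
#' @param db a [validation_db()].
#' @param special_rule the family's special rule.
#' @param scheme a [scoring_scheme()].
#' @return list with \code{validated} (logical), \code{matched_id},
#'   \code{matched_role}, \code{score}.
#' @export
reciprocal_validate <- function(sequence, family_name, db,
                                special_rule = "none",
                                scheme = scoring_scheme()) {
  if (NROW(db) == 0) stopf("empty validation database")
  scores <- vapply(db$sequence, function(s)
    align_local_score(s, sequence, scheme), 0, USE.NAMES = FALSE)
  pref <- ifelse(db$role == "decoy_proteome", 0L, 1L)  # queries win ties
  ord <- order(-scores, -pref, db$id)
  best <- ord[1]
  ok <- (db$role[best] == "registry_query" &&
           identical(db$family[best], family_name)) ||
    (special_rule == "mete_arabidopsis" &&
       db$role[best] == "arabidopsis_met_synthase")
  list(validated = ok,
       matched_id = db$id[best],
       matched_role = db$role[best],
       score = scores[best])
}

#' Validate a table of candidates
#'
#' Applies [reciprocal_validate()] to each candidate row, updating
#' \code{status} to \code{"validated"} or \code{"rejected_reciprocal"} and
#' recording the matched validation sequence.
#'
#' @param candidates candidate table from [find_candidates()].
#' @param library data.frame of records supplying candidate sequences.
#' @param db a [validation_db()].
#' @param registry a \code{b12_registry} (for special rules).
#' @param scheme a [scoring_scheme()].
#' @return The candidate table with \code{status}, \code{matched_id},
#'   \code{matched_role} filled in.
#' @export
validate_candidates <- function(candidates, library, db, registry,
                                scheme = scoring_scheme()) {
  if (NROW(candidates) == 0) {
    candidates$matched_id <- character(0)
    candidates$matched_role <- character(0)
    return(candidates)
  }
  seqs <- setNames(library$sequence, paste(library$library_id, library$id))
  candidates$matched_id <- NA_character_
  candidates$matched_role <- NA_character_
  for (i in seq_len(nrow(candidates))) {
    fam <- registry$families[[candidates$family[i]]]
    s <- seqs[[paste(candidates$library_id[i], candidates$id[i])]]
    r <- reciprocal_validate(s, candidates$family[i], db,
                             special_rule = fam$special_rule %||% "none",
                             scheme = scheme)
    candidates$status[i] <- if (r$validated) "validated" else "rejected_reciprocal"
    candidates$matched_id[i] <- r$matched_id
    candidates$matched_role[i] <- r$matched_role
  }
  candidates
}
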