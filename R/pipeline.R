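#' Run the full homologue screen
#'
#' Executes the pipeline end to end for every family in the registry:
#' forward search (E-value threshold), reciprocal best-hit validation,
#' tree-based curation (centre-star alignment, Poisson distances,
#' neighbour joining, iterative long-branch removal, column trimming,
#' optional bootstrap), contaminant/transfer screening against the
#' prokaryotic reference panel, domain-architecture validation with
#' split-gene-model rescue in genomes, and finally the strain-by-family
#' presence matrix, per-strain B12 status calls and summary tabulations.
#' Every candidate that does not reach the presence matrix appears in
#' exactly one exclusion-log row with a reason code
#' (\code{reciprocal_fail}, \code{divergent_branch}, \code{contaminant},
#' \code{incomplete_domains}).
#'
#' @param libraries data.frame of sequence records across all libraries
#'   (columns as [read_fasta()], with \code{library_id} and, for genome
#'   records, \code{scaffold_id}).
#' @param manifest library manifest data.frame (see [read_manifest()]).
#' @param registry a \code{b12_registry}.
#' @param vdb a [validation_db()].
#' @param reference_panel optional data.frame (\code{id}, \code{sequence},
#'   \code{family}, \code{domain}) of reference homologues — prokaryotic
#'   homologues plus distant eukaryotic outgroups — joined into each
#'   family's curation tree; without prokaryotic references the clade-based
#'   contaminant rule cannot fire.
#' @param config a [pipeline_config()].
#' @param synonyms optional strain synonym table for [dedupe_strains()].
#' @return A \code{b12_run}: list with \code{config}, \code{strains},
#'   \code{candidates}, \code{record_calls}, \code{exclusions},
#'   \code{stage_counts}, \code{trees}, \code{presence}, \code{statuses},
#'   \code{lineage_tables}, \code{habitat_table}, \code{warnings}.
#' @export
run_pipeline <- function(libraries, manifest, registry, vdb,
                         reference_panel = NULL,
                         config = pipeline_config(), synonyms = NULL) {
  manifest <- validate_manifest(manifest)
  strains <- dedupe_strains(manifest, synonyms)
  lib2strain <- setNames(strains$strain[match(
    normalize_strain(manifest$strain_name, synonyms), strains$strain_key)],
    manifest$library_id)
  lib2type <- setNames(manifest$library_type, manifest$library_id)
  lib2group <- setNames(manifest$lineage_group, manifest$library_id)
  scheme <- scoring_scheme()
  profiles <- suppressWarnings(registry_profiles(registry, scheme = scheme))
  set.seed(config$random_seed)

  all_cand <- list(); record_calls <- list(); exclusions <- list()
  stage_counts <- list(); trees <- list()
  rec_key <- function(lib, id) paste0(lib, "@", id)

  for (fam in registry$families) {
    f <- fam$name
    # --- forward search, per library (E-value uses library size) ---------
    cand <- do.call(rbind, lapply(unique(libraries$library_id), function(lib)
      find_candidates(fam, libraries[libraries$library_id == lib, ],
                      config, scheme)))
    n_cand <- NROW(cand)
    if (n_cand == 0) {
      stage_counts[[f]] <- data.frame(family = f, candidates = 0, validated = 0,
                                      post_curation = 0, complete = 0)
      next
    }
    # --- reciprocal validation ------------------------------------------
    cand <- validate_candidates(cand, libraries, vdb, registry, scheme)
    all_cand[[f]] <- cand
    rej <- cand[cand$status == "rejected_reciprocal", ]
    if (nrow(rej) > 0)
      exclusions[[length(exclusions) + 1]] <-
        data.frame(family = f, record = rec_key(rej$library_id, rej$id),
                   reason = "reciprocal_fail", stringsAsFactors = FALSE)
    val <- cand[cand$status == "validated", ]
    n_val <- nrow(val)
    if (n_val == 0) {
      stage_counts[[f]] <- data.frame(family = f, candidates = n_cand,
                                      validated = 0, post_curation = 0,
                                      complete = 0)
      next
    }

    keys <- rec_key(val$library_id, val$id)
    seqs <- setNames(libraries$sequence[match(paste(val$library_id, val$id),
                                              paste(libraries$library_id,
                                                    libraries$id))], keys)
    refs <- if (!is.null(reference_panel))
      reference_panel[reference_panel$family == f, , drop = FALSE]
    else NULL
    if (!is.null(refs) && is.null(refs$domain)) refs$domain <- "bacteria" 
    curset <- c(seqs, if (!is.null(refs)) setNames(refs$sequence, refs$id))

    flags <- setNames(rep("clean", length(keys)), keys)
    removed <- character(0)
    if (length(curset) >= 4) {
      pr <- prune_divergent(curset, config, scheme)
      removed <- intersect(pr$removed_log$id, keys)
      if (length(removed) > 0)
        exclusions[[length(exclusions) + 1]] <-
          data.frame(family = f, record = removed, reason = "divergent_branch",
                     stringsAsFactors = FALSE)
      msa <- tryCatch(trim_columns(pr$msa, config), error = function(e) pr$msa)
      tree <- if (config$nj_replicates > 0 && length(pr$retained) >= 4)
        bootstrap_support(msa, n_reps = config$nj_replicates,
                          seed = config$random_seed)
      else pr$tree
      trees[[f]] <- tree
      # --- contaminant / transfer screen --------------------------------
      surv <- intersect(keys, names(pr$retained))
      if (length(surv) > 0 && !is.null(refs) && nrow(refs) > 0 &&
          length(pr$retained) >= 4) {
        ann <- data.frame(tip = tree$tip.label, stringsAsFactors = FALSE)
        ridx <- match(ann$tip, refs$id)
        is_ref <- !is.na(ridx)
        libid <- sub("@.*$", "", ann$tip)
        ann$domain <- ifelse(is_ref, refs$domain[ridx], "eukaryote")
        ann$lineage_group <- ifelse(is_ref, paste0("ref_", refs$domain[ridx]),
                                    lib2group[libid])
        ann$strain <- ifelse(is_ref, ann$tip, lib2strain[libid])
        ids <- pairwise_identity(msa)
        fl <- flag_contaminants(tree, ann, ids, config)
        hit <- fl$tip %in% surv
        flags[fl$tip[hit]] <- fl$flag[hit]
      }
      cont <- names(flags)[flags == "contaminant"]
      if (length(cont) > 0)
        exclusions[[length(exclusions) + 1]] <-
          data.frame(family = f, record = cont, reason = "contaminant",
                     stringsAsFactors = FALSE)
    }
    survivors <- setdiff(keys, removed)
    n_surv <- length(survivors)

    # --- domain architecture --------------------------------------------
    fam_profiles <- profiles[intersect(
      c(fam$required_domains,
        if (fam$special_rule == "cba1_consensus") paste0(f, "_consensus")),
      names(profiles))]
    calls_by_lib <- split(survivors, sub("@.*$", "", survivors))
    n_complete <- 0
    for (lib in names(calls_by_lib)) {
      ks <- calls_by_lib[[lib]]
      ccalls <- lapply(ks, function(k) {
        hits <- scan_domains(seqs[[k]], fam_profiles, config)
        assess_completeness(hits, fam, record_id = k)
      })
      recs <- data.frame(id = ks,
                         scaffold_id = libraries$scaffold_id[match(
                           paste(lib, sub("^.*@", "", ks)),
                           paste(libraries$library_id, libraries$id))],
                         stringsAsFactors = FALSE)
      lib_rescued <- if (lib2type[[lib]] == "genome")
        rescue_split_models(ccalls, recs, fam, "genome") else NULL
      for (cc in ccalls) {
        if (cc$status == "complete") n_complete <- n_complete + 1
        if (cc$status == "absent")
          exclusions[[length(exclusions) + 1]] <-
            data.frame(family = f, record = cc$record_id,
                       reason = "incomplete_domains", stringsAsFactors = FALSE)
        record_calls[[length(record_calls) + 1]] <-
          data.frame(strain = lib2strain[[lib]], family = f,
                     record_id = cc$record_id, library_id = lib,
                     id = sub("^.*@", "", cc$record_id),
                     status = cc$status,
                     flag = flags[[cc$record_id]],
                     note = cc$note, stringsAsFactors = FALSE)
      }
      if (!is.null(lib_rescued) && lib_rescued$status == "complete_split") {
        contrib_flags <- flags[lib_rescued$contributing_records]
        record_calls[[length(record_calls) + 1]] <-
          data.frame(strain = lib2strain[[lib]], family = f,
                     record_id = paste(lib_rescued$contributing_records,
                                       collapse = "+"),
                     library_id = lib, id = NA_character_,
                     status = "complete_split",
                     flag = if (any(contrib_flags == "contaminant"))
                       "contaminant" else "clean",
                     note = lib_rescued$note, stringsAsFactors = FALSE)
      }
    }
    stage_counts[[f]] <- data.frame(family = f, candidates = n_cand,
                                    validated = n_val,
                                    post_curation = n_surv,
                                    complete = n_complete)
  }

  record_calls <- if (length(record_calls)) do.call(rbind, record_calls)
  else data.frame(strain = character(), family = character(),
                  record_id = character(), library_id = character(),
                  id = character(), status = character(),
                  flag = character(), note = character(),
                  stringsAsFactors = FALSE)
  presence <- build_presence_matrix(record_calls, strains, registry)
  statuses <- classify_all(presence)
  structure(list(config = config, strains = strains,
                 candidates = if (length(all_cand)) do.call(rbind, all_cand)
                 else NULL,
                 record_calls = record_calls,
                 exclusions = if (length(exclusions)) do.call(rbind, exclusions)
                 else data.frame(family = character(), record = character(),
                                 reason = character(), stringsAsFactors = FALSE),
                 stage_counts = do.call(rbind, stage_counts),
                 trees = trees, presence = presence, statuses = statuses,
                 lineage_tables = tabulate_groups(presence, strains),
                 habitat_table = habitat_crosstab(statuses, strains)),
            class = "b12_run")
}

#' Summary artefacts of a pipeline run
#'
#' Produces the three summary outputs of the screen: per-lineage occurrence
#' counts (bar-plot-ready), the table of strains that retain METE but lack
#' METH and MTRR (the candidates for loss of B12-dependent metabolism, with
#' collection metadata and notes listing any retained adenosylcobalamin or
#' accessory families), and, when a species tree is supplied, that tree
#' with tips annotated by status class (\code{dependent},
#' \code{facultative}, \code{independent}, \code{unknown}).
#'
#' @param run a [run_pipeline()] result.
#' @param species_tree optional \code{phylo} whose tips are strain names.
#' @return list with \code{lineage_counts}, \code{occurrence},
#'   \code{loss_table}, and (optionally) \code{status_tree}.
#' @export
render_summaries <- function(run, species_tree = NULL) {
  mat <- run$presence; st <- run$statuses; strains <- run$strains
  sel <- cell_present(mat$METE %||% rep("absent", nrow(mat))) &
    !cell_present(mat$METH %||% rep("absent", nrow(mat))) &
    !cell_present(mat$MTRR %||% rep("absent", nrow(mat)))
  core <- c("strain", "has_genome", "low_coverage", "METE", "METH", "MTRR")
  loss <- do.call(rbind, lapply(which(sel), function(i) {
    s <- mat$strain[i]
    j <- match(s, strains$strain)
    acc <- setdiff(names(mat), core)
    acc <- acc[vapply(acc, function(f) cell_present(mat[[f]][i]), TRUE)]
    data.frame(species = s, lineage = strains$lineage_group[j], strain = s,
               ecological_context = strains$habitat[j] %||% NA,
               collection_latitude = strains$latitude[j],
               collection_longitude = strains$longitude[j],
               lost_known_b12 = st$lost_known_b12[match(s, st$strain)],
               notes = if (length(acc)) paste("encodes",
                                              paste(acc, collapse = ", "))
               else "",
               stringsAsFactors = FALSE)
  }))
  if (is.null(loss))
    loss <- data.frame(species = character(), lineage = character(),
                       strain = character(), ecological_context = character(),
                       collection_latitude = numeric(),
                       collection_longitude = numeric(),
                       lost_known_b12 = logical(), notes = character(),
                       stringsAsFactors = FALSE)
  out <- list(lineage_counts = run$lineage_tables$synthase,
              occurrence = run$lineage_tables$occurrence,
              loss_table = loss)
  if (!is.null(species_tree)) {
    cls <- c(dependent_only = "dependent", facultative = "facultative",
             independent_only = "independent", unknown = "unknown")
    lab <- cls[st$methionine_status[match(species_tree$tip.label, st$strain)]]
    lab[is.na(lab)] <- "unknown"
    tr <- species_tree
    tr$tip.label <- paste0(tr$tip.label, "|", lab)
    out$status_tree <- tr
  }
  out
}

#' Write the artefacts of a run to a directory
#'
#' Tab-separated presence matrix, status table, exclusion log, stage
#' counts, per-lineage tables and loss table; curated trees as newick.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(as.data.frame(run$presence), "presence_matrix.tsv")
  wt(run$statuses, "statuses.tsv")
  wt(run$exclusions, "exclusions.tsv")
  wt(run$stage_counts, "stage_counts.tsv")
  sm <- render_summaries(run)
  wt(sm$lineage_counts, "lineage_counts.tsv")
  wt(as.data.frame(sm$occurrence), "occurrence.tsv")
  wt(sm$loss_table, "loss_table.tsv")
  for (f in names(run$trees))
    ape::write.tree(run$trees[[f]], file.path(dir, paste0("tree_", f, ".nwk")))
  write_config(run$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
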