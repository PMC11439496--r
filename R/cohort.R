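#' Simulate a full benchmark cohort
#'
#' Runs every simulation stage under one seeded random stream: species tree,
#' lineage groups (five clades cut from the tree), per-family domain
#' segments and root proteins, presence evolution (loss and transfer),
#' sequence evolution, bacterial pools, and library assembly (genome
#' vs. transcriptome with dropout and truncation, composition-matched decoy
#' padding, contaminant insertion).  Also assembles the matching query
#' registry (seeds = family root plus a diverged variant; domain seed
#' alignments from the root segments) and the reciprocal-validation
#' database.  Fully deterministic given \code{spec$seed}.
#'
#' @param spec a [simulation_spec()].
#' @return A \code{b12_cohort}: list with \code{spec}, \code{tree},
#'   \code{manifest}, \code{libraries} (record data.frame),
#'   \code{registry}, \code{validation_db}, \code{reference_panel},
#'   \code{truth_species}, \code{truth_sequences}.
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  n <- spec$n_species
  tree <- simulate_species_tree(n, spec$birth_rate)
  species <- tree$tip.label

  # lineage groups: five clusters on the tree metric
  k <- min(5, max(2, n %/% 5))
  cl <- stats::cutree(stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)),
                                    method = "average"), k = k)
  groups <- setNames(sprintf("lineage%d", cl[species]), species)

  # shared domain segments (a domain id means the same segment everywhere)
  all_doms <- unique(unlist(lapply(spec$families, `[[`, "required_domains")))
  dlen <- spec$families[[1]]$domain_length
  segments <- setNames(lapply(all_doms, function(d) random_protein(dlen)),
                       all_doms)

  fam_data <- list()
  for (f in names(spec$families)) {
    fs <- spec$families[[f]]
    rs <- make_root_sequence(fs, segments[fs$required_domains])
    pres <- evolve_presence(tree, fs)
    sq <- evolve_sequences(tree, pres, fs,
                           root_sequence = rs$sequence, domain_mask = rs$mask)
    fam_data[[f]] <- list(spec = fs, root = rs, presence = pres, seqs = sq)
  }

  # library layout
  trans_only <- runif(n) < spec$transcriptome_fraction
  genome_sp <- species[!trans_only]
  dual <- head(genome_sp, 3)            # dual-library strains
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    sp <- species[i]
    rows <- list()
    habitat <- sample(c("marine", "freshwater", "terrestrial", "symbiotic"),
                      1, prob = c(0.4, 0.3, 0.2, 0.1))
    lat <- round(runif(1, -60, 60), 1); lon <- round(runif(1, -180, 180), 1)
    if (!trans_only[i])
      rows$g <- data.frame(library_id = paste0(sp, "_G"), strain_name = sp,
                           library_type = "genome", lineage_group = groups[[sp]],
                           latitude = lat, longitude = lon, habitat = habitat,
                           source_collection = "synthetic-genome",
                           stringsAsFactors = FALSE)
    if (trans_only[i] || sp %in% dual)
      rows$t <- data.frame(library_id = paste0(sp, "_T"), strain_name = sp,
                           library_type = "transcriptome",
                           lineage_group = groups[[sp]],
                           latitude = lat, longitude = lon, habitat = habitat,
                           source_collection = "synthetic-onekp",
                           stringsAsFactors = FALSE)
    do.call(rbind, rows)
  }))
  rownames(manifest) <- NULL

  comp <- table(factor(strsplit(paste(vapply(fam_data, function(x)
    x$root$sequence, ""), collapse = ""), "")[[1]], levels = ab20()))
  comp <- comp / sum(comp)

  libs <- list(); truth_seq <- list()
  for (li in seq_len(nrow(manifest))) {
    lib <- manifest$library_id[li]; sp <- manifest$strain_name[li]
    type <- manifest$library_type[li]
    for (f in names(fam_data)) {
      fd <- fam_data[[f]]
      st <- fd$presence$state[fd$presence$species == sp]
      if (st == "lost") next
      s <- fd$seqs$tip_sequences[[sp]]
      origin <- if (st == "hgt_acquired") "hgt" else "vertical"
      truncated <- FALSE
      if (type == "transcriptome") {
        if (runif(1) < spec$transcriptome_dropout) next
        if (runif(1) < spec$truncation_prob) {
          frac <- runif(1, 0.2, 0.6)
          ncut <- floor(frac * nchar(s))
          s <- if (runif(1) < 0.5) substr(s, ncut + 1, nchar(s))
               else substr(s, 1, nchar(s) - ncut)
          truncated <- TRUE
        }
      }
      label <- if (truncated) "truncated" else origin
      libs[[length(libs) + 1]] <-
        data.frame(id = sprintf("%s_%s", f, sp), description = "",
                   sequence = s, library_id = lib,
                   scaffold_id = if (type == "genome")
                     sprintf("scf_%s_%s", sp, f) else NA_character_,
                   stringsAsFactors = FALSE)
      truth_seq[[length(truth_seq) + 1]] <-
        data.frame(library_id = lib, id = sprintf("%s_%s", f, sp),
                   family = f, species = sp, label = label, origin = origin,
                   truncated = truncated, stringsAsFactors = FALSE)
    }
    for (d in seq_len(spec$n_decoys_per_library)) {
      id <- sprintf("DEC_%s_%02d", lib, d)
      libs[[length(libs) + 1]] <-
        data.frame(id = id, description = "",
                   sequence = random_protein(sample(150:350, 1), comp),
                   library_id = lib, scaffold_id = NA_character_,
                   stringsAsFactors = FALSE)
      truth_seq[[length(truth_seq) + 1]] <-
        data.frame(library_id = lib, id = id, family = NA_character_,
                   species = sp, label = "decoy", origin = "decoy",
                   truncated = FALSE, stringsAsFactors = FALSE)
    }
    if (runif(1) < spec$contamination_rate) {
      f <- sample(names(fam_data), 1)
      pool <- fam_data[[f]]$seqs$pool
      pk <- sample.int(length(pool), 1)
      id <- sprintf("%s_CONT_%s", f, lib)
      libs[[length(libs) + 1]] <-
        data.frame(id = id, description = names(pool)[pk],
                   sequence = pool[[pk]], library_id = lib,
                   scaffold_id = NA_character_, stringsAsFactors = FALSE)
      truth_seq[[length(truth_seq) + 1]] <-
        data.frame(library_id = lib, id = id, family = f, species = sp,
                   label = "contaminant", origin = "contaminant",
                   truncated = FALSE, stringsAsFactors = FALSE)
    }
  }
  libraries <- do.call(rbind, libs)
  truth_sequences <- do.call(rbind, truth_seq)

  # registry: root + diverged variant as seeds; domain seed alignments
  fams <- lapply(names(fam_data), function(f) {
    fd <- fam_data[[f]]
    seed2 <- evolve_seq(fd$root$sequence, 0.1, fd$root$mask,
                        fd$spec$domain_rate_scale)
    query_family(f,
                 data.frame(id = sprintf("%s_seed%d", f, 1:2),
                            sequence = c(fd$root$sequence, seed2),
                            stringsAsFactors = FALSE),
                 required_domains = fd$spec$required_domains,
                 special_rule = if (f == "METE") "mete_arabidopsis" else "none")
  })
  domain_seeds <- setNames(lapply(all_doms, function(d) {
    s <- segments[[d]]
    c(s, evolve_seq(s, 0.08), evolve_seq(s, 0.08))
  }), all_doms)
  registry <- new_registry(fams, domain_seeds)

  # validation database: decoy proteome + seeds (+ Arabidopsis METE trio)
  vseq <- data.frame(id = sprintf("ATDECOY%03d", seq_len(spec$n_validation_decoys)),
                     sequence = vapply(seq_len(spec$n_validation_decoys),
                                       function(i) random_protein(sample(150:350, 1), comp), ""),
                     stringsAsFactors = FALSE)
  vroles <- data.frame(id = vseq$id, role = "decoy_proteome",
                       family = NA_character_, stringsAsFactors = FALSE)
  for (f in registry$families) {
    vseq <- rbind(vseq, f$seed_sequences[, c("id", "sequence")])
    vroles <- rbind(vroles, data.frame(id = f$seed_sequences$id,
                                       role = "registry_query", family = f$name,
                                       stringsAsFactors = FALSE))
  }
  if ("METE" %in% names(fam_data)) {
    at_ids <- c("At5g17920", "At3g03780", "At5g20980")
    mete <- fam_data[["METE"]]
    at_seq <- vapply(at_ids, function(i)
      evolve_seq(mete$root$sequence, 0.15, mete$root$mask,
                 mete$spec$domain_rate_scale), "")
    vseq <- rbind(vseq, data.frame(id = at_ids, sequence = unname(at_seq),
                                   stringsAsFactors = FALSE))
    vroles <- rbind(vroles, data.frame(id = at_ids,
                                       role = "arabidopsis_met_synthase",
                                       family = "METE", stringsAsFactors = FALSE))
  }
  vdb <- validation_db(vseq, vroles)

  reference_panel <- do.call(rbind, lapply(names(fam_data), function(f) {
    pool <- fam_data[[f]]$seqs$pool
    outg <- fam_data[[f]]$seqs$outgroup
    rbind(data.frame(id = names(pool), sequence = unname(pool), family = f,
                     domain = "bacteria", stringsAsFactors = FALSE),
          data.frame(id = names(outg), sequence = unname(outg), family = f,
                     domain = "eukaryote", stringsAsFactors = FALSE))
  }))

  truth_species <- do.call(rbind, lapply(names(fam_data), function(f) {
    p <- fam_data[[f]]$presence
    data.frame(species = p$species, family = f, state = p$state,
               hgt_event = p$hgt_event, stringsAsFactors = FALSE)
  }))

  structure(list(spec = spec, tree = tree, groups = groups,
                 manifest = manifest, libraries = libraries,
                 registry = registry, validation_db = vdb,
                 reference_panel = reference_panel,
                 truth_species = truth_species,
                 truth_sequences = truth_sequences),
            class = "b12_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the input formats of the pipeline: one FASTA per library, a
#' tab-separated manifest, the registry directory, the validation database
#' (FASTA plus role sidecar TSV), the bacterial reference panel FASTA, and
#' the two truth tables.  Writing is deterministic: the same cohort object
#' always produces byte-identical files.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  libdir <- file.path(dir, "libraries")
  dir.create(libdir, showWarnings = FALSE)
  for (lib in unique(cohort$libraries$library_id)) {
    rec <- cohort$libraries[cohort$libraries$library_id == lib, ]
    write_fasta(setNames(rec$sequence, rec$id),
                file.path(libdir, paste0(lib, ".fasta")))
  }
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_registry(cohort$registry, file.path(dir, "registry"))
  write_fasta(setNames(cohort$validation_db$sequence, cohort$validation_db$id),
              file.path(dir, "validation_db.fasta"))
  write.table(cohort$validation_db[, c("id", "role", "family")],
              file.path(dir, "validation_roles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(setNames(cohort$reference_panel$sequence,
                       cohort$reference_panel$id),
              file.path(dir, "reference_panel.fasta"))
  write.table(cohort$reference_panel[, c("id", "family", "domain")],
              file.path(dir, "reference_roles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth_species, file.path(dir, "truth_species.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth_sequences, file.path(dir, "truth_sequences.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score pipeline output against simulation truth
#'
#' Compares a pipeline run on a simulated cohort with the cohort's ground
#' truth.  Reported metrics: per-family and overall presence precision and
#' recall over strain-by-family cells (truth present = gene retained or
#' transferred); contaminant detection recall over planted contaminants
#' that entered the candidate set; the false-positive rate of the
#' contaminant/transfer screen on vertically inherited records; the number
#' of presence cells driven purely by contamination; methionine-status
#' accuracy against the truth-derived status; and genome-gated accuracy of
#' METE absence calls.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param result a [run_pipeline()] result for that cohort.
#' @return list of metrics (see details) with a \code{summary} data.frame.
#' @export
score_pipeline <- function(cohort, result) {
  mat <- result$presence
  truth <- cohort$truth_species
  if (!setequal(mat$strain, unique(truth$species)))
    stopf("strain sets of truth and prediction differ")
  fams <- unique(truth$family)
  truth$present <- truth$state %in% c("retained", "hgt_acquired")
  tp <- fp <- fn <- 0
  perfam <- list()
  contam_false <- 0
  for (f in fams) {
    tf <- truth[truth$family == f, ]
    pred <- cell_present(mat[[f]][match(tf$species, mat$strain)])
    tpx <- sum(pred & tf$present); fpx <- sum(pred & !tf$present)
    fnx <- sum(!pred & tf$present)
    perfam[[f]] <- data.frame(family = f,
                              precision = ifelse(tpx + fpx > 0, tpx / (tpx + fpx), NA),
                              recall = ifelse(tpx + fnx > 0, tpx / (tpx + fnx), NA),
                              stringsAsFactors = FALSE)
    tp <- tp + tpx; fp <- fp + fpx; fn <- fn + fnx
    # false presences traceable to a planted contaminant
    ts <- cohort$truth_sequences
    for (i in which(pred & !tf$present)) {
      sp <- tf$species[i]
      if (any(ts$label == "contaminant" & ts$family == f & ts$species == sp))
        contam_false <- contam_false + 1
    }
  }

  rc <- result$record_calls
  ts <- cohort$truth_sequences
  key <- function(d) paste(d$library_id, d$id)
  rc$truth_origin <- ts$origin[match(key(rc), key(ts))]
  cont <- rc[!is.na(rc$truth_origin) & rc$truth_origin == "contaminant", ]
  contam_recall <- if (nrow(cont) > 0) mean(cont$flag == "contaminant") else NA
  vert <- rc[!is.na(rc$truth_origin) & rc$truth_origin == "vertical", ]
  vertical_fp <- if (nrow(vert) > 0) mean(vert$flag %in% c("contaminant", "hgt")) else 0
  hgt <- rc[!is.na(rc$truth_origin) & rc$truth_origin == "hgt", ]
  hgt_as_hgt <- if (nrow(hgt) > 0) mean(hgt$flag == "hgt") else NA

  # truth-derived status vs predicted status
  strains <- dedupe_strains(cohort$manifest)
  tmat <- data.frame(strain = strains$strain, has_genome = strains$has_genome,
                     low_coverage = FALSE, stringsAsFactors = FALSE)
  for (f in fams) {
    st <- truth[truth$family == f, ]
    tmat[[f]] <- ifelse(st$present[match(tmat$strain, st$species)],
                        "present", "absent")
  }
  class(tmat) <- c("presence_matrix", "data.frame")
  truth_status <- classify_all(tmat)
  pred_status <- result$statuses
  ord <- match(truth_status$strain, pred_status$strain)
  status_accuracy <- mean(truth_status$methionine_status ==
                            pred_status$methionine_status[ord])
  gen <- which(tmat$has_genome)
  mete_absence_acc <- if ("METE" %in% fams && length(gen) > 0) {
    mean((tmat$METE[gen] == "absent") ==
           !cell_present(mat$METE[match(tmat$strain[gen], mat$strain)]))
  } else NA

  list(presence_precision = ifelse(tp + fp > 0, tp / (tp + fp), NA),
       presence_recall = ifelse(tp + fn > 0, tp / (tp + fn), NA),
       per_family = do.call(rbind, perfam),
       contaminant_recall = contam_recall,
       n_planted_contaminants_in_calls = nrow(cont),
       contaminant_false_presences = contam_false,
       vertical_fp_rate = vertical_fp,
       hgt_labelled_hgt = hgt_as_hgt,
       status_accuracy = status_accuracy,
       mete_absence_accuracy_genome = mete_absence_acc,
       summary = data.frame(
         metric = c("presence_precision", "presence_recall",
                    "contaminant_recall", "contaminant_false_presences",
                    "vertical_fp_rate", "status_accuracy",
                    "mete_absence_accuracy_genome"),
         value = c(ifelse(tp + fp > 0, tp / (tp + fp), NA),
                   ifelse(tp + fn > 0, tp / (tp + fn), NA),
                   contam_recall, contam_false, vertical_fp,
                   status_accuracy, mete_absence_acc),
         stringsAsFactors = FALSE))
}

#' Curation-stage discrimination benchmark on a simulated cohort
#'
#' Isolates the contaminant/transfer screen: for every family, the cohort's
#' truth-labelled gene records (vertical, transferred, truncated,
#' contaminant) are joined with the family's reference panel, pruned,
#' aligned, trimmed and placed on a neighbour-joining tree, and
#' [flag_contaminants()] is applied.  Returns one row per library record
#' with its flag and truth origin, from which contaminant recall, transfer
#' labelling and the vertical false-positive rate are measured directly.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config a [pipeline_config()].
#' @return data.frame: \code{tip}, \code{flag}, \code{origin},
#'   \code{family}.
#' @export
curation_flags <- function(cohort, config = pipeline_config()) {
  tq <- cohort$truth_sequences
  man <- cohort$manifest
  out <- list()
  for (f in names(cohort$registry$families)) {
    lab <- tq[!is.na(tq$family) & tq$family == f, , drop = FALSE]
    sel <- match(paste(lab$library_id, lab$id),
                 paste(cohort$libraries$library_id, cohort$libraries$id))
    recs <- cohort$libraries[sel, , drop = FALSE]
    if (nrow(recs) == 0) next
    keys <- paste0(recs$library_id, "@", recs$id)
    refs <- cohort$reference_panel[cohort$reference_panel$family == f, ]
    curset <- c(setNames(recs$sequence, keys),
                setNames(refs$sequence, refs$id))
    if (length(curset) < 4) next
    pr <- prune_divergent(curset, config)
    msa <- tryCatch(trim_columns(pr$msa, config), error = function(e) pr$msa)
    tree <- nj_tree(suppressWarnings(poisson_distance(msa)))
    ridx <- match(tree$tip.label, refs$id)
    is_ref <- !is.na(ridx)
    libid <- sub("@.*$", "", tree$tip.label)
    ann <- data.frame(
      tip = tree$tip.label,
      domain = ifelse(is_ref, refs$domain[ridx], "eukaryote"),
      lineage_group = ifelse(is_ref, paste0("ref_", refs$domain[ridx]),
                             man$lineage_group[match(libid, man$library_id)]),
      strain = ifelse(is_ref, tree$tip.label,
                      man$strain_name[match(libid, man$library_id)]),
      stringsAsFactors = FALSE)
    fl <- flag_contaminants(tree, ann, pairwise_identity(msa), config)
    fl <- fl[!is_ref[match(fl$tip, tree$tip.label)], , drop = FALSE]
    fl$origin <- lab$origin[match(paste(sub("@.*$", "", fl$tip),
                                        sub("^.*@", "", fl$tip)),
                                  paste(lab$library_id, lab$id))]
    fl$family <- f
    out[[f]] <- fl
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
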