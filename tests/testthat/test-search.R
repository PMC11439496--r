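make_family <- function(name = "FAM", seed_seq = NULL, special = "none") {
  if (is.null(seed_seq)) seed_seq <- rand_prot(200)
  query_family(name,
               data.frame(id = paste0(name, "_seed"), sequence = seed_seq,
                          stringsAsFactors = FALSE),
               required_domains = "PFX", special_rule = special)
}

test_that("a planted homologue is recovered from a decoy library", {
  set.seed(11)
  fam <- make_family()
  homol <- mutate_prot(fam$seed_sequences$sequence[1], 0.3)
  lib <- data.frame(id = c(paste0("dec", 1:50), "planted"),
                    sequence = c(replicate(50, rand_prot(200)), homol),
                    library_id = "L1", stringsAsFactors = FALSE)
  hits <- find_candidates(fam, lib)
  expect_true("planted" %in% hits$id)
  expect_false(any(grepl("^dec", hits$id)))
})

test_that("shuffled sequences are never candidates at the default threshold", {
  set.seed(12)
  fam <- make_family()
  shuf <- vapply(1:40, function(i)
    paste(sample(strsplit(fam$seed_sequences$sequence[1], "")[[1]]),
          collapse = ""), "")
  lib <- data.frame(id = paste0("s", 1:40), sequence = shuf,
                    library_id = "L1", stringsAsFactors = FALSE)
  expect_equal(nrow(find_candidates(fam, lib)), 0)
})

test_that("an identical copy of a seed returns with identity 1", {
  fam <- make_family()
  lib <- data.frame(id = "copy", sequence = fam$seed_sequences$sequence[1],
                    library_id = "L1", stringsAsFactors = FALSE)
  hits <- find_candidates(fam, lib)
  expect_equal(hits$identity, 1)
  expect_equal(hits$status, "candidate")
})

test_that("raising the E-value threshold never removes a candidate", {
  set.seed(13)
  fam <- make_family()
  lib <- data.frame(id = paste0("r", 1:30),
                    sequence = c(vapply(1:5, function(i)
                      mutate_prot(fam$seed_sequences$sequence[1],
                                  runif(1, 0.3, 0.8)), ""),
                      replicate(25, rand_prot(200))),
                    library_id = "L1", stringsAsFactors = FALSE)
  loose <- find_candidates(fam, lib, pipeline_config(forward_evalue_threshold = 1))
  tight <- find_candidates(fam, lib, pipeline_config(forward_evalue_threshold = 1e-5))
  expect_true(all(tight$id %in% loose$id))
})

make_vdb <- function(fam, n_decoys = 20, extra = NULL) {
  set.seed(77)
  seqs <- data.frame(id = c(sprintf("dec%02d", seq_len(n_decoys)),
                            fam$seed_sequences$id),
                     sequence = c(replicate(n_decoys, rand_prot(200)),
                                  fam$seed_sequences$sequence),
                     stringsAsFactors = FALSE)
  roles <- data.frame(id = seqs$id,
                      role = c(rep("decoy_proteome", n_decoys),
                               rep("registry_query", nrow(fam$seed_sequences))),
                      family = c(rep(NA, n_decoys),
                                 rep(fam$name, nrow(fam$seed_sequences))),
                      stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    seqs <- rbind(seqs, extra$seqs); roles <- rbind(roles, extra$roles)
  }
  validation_db(seqs, roles)
}

test_that("reciprocal best hit to the same family validates; decoys reject", {
  set.seed(14)
  fam <- make_family("METH")
  db <- make_vdb(fam)
  homol <- mutate_prot(fam$seed_sequences$sequence[1], 0.3)
  r <- reciprocal_validate(homol, "METH", db)
  expect_true(r$validated)
  expect_equal(r$matched_id, "METH_seed")
  # a decoy itself retrieves a decoy best hit and is rejected
  r2 <- reciprocal_validate(db$sequence[db$id == "dec01"], "METH", db)
  expect_false(r2$validated)
  expect_equal(r2$matched_role, "decoy_proteome")
})

test_that("the METE special rule accepts Arabidopsis methionine synthases", {
  set.seed(15)
  mete_seed <- rand_prot(220)
  fam <- make_family("METE", seed_seq = rand_prot(220),
                     special = "mete_arabidopsis")
  at <- mutate_prot(mete_seed, 0.15)
  extra <- list(seqs = data.frame(id = "At5g17920", sequence = at,
                                  stringsAsFactors = FALSE),
                roles = data.frame(id = "At5g17920",
                                   role = "arabidopsis_met_synthase",
                                   family = "METE", stringsAsFactors = FALSE))
  db <- make_vdb(fam, extra = extra)
  cand <- mutate_prot(mete_seed, 0.25)   # closer to the At protein lineage
  r <- reciprocal_validate(cand, "METE", db, special_rule = "mete_arabidopsis")
  expect_true(r$validated)
  expect_equal(r$matched_id, "At5g17920")
  # without the special rule the same best hit does not validate
  r2 <- reciprocal_validate(cand, "METE", db, special_rule = "none")
  expect_false(r2$validated)
})

test_that("score ties prefer registry queries over decoys", {
  seqs <- data.frame(id = c("decX", "famQ"),
                     sequence = c("MKTAYIAKQRQISFVK", "MKTAYIAKQRQISFVK"),
                     stringsAsFactors = FALSE)
  roles <- data.frame(id = seqs$id, role = c("decoy_proteome", "registry_query"),
                      family = c(NA, "FAM"), stringsAsFactors = FALSE)
  db <- validation_db(seqs, roles)
  r <- reciprocal_validate("MKTAYIAKQRQISFVK", "FAM", db)
  expect_true(r$validated)
  expect_equal(r$matched_id, "famQ")
})

test_that("an empty validation database is a configuration error", {
  db <- validation_db(data.frame(id = character(), sequence = character()),
                      data.frame(id = character(), role = character()))
  expect_error(reciprocal_validate("ACDEF", "FAM", db), "empty validation")
})

test_that("reciprocal validation is order independent", {
  set.seed(16)
  fam <- make_family("MCM")
  db <- make_vdb(fam)
  cand <- mutate_prot(fam$seed_sequences$sequence[1], 0.35)
  r1 <- reciprocal_validate(cand, "MCM", db)
  db_shuf <- db[sample(nrow(db)), ]
  class(db_shuf) <- class(db)
  r2 <- reciprocal_validate(cand, "MCM", db_shuf)
  expect_equal(r1$validated, r2$validated)
  expect_equal(r1$matched_id, r2$matched_id)
})
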