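test_that("the strongest call wins per strain and family", {
  calls <- rbind(call_row("S1", "METH", "complete_split", id = "a"),
                 call_row("S1", "METH", "complete", id = "b"),
                 call_row("S2", "METH", "partial"),
                 call_row("S3", "METH", "complete", flag = "contaminant"))
  mat <- build_presence_matrix(calls, mini_strains(), mini_registry())
  expect_equal(mat$METH, c("present", "present_partial", "contaminant_only"))
})

test_that("contaminant-flagged records never yield presence", {
  calls <- rbind(call_row("S1", "METE", "complete", flag = "contaminant"),
                 call_row("S1", "METE", "partial", flag = "contaminant"))
  mat <- build_presence_matrix(calls, mini_strains(), mini_registry())
  expect_equal(mat$METE[1], "contaminant_only")
  st <- classify_b12_status(mat[1, ])
  expect_equal(st$methionine_status, "unknown")
})

test_that("an empty call set gives an all-absent matrix", {
  calls <- call_row("S1", "METH")[0, ]
  mat <- build_presence_matrix(calls, mini_strains(), mini_registry())
  expect_true(all(mat$METH == "absent"))
  expect_error(build_presence_matrix(call_row("S9", "METH"), mini_strains(),
                                     mini_registry()), "unknown strain")
})

test_that("methionine status logic covers the four classes", {
  expect_equal(classify_b12_status(
    status_row(METH = "present", METE = "present", MTRR = "present")
  )$methionine_status, "facultative")
  expect_equal(classify_b12_status(
    status_row(METH = "present"))$methionine_status, "dependent_only")
  expect_equal(classify_b12_status(
    status_row(METE = "present"))$methionine_status, "independent_only")
  expect_equal(classify_b12_status(status_row())$methionine_status, "unknown")
})

test_that("loss of known B12 metabolism requires a genome and full absence", {
  st <- classify_b12_status(status_row(METE = "present", has_genome = TRUE))
  expect_true(st$lost_known_b12)
  st2 <- classify_b12_status(status_row(METE = "present", MCM = "present",
                                        has_genome = TRUE))
  expect_false(st2$lost_known_b12)
  expect_equal(st2$adenosyl_users, "MCM")
  st3 <- classify_b12_status(status_row(METE = "present", has_genome = FALSE))
  expect_true(is.na(st3$lost_known_b12))
})

test_that("partial presence counts as absent for status but split counts", {
  st <- classify_b12_status(status_row(METE = "present_partial",
                                       METH = "present"))
  expect_equal(st$methionine_status, "dependent_only")
  st2 <- classify_b12_status(status_row(METE = "present_split",
                                        METH = "present"))
  expect_equal(st2$methionine_status, "facultative")
})

test_that("transcriptome-only METH calls carry a low-confidence flag", {
  st <- classify_b12_status(status_row(METH = "present", has_genome = FALSE))
  expect_equal(st$methionine_status, "dependent_only")
  expect_true(st$low_confidence)
  st2 <- classify_b12_status(status_row(METH = "present", has_genome = TRUE))
  expect_false(st2$low_confidence)
})

test_that("loss implies the independent-only colour class, always", {
  set.seed(51)
  cells <- c("present", "present_partial", "present_split", "absent",
             "contaminant_only")
  for (k in 1:200) {
    row <- status_row(has_genome = sample(c(TRUE, FALSE), 1))
    for (f in c("METE", "METH", "MTRR", "MCM", "RNR-II", "CblA"))
      row[[f]] <- sample(cells, 1)
    st <- classify_b12_status(row)
    if (isTRUE(st$lost_known_b12)) {
      expect_equal(st$methionine_status, "independent_only")
      expect_length(st$adenosyl_users, 0)
    }
  }
})

test_that("classification is a pure per-row function (order invariant)", {
  strains <- mini_strains(4)
  calls <- rbind(call_row("S1", "METH"), call_row("S2", "METE"),
                 call_row("S3", "METH"), call_row("S3", "METE"))
  mat <- build_presence_matrix(calls, strains, mini_registry())
  st1 <- classify_all(mat)
  perm <- mat[c(3, 1, 4, 2), ]
  st2 <- classify_all(perm)
  expect_equal(st2[order(st2$strain), ], st1[order(st1$strain), ],
               ignore_attr = TRUE)
})

test_that("targeting consensus uses a strict majority of >= 3 tools", {
  r <- targeting_consensus(c(WolfPSort = "mitochondrion", SignalP = "mitochondrion",
                             ASAFind = "mitochondrion", TargetP = "mitochondrion",
                             HECTAR = "secretory"))
  expect_equal(r$consensus, "mitochondrion")
  r2 <- targeting_consensus(c(a = "plastid", b = "plastid", c = "secretory",
                              d = "secretory", e = "none"))
  expect_equal(r2$consensus, "ambiguous")
  r3 <- targeting_consensus(c(a = "plastid"))
  expect_equal(r3$consensus, "ambiguous")
  expect_match(r3$note, "fewer than 3")
  expect_error(targeting_consensus(c(a = "nucleus")), "accepted terms")
})

test_that("per-lineage tabulation counts strains, not libraries", {
  strains <- mini_strains(4)
  calls <- rbind(call_row("S1", "METH"), call_row("S2", "METE"),
                 call_row("S3", "METH"), call_row("S3", "METE"),
                 call_row("S3", "MCM"))
  mat <- build_presence_matrix(calls, strains, mini_registry())
  tab <- tabulate_groups(mat, strains)
  syn <- tab$synthase
  expect_equal(sum(syn$meth_only), 1)
  expect_equal(sum(syn$mete_only), 1)
  expect_equal(sum(syn$both), 1)
  expect_equal(sum(syn$total_assessable), 4)
  expect_true(all(syn$meth_only + syn$mete_only + syn$both <=
                    syn$total_assessable))
  expect_equal(tab$occurrence[strains$lineage_group[3], "MCM"], 1)
})

test_that("habitat cross-tabulation counts and excludes correctly", {
  strains <- mini_strains(5)
  strains$habitat <- c("freshwater", "freshwater", "marine", NA, "hot spring")
  statuses <- data.frame(strain = strains$strain,
                         methionine_status = "independent_only",
                         low_confidence = FALSE, adenosyl_users = "",
                         accessory_present = "",
                         lost_known_b12 = c(TRUE, TRUE, FALSE, TRUE, NA),
                         stringsAsFactors = FALSE)
  hc <- habitat_crosstab(statuses, strains)
  expect_equal(hc$table["freshwater", "TRUE"], 2)
  expect_equal(hc$table["marine", "FALSE"], 1)
  expect_equal(hc$excluded, 2)           # missing habitat + NA loss status
  expect_equal(sum(hc$table), 3)
})

test_that("a survey-style loss cohort round-trips through the cross-tab", {
  # 15 species with habitat classes matching a published-style loss survey
  habs <- c("marine", "freshwater", "marine", "terrestrial", "freshwater",
            "other", "other", "marine", "freshwater", "freshwater",
            "freshwater", "freshwater", "marine", "freshwater", "marine")
  strains <- mini_strains(15)
  strains$habitat <- habs
  statuses <- data.frame(strain = strains$strain,
                         methionine_status = "independent_only",
                         low_confidence = FALSE, adenosyl_users = "",
                         accessory_present = "",
                         lost_known_b12 = c(rep(TRUE, 11), rep(FALSE, 4)),
                         stringsAsFactors = FALSE)
  hc <- habitat_crosstab(statuses, strains)
  expect_equal(sum(hc$table), 15)
  expect_equal(as.numeric(rowSums(hc$table)[names(table(habs))]),
               as.numeric(table(habs)))
  expect_equal(sum(hc$table[, "TRUE"]), 11)
})
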