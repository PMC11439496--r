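test_that("profile scores match hand-computed add-alpha log odds", {
  seed <- c("ACDA", "ACDC", "ACDA")   # 3 rows, 4 columns
  p <- suppressWarnings(build_profile(seed, pseudocount = 0.5))
  # column 1: 3 x A -> log(((3 + .5)/(3 + 10)) / 0.05)
  expect_equal(unname(p$scores[1, "A"]), log((3.5 / 13) / 0.05))
  expect_equal(unname(p$scores[1, "C"]), log((0.5 / 13) / 0.05))
  # column 4: 2 x A, 1 x C
  expect_equal(unname(p$scores[4, "A"]), log((2.5 / 13) / 0.05))
  expect_equal(unname(p$scores[4, "C"]), log((1.5 / 13) / 0.05))
  expect_equal(p$length, 4)
})

test_that("pseudocount limits behave as expected", {
  seed <- c("MKLM", "MKLM", "MKLM")
  tiny <- suppressWarnings(build_profile(seed, pseudocount = 1e-9))
  expect_equal(unname(tiny$scores[1, "M"]), log((3 / 3) / 0.05), tolerance = 1e-6)
  huge <- suppressWarnings(build_profile(seed, pseudocount = 1e6))
  expect_lt(max(abs(huge$scores)), 1e-4)   # prior dominates, scores -> 0
})

test_that("majority-gap columns are excluded from the model", {
  seed <- c("A-CD", "A-CD", "ABCD")
  p <- suppressWarnings(build_profile(seed))
  expect_equal(p$length, 3)
  expect_error(build_profile(c("--", "--", "A-")), "majority-gap")
})

test_that("profile scanning equals the positional brute-force oracle", {
  set.seed(41)
  for (k in 1:25) {
    L <- sample(3:6, 1)
    S <- matrix(runif(L * 21, -1.5, 2), L, 21)
    seqlen <- sample(4:12, 1)
    enc <- sample(21, seqlen, TRUE)
    ours <- b12screen:::align_dp_cpp(S[, enc, drop = FALSE], 4, 0.5, TRUE, FALSE)$score
    expect_equal(ours, oracle_local_matrix(S[, enc, drop = FALSE], 4, 0.5))
  }
})

test_that("registry seeds are domain-complete against their own profiles", {
  reg <- default_registry()
  profs <- suppressWarnings(registry_profiles(reg))
  for (f in reg$families) {
    need <- if (f$special_rule == "cba1_consensus")
      paste0(f$name, "_consensus") else f$required_domains
    fp <- profs[need]
    hits <- scan_domains(f$seed_sequences$sequence[1], fp)
    cc <- assess_completeness(hits, f, "seed1")
    expect_equal(cc$status, "complete", info = f$name)
    # architecture order: hits come back sorted by sequence position
    expect_equal(hits$profile[order(hits$start)], hits$profile)
  }
})

test_that("truncation removes the corresponding domain hit", {
  reg <- default_registry()
  profs <- suppressWarnings(registry_profiles(reg))
  meth <- reg$families$METH
  s <- meth$seed_sequences$sequence[1]
  full <- scan_domains(s, profs[meth$required_domains])
  trunc <- scan_domains(substr(s, full$end[1] + 10, nchar(s)),
                        profs[meth$required_domains])
  expect_false(full$profile[1] %in% trunc$profile)
  cc <- assess_completeness(trunc, meth, "t")
  expect_equal(cc$status, "partial")
  expect_true(full$profile[1] %in% cc$missing_domains)
})

test_that("scanning with no profiles yields no hits", {
  expect_equal(nrow(scan_domains("MKTAYIAK", list())), 0)
})

test_that("a consensus profile of identical sequences equals the single PSSM", {
  s <- rand_prot(80)
  cp <- consensus_profile(s, s)
  sp <- build_profile(c(s, s))
  expect_equal(cp$scores, sp$scores)
})

test_that("a consensus profile recognises both diverged parents", {
  set.seed(42)
  a <- rand_prot(220)
  b <- mutate_prot(a, 0.72)             # ~28% identity
  cp <- consensus_profile(a, b)
  for (parent in c(a, b)) {
    hits <- scan_domains(parent, list(cp))
    expect_equal(nrow(hits), 1)
    expect_lte(hits$evalue, 1e-5)
  }
  shuffled <- paste(sample(strsplit(a, "")[[1]]), collapse = "")
  expect_equal(nrow(scan_domains(shuffled, list(cp))), 0)
})

test_that("completeness is monotone in hits and lists misses in order", {
  fam <- query_family("METH",
                      data.frame(id = "s", sequence = "ACD",
                                 stringsAsFactors = FALSE),
                      required_domains = c("PF02574", "PF00809", "PF02607",
                                           "PF02310", "PF02965"))
  h <- function(p) data.frame(profile = as.character(p),
                              start = rep(0L, length(p)),
                              end = rep(10L, length(p)),
                              score = rep(50, length(p)),
                              evalue = rep(1e-10, length(p)),
                              stringsAsFactors = FALSE)
  none <- assess_completeness(h(character(0)), fam, "r")
  expect_equal(none$status, "absent")
  part <- assess_completeness(h(c("PF02574", "PF02310")), fam, "r")
  expect_equal(part$status, "partial")
  expect_equal(part$missing_domains, c("PF00809", "PF02607", "PF02965"))
  full <- assess_completeness(h(c("PF02574", "PF00809", "PF02607",
                                  "PF02310", "PF02965")), fam, "r")
  expect_equal(full$status, "complete")
  expect_equal(full$missing_domains, character(0))
})

meth_fam <- function() query_family(
  "METH", data.frame(id = "s", sequence = "ACD", stringsAsFactors = FALSE),
  required_domains = c("PF02574", "PF00809", "PF02607", "PF02310", "PF02965"))

call_with <- function(doms, id) {
  fam <- meth_fam()
  hits <- data.frame(profile = doms, start = 0L, end = 1L, score = 50,
                     evalue = 1e-10, stringsAsFactors = FALSE)
  assess_completeness(hits, fam, id)
}

test_that("split gene models on one scaffold are rescued; across scaffolds not", {
  fam <- meth_fam()
  a <- call_with(c("PF02574", "PF00809", "PF02310", "PF02965"), "modelA")
  b <- call_with("PF02607", "modelB")
  recs_same <- data.frame(id = c("modelA", "modelB"),
                          scaffold_id = c("utg000003l", "utg000003l"),
                          stringsAsFactors = FALSE)
  r <- rescue_split_models(list(a, b), recs_same, fam, "genome")
  expect_equal(r$status, "complete_split")
  expect_setequal(r$contributing_records, c("modelA", "modelB"))
  recs_diff <- data.frame(id = c("modelA", "modelB"),
                          scaffold_id = c("utg000003l", "utg000145l"),
                          stringsAsFactors = FALSE)
  r2 <- rescue_split_models(list(a, b), recs_diff, fam, "genome")
  expect_equal(r2$status, "partial")
  expect_match(r2$note, "multi-scaffold")
})

test_that("a complete record takes precedence and transcriptomes never rescue", {
  fam <- meth_fam()
  full <- call_with(fam$required_domains, "whole")
  a <- call_with(c("PF02574", "PF00809", "PF02310", "PF02965"), "modelA")
  b <- call_with("PF02607", "modelB")
  recs <- data.frame(id = c("whole", "modelA", "modelB"),
                     scaffold_id = rep("sc1", 3), stringsAsFactors = FALSE)
  r <- rescue_split_models(list(full, a, b), recs, fam, "genome")
  expect_equal(r$status, "complete")
  expect_equal(r$record_id, "whole")
  rt <- rescue_split_models(list(a, b), recs[2:3, ], fam, "transcriptome")
  expect_equal(rt$status, "partial")
})

test_that("records without scaffold ids are skipped from rescue with warning", {
  fam <- meth_fam()
  a <- call_with(c("PF02574", "PF00809", "PF02310", "PF02965"), "modelA")
  b <- call_with("PF02607", "modelB")
  recs <- data.frame(id = c("modelA", "modelB"),
                     scaffold_id = c("sc1", NA), stringsAsFactors = FALSE)
  expect_warning(r <- rescue_split_models(list(a, b), recs, fam, "genome"),
                 "scaffold")
  expect_equal(r$status, "partial")
})
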