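test_that("centre-star alignment handles identical and near-identical pairs", {
  m <- profile_align(c(a = "MKTAYIAK", b = "MKTAYIAK"))
  expect_equal(unname(unclass(m)), c("MKTAYIAK", "MKTAYIAK"))
  m2 <- profile_align(c(x = "ACDE", y = "ACE"))
  expect_equal(unclass(m2)[["y"]], "AC-E")
})

test_that("ungapping any alignment row reproduces its input sequence", {
  set.seed(21)
  base <- rand_prot(60)
  seqs <- setNames(c(vapply(1:5, function(i) mutate_prot(base, 0.2), ""),
                     substr(base, 20, 60)),
                   paste0("s", 1:6))
  m <- profile_align(seqs)
  expect_equal(gsub("-", "", unclass(m))[names(seqs)], seqs)
})

test_that("column trimming follows the >=50% ungapped rule exactly", {
  rows <- vapply(1:10, function(i) {
    g1 <- if (i <= 6) "-" else "A"   # column 2: 6 gaps  -> drop (0.4 < 0.5)
    g2 <- if (i <= 5) "-" else "C"   # column 4: 5 gaps  -> keep (0.5 >= 0.5)
    paste0("M", g1, "K", g2, "L")
  }, "")
  msa <- as_msa(setNames(rows, paste0("r", 1:10)))
  tr <- trim_columns(msa)
  expect_equal(nchar(tr[[1]]), 4)
  expect_equal(substr(tr[[1]], 1, 1), "M")
  expect_true(grepl("[C-]", substr(tr[[7]], 3, 3)))
  # idempotent and never longer
  expect_equal(unclass(trim_columns(tr)), unclass(tr))
  gapless <- as_msa(c(a = "MKL", b = "MKL"))
  expect_equal(unclass(trim_columns(gapless)), unclass(gapless))
})

test_that("trimming drops rows made all-gap and errors on empty results", {
  msa <- as_msa(c(a = "MK--", b = "MKAC", c = "--AC", d = "MKAC"))
  msa2 <- as_msa(c(a = "M---", b = "MACD", c = "MACD", d = "MACD"))
  tr <- trim_columns(msa2, pipeline_config(gap_threshold = 1))
  expect_equal(nchar(tr[[1]]), 1)
  all_gappy <- as_msa(c(a = "A---", b = "-C--", c = "--G-", d = "---T"))
  expect_error(trim_columns(all_gappy), "every column")
})

test_that("Poisson distances match the closed form and cap at saturation", {
  msa <- as_msa(c(a = "AAAA", b = "AAAA"))
  expect_equal(poisson_distance(msa)["a", "b"], 0)
  m2 <- as_msa(c(a = "AAAACCCC", b = "AAAAGGGG"))  # p = 0.5
  expect_equal(poisson_distance(m2)["a", "b"], -log(0.5), tolerance = 1e-12)
  m3 <- as_msa(c(a = strrep("A", 20),
                 b = paste(c(rep("G", 19), "C"), collapse = "")))  # p = 0.95
  d3 <- poisson_distance(m3)["a", "b"]
  expect_equal(d3, -log(1 - 0.95))
  m4 <- as_msa(c(a = strrep("A", 20), b = strrep("G", 20)))        # p = 1
  expect_equal(poisson_distance(m4)["a", "b"], d3)   # cap, not larger
})

test_that("pairs with no overlapping columns warn and take the cap", {
  msa <- as_msa(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_warning(D <- poisson_distance(msa), "no mutually ungapped")
  expect_equal(D["a", "b"], -log(1 - 0.95))
})

test_that("iterative pruning removes a planted rogue and is idempotent", {
  set.seed(22)
  base <- rand_prot(60)
  seqs <- setNames(c(vapply(1:9, function(i) mutate_prot(base, 0.15), ""),
                     rand_prot(60)), c(paste0("h", 1:9), "rogue"))
  pr <- prune_divergent(seqs)
  expect_equal(pr$removed_log$id, "rogue")
  expect_equal(pr$removed_log$iteration, 1L)
  expect_gt(pr$removed_log$branch_length, 1)
  expect_false(pr$unalignable)
  # second pass removes nothing
  pr2 <- prune_divergent(pr$retained)
  expect_equal(nrow(pr2$removed_log), 0)
  expect_equal(names(pr2$retained), names(pr$retained))
})

test_that("a conserved set is returned untouched", {
  set.seed(23)
  base <- rand_prot(50)
  seqs <- setNames(vapply(1:6, function(i) mutate_prot(base, 0.1), ""),
                   paste0("s", 1:6))
  pr <- prune_divergent(seqs)
  expect_equal(pr$retained, seqs)
  expect_equal(nrow(pr$removed_log), 0)
})

test_that("the long-branch rule is strictly greater-than", {
  tr <- ape::read.tree(text = "((A:1.0,B:0.2):0.1,(C:0.3,D:1.000001):0.1);")
  expect_equal(names(long_terminal_branches(tr, 1.0)), "D")
  tr2 <- ape::read.tree(text = "((A:1.0,B:0.2):0.1,(C:0.3,D:0.9):0.1);")
  expect_length(long_terminal_branches(tr2, 1.0), 0)
})

# --- contaminant / transfer discrimination on hand-built trees -----------

ann_tips <- function(tree, proks, groups, strains = NULL) {
  tips <- tree$tip.label
  data.frame(tip = tips,
             domain = ifelse(tips %in% proks, "bacteria", "eukaryote"),
             lineage_group = groups[tips],
             strain = if (is.null(strains)) tips else strains[tips],
             stringsAsFactors = FALSE)
}

test_that("a single library resolving among bacteria is a contaminant", {
  tr <- ape::read.tree(text = paste0(
    "(((liv1:0.1,(b1:0.1,b2:0.1):0.05):0.1,(b3:0.1,b4:0.1):0.1):0.2,",
    "((e1:0.1,e2:0.1):0.05,e3:0.2):0.2);"))
  groups <- c(liv1 = "liverworts", b1 = "ref", b2 = "ref", b3 = "ref",
              b4 = "ref", e1 = "mosses", e2 = "mosses", e3 = "hornworts")
  fl <- flag_contaminants(tr, ann_tips(tr, paste0("b", 1:4), groups))
  expect_equal(fl$flag[fl$tip == "liv1"], "contaminant")
  expect_equal(fl$flag[fl$tip == "e1"], "clean")   # sits with other eukaryotes
  expect_equal(fl$flag[fl$tip == "e3"], "clean")
})

test_that("near-identity to a bacterial sequence flags contamination directly", {
  tr <- ape::read.tree(
    text = "((liv1:0.01,e3:0.3):0.1,((b1:0.1,b2:0.1):0.1,(e1:0.1,e2:0.1):0.1):0.1);")
  groups <- c(liv1 = "liverworts", e3 = "liverworts", b1 = "ref", b2 = "ref",
              e1 = "mosses", e2 = "mosses")
  ids <- matrix(0.5, 6, 6, dimnames = list(tr$tip.label, tr$tip.label))
  diag(ids) <- 1
  ids["liv1", "b1"] <- ids["b1", "liv1"] <- 0.995
  fl <- flag_contaminants(tr, ann_tips(tr, c("b1", "b2"), groups), ids)
  expect_equal(fl$flag[fl$tip == "liv1"], "contaminant")
})

test_that("two strains of one lineage nested in bacteria are transfers", {
  tr <- ape::read.tree(text = paste0(
    "((((red1:0.1,red2:0.1):0.05,(b1:0.1,b2:0.1):0.05):0.05,(b3:0.1,b4:0.1):0.1):0.2,",
    "((e1:0.1,e2:0.1):0.05,e3:0.2):0.2);"))
  groups <- c(red1 = "red_algae", red2 = "red_algae", b1 = "ref", b2 = "ref",
              b3 = "ref", b4 = "ref", e1 = "greens", e2 = "greens",
              e3 = "hornworts")
  fl <- flag_contaminants(tr, ann_tips(tr, paste0("b", 1:4), groups))
  expect_equal(fl$flag[fl$tip == "red1"], "hgt")
  expect_equal(fl$flag[fl$tip == "red2"], "hgt")
  expect_equal(fl$flag[fl$tip == "e1"], "clean")
})

test_that("same-strain duplicate libraries do not fake a multi-strain transfer", {
  tr <- ape::read.tree(text = paste0(
    "((((rG:0.05,rT:0.05):0.05,(b1:0.1,b2:0.1):0.05):0.05,(b3:0.1,b4:0.1):0.1):0.2,",
    "((e1:0.1,e2:0.1):0.05,e3:0.2):0.2);"))
  groups <- c(rG = "red_algae", rT = "red_algae", b1 = "ref", b2 = "ref",
              b3 = "ref", b4 = "ref", e1 = "greens", e2 = "greens",
              e3 = "hornworts")
  strains <- c(rG = "Porphyridium", rT = "Porphyridium", b1 = "b1", b2 = "b2",
               b3 = "b3", b4 = "b4", e1 = "e1", e2 = "e2", e3 = "e3")
  fl <- flag_contaminants(tr, ann_tips(tr, paste0("b", 1:4), groups, strains))
  expect_equal(fl$flag[fl$tip == "rG"], "contaminant")
  expect_equal(fl$flag[fl$tip == "rT"], "contaminant")
})

test_that("a tip nested among other eukaryote lineages is clean", {
  tr <- ape::read.tree(
    text = "((horn1:0.1,(s1:0.1,s2:0.1):0.05):0.1,(b1:0.2,b2:0.2):0.3);")
  groups <- c(horn1 = "hornworts", s1 = "streptophytes", s2 = "streptophytes",
              b1 = "ref", b2 = "ref")
  fl <- flag_contaminants(tr, ann_tips(tr, c("b1", "b2"), groups))
  expect_equal(fl$flag[fl$tip == "horn1"], "clean")
})

test_that("unannotated tips are an error", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ann <- data.frame(tip = c("a", "b", "c"), domain = "eukaryote",
                    lineage_group = "g", strain = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  expect_error(flag_contaminants(tr, ann), "unannotated.*d")
})

# --- anchored isoform clades ---------------------------------------------

iso_tree <- ape::read.tree(text = paste0(
  "(((At1:0.1,At2:0.1):0.05,(At3:0.1,(p1:0.1,p2:0.1):0.05):0.05):0.2,",
  "((q1:0.1,q2:0.1):0.05,(q3:0.1,q4:0.1):0.05):0.2,(out1:0.3,out2:0.3):0.3);"))

test_that("tips are assigned to the anchored isoform clades", {
  anchors <- list(`Clade I` = c("At1", "At2", "At3"),
                  `Clade II` = c("q1", "q4"))
  asn <- assign_isoform_clade(iso_tree, anchors)
  lab <- setNames(asn$clade, asn$tip)
  expect_equal(unname(lab[c("p1", "p2")]), rep("Clade I", 2))
  expect_equal(unname(lab[c("q2", "q3")]), rep("Clade II", 2))
  expect_equal(unname(lab[c("out1", "out2")]), rep("unassigned", 2))
})

test_that("inseparable anchor sets are an error", {
  anchors <- list(A = c("At1", "q1"), B = c("At2", "q2"))
  expect_error(assign_isoform_clade(iso_tree, anchors), "conflict")
  expect_error(assign_isoform_clade(iso_tree, list(A = "At1", B = "At1")),
               "mutually exclusive")
})
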