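# Generates the shipped default registry (inst/extdata/registry): 13 B12
# query families plus CBA1, with synthetic seed proteins and domain seed
# alignments.  Deterministic; rerun only to regenerate the fixtures.
# Run from the package root:  Rscript -e 'pkgload::load_all(".")' then source.
pkgload::load_all(".", quiet = TRUE)

set.seed(20260926)

doms <- list(
  METE = c("PF08267", "PF01717"),
  METH = c("PF02574", "PF00809", "PF02607", "PF02310", "PF02965"),
  MTRR = c("PF00258", "PF00667", "PF00175"),
  MCM = c("PF01642", "PF02310"),
  `RNR-II` = c("PF02867"),
  CblA = c("PF03308"),
  CblB = c("PF01923"),
  CblC = c("PF16690"),
  CblD = c("PF10229"),
  CblF = c("PF04791"),
  CblJ = c("PF00005"),
  CblX = c("PF13415"),
  `epi-CblC` = c("PF16690"))

all_doms <- unique(unlist(doms))
segments <- setNames(lapply(all_doms, function(d)
  b12screen:::random_protein(40)), all_doms)

fams <- lapply(names(doms), function(f) {
  fs <- family_spec(f, doms[[f]])
  rs <- b12screen:::make_root_sequence(fs, segments[doms[[f]]])
  seed2 <- b12screen:::evolve_seq(rs$sequence, 0.1, rs$mask, 0.3)
  query_family(f, data.frame(id = sprintf("%s_seed%d", f, 1:2),
                             sequence = c(rs$sequence, seed2),
                             stringsAsFactors = FALSE),
               required_domains = doms[[f]],
               special_rule = if (f == "METE") "mete_arabidopsis" else "none")
})

# CBA1: no shared domain model; two moderately diverged seeds validated by
# a consensus profile (target pairwise identity ~0.28)
cba_a <- b12screen:::random_protein(250)
cba_b <- b12screen:::evolve_seq(cba_a, 1.3)
fams <- c(fams, list(query_family("CBA1",
  data.frame(id = c("CBA1_seed1", "CBA1_seed2"),
             sequence = c(cba_a, cba_b), stringsAsFactors = FALSE),
  required_domains = character(), special_rule = "cba1_consensus")))

domain_seeds <- setNames(lapply(all_doms, function(d) {
  s <- segments[[d]]
  c(s, b12screen:::evolve_seq(s, 0.08), b12screen:::evolve_seq(s, 0.08))
}), all_doms)

reg <- b12screen:::new_registry(fams, domain_seeds)
write_registry(reg, "inst/extdata/registry")
cat("wrote", length(reg$families), "families\n")
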