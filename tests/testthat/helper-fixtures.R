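# Small hand-built fixtures shared across test files.

mini_registry <- function(fams = c("METE", "METH", "MTRR", "MCM")) {
  b12screen:::new_registry(lapply(fams, function(f)
    query_family(f, data.frame(id = paste0(f, "_s"), sequence = "ACD",
                               stringsAsFactors = FALSE),
                 required_domains = "PFX")))
}

mini_strains <- function(n = 3, genome = rep(TRUE, n)) {
  data.frame(strain = paste0("S", seq_len(n)),
             strain_key = tolower(paste0("s", seq_len(n))),
             lineage_group = rep(c("g1", "g2"), length.out = n),
             has_genome = genome,
             library_ids = paste0("L", seq_len(n)),
             habitat = rep(c("freshwater", "marine"), length.out = n),
             latitude = 0, longitude = 0, stringsAsFactors = FALSE)
}

call_row <- function(strain, family, status = "complete", flag = "clean",
                     id = paste0(family, "_", strain)) {
  data.frame(strain = strain, family = family, record_id = id,
             library_id = paste0(strain, "_L"), id = id, status = status,
             flag = flag, note = "", stringsAsFactors = FALSE)
}
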