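#' Family specification for the synthetic cohort generator
#'
#' Describes how one query family evolves in a simulated cohort.  The root
#' protein is built from one random segment per required domain (length
#' \code{domain_length}) joined by linkers; domain segments evolve at
#' \code{domain_rate_scale} times the background rate, which is what keeps
#' domain hits detectable at realistic divergence.  A bacterial pool —
#' homologues diverged from the family root along a long stem — supplies
#' horizontal-transfer donors, contaminants, and the prokaryotic reference
#' panel used by the curation stage.
#'
#' @param name family name.
#' @param required_domains character vector of domain ids embedded, in
#'   order, in the root protein.
#' @param substitution_rate expected substitutions per site per unit branch
#'   length on the species tree.
#' @param loss_prob per-branch probability of (irreversible) gene loss.
#' @param hgt_prob per-branch probability that the gene is replaced by a
#'   bacterial-pool descendant.
#' @param domain_rate_scale rate multiplier inside domain segments.
#' @param domain_length,linker_length segment sizes in residues.
#' @param bacterial_stem divergence (substitutions per site) from the family
#'   root to the bacterial pool root.
#' @param bacterial_pool_size,bacterial_depth number of bacterial lineages
#'   and their divergence from the pool root.
#' @param outgroup_stem,outgroup_pool_size,outgroup_depth the eukaryotic
#'   outgroup reference panel (distantly related eukaryote homologues, as a
#'   curation tree context for vertical sequences).
#' @return A \code{family_spec} list (root sequence is generated later, when
#'   the cohort seed is known).
#' @export
family_spec <- function(name, required_domains,
                        substitution_rate = 0.15,
                        loss_prob = 0.3, hgt_prob = 0.05,
                        domain_rate_scale = 0.3,
                        domain_length = 40, linker_length = 15,
                        bacterial_stem = 0.5, bacterial_pool_size = 20,
                        bacterial_depth = 0.25,
                        outgroup_stem = 0.35, outgroup_pool_size = 8,
                        outgroup_depth = 0.2) {
  stopifnot(length(required_domains) >= 1,
            loss_prob >= 0, loss_prob <= 1, hgt_prob >= 0, hgt_prob <= 1)
  structure(list(name = name, required_domains = required_domains,
                 substitution_rate = substitution_rate,
                 loss_prob = loss_prob, hgt_prob = hgt_prob,
                 domain_rate_scale = domain_rate_scale,
                 domain_length = domain_length, linker_length = linker_length,
                 bacterial_stem = bacterial_stem,
                 bacterial_pool_size = bacterial_pool_size,
                 bacterial_depth = bacterial_depth,
                 outgroup_stem = outgroup_stem,
                 outgroup_pool_size = outgroup_pool_size,
                 outgroup_depth = outgroup_depth),
            class = "family_spec")
}

#' Default family roster for the synthetic cohort
#'
#' Six families covering every branch of the status logic: the two
#' methionine synthase isoforms (METE, METH), the METH reactivator MTRR,
#' the two adenosylcobalamin users (MCM, RNR-II) and one accessory
#' trafficking protein (CblB).  Domain ids match the shipped registry.
#' @param ... overrides passed to every [family_spec()].
#' @return Named list of \code{family_spec}s.
#' @export
default_family_specs <- function(...) {
  doms <- list(
    METE = c("PF08267", "PF01717"),
    METH = c("PF02574", "PF00809", "PF02607", "PF02310", "PF02965"),
    MTRR = c("PF00258", "PF00667", "PF00175"),
    MCM = c("PF01642", "PF02310"),
    `RNR-II` = c("PF02867"),
    CblB = c("PF01923"))
  setNames(lapply(names(doms), function(f)
    family_spec(f, doms[[f]], ...)), names(doms))
}

#' Simulation specification
#'
#' The default values define the reference benchmark cohort: 30 species on
#' a Yule tree (birth rate 1), six families with per-branch loss probability
#' 0.3 and horizontal-transfer probability 0.05, a 5% per-library
#' contamination rate, 20% transcript truncation, 20% transcriptome
#' dropout, and half the species represented by transcriptome-only
#' libraries.
#'
#' @param n_species number of species (>= 4).
#' @param birth_rate Yule birth rate.
#' @param families named list of [family_spec()]s.
#' @param contamination_rate per-library probability of one inserted
#'   (unmodified) bacterial-pool sequence.
#' @param truncation_prob per-transcript probability of losing a uniform
#'   20-60% prefix or suffix.
#' @param transcriptome_dropout per-transcript probability that a truly
#'   present gene is missing from a transcriptome library.
#' @param transcriptome_fraction fraction of species with transcriptome-only
#'   libraries (the rest have genomes; a few genome species also carry a
#'   transcriptome, mirroring dual-library strains).
#' @param n_decoys_per_library composition-matched shuffled background
#'   sequences padding every library.
#' @param n_validation_decoys size of the decoy proteome in the reciprocal
#'   validation database.
#' @param seed integer seed governing every random draw.
#' @return A \code{simulation_spec} list.
#' @export
simulation_spec <- function(n_species = 30, birth_rate = 1,
                            families = default_family_specs(),
                            contamination_rate = 0.05,
                            truncation_prob = 0.2,
                            transcriptome_dropout = 0.2,
                            transcriptome_fraction = 0.5,
                            n_decoys_per_library = 8,
                            n_validation_decoys = 60,
                            seed = 1L) {
  stopifnot(n_species >= 4,
            contamination_rate >= 0, contamination_rate <= 1,
            truncation_prob >= 0, truncation_prob <= 1,
            transcriptome_dropout >= 0, transcriptome_dropout <= 1,
            transcriptome_fraction >= 0, transcriptome_fraction <= 1)
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 families = families,
                 contamination_rate = contamination_rate,
                 truncation_prob = truncation_prob,
                 transcriptome_dropout = transcriptome_dropout,
                 transcriptome_fraction = transcriptome_fraction,
                 n_decoys_per_library = n_decoys_per_library,
                 n_validation_decoys = n_validation_decoys,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

ab20 <- function() aa_alphabet()[1:20]

random_protein <- function(n, freqs = NULL) {
  if (is.null(freqs)) paste(sample(ab20(), n, TRUE), collapse = "")
  else paste(sample(names(freqs), n, TRUE, prob = freqs), collapse = "")
}

# evolve a character vector of residues along d expected substitutions/site;
# per site the substitution count is Poisson and each event replaces the
# residue uniformly among the 19 alternatives
evolve_residues <- function(chars, d, mask = NULL, rate_scale = 1) {
  lam <- rep(d, length(chars))
  if (!is.null(mask)) lam[mask] <- d * rate_scale
  k <- rpois(length(chars), lam)
  for (i in which(k > 0)) {
    cur <- chars[i]
    for (s in seq_len(k[i])) cur <- sample(setdiff(ab20(), cur), 1)
    chars[i] <- cur
  }
  chars
}

evolve_seq <- function(seq, d, mask = NULL, rate_scale = 1) {
  paste(evolve_residues(strsplit(seq, "")[[1]], d, mask, rate_scale),
        collapse = "")
}

#' Simulate a Yule species tree
#'
#' Pure-birth process: starting from two lineages at the root, the waiting
#' time with \code{k} lineages is exponential with rate \code{k *
#' birth_rate} and a uniformly chosen lineage splits, until \code{n_species}
#' lineages exist; a final exponential waiting time with rate
#' \code{n_species * birth_rate} runs to the present, so the tree is
#' ultrametric and the expected root-to-tip depth is \code{(1/birth_rate) *
#' sum_{k=2..n} 1/k}.  Deterministic given the seed.
#'
#' @param n_species number of tips (>= 4).
#' @param birth_rate per-lineage birth rate.
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return An ultrametric \code{phylo} with tips \code{SP01}, \code{SP02}, ...
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_species >= 4)
  n <- n_species
  # active branches: parent internal node (temp id), start time
  next_int <- -1L
  root <- next_int; next_int <- next_int - 1L
  active_parent <- c(root, root)
  active_start <- c(0, 0)
  edges <- list()
  t_now <- 0
  while (length(active_parent) < n) {
    k <- length(active_parent)
    t_now <- t_now + rexp(1, rate = k * birth_rate)
    pick <- sample.int(k, 1)
    v <- next_int; next_int <- next_int - 1L
    edges[[length(edges) + 1]] <-
      c(active_parent[pick], v, t_now - active_start[pick])
    active_parent <- c(active_parent[-pick], v, v)
    active_start <- c(active_start[-pick], t_now, t_now)
  }
  t_now <- t_now + rexp(1, rate = n * birth_rate)
  for (i in seq_len(n))
    edges[[length(edges) + 1]] <-
      c(active_parent[i], i, t_now - active_start[i])
  em <- do.call(rbind, edges)
  # remap temp internal ids (-1, -2, ...) to n+1, n+2, ...
  remap <- function(x) ifelse(x < 0, n - x, x)
  tree <- list(edge = cbind(remap(em[, 1]), remap(em[, 2])),
               edge.length = em[, 3],
               tip.label = sprintf("SP%02d", seq_len(n)),
               Nnode = n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Evolve gene presence along a species tree
#'
#' Root-to-tip walk: on every branch a present gene is lost with probability
#' \code{loss_prob} (irreversibly, for the vertical copy) and, independently,
#' replaced by a bacterial-pool descendant with probability \code{hgt_prob}
#' (a fresh acquisition, possible even after loss).  Each transfer event
#' gets an id shared by all descendants inheriting it.
#'
#' @param tree a \code{phylo}.
#' @param fspec a [family_spec()].
#' @param seed optional integer seed.
#' @return data.frame: \code{species}, \code{state} (\code{retained},
#'   \code{lost}, \code{hgt_acquired}), \code{hgt_event} (NA or event id).
#' @export
evolve_presence <- function(tree, fspec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  state <- rep("retained", nn)
  event <- rep(NA_integer_, nn)
  ev_counter <- 0L
  event_edge <- integer(0)           # event id -> edge where it started
  ord <- rev(ape::postorder(tree))   # parents before children
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    st <- state[p]; ev <- event[p]
    if (st != "lost" && runif(1) < fspec$loss_prob) { st <- "lost"; ev <- NA }
    if (runif(1) < fspec$hgt_prob) {
      ev_counter <- ev_counter + 1L
      st <- "hgt_acquired"; ev <- ev_counter
      event_edge[ev_counter] <- e
    }
    state[ch] <- st; event[ch] <- ev
  }
  out <- data.frame(species = tree$tip.label,
                    state = state[seq_len(ntip)],
                    hgt_event = event[seq_len(ntip)],
                    stringsAsFactors = FALSE)
  attr(out, "node_state") <- state
  attr(out, "node_event") <- event
  attr(out, "event_edge") <- event_edge
  out
}

#' Evolve sequences for one family along a species tree
#'
#' Generates the bacterial pool (pool root diverged \code{bacterial_stem}
#' substitutions per site from the family root, pool members a further
#' \code{bacterial_depth}), then walks the species tree evolving the root
#' protein with per-site Poisson substitutions (domain segments at
#' \code{domain_rate_scale} times the background rate).  Branches carrying a
#' new transfer event restart from a randomly drawn pool member (plus a
#' small 0.05 substitutions-per-site divergence).
#'
#' @param tree a \code{phylo}.
#' @param presence result of [evolve_presence()] for the same tree/family.
#' @param fspec a [family_spec()] (with \code{root_sequence} and
#'   \code{domain_mask} attached by the cohort generator, or supplied here).
#' @param root_sequence,domain_mask root protein and logical domain mask;
#'   generated from the spec seed when missing.
#' @param seed optional integer seed.
#' @return list: \code{tip_sequences} (named by species; only species whose
#'   state is not \code{lost}), \code{pool} (named vector of bacterial
#'   sequences), \code{donors} (event id -> pool member used).
#' @export
evolve_sequences <- function(tree, presence, fspec,
                             root_sequence = NULL, domain_mask = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(root_sequence)) {
    rs <- make_root_sequence(fspec)
    root_sequence <- rs$sequence; domain_mask <- rs$mask
  }
  mask <- domain_mask
  pool_root <- evolve_seq(root_sequence, fspec$bacterial_stem, mask,
                          fspec$domain_rate_scale)
  pool <- setNames(
    vapply(seq_len(fspec$bacterial_pool_size), function(i)
      evolve_seq(pool_root, fspec$bacterial_depth, mask,
                 fspec$domain_rate_scale), ""),
    sprintf("BACT_%s_%02d", fspec$name, seq_len(fspec$bacterial_pool_size)))
  outg_root <- evolve_seq(root_sequence, fspec$outgroup_stem, mask,
                          fspec$domain_rate_scale)
  outgroup <- setNames(
    vapply(seq_len(fspec$outgroup_pool_size), function(i)
      evolve_seq(outg_root, fspec$outgroup_depth, mask,
                 fspec$domain_rate_scale), ""),
    sprintf("OUTG_%s_%02d", fspec$name, seq_len(fspec$outgroup_pool_size)))

  event_edge <- attr(presence, "event_edge")
  if (is.null(event_edge))
    stopf("presence must come from evolve_presence() (per-branch events missing)")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  seqs <- vector("character", nn)
  seqs[ntip + 1L] <- root_sequence
  donors <- setNames(integer(0), character(0))
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- fspec$substitution_rate * tree$edge.length[e]
    started <- which(event_edge == e)
    if (length(started) > 0) {
      ev <- started[length(started)]   # the surviving (last) event on e
      donor <- sample.int(length(pool), 1)
      donors[as.character(ev)] <- donor
      seqs[ch] <- evolve_seq(evolve_seq(pool[[donor]], 0.05, mask,
                                        fspec$domain_rate_scale),
                             d, mask, fspec$domain_rate_scale)
    } else {
      seqs[ch] <- evolve_seq(seqs[p], d, mask, fspec$domain_rate_scale)
    }
  }
  keep <- presence$state != "lost"
  list(tip_sequences = setNames(seqs[seq_len(ntip)],
                                tree$tip.label)[presence$species[keep]],
       pool = pool, outgroup = outgroup, donors = donors)
}

make_root_sequence <- function(fspec, domain_segments = NULL) {
  segs <- domain_segments %||%
    setNames(lapply(fspec$required_domains,
                    function(d) random_protein(fspec$domain_length)),
             fspec$required_domains)
  parts <- character(0); mask <- logical(0)
  link <- function() {
    l <- random_protein(fspec$linker_length)
    parts <<- c(parts, l); mask <<- c(mask, rep(FALSE, nchar(l)))
  }
  link()
  for (d in fspec$required_domains) {
    s <- segs[[d]]
    parts <- c(parts, s); mask <- c(mask, rep(TRUE, nchar(s)))
    link()
  }
  list(sequence = paste(parts, collapse = ""), mask = mask, segments = segs)
}
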