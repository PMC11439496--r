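#' Construct a query-family entry
#'
#' A query family bundles the seed (query) protein sequences used for the
#' forward homologue search with the ordered list of domain models its
#' members must carry.  Two families need special handling: the
#' B12-independent methionine synthase METE (\code{special_rule =
#' "mete_arabidopsis"}), whose candidates may reciprocally match any of the
#' three characterised Arabidopsis methionine synthases; and the uptake
#' protein CBA1 (\code{special_rule = "cba1_consensus"}), which has no shared
#' domain model and is validated with a two-sequence consensus profile built
#' from its seeds.
#'
#' @param name family identifier (e.g. \code{"METH"}).
#' @param seed_sequences data.frame with \code{id} and \code{sequence}
#'   columns; non-empty.
#' @param required_domains ordered character vector of domain-model ids;
#'   non-empty unless \code{special_rule == "cba1_consensus"}.
#' @param special_rule one of \code{"none"}, \code{"mete_arabidopsis"},
#'   \code{"cba1_consensus"}.
#' @return A list of class \code{query_family}.
#' @export
query_family <- function(name, seed_sequences, required_domains = character(),
                         special_rule = c("none", "mete_arabidopsis",
                                          "cba1_consensus")) {
  special_rule <- match.arg(special_rule)
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stopf("family name must be a non-empty string")
  if (NROW(seed_sequences) == 0)
    stopf("family %s: seed_sequences must be non-empty", name)
  if (length(required_domains) == 0 && special_rule != "cba1_consensus")
    stopf("family %s: required_domains empty but special_rule is not cba1_consensus",
          name)
  structure(list(name = name,
                 seed_sequences = seed_sequences,
                 required_domains = as.character(required_domains),
                 special_rule = special_rule),
            class = "query_family")
}

new_registry <- function(families, domain_seeds = list()) {
  nm <- vapply(families, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("duplicate family name: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(families = setNames(families, nm), domain_seeds = domain_seeds),
            class = "b12_registry")
}

#' Load a query-family registry
#'
#' The registry is a YAML file listing the families, with seed sequences and
#' per-domain seed alignments in FASTA files referenced relative to the YAML
#' (\code{seeds_fasta}, \code{domain_seeds_fasta}; domain-seed record ids are
#' \code{<domain>|<row>}).  See [default_registry()] for the shipped
#' registry.
#'
#' @param path registry YAML file.
#' @return A \code{b12_registry}: named list of [query_family()] entries plus
#'   the domain seed alignments (named list of equal-length character
#'   vectors of aligned rows).
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$families)) stopf("registry parse error: missing field 'families'")
  dir <- dirname(path)
  if (is.null(raw$seeds_fasta)) stopf("registry parse error: missing field 'seeds_fasta'")
  seeds <- read_fasta(file.path(dir, raw$seeds_fasta))
  domain_seeds <- list()
  if (!is.null(raw$domain_seeds_fasta)) {
    ds <- read_fasta(file.path(dir, raw$domain_seeds_fasta))
    dom <- sub("\\|.*$", "", ds$id)
    domain_seeds <- lapply(split(ds$sequence, dom), unname)
  }
  fams <- lapply(raw$families, function(f) {
    for (fld in c("name", "seeds")) if (is.null(f[[fld]]))
      stopf("registry parse error: family entry missing field '%s'", fld)
    sel <- seeds[seeds$id %in% unlist(f$seeds), c("id", "sequence")]
    if (nrow(sel) < length(unlist(f$seeds)))
      stopf("registry parse error: family %s references unknown seed id", f$name)
    query_family(f$name, sel,
                 required_domains = unlist(f$required_domains) %||% character(),
                 special_rule = f$special_rule %||% "none")
  })
  reg <- new_registry(fams, domain_seeds)
  missing <- setdiff(unlist(lapply(fams, `[[`, "required_domains")),
                     names(domain_seeds))
  if (length(missing) > 0 && length(domain_seeds) > 0)
    warnf("no domain seed alignment for: %s", paste(missing, collapse = ", "))
  reg
}

#' Write a registry to a directory
#'
#' Serialises the registry as \code{registry.yaml}, \code{seeds.fasta} and
#' \code{domain_seeds.fasta}; loading the result with [load_registry()]
#' reproduces the registry.
#'
#' @param registry a \code{b12_registry}.
#' @param dir output directory (created if needed).
#' @return Path to the written YAML, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- do.call(rbind, lapply(registry$families, function(f)
    f$seed_sequences[, c("id", "sequence")]))
  write_fasta(setNames(seeds$sequence, seeds$id), file.path(dir, "seeds.fasta"))
  yml <- list(seeds_fasta = "seeds.fasta",
              families = lapply(unname(registry$families), function(f)
                list(name = f$name,
                     special_rule = f$special_rule,
                     required_domains = as.list(f$required_domains),
                     seeds = as.list(f$seed_sequences$id))))
  if (length(registry$domain_seeds) > 0) {
    rows <- unlist(lapply(names(registry$domain_seeds), function(d) {
      v <- registry$domain_seeds[[d]]
      setNames(v, paste0(d, "|", seq_along(v)))
    }))
    write_fasta(rows, file.path(dir, "domain_seeds.fasta"))
    yml$domain_seeds_fasta <- "domain_seeds.fasta"
  }
  out <- file.path(dir, "registry.yaml")
  yaml::write_yaml(yml, out)
  invisible(out)
}

#' The shipped default registry
#'
#' Thirteen B12-associated query families (METE, METH, MTRR, MCM, RNR-II,
#' CblA, CblB, CblC, CblD, CblF, CblJ, CblX, epi-CblC) plus the uptake
#' protein CBA1.  METH requires the five domains PF02574 (homocysteine
#' S-methyltransferase), PF00809 (pterin-binding), PF02607 and PF02310
#' (B12-binding) and PF02965 (activation domain); METE requires PF08267 and
#' PF01717; MTRR requires PF00258, PF00667 and PF00175.  CBA1 carries no
#' shared domain model and is flagged \code{cba1_consensus}.
#'
#' Seed sequences and domain seed alignments in the shipped registry are
#' synthetic stand-ins generated deterministically (each seed embeds one
#' segment per required domain); the domain accessions are opaque
#' identifiers.  Replace the registry files to screen with real seed
#' proteins and domain alignments.
#'
#' @return A \code{b12_registry} with 14 families.
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "registry", "registry.yaml",
                            package = "b12screen", mustWork = TRUE))
}

#' @export
print.b12_registry <- function(x, ...) {
  cat(sprintf("b12 query registry: %d families\n", length(x$families)))
  for (f in x$families)
    cat(sprintf("  %-9s %d seed(s), domains: %s%s\n", f$name,
                nrow(f$seed_sequences),
                if (length(f$required_domains)) paste(f$required_domains, collapse = " ")
                else "(none)",
                if (f$special_rule != "none") paste0(" [", f$special_rule, "]") else ""))
  invisible(x)
}
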