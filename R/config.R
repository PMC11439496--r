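#' Pipeline configuration
#'
#' Thresholds governing every stage of the screen.  Defaults follow the
#' standard practice for this kind of survey: an E-value cutoff of 1e-5 for
#' both the forward homologue search and the domain scan, iterative removal
#' of terminal branches longer than 1.0 substitutions per site, alignment
#' columns kept when at least half the rows are ungapped, 100
#' neighbour-joining bootstrap replicates, and a 99% identity rule for
#' flagging suspected cross-library bacterial contamination.
#'
#' @param forward_evalue_threshold E-value cutoff for the forward search.
#' @param domain_evalue_threshold E-value cutoff for profile/domain hits.
#' @param branch_length_threshold terminal branch length (substitutions per
#'   site) above which a tip is considered divergent; strictly greater
#'   triggers removal.
#' @param gap_threshold minimum fraction of ungapped rows for an alignment
#'   column to be kept (columns at exactly the threshold are kept).
#' @param nj_replicates,bootstrap_replicates bootstrap replicate counts for
#'   the neighbour-joining screening trees.
#' @param contaminant_identity_threshold pairwise identity to a bacterial
#'   sequence at or above which a single-library tip is called a contaminant.
#' @param random_seed integer seed used for all stochastic steps.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(forward_evalue_threshold = 1e-5,
                            domain_evalue_threshold = 1e-5,
                            branch_length_threshold = 1.0,
                            gap_threshold = 0.5,
                            nj_replicates = 100,
                            bootstrap_replicates = 100,
                            contaminant_identity_threshold = 0.99,
                            random_seed = 1L) {
  cfg <- list(forward_evalue_threshold = forward_evalue_threshold,
              domain_evalue_threshold = domain_evalue_threshold,
              branch_length_threshold = branch_length_threshold,
              gap_threshold = gap_threshold,
              nj_replicates = nj_replicates,
              bootstrap_replicates = bootstrap_replicates,
              contaminant_identity_threshold = contaminant_identity_threshold,
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num <- c("forward_evalue_threshold", "domain_evalue_threshold",
           "branch_length_threshold", "gap_threshold",
           "contaminant_identity_threshold")
  for (f in num) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stopf("config field '%s' must be a positive number", f)
  }
  for (f in c("nj_replicates", "bootstrap_replicates")) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stopf("config field '%s' must be a non-negative count", f)
  }
  if (cfg$gap_threshold > 1) stopf("gap_threshold must lie in (0, 1]")
  if (cfg$contaminant_identity_threshold > 1)
    stopf("contaminant_identity_threshold must lie in (0, 1]")
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return \code{read_config} returns a \code{pipeline_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
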