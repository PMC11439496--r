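#' Build a position-specific scoring model from a seed alignment
#'
#' A lightweight stand-in for externally fetched domain models: per-position
#' natural-log odds scores with add-alpha pseudocounts against a uniform (or
#' supplied) background.  Columns with more than 50% gaps are excluded from
#' the model.  Model scores are in nats, so the scan statistics use
#' \code{lambda = 1}.
#'
#' @param seed_msa character vector of at least 2 aligned rows (gaps allowed),
#'   or a \code{b12_msa}.
#' @param id model identifier.
#' @param pseudocount add-alpha pseudocount (default 1).
#' @param background named numeric vector of residue frequencies over the 20
#'   standard residues (sums to 1); uniform by default.
#' @return A \code{profile_model}: list with \code{id}, \code{scores}
#'   (length x 20 matrix, nats), \code{length}, \code{background}.
#' @export
build_profile <- function(seed_msa, id = "profile", pseudocount = 1,
                          background = NULL) {
  rows <- unclass(seed_msa)
  if (length(rows) < 2) stopf("profile seed alignment needs >= 2 rows")
  if (length(unique(nchar(rows))) != 1) stopf("seed rows differ in length")
  ab20 <- aa_alphabet()[1:20]
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), ab20)
  if (abs(sum(background) - 1) > 1e-8) stopf("background must sum to 1")
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- colMeans(m == "-") <= 0.5
  if (!any(keep)) stopf("every seed column is majority-gap")
  m <- m[, keep, drop = FALSE]
  L <- ncol(m)
  scores <- matrix(0, L, 20, dimnames = list(NULL, ab20))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% ab20]
    N <- length(col)
    cnt <- table(factor(col, levels = ab20))
    p <- (as.numeric(cnt) + pseudocount) / (N + 20 * pseudocount)
    scores[j, ] <- log(p / unname(background[ab20]))
  }
  if (L < 5) warnf("profile %s is very short (%d columns)", id, L)
  structure(list(id = id, scores = scores, length = L,
                 background = background),
            class = "profile_model")
}

#' Two-sequence consensus profile
#'
#' Builds a validation profile from exactly two characterised proteins (the
#' CBA1 route, where the two known proteins share no domain model): the pair
#' is locally aligned, the alignment is globalised by end-extension (the
#' unaligned flanks are appended, padded with gaps on the outside), and a
#' [build_profile()] model is built over the 2-row alignment.  If the local
#' alignment identity is below 0.1 the profile is still built but flagged
#' weakly informative with a warning.
#'
#' @param seq_a,seq_b the two protein sequences.
#' @param id model identifier.
#' @param pseudocount passed to [build_profile()].
#' @param scheme a [scoring_scheme()] for the pairwise alignment.
#' @return A \code{profile_model}.
#' @export
consensus_profile <- function(seq_a, seq_b, id = "consensus", pseudocount = 1,
                              scheme = scoring_scheme()) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  al <- align_local(seq_a, seq_b, scheme)
  if (is.na(al$identity) || al$identity < 0.1)
    warnf("consensus profile %s: alignment identity %.2f; weakly informative",
          id, al$identity %||% 0)
  pre_a <- substr(seq_a, 1, al$query_span[1])
  pre_b <- substr(seq_b, 1, al$subject_span[1])
  post_a <- substr(seq_a, al$query_span[2] + 1, nchar(seq_a))
  post_b <- substr(seq_b, al$subject_span[2] + 1, nchar(seq_b))
  pad <- function(x, n, left) {
    g <- strrep("-", n - nchar(x))
    if (left) paste0(g, x) else paste0(x, g)
  }
  npre <- max(nchar(pre_a), nchar(pre_b))
  npost <- max(nchar(post_a), nchar(post_b))
  row_a <- paste0(pad(pre_a, npre, TRUE), al$aligned_a, pad(post_a, npost, FALSE))
  row_b <- paste0(pad(pre_b, npre, TRUE), al$aligned_b, pad(post_b, npost, FALSE))
  build_profile(c(a = row_a, b = row_b), id = id, pseudocount = pseudocount)
}

#' Scan a sequence for profile hits
#'
#' Best local profile-to-sequence alignment score per profile, computed by
#' the same affine-gap dynamic programme as the sequence search (gap
#' penalties in nats).  The E-value is \code{K * L * n * exp(-S)} with the
#' profile length \code{L}, sequence length \code{n} and score \code{S} in
#' nats; hits with E-value at or below
#' \code{config$domain_evalue_threshold} are returned sorted by sequence
#' position.  An external domain scanner's tabular output can be ingested
#' instead via [read_domain_hits()].
#'
#' @param sequence protein sequence.
#' @param profiles list of [build_profile()] models (possibly named).
#' @param config a [pipeline_config()].
#' @param gap_open,gap_extend affine gap penalties in nats.
#' @param karlin_K K parameter for the E-value.
#' @return data.frame: \code{profile}, \code{start}, \code{end} (0-based
#'   half-open sequence span), \code{score}, \code{evalue}.
#' @export
scan_domains <- function(sequence, profiles, config = pipeline_config(),
                         gap_open = 4, gap_extend = 0.5, karlin_K = 0.041) {
  stopifnot(nchar(sequence) > 0)
  out <- data.frame(profile = character(), start = integer(), end = integer(),
                    score = numeric(), evalue = numeric(),
                    stringsAsFactors = FALSE)
  if (length(profiles) == 0) return(out)
  enc <- encode_seq(sequence)
  n <- length(enc)
  for (p in profiles) {
    sc <- cbind(p$scores, X = 0)            # X scores 0 everywhere
    S <- sc[, enc, drop = FALSE]
    res <- align_dp_cpp(as.matrix(S), gap_open, gap_extend, TRUE, TRUE)
    ev <- karlin_K * p$length * n * exp(-res$score)
    if (!is.finite(ev) || ev < 0) ev <- 0
    if (ev <= config$domain_evalue_threshold && length(res$b_idx) > 0) {
      bpos <- res$b_idx[res$b_idx > 0]
      out <- rbind(out, data.frame(profile = p$id,
                                   start = min(bpos) - 1L, end = max(bpos),
                                   score = res$score, evalue = ev,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Ingest external domain-scan tabular output
#'
#' Adapter for tab-separated output of an external scanner with columns
#' \code{target} (sequence id), \code{query} (domain id), \code{evalue},
#' \code{start}, \code{end}.  Hits above the configured E-value threshold
#' are dropped, matching the contract of [scan_domains()].
#'
#' @param path tab-separated file.
#' @param config a [pipeline_config()].
#' @return data.frame: \code{id}, \code{profile}, \code{start}, \code{end},
#'   \code{evalue}.
#' @export
read_domain_hits <- function(path, config = pipeline_config()) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("target", "query", "evalue")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("domain hit table missing column(s): %s",
                          paste(miss, collapse = ", "))
  d <- d[d$evalue <= config$domain_evalue_threshold, , drop = FALSE]
  data.frame(id = d$target, profile = d$query,
             start = d$start %||% NA_integer_, end = d$end %||% NA_integer_,
             evalue = d$evalue, stringsAsFactors = FALSE)
}

#' Build the domain models needed by a registry
#'
#' One model per distinct required domain (from the registry's domain seed
#' alignments), plus the two-sequence consensus model for families flagged
#' \code{cba1_consensus}.
#'
#' @param registry a \code{b12_registry}.
#' @param pseudocount passed to [build_profile()].
#' @param scheme a [scoring_scheme()] (for consensus profiles).
#' @return Named list of \code{profile_model}s; consensus models are named
#'   \code{<family>_consensus}.
#' @export
registry_profiles <- function(registry, pseudocount = 1,
                              scheme = scoring_scheme()) {
  profs <- list()
  for (d in names(registry$domain_seeds))
    profs[[d]] <- build_profile(registry$domain_seeds[[d]], id = d,
                                pseudocount = pseudocount)
  for (f in registry$families) {
    if (f$special_rule == "cba1_consensus") {
      if (nrow(f$seed_sequences) < 2)
        stopf("family %s: consensus rule needs 2 seeds", f$name)
      nm <- paste0(f$name, "_consensus")
      profs[[nm]] <- consensus_profile(f$seed_sequences$sequence[1],
                                       f$seed_sequences$sequence[2],
                                       id = nm, pseudocount = pseudocount,
                                       scheme = scheme)
    }
    miss <- setdiff(f$required_domains, names(profs))
    if (length(miss))
      warnf("family %s: no seed alignment for domain(s) %s", f$name,
            paste(miss, collapse = ", "))
  }
  profs
}
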