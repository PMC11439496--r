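#' Read and validate a library manifest
#'
#' One row per sequence library.  Required columns: \code{library_id},
#' \code{strain_name}, \code{library_type} (\code{genome} or
#' \code{transcriptome}), \code{lineage_group}.  Optional: \code{latitude},
#' \code{longitude}, \code{habitat}, \code{source_collection}.  A strain may
#' appear in several libraries (e.g. genome plus transcriptome); strains are
#' merged downstream by [dedupe_strains()].
#'
#' @param path tab-separated manifest file.
#' @return Validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
validate_manifest <- function(manifest) {
  req <- c("library_id", "strain_name", "library_type", "lineage_group")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stopf("manifest missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$library_id))
    stopf("duplicate library_id in manifest")
  bad <- !manifest$library_type %in% c("genome", "transcriptome")
  if (any(bad)) stopf("invalid library_type: %s",
                      paste(unique(manifest$library_type[bad]), collapse = ", "))
  for (col in c("latitude", "longitude", "habitat", "source_collection"))
    if (is.null(manifest[[col]])) manifest[[col]] <- NA
  ok_lat <- is.na(manifest$latitude) |
    (manifest$latitude >= -90 & manifest$latitude <= 90)
  ok_lon <- is.na(manifest$longitude) |
    (manifest$longitude >= -180 & manifest$longitude <= 180)
  if (!all(ok_lat, ok_lon)) stopf("collection coordinates out of range")
  manifest
}

normalize_strain <- function(x, synonyms = NULL) {
  x <- gsub("\\s+", " ", trimws(x))
  key <- tolower(x)
  if (!is.null(synonyms)) {
    stopifnot(all(c("name", "canonical") %in% names(synonyms)))
    skey <- tolower(gsub("\\s+", " ", trimws(synonyms$name)))
    hit <- match(key, skey)
    key[!is.na(hit)] <- tolower(gsub("\\s+", " ",
                                     trimws(synonyms$canonical[hit[!is.na(hit)]])))
  }
  key
}

#' Merge manifest rows into unique strains
#'
#' Strains are matched case-insensitively on the whitespace-collapsed strain
#' name, after resolving culture-collection synonyms through an explicit
#' user-supplied table (no fuzzy matching).  Each unique strain carries the
#' union of its libraries; a genome library anywhere flags the strain
#' \code{has_genome} — transcriptome-only strains are treated with caution
#' when absence of a gene is interpreted downstream.
#'
#' @param manifest validated manifest data.frame.
#' @param synonyms optional data.frame with columns \code{name} and
#'   \code{canonical} mapping alternative strain names.
#' @return data.frame with one row per strain: \code{strain}, \code{strain_key},
#'   \code{lineage_group}, \code{has_genome}, \code{library_ids}
#'   (comma-separated), \code{habitat}, \code{latitude}, \code{longitude}.
#' @export
dedupe_strains <- function(manifest, synonyms = NULL) {
  manifest <- validate_manifest(manifest)
  key <- normalize_strain(manifest$strain_name, synonyms)
  out <- lapply(split(seq_len(nrow(manifest)), key), function(idx) {
    rows <- manifest[idx, , drop = FALSE]
    lg <- unique(rows$lineage_group)
    if (length(lg) > 1)
      stopf("conflicting lineage_group for strain '%s': %s",
            rows$strain_name[1], paste(lg, collapse = " vs "))
    data.frame(strain = rows$strain_name[1],
               strain_key = key[idx[1]],
               lineage_group = lg,
               has_genome = any(rows$library_type == "genome"),
               library_ids = paste(rows$library_id, collapse = ","),
               habitat = stats::na.omit(rows$habitat)[1] %||% NA,
               latitude = stats::na.omit(rows$latitude)[1] %||% NA,
               longitude = stats::na.omit(rows$longitude)[1] %||% NA,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$strain_key), , drop = FALSE]
}
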