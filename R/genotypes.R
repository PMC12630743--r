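#' Build a genotype table
#'
#' The genotype table is the universal currency of the package: one row per
#' sample, one character column per marker, holding unordered biallelic calls
#' written `"A/G"` with the two alleles sorted lexicographically, or `NA` for
#' a missing call. The Y marker, which is scored as detected / not detected
#' on the array, is stored as a pseudo-homozygous call (e.g. `"A/A"`) when
#' detected and `NA` otherwise, so every downstream operation can treat calls
#' uniformly.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param calls A character matrix (samples x markers) of `"X/Y"` calls or
#'   `NA`, with column names giving marker ids; allele order within a call is
#'   normalised on construction.
#' @return A tibble with a `sample_id` column followed by one column per
#'   marker.
#' @export
genotype_table <- function(sample_ids, calls) {
  stopifnot(is.character(sample_ids), !anyDuplicated(sample_ids))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(sample_ids))
  stopifnot(nrow(calls) == length(sample_ids))
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("m", seq_len(ncol(calls)))
  }
  stopifnot(!anyDuplicated(colnames(calls)))
  calls[] <- normalise_call(calls)
  out <- tibble::as_tibble(as.data.frame(calls, stringsAsFactors = FALSE,
                                         optional = TRUE))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
}

#' Normalise a genotype call string
#'
#' Sorts the two alleles of an `"X/Y"` call lexicographically so that
#' `"G/A"` and `"A/G"` compare equal. `NA` and already-sorted calls pass
#' through unchanged.
#'
#' @param call Character vector of calls.
#' @return Character vector of normalised calls.
#' @export
normalise_call <- function(call) {
  out <- call
  idx <- which(!is.na(call))
  if (!length(idx)) return(out)
  parts <- strsplit(call[idx], "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed genotype call(s): ",
         paste(unique(call[idx][bad]), collapse = ", "))
  }
  out[idx] <- vapply(parts, function(p) paste(sort(p), collapse = "/"), "")
  out
}

#' Marker-id columns of a genotype table
#'
#' @param geno A genotype table.
#' @return Character vector of marker ids (all columns except `sample_id`).
#' @export
marker_ids <- function(geno) setdiff(names(geno), "sample_id")

#' Extract the call matrix of a genotype table
#'
#' @param geno A genotype table.
#' @param markers Optional marker ids to keep (in this order).
#' @return Character matrix with sample ids as row names.
#' @export
call_matrix <- function(geno, markers = NULL) {
  if (is.null(markers)) markers <- marker_ids(geno)
  m <- as.matrix(geno[, markers, drop = FALSE])
  rownames(m) <- geno$sample_id
  m
}

#' Marker metadata table
#'
#' @param marker_id Marker identifiers.
#' @param chrom Chromosome label as written in a MAP file ("1".."38", "X",
#'   "Y").
#' @param position 1-based physical position.
#' @param allele_a,allele_b The two allele labels; for the presence-scored Y
#'   marker both may be the same label.
#' @param category One of `"HIGH_MAF"`, `"WOLF_DOG_DIAG"`,
#'   `"WOLF_JACKAL_DIAG"`, `"X_SEX"`, `"Y_SEX"`.
#' @param par_flag Whether an X marker falls inside the configured
#'   pseudoautosomal interval (PAR markers recombine with the Y and are
#'   unusable for sexing).
#' @return A tibble with one row per marker and a derived `chrom_class`
#'   column (`AUTOSOME`/`X`/`Y`).
#' @export
marker_info <- function(marker_id, chrom, position,
                        allele_a, allele_b,
                        category = "HIGH_MAF", par_flag = FALSE) {
  stopifnot(!anyDuplicated(marker_id))
  category <- match_category(category, length(marker_id))
  chrom <- as.character(chrom)
  chrom_class <- dplyr::case_when(
    chrom %in% c("X", "x", "39") ~ "X",
    chrom %in% c("Y", "y") ~ "Y",
    TRUE ~ "AUTOSOME"
  )
  if (any(chrom_class == "Y" & category != "Y_SEX")) {
    stop("Y-chromosome markers must carry category Y_SEX")
  }
  tibble::tibble(
    marker_id = as.character(marker_id),
    chrom = chrom,
    chrom_class = chrom_class,
    position = as.integer(position),
    allele_a = as.character(allele_a),
    allele_b = as.character(allele_b),
    category = category,
    par_flag = rep_len(par_flag, length(marker_id)) & chrom_class == "X"
  )
}

match_category <- function(category, n) {
  valid <- c("HIGH_MAF", "WOLF_DOG_DIAG", "WOLF_JACKAL_DIAG", "X_SEX", "Y_SEX")
  category <- rep_len(as.character(category), n)
  bad <- setdiff(unique(category), valid)
  if (length(bad)) stop("unknown marker category: ", paste(bad, collapse = ", "))
  category
}

#' Sample metadata table
#'
#' @param sample_id Unique sample identifiers.
#' @param material Sample material: `tissue`, `scat`, `urine`, `hair`,
#'   `blood`, `saliva` or `unknown`.
#' @param replicate_group Key joining genotyping replicates of one physical
#'   sample; defaults to the sample id (group of one).
#' @param known_species,known_sex Field labels where available, else `NA`.
#' @param is_control `"POSITIVE"`, `"NEGATIVE"` or `NA` for ordinary samples.
#' @return A tibble with one row per sample.
#' @export
sample_record <- function(sample_id, material = "unknown",
                          replicate_group = sample_id,
                          known_species = NA_character_,
                          known_sex = NA_character_,
                          is_control = NA_character_) {
  stopifnot(!anyDuplicated(sample_id))
  n <- length(sample_id)
  material <- rep_len(as.character(material), n)
  valid <- c("tissue", "scat", "urine", "hair", "blood", "saliva", "unknown")
  bad <- setdiff(unique(material), valid)
  if (length(bad)) stop("unknown sample material: ", paste(bad, collapse = ", "))
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    material = material,
    replicate_group = rep_len(as.character(replicate_group), n),
    known_species = rep_len(as.character(known_species), n),
    known_sex = rep_len(as.character(known_sex), n),
    is_control = rep_len(as.character(is_control), n)
  )
  if (any(!is.na(out$is_control) & out$is_control == "NEGATIVE" &
          (!is.na(out$known_species) | !is.na(out$known_sex)))) {
    stop("negative controls cannot carry known species or sex labels")
  }
  if (any(!nzchar(out$replicate_group))) stop("replicate_group must be non-empty")
  out
}

#' Validate calls against registered marker alleles
#'
#' Checks that every non-missing call in the table uses only the two allele
#' labels registered for its marker, and that table and metadata cover the
#' same markers.
#'
#' @param geno A genotype table.
#' @param markers A [marker_info()] tibble.
#' @return `geno`, invisibly, if valid; otherwise an error naming the first
#'   offending marker.
#' @export
validate_genotypes <- function(geno, markers) {
  ids <- marker_ids(geno)
  missing_meta <- setdiff(ids, markers$marker_id)
  if (length(missing_meta)) {
    stop("markers without metadata: ", paste(missing_meta, collapse = ", "))
  }
  for (mk in ids) {
    row <- markers[markers$marker_id == mk, ]
    allowed <- unique(c(row$allele_a, row$allele_b))
    calls <- geno[[mk]]
    seen <- unique(unlist(strsplit(calls[!is.na(calls)], "/", fixed = TRUE)))
    bad <- setdiff(seen, allowed)
    if (length(bad)) {
      stop("marker ", mk, " carries unregistered allele(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(geno)
}

#' Minor-allele dosage matrix
#'
#' Converts calls to counts of `allele_b` per marker (0, 1 or 2), the dosage
#' coding used for LD, PCA and assignment work. Missing calls become `NA`.
#'
#' @param geno A genotype table.
#' @param markers A [marker_info()] tibble registering allele labels.
#' @return Numeric matrix, samples x markers.
#' @export
dosage_matrix <- function(geno, markers = NULL) {
  ids <- marker_ids(geno)
  cm <- call_matrix(geno)
  out <- matrix(NA_real_, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  for (j in seq_along(ids)) {
    b <- if (!is.null(markers)) {
      markers$allele_b[match(ids[j], markers$marker_id)]
    } else {
      # without metadata, count the lexicographically larger observed allele
      al <- sort(unique(unlist(strsplit(stats::na.omit(cm[, j]), "/", TRUE))))
      if (!length(al)) NA_character_ else al[length(al)]
    }
    if (is.na(b)) next
    calls <- cm[, j]
    idx <- !is.na(calls)
    parts <- strsplit(calls[idx], "/", fixed = TRUE)
    out[idx, j] <- vapply(parts, function(p) sum(p == b), 0)
  }
  out
}

het_call <- function(call) {
  !is.na(call) & vapply(strsplit(call, "/", fixed = TRUE),
                        function(p) p[1] != p[2], TRUE)
}
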