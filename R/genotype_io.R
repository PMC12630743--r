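#' Read genotypes from PED/MAP text files
#'
#' Reads the PLINK text dialect: a MAP file with columns chromosome,
#' marker id, genetic distance, position, and a PED file whose first six
#' columns are family id, individual id, father, mother, sex code and
#' phenotype, followed by two allele columns per marker. `"0"` encodes a
#' missing allele; a `0 0` pair becomes a missing call. Allele order within
#' a call is normalised so `A G` and `G A` read back identically.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A list with elements `genotypes` (genotype table), `markers`
#'   ([marker_info()] tibble with allele labels collected from the data) and
#'   `samples` ([sample_record()] tibble; PED sex codes 1/2 become
#'   `MALE`/`FEMALE`).
#' @export
read_pedmap <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character",
                           col.names = c("chrom", "marker_id", "cm", "pos"))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids in MAP file")
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_geno_cols <- lengths(fields) - 6L
  if (any(n_geno_cols < 0L) || length(unique(n_geno_cols)) > 1L) {
    stop("PED format error: ragged rows")
  }
  if (any(n_geno_cols %% 2L != 0L)) {
    stop("PED format error: odd number of allele columns")
  }
  if (n_geno_cols[1] / 2L != nrow(map)) {
    stop("PED/MAP dimension mismatch: ", n_geno_cols[1] / 2L,
         " markers in PED vs ", nrow(map), " in MAP")
  }
  n <- length(fields)
  ids <- vapply(fields, `[[`, "", 2L)
  sexes <- vapply(fields, `[[`, "", 5L)
  calls <- matrix(NA_character_, n, nrow(map),
                  dimnames = list(NULL, map$marker_id))
  for (i in seq_len(n)) {
    al <- fields[[i]][-(1:6)]
    a1 <- al[c(TRUE, FALSE)]
    a2 <- al[c(FALSE, TRUE)]
    half <- xor(a1 == "0", a2 == "0")
    if (any(half)) stop("PED format error: half-missing call for sample ", ids[i])
    ok <- a1 != "0"
    calls[i, ok] <- paste(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok]), sep = "/")
  }
  # collect the observed allele pair per marker
  alleles <- apply(calls, 2, function(col) {
    al <- sort(unique(unlist(strsplit(col[!is.na(col)], "/", fixed = TRUE))))
    if (length(al) > 2) {
      stop("marker with >2 alleles: ",
           paste(al, collapse = "/"))
    }
    c(al, al, "?", "?")[1:2]
  })
  markers <- marker_info(
    marker_id = map$marker_id, chrom = map$chrom,
    position = as.integer(map$pos),
    allele_a = alleles[1, ], allele_b = alleles[2, ],
    category = ifelse(map$chrom %in% c("Y", "y"), "Y_SEX",
                      ifelse(map$chrom %in% c("X", "x", "39"), "X_SEX",
                             "HIGH_MAF"))
  )
  samples <- sample_record(
    sample_id = ids,
    known_sex = dplyr::case_when(sexes == "1" ~ "MALE",
                                 sexes == "2" ~ "FEMALE",
                                 TRUE ~ NA_character_)
  )
  list(genotypes = genotype_table(ids, calls), markers = markers,
       samples = samples)
}

#' Write genotypes to PED/MAP text files
#'
#' Inverse of [read_pedmap()]; missing calls are written as `0 0`.
#'
#' @param geno A genotype table.
#' @param markers A [marker_info()] tibble (defines marker order, chromosome
#'   and position).
#' @param ped_path,map_path Output paths.
#' @param samples Optional [sample_record()] tibble supplying sex codes.
#' @return The PED path, invisibly.
#' @export
write_pedmap <- function(geno, markers, ped_path, map_path, samples = NULL) {
  mk <- intersect(markers$marker_id, marker_ids(geno))
  markers <- markers[match(mk, markers$marker_id), ]
  readr::write_tsv(
    tibble::tibble(chrom = markers$chrom, marker_id = markers$marker_id,
                   cm = 0, pos = markers$position),
    map_path, col_names = FALSE)
  cm <- call_matrix(geno, mk)
  sex_code <- rep("0", nrow(cm))
  if (!is.null(samples)) {
    ks <- samples$known_sex[match(geno$sample_id, samples$sample_id)]
    sex_code <- dplyr::case_when(ks == "MALE" ~ "1", ks == "FEMALE" ~ "2",
                                 TRUE ~ "0")
  }
  lines <- vapply(seq_len(nrow(cm)), function(i) {
    al <- unlist(strsplit(ifelse(is.na(cm[i, ]), "0/0", cm[i, ]), "/",
                          fixed = TRUE))
    paste(c(geno$sample_id[i], geno$sample_id[i], "0", "0", sex_code[i], "-9",
            al), collapse = " ")
  }, "")
  writeLines(lines, ped_path)
  invisible(ped_path)
}

#' Read a long-format genotyping export
#'
#' Reads the per-call export of the array software: one row per
#' (sample, assay) with columns `sample_id`, `assay_id`, `allele1`,
#' `allele2`. Blank alleles and the tokens `"No Call"`, `"NoCall"`,
#' `"Invalid"` and `"NTC"` map to a missing call. Rows whose sample id
#' matches `^NTC` (or whose call token is `NTC`) are recorded as negative
#' controls.
#'
#' @param csv_path Path to the CSV export.
#' @return A list with `genotypes` (genotype table, samples x assays) and
#'   `samples` (a [sample_record()] tibble flagging no-template controls).
#' @export
read_long_format <- function(csv_path) {
  stopifnot(file.exists(csv_path))
  raw <- readr::read_csv(csv_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("sample_id", "assay_id", "allele1", "allele2")
  if (!all(need %in% names(raw))) {
    stop("long-format export must have columns ", paste(need, collapse = ", "))
  }
  nocall <- function(x) is.na(x) | !nzchar(trimws(x)) |
    trimws(x) %in% c("No Call", "NoCall", "Invalid", "NTC", "0")
  raw$call <- ifelse(nocall(raw$allele1) | nocall(raw$allele2), NA_character_,
                     paste(pmin(raw$allele1, raw$allele2),
                           pmax(raw$allele1, raw$allele2), sep = "/"))
  dup <- raw |>
    dplyr::summarise(n_calls = dplyr::n_distinct(call[!is.na(call)]),
                     .by = c("sample_id", "assay_id"))
  bad <- dup[dup$n_calls > 1, ]
  if (nrow(bad)) {
    stop("conflicting duplicate rows for (sample, assay): ",
         paste(paste(bad$sample_id, bad$assay_id, sep = "/"), collapse = ", "))
  }
  wide <- raw |>
    dplyr::summarise(
      call = if (all(is.na(call))) NA_character_ else call[!is.na(call)][1],
      .by = c("sample_id", "assay_id")) |>
    tidyr::pivot_wider(names_from = "assay_id", values_from = "call")
  geno <- genotype_table(wide$sample_id,
                         as.matrix(wide[, -1, drop = FALSE]))
  is_ntc <- grepl("^NTC", wide$sample_id, ignore.case = TRUE)
  samples <- sample_record(
    wide$sample_id,
    is_control = ifelse(is_ntc, "NEGATIVE", NA_character_))
  list(genotypes = geno, samples = samples)
}

#' Write pipeline result tables as TSV reports
#'
#' Writes every element of a named list of data frames as
#' `<out_dir>/<name>.tsv` with a stable column order. Given identical
#' inputs the files are byte-identical, which makes report bundles
#' diffable across reruns.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of paths written, invisibly.
#' @export
write_reports <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tables[[nm]]), path, progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
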