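#' Read a phenotype table
#'
#' Reads a CSV or TSV phenotype file with the design columns `plant_id`,
#' `block`, `tray`, `accession`, `population`, `mother`, `treatment` followed
#' by one or more trait columns. Empty cells and `"NA"` become missing
#' values; character fields are whitespace-trimmed and compared
#' case-sensitively. Design nesting is validated with [check_design()] and
#' treatment labels are checked against the known levels.
#'
#' @param path Path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param treatments Allowed treatment labels.
#' @return A tibble, one row per plant.
#' @export
read_phenotypes <- function(path,
                            treatments = c("ancestral", "control", "BB", "LE")) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_guess()),
                         trim_ws = TRUE, show_col_types = FALSE)
  required <- c("plant_id", "block", "tray", "accession", "population",
                "mother", "treatment")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("Phenotype file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (ncol(x) <= length(required)) {
    stop("Phenotype file has no trait columns.", call. = FALSE)
  }
  x <- dplyr::mutate(x, dplyr::across(dplyr::all_of(required),
                                      ~ trimws(as.character(.x))))
  bad <- setdiff(unique(x$treatment), treatments)
  if (length(bad)) {
    stop("Unknown treatment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_design(x)
  trait_cols <- setdiff(names(x), required)
  x <- dplyr::mutate(x, dplyr::across(dplyr::all_of(trait_cols), as.numeric))
  neg <- trait_cols[vapply(trait_cols,
                           function(tc) any(x[[tc]] < 0, na.rm = TRUE),
                           logical(1))]
  if (length(neg)) {
    stop("Trait column(s) with negative values: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a phenotype table
#'
#' Writes the exact format [read_phenotypes()] consumes; missing values are
#' written as `NA`.
#'
#' @param data Phenotype tibble.
#' @param path Output path (`.csv` for comma-separated, otherwise TSV).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(data, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(data, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' Expects a long table with columns `variant_id`, `sample_id`, `dosage`
#' (alternate-allele dosage 0/1/2 or `NA`) and optionally `coverage`.
#'
#' @param path Path to a TSV file.
#' @return A tibble in long genotype format.
#' @export
read_genotype_tsv <- function(path) {
  x <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE)
  required <- c("variant_id", "sample_id", "dosage")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("Genotype TSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(x$dosage %in% c(0, 1, 2) | is.na(x$dosage))) {
    stop("Dosage values must be 0, 1, 2 or NA.", call. = FALSE)
  }
  x
}

#' @rdname read_genotype_tsv
#' @param data Long genotype tibble.
#' @export
write_genotype_tsv <- function(data, path) {
  readr::write_tsv(data, path, na = "NA")
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Extracts biallelic-variant genotypes (as alternate-allele dosages) and
#' per-cell read depth from the `GT` and `DP` FORMAT fields of a VCF 4.x
#' file. Multi-allelic sites are dropped.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A long tibble with `variant_id`, `sample_id`, `dosage`, `coverage`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v)))
  keep <- !grepl(",", fix$ALT %||% "")
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  gt <- gt[keep, , drop = FALSE]
  ids <- ids[keep]
  dosage <- apply(gt, 2, function(g) {
    a1 <- substr(g, 1, 1)
    a2 <- substr(g, 3, 3)
    out <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
    out
  })
  res <- tibble::tibble(
    variant_id = rep(ids, times = ncol(gt)),
    sample_id = rep(colnames(gt), each = nrow(gt)),
    dosage = as.vector(dosage)
  )
  if (!is.null(dp)) {
    res$coverage <- as.vector(dp[keep, , drop = FALSE])
  }
  res
}

#' Write genotypes to a minimal VCF 4.2 file
#'
#' Emits a plain-text VCF with `GT:DP` FORMAT fields, one line per variant,
#' suitable for round-tripping through [read_genotype_vcf()]. Dosage 0/1/2 is
#' written as `0/0`, `0/1`, `1/1`; missing dosage as `./.`.
#'
#' @param data Long genotype tibble with `variant_id`, `sample_id`, `dosage`
#'   and optionally `coverage`; `variant_id` of the form `chrom:pos` is
#'   split back into CHROM/POS, anything else goes on a synthetic chromosome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(data, path) {
  samples <- sort(unique(data$sample_id))
  variants <- unique(data$variant_id)
  has_cov <- "coverage" %in% names(data)
  wide_g <- tidyr::pivot_wider(
    dplyr::select(data, "variant_id", "sample_id", "dosage"),
    names_from = "sample_id", values_from = "dosage")
  wide_g <- wide_g[match(variants, wide_g$variant_id), c("variant_id", samples)]
  if (has_cov) {
    wide_c <- tidyr::pivot_wider(
      dplyr::select(data, "variant_id", "sample_id", "coverage"),
      names_from = "sample_id", values_from = "coverage")
    wide_c <- wide_c[match(variants, wide_c$variant_id), c("variant_id", samples)]
  }
  looks_pos <- grepl("^[^:]+:[0-9]+$", variants)
  chrom <- ifelse(looks_pos, sub(":.*$", "", variants), "chrS")
  pos <- ifelse(looks_pos, as.integer(sub("^.*:", "", variants)),
                seq_along(variants))
  gt_code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(variants), function(i) {
    g <- gt_code(as.numeric(wide_g[i, samples]))
    if (has_cov) {
      dp <- as.numeric(wide_c[i, samples])
      cell <- paste0(g, ":", ifelse(is.na(dp), ".", as.integer(dp)))
    } else {
      cell <- g
    }
    paste(c(chrom[i], pos[i], variants[i], "A", "T", ".", "PASS", ".",
            if (has_cov) "GT:DP" else "GT", cell), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read per-sample cytosine reports
#'
#' Each report is a TSV with columns `chrom`, `pos`, `strand`, `context`,
#' `meth`, `total` for one sample; the sample id is taken from the file name
#' (without extension) unless `sample_ids` is given.
#'
#' @param paths Character vector of file paths.
#' @param sample_ids Optional sample ids matching `paths`.
#' @return A long methylation tibble with a `sample_id` column.
#' @export
read_cytosine_reports <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(paths) == length(sample_ids))
  purrr::map2_dfr(paths, sample_ids, function(p, s) {
    x <- readr::read_tsv(p, na = c("", "NA"), show_col_types = FALSE)
    required <- c("chrom", "pos", "strand", "context", "meth", "total")
    missing_cols <- setdiff(required, names(x))
    if (length(missing_cols)) {
      stop("Cytosine report ", p, " lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (any(x$meth > x$total, na.rm = TRUE)) {
      stop("Cytosine report ", p, ": methylated count exceeds total.",
           call. = FALSE)
    }
    if (!all(x$context %in% c("CG", "CHG", "CHH"))) {
      stop("Cytosine report ", p, ": invalid context label.", call. = FALSE)
    }
    dplyr::mutate(x, sample_id = s)
  })
}

#' Write per-sample cytosine reports
#'
#' Splits a long methylation tibble by sample and writes one TSV per sample
#' into `dir`, named `<sample_id>.tsv`.
#'
#' @param data Long methylation tibble with `sample_id` column.
#' @param dir Output directory (created if absent).
#' @return The written paths, invisibly.
#' @export
write_cytosine_reports <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  split_data <- split(data, data$sample_id)
  paths <- vapply(names(split_data), function(s) {
    p <- file.path(dir, paste0(s, ".tsv"))
    readr::write_tsv(
      dplyr::select(split_data[[s]], "chrom", "pos", "strand", "context",
                    "meth", "total"), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a gene/TE annotation from GFF3
#'
#' Imports a GFF3 file and keeps `gene` and transposable-element features
#' (types `transposable_element`, `transposon_fragment` or `TE`), returned as
#' a tibble with 1-based inclusive coordinates.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with `chrom`, `start`, `end`, `strand`, `feature`
#'   (`"gene"` or `"TE"`) and `feature_id`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_gene <- type == "gene"
  is_te <- type %in% c("transposable_element", "transposon_fragment", "TE")
  gr <- gr[is_gene | is_te]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("feat", seq_along(gr))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = ifelse(as.character(gr$type) == "gene", "gene", "TE"),
    feature_id = ids
  )
}

#' Write a gene/TE annotation to GFF3
#'
#' @param data Annotation tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(data, path) {
  type <- ifelse(data$feature == "gene", "gene", "transposable_element")
  strand <- ifelse(data$strand %in% c("+", "-"), data$strand, ".")
  lines <- c("##gff-version 3",
             paste(data$chrom, "episelect", type, data$start, data$end, ".",
                   strand, ".", paste0("ID=", data$feature_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulation manifest
#'
#' Records the seed and configuration of a synthetic dataset as plain
#' `key=value` text next to the data it describes.
#'
#' @param config Named list of scalar settings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  flat <- vapply(config, function(v) paste(format(v), collapse = ","),
                 character(1))
  writeLines(paste0(names(flat), "=", flat), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
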