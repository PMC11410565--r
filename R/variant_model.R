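#' Build a canonical variant identifier
#'
#' Joins the four key fields into the `chrom:pos:ref:alt` string used as the
#' join key everywhere in the package. Inputs are assumed normalized (see
#' [normalize_variants()]).
#'
#' @param chrom,pos,ref,alt Vectors of the key fields.
#' @return Character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# maximum allele length: small-variant calling covers indels of up to 50 bp,
# so with the one-base anchor an allele string may be at most 51 characters
.max_allele_len <- 51L

.check_alleles <- function(ref, alt) {
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("alleles must be non-empty strings over {A,C,G,T}; offending: ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "),
         call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  invisible(TRUE)
}

# trim one (pos, ref, alt) triple to its minimal representation:
# shared trailing bases first, then shared leading bases (advancing pos),
# always keeping at least one base on each side as the indel anchor
.trim_one <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Normalize variant representations
#'
#' Reduces each `(pos, ref, alt)` triple to its minimal parsimonious
#' spelling: shared trailing bases are trimmed first, then shared leading
#' bases (advancing `pos`), keeping one anchor base for indels. The
#' operation is idempotent, and every padded spelling of the same event
#' maps to the same key. Full left-alignment across repeat tracts requires
#' flanking reference sequence and is out of scope; trimming resolves all
#' paddings of a fixed event.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (extra columns are passed through).
#' @return Tibble with normalized `pos`, `ref`, `alt` and a rebuilt
#'   `variant_id` column.
#' @export
#' @examples
#' normalize_variants(data.frame(chrom = "1", pos = 100, ref = "CAG", alt = "CG"))
normalize_variants <- function(variants) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) == 0L) {
    variants$variant_id <- character(0)
    return(variants)
  }
  if (any(variants$pos < 1L)) stop("pos must be >= 1", call. = FALSE)
  .check_alleles(variants$ref, variants$alt)
  trimmed <- purrr::pmap(
    list(as.integer(variants$pos), variants$ref, variants$alt),
    .trim_one
  )
  variants$pos <- purrr::map_int(trimmed, "pos")
  variants$ref <- purrr::map_chr(trimmed, "ref")
  variants$alt <- purrr::map_chr(trimmed, "alt")
  too_long <- pmax(nchar(variants$ref), nchar(variants$alt)) > .max_allele_len
  if (any(too_long)) {
    stop(sum(too_long), " variant(s) exceed the 50 bp small-variant limit",
         call. = FALSE)
  }
  variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  variants
}

#' Read a multi-sample cohort VCF
#'
#' Reads a VCF 4.2+ file (plain or bgzipped) with `vcfR`, decomposes
#' multi-allelic records into one key per alternate allele, normalizes the
#' keys, and translates diploid GT fields into per-allele dosages. All
#' contigs are treated as diploid autosomes (the whole 28-gene panel is
#' autosomal); missing genotypes become `NA` and are excluded from both
#' numerator and denominator of downstream allele counts. Records whose
#' alleles exceed the 50 bp small-variant limit are dropped with a warning.
#'
#' @param path Path to the VCF file.
#' @return List with `variants` (tibble: `chrom`, `pos`, `ref`, `alt`,
#'   `variant_id`) and `dosage` (integer matrix, samples in rows, variants
#'   in columns, entries in `{0, 1, 2, NA}`).
#' @export
read_cohort_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {    # single-record VCFs come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (nrow(fix) == 0L) {
    return(list(
      variants = tibble::tibble(chrom = character(), pos = integer(),
                                ref = character(), alt = character(),
                                variant_id = character()),
      dosage = matrix(integer(0), nrow = length(samples), ncol = 0,
                      dimnames = list(samples, NULL))
    ))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(fix), ncol = length(samples),
                 dimnames = list(NULL, samples))
  }
  keys <- list()
  cols <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gti <- gt[i, , drop = TRUE]
    alleles <- strsplit(gti, "[/|]")
    n_all <- lengths(alleles)
    known <- !is.na(gti)
    if (any(n_all[known] != 2L)) {
      stop("non-diploid GT at ", fix$CHROM[i], ":", fix$POS[i],
           " (autosomal diploid genotypes are assumed)", call. = FALSE)
    }
    for (k in seq_along(alts)) {
      dos <- vapply(alleles, function(a) {
        if (length(a) != 2L || any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      keys[[length(keys) + 1L]] <- tibble::tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k]
      )
      cols[[length(cols) + 1L]] <- dos
    }
  }
  variants <- dplyr::bind_rows(keys)
  dosage <- do.call(cbind, cols)
  rownames(dosage) <- samples
  too_long <- pmax(nchar(variants$ref), nchar(variants$alt)) > .max_allele_len
  if (any(too_long)) {
    warning(sum(too_long),
            " record(s) exceeding the 50 bp small-variant limit dropped")
    variants <- variants[!too_long, , drop = FALSE]
    dosage <- dosage[, !too_long, drop = FALSE]
  }
  variants <- normalize_variants(variants)
  colnames(dosage) <- variants$variant_id
  list(variants = variants, dosage = dosage)
}

#' Write a cohort VCF
#'
#' Emits a minimal, deterministic VCF 4.2 file (one alternate allele per
#' record, GT-only FORMAT). Written directly rather than through a VCF
#' library so that identical inputs give byte-identical files, which the
#' reproducibility contract of the synthetic-cohort generator relies on.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param dosage Integer matrix (samples x variants) of alt-allele counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, dosage, path) {
  stopifnot(nrow(variants) == ncol(dosage))
  samples <- rownames(dosage)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(variants))
  for (j in seq_len(nrow(variants))) {
    gts <- gt_code[as.character(dosage[, j])]
    gts[is.na(gts)] <- "./."
    body[j] <- paste(c(variants$chrom[j], variants$pos[j], ".",
                       variants$ref[j], variants$alt[j], ".", "PASS", ".",
                       "GT", gts), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

.annotation_cols <- function() {
  c("chrom", "pos", "ref", "alt", "gene", "functional_class", "hgvs_g",
    "rsid", "gnomad_af", "clinvar_class", "clinvar_status", "sift",
    "polyphen2_hdiv", "mutation_assessor", "mcap", "cadd", "revel",
    "metalr", "acmg_flags", "gof_lof", "literature_support")
}

.check_enum <- function(x, allowed, what) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (any(bad)) {
    stop("invalid ", what, " token(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a per-variant annotation table
#'
#' Reads the fixed-header annotation TSV (one row per normalized variant)
#' carrying gene, functional class, gnomAD AF, ClinVar class and review
#' status, the seven in-silico predictor scores, semicolon-joined ACMG
#' criterion flags, GoF/LoF labels and the literature-support flag. Empty
#' numeric cells become missing (`NA`), never zero. Enum columns are
#' validated against their token sets, genes against the 28-gene panel,
#' and duplicate keys rejected.
#'
#' @param path Path to the TSV file.
#' @param panel Character vector of allowed gene symbols
#'   (default [acmg_sf_genes()]).
#' @return Tibble keyed by `variant_id`, one row per variant.
#' @export
read_annotation_table <- function(path, panel = acmg_sf_genes()) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    gene = readr::col_character(),
    functional_class = readr::col_character(),
    hgvs_g = readr::col_character(),
    rsid = readr::col_character(),
    gnomad_af = readr::col_double(),
    clinvar_class = readr::col_character(),
    clinvar_status = readr::col_character(),
    sift = readr::col_double(),
    polyphen2_hdiv = readr::col_double(),
    mutation_assessor = readr::col_double(),
    mcap = readr::col_double(),
    cadd = readr::col_double(),
    revel = readr::col_double(),
    metalr = readr::col_double(),
    acmg_flags = readr::col_character(),
    gof_lof = readr::col_character(),
    literature_support = readr::col_logical()
  ), na = c("", "NA", "."))
  missing_cols <- setdiff(.annotation_cols(), names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  required <- c("gene", "functional_class", "clinvar_class", "clinvar_status")
  for (col in required) {
    if (any(is.na(ann[[col]]))) {
      stop("column '", col, "' may not be missing", call. = FALSE)
    }
  }
  off_panel <- setdiff(unique(ann$gene), panel)
  if (length(off_panel) > 0L) {
    stop("gene(s) outside the panel: ",
         paste(off_panel, collapse = ", "), call. = FALSE)
  }
  .check_enum(ann$functional_class, functional_classes(), "functional_class")
  .check_enum(ann$clinvar_class, clinvar_classes(), "clinvar_class")
  .check_enum(ann$clinvar_status, clinvar_statuses(), "clinvar_status")
  .check_enum(ann$gof_lof, gof_lof_labels(), "gof_lof")
  ann$gof_lof[is.na(ann$gof_lof)] <- "unknown"
  ann$literature_support[is.na(ann$literature_support)] <- FALSE
  # a variant absent from ClinVar must be absent in both fields at once
  mismatch <- (ann$clinvar_class == "not_submitted") !=
    (ann$clinvar_status == "not_submitted")
  if (any(mismatch)) {
    stop("clinvar_class and clinvar_status disagree about submission at row(s) ",
         paste(which(mismatch), collapse = ", "), call. = FALSE)
  }
  flag_tokens <- unlist(strsplit(ann$acmg_flags[!is.na(ann$acmg_flags)], ";",
                                 fixed = TRUE))
  .check_enum(flag_tokens, acmg_flag_names(), "ACMG criterion")
  ann <- normalize_variants(ann)
  if (anyDuplicated(ann$variant_id)) {
    stop("duplicate variant key(s): ",
         paste(unique(ann$variant_id[duplicated(ann$variant_id)]),
               collapse = ", "), call. = FALSE)
  }
  dplyr::relocate(ann, "variant_id")
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]; used by the synthetic-cohort
#' generator and the report bundle.
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  readr::write_tsv(annotations[, .annotation_cols()], path, na = "")
  invisible(path)
}

#' Read sample metadata
#'
#' Reads the sample metadata TSV (`sample_id`, `cohort`, `age`, `sex`,
#' `birth_region`, `residence_region`). Sample ids must be unique and every
#' sample must carry a cohort label; region fields may be missing.
#'
#' @param path Path to the TSV file.
#' @return Tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cohort = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    birth_region = readr::col_character(),
    residence_region = readr::col_character()
  ), na = c("", "NA"))
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id(s)", call. = FALSE)
  }
  if (any(is.na(meta$cohort))) {
    stop("every sample needs a cohort label", call. = FALSE)
  }
  meta
}
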