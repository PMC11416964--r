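# Genotype containers and file I/O.
#
# A genotype matrix is a plain numeric matrix: rows are lines (or hybrids),
# columns are markers, entries are alt-allele dosages in {0, 1, 2} with NA
# for missing calls. Row and column names are mandatory and unique. Marker
# metadata (chrom, pos, ref, alt) travels in the "marker_info" attribute as
# a tibble when known; it is optional everywhere except VCF export.

#' Validate a genotype matrix
#'
#' Checks the conventions every `hybridgp` function relies on: a numeric
#' matrix with unique row (line) and column (marker) names, and every
#' non-missing dosage in `{0, 1, 2}` unless `fractional = TRUE` (hybrid or
#' imputed matrices carry fractional dosages in `[0, 2]`).
#'
#' @param g numeric matrix of allele dosages, lines x markers.
#' @param fractional allow any dosage in `[0, 2]` rather than only `{0,1,2}`.
#' @return `g`, invisibly, after validation.
#' @export
validate_genotypes <- function(g, fractional = FALSE) {
  if (!is.matrix(g) || !is.numeric(g)) {
    abort("genotypes must be a numeric matrix (lines x markers)")
  }
  if (is.null(rownames(g)) || is.null(colnames(g))) {
    abort("genotype matrix needs line ids as rownames and marker ids as colnames")
  }
  if (anyDuplicated(rownames(g))) abort("duplicate line ids in genotype matrix")
  if (anyDuplicated(colnames(g))) abort("duplicate marker ids in genotype matrix")
  v <- g[!is.na(g)]
  if (fractional) {
    if (length(v) && (min(v) < 0 || max(v) > 2)) {
      abort("dosages must lie in [0, 2]")
    }
  } else if (length(v) && !all(v %in% c(0, 1, 2))) {
    abort("dosages must be 0, 1, 2 or NA; use fractional = TRUE for hybrid/imputed matrices")
  }
  invisible(g)
}

marker_info_or_default <- function(g) {
  info <- attr(g, "marker_info")
  if (is.null(info)) {
    info <- tibble::tibble(
      marker_id = colnames(g),
      chrom = "1",
      pos = seq_len(ncol(g)),
      ref = "A",
      alt = "T"
    )
  }
  info
}

#' Read a genotype matrix from VCF or TSV
#'
#' VCF input uses the GT field of biallelic SNP records, coded as the count
#' of the ALT allele (`0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`).
#' Multiallelic records are dropped with a message. TSV input is a dosage
#' table with lines as rows (first column = line id) and marker ids as the
#' header.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @return numeric genotype matrix with a `marker_info` attribute (VCF only).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & !is.na(fix$ALT)
  n_drop <- sum(!biallelic)
  if (n_drop > 0) {
    message(n_drop, " multiallelic record(s) dropped")
    v <- v[biallelic, ]
    fix <- fix[biallelic, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  rownames(gt) <- ids
  if (anyDuplicated(colnames(gt))) abort("duplicate sample id in VCF")
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  g <- t(dos)
  storage.mode(g) <- "double"
  attr(g, "marker_info") <- tibble::tibble(
    marker_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  validate_genotypes(g)
  g
}

gt_to_dosage <- function(x) {
  if (is.na(x)) return(NA_real_)
  alleles <- strsplit(x, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

read_genotypes_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1, na.strings = c("NA", "."))
  g <- as.matrix(tab)
  storage.mode(g) <- "double"
  validate_genotypes(g, fractional = TRUE)
  g
}

#' Write a genotype matrix
#'
#' @param g genotype matrix.
#' @param path output path.
#' @param format `"vcf"` writes a minimal VCFv4.2 with GT fields (requires
#'   integer dosages); `"tsv"` writes the dosage table.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(line_id = rownames(g), g, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  validate_genotypes(g)
  info <- marker_info_or_default(g)
  dosage_to_gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(g)), function(j) {
    d <- g[, j]
    gt <- ifelse(is.na(d), "./.", dosage_to_gt[as.character(d)])
    paste(c(info$chrom[j], info$pos[j], info$marker_id[j], info$ref[j],
            info$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read and write hybrid phenotype tables
#'
#' A phenotype table records one row per phenotyped hybrid: `hybrid_id`,
#' `parent1`, `parent2`, then one numeric column per trait (NA = not
#' scored). Parent pairs are unordered-unique and self-crosses are rejected.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_phenotypes <- function(path) {
  tab <- tibble::as_tibble(read.table(path, header = TRUE, sep = ",",
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
  validate_phenotypes(tab)
  tab
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  validate_phenotypes(phenotypes)
  write.table(phenotypes, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
validate_phenotypes <- function(phenotypes) {
  need <- c("hybrid_id", "parent1", "parent2")
  if (!all(need %in% names(phenotypes))) {
    abort("phenotype table needs columns hybrid_id, parent1, parent2")
  }
  if (any(phenotypes$parent1 == phenotypes$parent2)) {
    abort("self-crosses are not allowed in the phenotype table")
  }
  key <- canonical_pair_id(phenotypes$parent1, phenotypes$parent2)
  if (anyDuplicated(key)) abort("duplicate parent pair in phenotype table")
  invisible(phenotypes)
}

#' Canonical hybrid identifier
#'
#' Hybrids are unordered crosses; the canonical id places the
#' lexicographically smaller parent first, so `A x B` and `B x A` share one
#' id.
#'
#' @param p1,p2 parent id vectors.
#' @return character vector of ids `"<p1> x <p2>"`.
#' @export
canonical_pair_id <- function(p1, p2) {
  a <- ifelse(p1 <= p2, p1, p2)
  b <- ifelse(p1 <= p2, p2, p1)
  paste(a, b, sep = " x ")
}

canonical_pairs <- function(p1, p2) {
  tibble::tibble(
    parent1 = ifelse(p1 <= p2, p1, p2),
    parent2 = ifelse(p1 <= p2, p2, p1)
  )
}
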