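#' Country-to-region lookup for African peanut breeding programs
#'
#' Fixed mapping used when a metadata table carries a country but no
#' region. Countries outside the table map to `"other"`.
#' @keywords internal
COUNTRY_REGION <- c(
  Ghana = "West", Mali = "West", Niger = "West", Senegal = "West",
  Togo = "West",
  Malawi = "Southern", Mozambique = "Southern", Zambia = "Southern",
  Uganda = "East")

PROGRAM_COUNTRY <- c(
  Gh1 = "Ghana", Gh2 = "Ghana", Mlw = "Malawi", Ml = "Mali",
  Mz = "Mozambique", Ng = "Niger", Sn = "Senegal", Tg = "Togo",
  Ug = "Uganda", Zam = "Zambia")

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file with GT fields into a [GenotypeMatrix-class].
#' Diploid genotypes are mapped `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./. -> -1`; phased separators (`|`) are accepted and
#' treated as unphased, since SNP-array calls carry no phase.
#'
#' @param path path to a (plain-text or gzipped) VCF file.
#' @param multiallelic what to do with records whose ALT holds more than
#'   one allele: `"error"` (default) aborts, `"skip"` drops them.
#' @return a [GenotypeMatrix-class] with sample order as in the VCF
#'   header and marker order as in the body.
#' @export
readVCF <- function(path, multiallelic = c("error", "skip")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  if (ncol(v@gt) < 2L) stop("VCF contains no sample columns")
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " non-biallelic record(s); use multiallelic = 'skip'")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
    if (nrow(fix) == 0L) stop("no biallelic records left after skipping")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- sub("\\|", "/", gt)
  code <- matrix(-1L, nrow = nrow(gt), ncol = ncol(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  bad <- !is.na(gt) & !(gt %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(bad))
    stop("unsupported GT value(s), e.g. ", gt[which(bad)[1]])
  ids <- fix$ID
  if (any(is.na(ids) | ids == "."))
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, "_", fix$POS), ids)
  calls <- t(code)
  rownames(calls) <- colnames(gt)
  colnames(calls) <- ids
  markers <- data.frame(id = ids, chrom = fix$CHROM,
                        pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  GenotypeMatrix(calls, markers)
}

#' Write a GenotypeMatrix to a VCF file
#'
#' Emits a minimal spec-conformant VCF 4.2 file with a GT-only FORMAT
#' column. `readVCF(writeVCF(gm))` reproduces calls, sample order and
#' marker order exactly.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(gm, path) {
  validObject(gm)
  gtmap <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- genotypeCalls(gm)
  mk <- markerInfo(gm)
  gt <- matrix(gtmap[as.character(t(calls))],
               nrow = ncol(calls), ncol = nrow(calls))
  body <- cbind(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", ".", ".",
                "GT", gt)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=germDiv",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sampleIds(gm)), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a UTF-8 CSV with (at least) columns `id`, `name` and `program`.
#' Optional columns: `country` (inferred from the program code for the
#' known program set when absent), `region` (inferred from country via a
#' fixed lookup when absent), `breeder_nominated` (logical, default
#' `FALSE`). Duplicate display names are allowed — they are real in
#' germplasm collections and are reported by [detectNameDuplicates()] —
#' but sample ids must be unique.
#'
#' @param path CSV file path.
#' @return data.frame with columns `id`, `name`, `program`, `country`,
#'   `region`, `breeder_nominated`.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(md) == 0L) stop("metadata file is empty")
  need <- c("id", "name", "program")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(md$id))
    stop("sample ids must be unique in metadata")
  if (any(!nzchar(md$program)))
    stop("program codes must be nonempty")
  unknown <- setdiff(unique(md$program), names(PROGRAM_COUNTRY))
  if (length(unknown))
    warning("unknown program code(s) kept as-is: ",
            paste(unknown, collapse = ", "))
  if (is.null(md$country))
    md$country <- unname(PROGRAM_COUNTRY[md$program])
  if (is.null(md$region)) md$region <- NA_character_
  infer <- is.na(md$region) | !nzchar(md$region)
  md$region[infer] <- unname(COUNTRY_REGION[md$country[infer]])
  md$region[is.na(md$region)] <- "other"
  bad <- !(md$region %in% REGIONS)
  if (any(bad)) {
    warning("region(s) outside the controlled set mapped to 'other': ",
            paste(unique(md$region[bad]), collapse = ", "))
    md$region[bad] <- "other"
  }
  if (is.null(md$breeder_nominated)) md$breeder_nominated <- FALSE
  md$breeder_nominated <- as.logical(md$breeder_nominated)
  md[c("id", "name", "program", "country", "region", "breeder_nominated")]
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePhylipDist <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i],
                       formatC(d[i, ], format = "f", digits = 6)),
                     collapse = "  "), con)
  invisible(path)
}
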