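.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("malformed CSV %s: %s", path,
                                           conditionMessage(e)))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("%s (%s) lacks column(s): %s", what, path,
          paste(missing_cols, collapse = ", "))
  df
}

.offender_lines <- function(bad_rows) {
  # +1 for the CSV header row
  paste(utils::head(bad_rows + 1L, 10), collapse = ", ")
}

#' Read pipeline input tables from CSV
#'
#' All readers validate required columns, controlled vocabularies and
#' value ranges, reporting offending file line numbers.
#'
#' @param path CSV path; dates ISO-8601, UTF-8, header row.
#' @return A `data.table` of the validated records.
#' @name readers
NULL

#' @rdname readers
#' @export
read_prescriptions <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "drug", "daily_dose_mg",
                                  "start_date", "days_supply"),
                          "prescriptions")
  bad <- which(!df$drug %in% statin_vocabulary)
  if (length(bad))
    stopf("unknown drug code(s) %s in %s at line(s) %s",
          paste(unique(df$drug[bad]), collapse = ", "), path,
          .offender_lines(bad))
  bad <- which(!is.finite(df$daily_dose_mg) | df$daily_dose_mg <= 0)
  if (length(bad))
    stopf("non-positive daily_dose_mg in %s at line(s) %s", path,
          .offender_lines(bad))
  bad <- which(!is.finite(df$days_supply) | df$days_supply < 1)
  if (length(bad))
    stopf("days_supply < 1 in %s at line(s) %s", path, .offender_lines(bad))
  df$start_date <- as_date_safe(df$start_date, sprintf("start_date in %s", path))
  setDT(df)[]
}

#' @rdname readers
#' @export
read_labs <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "date", "analyte", "value"),
                          "labs")
  bad <- which(!df$analyte %in% c("CK", "LDL"))
  if (length(bad))
    stopf("unknown analyte(s) %s in %s at line(s) %s",
          paste(unique(df$analyte[bad]), collapse = ", "), path,
          .offender_lines(bad))
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad))
    stopf("negative or missing lab value in %s at line(s) %s", path,
          .offender_lines(bad))
  df$date <- as_date_safe(df$date, sprintf("date in %s", path))
  setDT(df)[]
}

#' @rdname readers
#' @export
read_covariates <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "age", "sex", "t2d",
                                  "comedication"), "covariates")
  bad <- which(!df$sex %in% c("M", "F"))
  if (length(bad))
    stopf("sex must be 'M'/'F' in %s at line(s) %s", path,
          .offender_lines(bad))
  setDT(df)[]
}

#' @rdname readers
#' @export
read_studies <- function(path) {
  df <- .read_csv_checked(path, c("study", "or", "ci_lo", "ci_hi"),
                          "study effects")
  setDT(df)[]
}

#' Read genotype calls from CSV or a minimal single-variant VCF
#'
#' Both input paths yield the same table, so downstream analysis tables
#' are identical for equivalent content.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"csv"` or `"vcf"`.
#' @return `data.table` with `patient_id`, `rsid`, `genotype`.
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- .read_csv_checked(path, c("patient_id", "genotype"), "genotypes")
  if (!"rsid" %in% names(df)) df$rsid <- "rs12975366"
  df$genotype[df$genotype == "C/T"] <- "T/C"
  bad <- which(!df$genotype %in% c("T/T", "T/C", "C/C"))
  if (length(bad))
    stopf("unknown genotype code(s) %s in %s at line(s) %s",
          paste(unique(df$genotype[bad]), collapse = ", "), path,
          .offender_lines(bad))
  setDT(df)
  df[, .(patient_id, rsid, genotype)]
}

#' @rdname read_genotypes
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) != 1)
    stopf("expected a single-variant VCF, found %d records in %s",
          nrow(vcf@fix), path)
  fix <- vcf@fix[1, ]
  if (!identical(unname(fix[["REF"]]), "T") ||
      !identical(unname(fix[["ALT"]]), "C"))
    stopf("VCF %s is not the expected T>C variant (REF %s, ALT %s)",
          path, fix[["REF"]], fix[["ALT"]])
  gt <- vcfR::extract.gt(vcf)[1, ]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = "T/T", "0/1" = "T/C", "1/0" = "T/C", "1/1" = "C/C")
  bad <- names(gt)[!gt %in% names(map) & !is.na(gt)]
  if (length(bad))
    stopf("unknown GT code(s) in %s for sample(s): %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  data.table(patient_id = names(gt),
             rsid = fix[["ID"]] %||% "rs12975366",
             genotype = unname(map[gt]))
}

#' Write genotype calls as a minimal VCF v4.2
#'
#' Single biallelic record (GRCh37 chr19:54759361 T>C by default) with a
#' GT-only FORMAT field, one sample column per patient.
#'
#' @param genotypes table with `patient_id`, `genotype` (and optionally
#'   `rsid`).
#' @param path output path.
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, chrom = "19",
                                pos = 54759361L, ref = "T", alt = "C") {
  genotypes <- as.data.table(genotypes)
  map <- c("T/T" = "0/0", "T/C" = "0/1", "C/T" = "0/1", "C/C" = "1/1")
  gt <- map[genotypes$genotype]
  if (anyNA(gt)) stopf("genotypes contain codes outside {T/T, T/C, C/C}")
  rsid <- if ("rsid" %in% names(genotypes)) genotypes$rsid[1] else "rs12975366"
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=statintol %s", as.character(utils::packageVersion("statintol"))),
    "##reference=GRCh37",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$patient_id), collapse = "\t"),
    paste(c(chrom, pos, rsid, ref, alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# write via a temporary file in the same directory, then rename (atomic
# on the same filesystem)
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not write %s", path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  write_atomic(function(p) utils::write.csv(df, p, row.names = FALSE,
                                            quote = FALSE, na = ""), path)
}

#' Write a cohort bundle's tables to a directory
#'
#' Five CSV tables with ISO-8601 dates; genotypes optionally as a minimal
#' single-record VCF.
#'
#' @param bundle a [cohort_bundle()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"vcf"` for the genotype table.
#' @return character vector of the files written, invisibly.
#' @export
write_cohort <- function(bundle, dir, format = c("csv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(patients = "patients.csv", prescriptions = "prescriptions.csv",
             labs = "labs.csv", truth = "truth.csv")
  out <- character(0)
  for (nm in names(files)) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(dir, files[[nm]])
    write_csv_atomic(bundle[[nm]], p)
    out <- c(out, p)
  }
  gp <- file.path(dir, if (format == "vcf") "genotypes.vcf" else "genotypes.csv")
  if (format == "vcf")
    write_atomic(function(tmp) write_genotypes_vcf(bundle$genotypes, tmp), gp)
  else write_csv_atomic(bundle$genotypes, gp)
  out <- c(out, gp)
  invisible(out)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata`; listed when
#'   missing.
#' @export
statintol_example <- function(file = NULL) {
  base <- system.file("extdata", package = "statintol")
  if (is.null(file)) return(list.files(base))
  path <- file.path(base, file)
  if (!file.exists(path)) stopf("no packaged file '%s'", file)
  path
}
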