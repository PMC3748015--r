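#' Write genotypes as a dosage TSV
#'
#' Individuals in rows (first column `id`), markers in columns with a
#' header row of marker IDs; entries are counts of the reference-labelled
#' allele.
#'
#' @param geno dosage matrix with individual rownames.
#' @param path output file.
#' @param markerIds column names; default `M<index>`.
#' @export
writeGenotypesTsv <- function(geno, path,
                              markerIds = sprintf("M%d", seq_len(ncol(geno)))) {
  dt <- data.table::as.data.table(geno)
  data.table::setnames(dt, markerIds)
  dt <- cbind(data.table::data.table(
    id = rownames(geno) %||% as.character(seq_len(nrow(geno)))), dt)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a dosage TSV
#'
#' @param path file written by [writeGenotypesTsv()] (or compatible).
#' @return Integer dosage matrix with individual rownames and marker
#'   colnames.
#' @export
readGenotypesTsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- as.character(dt[[1]])
  geno <- as.matrix(dt[, -1])
  if (anyNA(geno) || any(geno < 0 | geno > 2))
    stop("dosages must be 0, 1 or 2 with no missing values")
  storage.mode(geno) <- "integer"
  rownames(geno) <- ids
  geno
}

#' Write genotypes as VCF 4.2
#'
#' Diploid unphased GT records, one biallelic SNP per marker; dosages count
#' the ALT allele. Map positions in Morgan are exported as base pairs at
#' 1 cM = 1 Mb.
#'
#' @param geno dosage matrix (individuals x markers).
#' @param map a [GenomeMap-class] for the marker coordinates.
#' @param path output file (plain text).
#' @export
writeGenotypesVcf <- function(geno, map, path) {
  m <- ncol(geno)
  if (m != nMarkers(map)) stop("genotype/map marker mismatch")
  ids <- rownames(geno) %||% sprintf("ind%d", seq_len(nrow(geno)))
  pos <- as.integer(round(map@positions * 1e8)) + 1L # 1 Morgan = 100 Mb
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=epibayes",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               sprintf("##contig=<ID=%d>", seq_len(map@nChrom)),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gtCode <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(m), function(j) {
    paste(c(map@chrom[j], pos[j], sprintf("M%d", j), "A", "C", ".", ".",
            ".", "GT", gtCode[geno[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Load genotypes from VCF or TSV
#'
#' VCF records must be biallelic diploid SNPs; a multiallelic record or a
#' malformed GT field is an error naming the record. Missing genotypes are
#' an error unless `imputeMean` is set, in which case they are replaced by
#' the rounded marker mean dosage.
#'
#' @param path input file.
#' @param format "vcf" or "tsv"; guessed from the file extension when
#'   omitted.
#' @param imputeMean mean-impute missing VCF genotypes?
#' @return Integer dosage matrix (individuals x markers).
#' @export
loadGenotypes <- function(path, format = NULL, imputeMean = FALSE) {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  format <- match.arg(format, c("vcf", "tsv"))
  if (format == "tsv") return(readGenotypesTsv(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multiallelic record at ", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- gsub("\\|", "/", gt)
  dose <- matrix(NA_real_, nrow(code), ncol(code))
  dose[code == "0/0"] <- 0
  dose[code %in% c("0/1", "1/0")] <- 1
  dose[code == "1/1"] <- 2
  missing <- is.na(code) | code %in% c("./.", ".")
  bad <- is.na(dose) & !missing
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)
    w <- if (is.matrix(w)) w[1, ] else c(1L, 1L)
    stop("malformed GT field '", gt[w[1], w[2]], "' at record ",
         fix[w[1], "CHROM"], ":", fix[w[1], "POS"])
  }
  if (any(missing)) {
    if (!imputeMean)
      stop("missing genotypes present; rerun with imputeMean = TRUE")
    dose[missing] <- NA
    mu <- rowMeans(dose, na.rm = TRUE)
    idx <- which(is.na(dose), arr.ind = TRUE)
    dose[idx] <- round(mu[idx[, 1]])
  }
  geno <- t(dose)
  storage.mode(geno) <- "integer"
  rownames(geno) <- colnames(gt)
  colnames(geno) <- rownames(gt)
  geno
}

#' Write a pedigree TSV
#'
#' @param pop a [Population-class].
#' @param path output file.
#' @export
writePedigree <- function(pop, path) {
  data.table::fwrite(pop@pedigree[c("id", "sire", "dam", "generation",
                                    "sex")], path, sep = "\t")
  invisible(path)
}

#' Write phenotypes as TSV (id, y)
#'
#' @param ids individual ids.
#' @param y phenotypes.
#' @param path output file.
#' @export
writePhenotypes <- function(ids, y, path) {
  data.table::fwrite(data.table::data.table(id = ids, y = y), path,
                     sep = "\t")
  invisible(path)
}

#' Read phenotypes written by [writePhenotypes()]
#'
#' @param path input file.
#' @return Named numeric vector.
#' @export
readPhenotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  setNames(as.numeric(dt$y), as.character(dt$id))
}

#' Serialise a trait architecture to JSON (for replay)
#'
#' @param arch a [TraitArchitecture-class].
#' @param path output file.
#' @export
writeArchitectureJson <- function(arch, path) {
  jsonlite::write_json(list(
    qtl = arch@qtl, a = arch@a, d = arch@d,
    pairs = arch@pairs, h2 = arch@h2, sigmaE2 = arch@sigmaE2,
    class22dose = arch@class22dose), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trait architecture from JSON
#'
#' @param path file written by [writeArchitectureJson()].
#' @return A [TraitArchitecture-class].
#' @export
readArchitectureJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- if (is.data.frame(x$pairs) && nrow(x$pairs)) x$pairs else
    data.frame(source = character(), j = integer(), k = integer(),
               effect = numeric())
  new("TraitArchitecture", qtl = as.integer(x$qtl), a = as.numeric(x$a),
      d = as.numeric(x$d), pairs = pairs, h2 = as.numeric(x$h2),
      sigmaE2 = as.numeric(x$sigmaE2),
      class22dose = as.integer(x$class22dose))
}
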