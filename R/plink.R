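# PLINK 1.9 file input/output: binary bed/bim/fam (SNP-major) and text
# ped/map.  Dosages count the alternate allele, which is written as A1 in
# the .bim file so that binary round trips are exact.  The .map format
# carries no allele roles, so the ped writer additionally emits
# <prefix>.ref (snp_id, counted allele); the reader uses it when present
# and otherwise counts the lexicographically later allele character.

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))
PLINK_SNP_MAJOR <- as.raw(0x01)

#' Write genotypes to PLINK files
#'
#' @param panel A \code{hap_panel}, or a dosage matrix in \{0, 1, 2, NA\}
#'   with individual row names (alternate-allele counts).
#' @param prefix Output path prefix (files \code{prefix.bed/.bim/.fam} or
#'   \code{prefix.ped/.map/.ref}).
#' @param format \code{"bed"} (binary, SNP-major) or \code{"ped"} (text).
#' @param map Variant table (\code{chrom}, \code{snp_id}, \code{bp},
#'   \code{allele_ref}, \code{allele_alt}); taken from the panel when omitted.
#' @param sex Optional per-individual \code{"M"}/\code{"F"} vector.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(panel, prefix, format = c("bed", "ped"),
                        map = NULL, sex = NULL) {
  format <- match.arg(format)
  if (inherits(panel, "hap_panel")) {
    d <- dosages(panel)
    map <- map %||% panel$map
    sex <- sex %||% panel$sex
  } else {
    d <- panel
    if (is.null(map)) stop("'map' is required when writing a dosage matrix")
    if (is.null(rownames(d))) rownames(d) <- sprintf("I%d", seq_len(nrow(d)))
  }
  n <- nrow(d); m <- ncol(d)
  stopifnot(m == nrow(map))
  ids <- rownames(d)
  sex_code <- if (is.null(sex)) rep(0L, n) else ifelse(sex == "M", 1L, 2L)

  if (format == "bed") {
    fam <- data.frame(ids, ids, 0L, 0L, sex_code, -9L)
    utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    bim <- data.frame(map$chrom, map$snp_id, 0L, map$bp,
                      map$allele_alt, map$allele_ref)
    utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    # 2-bit codes: 00 hom A1 (=alt), 10 het, 11 hom A2, 01 missing
    code <- matrix(0L, n, m)
    code[d == 1L] <- 2L
    code[d == 0L] <- 3L
    code[is.na(d)] <- 1L
    n4 <- 4L * ceiling(n / 4)
    if (n4 > n) code <- rbind(code, matrix(0L, n4 - n, m))
    q <- matrix(code, nrow = 4L)
    bytes <- q[1L, ] + 4L * q[2L, ] + 16L * q[3L, ] + 64L * q[4L, ]
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(c(PLINK_MAGIC, PLINK_SNP_MAJOR), con)
    writeBin(as.raw(bytes), con)
  } else {
    utils::write.table(
      data.frame(map$chrom, map$snp_id, 0L, map$bp),
      paste0(prefix, ".map"), quote = FALSE,
      row.names = FALSE, col.names = FALSE, sep = "\t")
    utils::write.table(
      data.frame(map$snp_id, map$allele_alt),
      paste0(prefix, ".ref"), quote = FALSE,
      row.names = FALSE, col.names = FALSE, sep = "\t")
    ref <- map$allele_ref; alt <- map$allele_alt
    a1 <- matrix(ref, n, m, byrow = TRUE)
    a2 <- a1
    a1[d >= 1L & !is.na(d)] <- matrix(alt, n, m, byrow = TRUE)[d >= 1L & !is.na(d)]
    a2[d == 2L & !is.na(d)] <- matrix(alt, n, m, byrow = TRUE)[d == 2L & !is.na(d)]
    a1[is.na(d)] <- "0"; a2[is.na(d)] <- "0"
    geno <- matrix("", n, 2L * m)
    geno[, seq(1L, 2L * m, by = 2L)] <- a1
    geno[, seq(2L, 2L * m, by = 2L)] <- a2
    ped <- cbind(ids, ids, "0", "0", sex_code, "-9", geno)
    utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK files
#'
#' Reads \code{prefix.bed/.bim/.fam} when a \code{.bed} file exists,
#' otherwise \code{prefix.ped/.map}.  Binary files must carry the PLINK 1.9
#' magic bytes in SNP-major orientation.
#'
#' @param prefix Path prefix of the fileset.
#' @return List with \code{dosages} (individual-by-SNP matrix of
#'   alternate-allele counts, \code{NA} = missing), \code{map} (variant
#'   table) and \code{fam} (individual table with \code{id} and \code{sex}).
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) read_plink_bed(prefix)
  else if (file.exists(paste0(prefix, ".ped"))) read_plink_ped(prefix)
  else stop("no PLINK fileset at prefix '", prefix,
            "': neither .bed nor .ped found")
}

require_file <- function(path) {
  if (!file.exists(path)) stop("missing PLINK file: ", path)
  path
}

read_bim <- function(path) {
  bim <- utils::read.table(require_file(path), stringsAsFactors = FALSE)
  if (ncol(bim) != 6L) stop("malformed .bim file: expected 6 columns")
  data.frame(chrom = bim[[1]], snp_id = as.character(bim[[2]]),
             bp = bim[[4]], allele_ref = as.character(bim[[6]]),
             allele_alt = as.character(bim[[5]]), stringsAsFactors = FALSE)
}

read_fam <- function(path) {
  fam <- utils::read.table(require_file(path), stringsAsFactors = FALSE)
  data.frame(id = as.character(fam[[2]]),
             sex = c("M", "F", NA)[match(fam[[5]], c(1L, 2L, 0L))],
             stringsAsFactors = FALSE)
}

read_plink_bed <- function(prefix) {
  fam <- read_fam(paste0(prefix, ".fam"))
  map <- read_bim(paste0(prefix, ".bim"))
  n <- nrow(fam); m <- nrow(map)
  bed_path <- require_file(paste0(prefix, ".bed"))
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1L] != PLINK_MAGIC[1L] || raw[2L] != PLINK_MAGIC[2L])
    stop("not a PLINK .bed file (bad magic bytes): ", bed_path)
  if (raw[3L] != PLINK_SNP_MAJOR)
    stop("unsupported .bed orientation (expected SNP-major, mode 0x01)")
  bpp <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpp * m)
    stop(sprintf("truncated or oversized .bed: expected %d data bytes, found %d",
                 bpp * m, length(body)))
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = 4L * bpp)[seq_len(n), , drop = FALSE]
  d <- matrix(c(2L, NA, 1L, 0L)[codes + 1L], n, m,
              dimnames = list(fam$id, map$snp_id))
  list(dosages = d, map = map, fam = fam)
}

read_plink_ped <- function(prefix) {
  map0 <- utils::read.table(require_file(paste0(prefix, ".map")),
                            stringsAsFactors = FALSE)
  m <- nrow(map0)
  lines <- readLines(require_file(paste0(prefix, ".ped")))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- length(fields)
  if (n == 0L) stop("empty .ped file")
  if (any(lengths(fields) != 6L + 2L * m))
    stop("malformed .ped: expected ", 6L + 2L * m, " fields per line")
  ped <- do.call(rbind, fields)
  fam <- data.frame(id = ped[, 2L],
                    sex = c("M", "F", NA)[match(ped[, 5L], c("1", "2", "0"))],
                    stringsAsFactors = FALSE)
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  ref_path <- paste0(prefix, ".ref")
  counted <- if (file.exists(ref_path)) {
    ref <- utils::read.table(ref_path, stringsAsFactors = FALSE)
    ref[[2L]][match(map0[[2L]], ref[[1L]])]
  } else {
    vapply(seq_len(m), function(j) {
      al <- setdiff(unique(c(a1[, j], a2[, j])), "0")
      if (length(al) == 0L) "B" else sort(al)[length(al)]
    }, "")
  }
  cnt <- matrix(counted, n, m, byrow = TRUE)
  d <- (a1 == cnt) + (a2 == cnt)
  d[a1 == "0" | a2 == "0"] <- NA
  other <- vapply(seq_len(m), function(j) {
    al <- setdiff(unique(c(a1[, j], a2[, j])), c("0", counted[j]))
    if (length(al) == 0L) "A" else sort(al)[1L]
  }, "")
  storage.mode(d) <- "integer"
  map <- data.frame(chrom = map0[[1L]], snp_id = as.character(map0[[2L]]),
                    bp = map0[[4L]], allele_ref = other,
                    allele_alt = counted, stringsAsFactors = FALSE)
  dimnames(d) <- list(fam$id, map$snp_id)
  list(dosages = d, map = map, fam = fam)
}
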