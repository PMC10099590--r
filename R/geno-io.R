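#' Construct a marker set
#'
#' The container used by all genotype operations: reference-allele dosage
#' matrix (individuals x markers, codes 0/1/2/NA) plus a marker map and,
#' optionally, the two phased haplotype matrices (codes 0/1/NA).
#'
#' @param geno Integer matrix, individuals in rows, markers in columns.
#' @param map Data frame with columns \code{name}, \code{chrom}, \code{pos}
#'   (1-based bp, strictly increasing within chromosome).
#' @param ids Individual ids (defaults to rownames of \code{geno}).
#' @param hap1,hap2 Optional phased haplotype matrices (same shape as
#'   \code{geno}); their sum must reproduce \code{geno} wherever both are
#'   non-missing.
#' @return Object of class \code{"marker_set"}.
#' @export
marker_set <- function(geno, map, ids = rownames(geno),
                       hap1 = NULL, hap2 = NULL) {
  geno <- as.matrix(geno)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(geno)))
  stopifnot(nrow(map) == ncol(geno),
            all(c("name", "chrom", "pos") %in% names(map)))
  map$name <- as.character(map$name)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  rownames(geno) <- ids
  colnames(geno) <- map$name
  phased <- !is.null(hap1) && !is.null(hap2)
  if (phased) {
    stopifnot(identical(dim(hap1), dim(geno)),
              identical(dim(hap2), dim(geno)))
    dimnames(hap1) <- dimnames(hap2) <- dimnames(geno)
    both <- !is.na(hap1) & !is.na(hap2) & !is.na(geno)
    if (any((hap1 + hap2)[both] != geno[both]))
      stop("haplotype pair sums do not reproduce the genotype matrix")
  }
  structure(list(ids = ids, map = map, geno = geno,
                 hap1 = hap1, hap2 = hap2, phased = phased),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", length(x$ids), "individuals x", nrow(x$map), "markers;",
      if (x$phased) "phased" else "unphased", "\n")
  cat("chromosomes:", paste(unique(x$map$chrom), collapse = " "), "\n")
  invisible(x)
}

#' Read genotypes from VCF or PLINK ped/map files
#'
#' VCF input (via the vcfR package) uses the first ALT allele as the counted
#' reference allele; \code{"|"}-separated genotypes populate the phased
#' haplotype matrices, \code{"/"}-separated ones leave the set unphased.
#' PLINK text input expects the classic .ped/.map pair; the counted allele is
#' the first allele observed for each marker (recorded in the map).
#'
#' @param path Path to a \code{.vcf} file, or the common prefix of a
#'   \code{.ped}/\code{.map} pair.
#' @param format \code{"vcf"} or \code{"plink_pedmap"}; guessed from the file
#'   extension by default.
#' @return A [marker_set()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink_pedmap")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink_pedmap"
  if (format == "vcf") read_vcf_markers(path) else read_pedmap(path)
}

read_vcf_markers <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  nm <- fix[, "ID"]
  nm[is.na(nm) | nm == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[
    is.na(nm) | nm == "."]
  map <- data.frame(name = nm, chrom = as.character(fix[, "CHROM"]),
                    pos = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  ids <- colnames(gt)
  m <- nrow(gt); n <- length(ids)
  h1 <- matrix(NA_integer_, n, m)
  h2 <- matrix(NA_integer_, n, m)
  phased_all <- TRUE
  for (j in seq_len(m)) {
    g <- gt[j, ]
    present <- !is.na(g) & !(g %in% c(".", "./.", ".|."))
    if (any(present)) {
      bad <- present & !grepl("^[0-9.]+[|/][0-9.]+$", g)
      if (any(bad))
        stop("malformed or non-diploid GT '", g[bad][1], "' at marker row ", j)
      if (any(present & grepl("/", g, fixed = TRUE))) phased_all <- FALSE
      a1 <- suppressWarnings(as.integer(sub("^([0-9.]+)[|/].*$", "\\1", g)))
      a2 <- suppressWarnings(as.integer(sub("^[0-9.]+[|/]([0-9.]+)$", "\\1", g)))
      a1[!present] <- NA_integer_
      a2[!present] <- NA_integer_
      h1[, j] <- a1
      h2[, j] <- a2
    }
  }
  if (any(stats::na.omit(c(h1, h2)) > 1))
    stop("multi-allelic genotypes are not supported")
  geno <- h1 + h2
  if (phased_all)
    marker_set(geno, map, ids, hap1 = h1, hap2 = h2)
  else
    marker_set(geno, map, ids)
}

read_pedmap <- function(prefix) {
  prefix <- sub("\\.(ped|map)$", "", prefix)
  map_raw <- utils::read.table(paste0(prefix, ".map"),
                               stringsAsFactors = FALSE)
  names(map_raw)[1:4] <- c("chrom", "name", "cm", "pos")
  ped_raw <- utils::read.table(paste0(prefix, ".ped"),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  m <- nrow(map_raw)
  if (ncol(ped_raw) != 6 + 2 * m)
    stop("ped file has ", ncol(ped_raw), " columns; expected ", 6 + 2 * m)
  ids <- ped_raw[[2]]
  al <- as.matrix(ped_raw[, -(1:6), drop = FALSE])
  al[al == "0"] <- NA
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  geno <- matrix(NA_integer_, length(ids), m)
  counted <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    counted[j] <- stats::na.omit(obs)[1]
    geno[, j] <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
  }
  map <- data.frame(name = map_raw$name, chrom = as.character(map_raw$chrom),
                    pos = as.numeric(map_raw$pos), counted_allele = counted,
                    stringsAsFactors = FALSE)
  marker_set(geno, map, ids)
}

#' Write a marker set as a phased VCF
#'
#' Plain-text VCFv4.2 with GT-only genotype columns. Phased sets use
#' \code{"|"} separators; unphased sets write unordered \code{"/"} genotypes
#' (heterozygotes as 0/1).
#'
#' @param ms A [marker_set()].
#' @param path Output path.
#' @export
write_vcf <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ms$ids), collapse = "\t")), con)
  m <- nrow(ms$map)
  for (j in seq_len(m)) {
    if (ms$phased) {
      a1 <- ms$hap1[, j]; a2 <- ms$hap2[, j]
      g <- ifelse(is.na(a1) | is.na(a2), ".|.", paste0(a1, "|", a2))
    } else {
      gj <- ms$geno[, j]
      g <- c("0/0", "0/1", "1/1")[gj + 1L]
      g[is.na(gj)] <- "./."
    }
    writeLines(paste(c(ms$map$chrom[j], format(ms$map$pos[j], scientific = FALSE),
                       ms$map$name[j], "A", "B", ".", "PASS", ".", "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Intersect two genotype panels
#'
#' Keeps markers present in both sets (matched by name, falling back to
#' chromosome+position for unnamed markers) and concatenates the samples.
#' Markers whose positions disagree between the panels are dropped and logged.
#'
#' @param a,b [marker_set()] objects.
#' @return A [marker_set()] on the common markers with the samples of both
#'   panels; attribute \code{"dropped"} lists conflicting markers.
#' @export
intersect_panels <- function(a, b) {
  key <- function(ms) ms$map$name
  common <- intersect(key(a), key(b))
  if (!length(common)) stop("no markers in common between the two panels")
  ia <- match(common, key(a))
  ib <- match(common, key(b))
  conflict <- a$map$chrom[ia] != b$map$chrom[ib] |
    a$map$pos[ia] != b$map$pos[ib]
  dropped <- common[conflict]
  common <- common[!conflict]
  ia <- ia[!conflict]; ib <- ib[!conflict]
  if (!length(common)) stop("all shared markers conflict in map position")
  ord <- order(a$map$chrom[ia], a$map$pos[ia])
  ia <- ia[ord]; ib <- ib[ord]
  geno <- rbind(a$geno[, ia, drop = FALSE], b$geno[, ib, drop = FALSE])
  phased <- a$phased && b$phased
  h1 <- if (phased) rbind(a$hap1[, ia, drop = FALSE],
                          b$hap1[, ib, drop = FALSE]) else NULL
  h2 <- if (phased) rbind(a$hap2[, ia, drop = FALSE],
                          b$hap2[, ib, drop = FALSE]) else NULL
  out <- marker_set(geno, a$map[ia, c("name", "chrom", "pos")],
                    c(a$ids, b$ids), hap1 = h1, hap2 = h2)
  attr(out, "dropped") <- dropped
  out
}

subset_markers <- function(ms, marker_idx = NULL, sample_idx = NULL) {
  if (is.null(marker_idx)) marker_idx <- seq_len(nrow(ms$map))
  if (is.null(sample_idx)) sample_idx <- seq_along(ms$ids)
  marker_set(ms$geno[sample_idx, marker_idx, drop = FALSE],
             ms$map[marker_idx, , drop = FALSE],
             ms$ids[sample_idx],
             hap1 = if (ms$phased) ms$hap1[sample_idx, marker_idx, drop = FALSE],
             hap2 = if (ms$phased) ms$hap2[sample_idx, marker_idx, drop = FALSE])
}
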