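#' Construct a GenotypeTable from allele-label matrices
#'
#' @param allele1,allele2 character (or coercible) matrices of allele labels,
#'   individuals x loci, `NA` for missing calls. Pair order is irrelevant.
#' @param individualIds,locusNames identifiers; defaults taken from dimnames.
#' @return a [GenotypeTable-class].
#' @export
genotypeTable <- function(allele1, allele2,
                          individualIds = rownames(allele1),
                          locusNames = colnames(allele1)) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  if (is.null(individualIds))
    individualIds <- paste0("ind", seq_len(nrow(allele1)))
  if (is.null(locusNames))
    locusNames <- paste0("loc", seq_len(ncol(allele1)))
  if (!identical(is.na(allele1), is.na(allele2)))
    stop("half-missing calls are not allowed: both alleles or neither")
  n <- nrow(allele1); L <- ncol(allele1)
  i1 <- matrix(NA_integer_, n, L)
  i2 <- matrix(NA_integer_, n, L)
  registry <- vector("list", L)
  for (l in seq_len(L)) {
    labs <- sort(unique(c(allele1[, l], allele2[, l])))
    labs <- labs[!is.na(labs)]
    registry[[l]] <- as.character(labs)
    a <- match(as.character(allele1[, l]), registry[[l]])
    b <- match(as.character(allele2[, l]), registry[[l]])
    i1[, l] <- pmin(a, b)
    i2[, l] <- pmax(a, b)
  }
  new("GenotypeTable", individualIds = as.character(individualIds),
      locusNames = as.character(locusNames),
      allele1 = i1, allele2 = i2, alleleRegistry = registry)
}

#' Read a GenePop genotype file
#'
#' Parses the GenePop dialect: a title line, one locus name per line (or a
#' single comma-separated line), then `Pop` blocks of lines
#' `id , g1 g2 ...` where each genotype is a concatenated pair of 2- or
#' 3-digit allele codes and `00`/`000` marks a missing allele. Calls with
#' either allele missing are treated as missing.
#'
#' @param path path to the GenePop file.
#' @return a [GenotypeTable-class]; multiple `Pop` blocks are concatenated.
#' @export
readGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("GenePop parse error: file too short")
  body <- lines[-1]                       # drop title
  popIdx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(popIdx)) stop("GenePop parse error: no 'Pop' line found")
  locLines <- body[seq_len(popIdx[1] - 1)]
  loci <- trimws(unlist(strsplit(locLines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GenePop parse error: no locus names before 'Pop'")
  L <- length(loci)

  ids <- character(); a1 <- list(); a2 <- list()
  digits <- NA_integer_
  for (k in seq_along(popIdx)) {
    from <- popIdx[k] + 1
    to <- if (k < length(popIdx)) popIdx[k + 1] - 1 else length(body)
    if (to < from) next
    for (ln in body[from:to]) {
      lineNo <- 1 + which(lines == ln)[1]
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2)
        stop(sprintf("GenePop parse error at line %d: missing ',' separator",
                     lineNo))
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "\\s+")[[1]]
      codes <- codes[nzchar(codes)]
      if (length(codes) != L)
        stop(sprintf(
          "GenePop parse error at line %d: %d genotypes for %d loci",
          lineNo, length(codes), L))
      w <- unique(nchar(codes))
      if (length(w) != 1 || !(w %in% c(4L, 6L)))
        stop(sprintf(
          "GenePop parse error at line %d: allele codes must be uniform 2- or 3-digit pairs",
          lineNo))
      d <- w / 2L
      if (is.na(digits)) digits <- d
      else if (d != digits)
        stop(sprintf("GenePop parse error at line %d: mixed code widths",
                     lineNo))
      miss <- strrep("0", d)
      x1 <- substr(codes, 1, d)
      x2 <- substr(codes, d + 1, 2 * d)
      x1[x1 == miss | x2 == miss] <- NA
      x2[is.na(x1)] <- NA
      ids <- c(ids, id)
      a1[[length(a1) + 1]] <- x1
      a2[[length(a2) + 1]] <- x2
    }
  }
  if (!length(ids)) stop("GenePop parse error: no individuals")
  if (anyDuplicated(ids))
    stop("validation error: duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m1 <- do.call(rbind, a1); m2 <- do.call(rbind, a2)
  rownames(m1) <- rownames(m2) <- ids
  colnames(m1) <- colnames(m2) <- loci
  genotypeTable(m1, m2)
}

#' Write a GenotypeTable to a GenePop file
#'
#' @param table a [GenotypeTable-class].
#' @param path output path.
#' @param title title line.
#' @param digits 2 or 3 digit allele codes.
#' @return `path`, invisibly.
#' @export
writeGenepop <- function(table, path, title = "dcinbreed export",
                         digits = 2) {
  stopifnot(digits %in% c(2, 3))
  fmt <- function(lab) formatC(as.integer(lab), width = digits, flag = "0")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(locusNames(table), con)
  writeLines("Pop", con)
  miss <- strrep("0", digits)
  for (i in seq_len(nIndividuals(table))) {
    g <- vapply(seq_len(nLoci(table)), function(l) {
      a <- table@allele1[i, l]
      if (is.na(a)) return(paste0(miss, miss))
      reg <- table@alleleRegistry[[l]]
      paste0(fmt(reg[a]), fmt(reg[table@allele2[i, l]]))
    }, character(1))
    writeLines(paste0(individualIds(table)[i], " , ",
                      paste(g, collapse = " ")), con)
  }
  invisible(path)
}

# integer matrix of heterozygosity (1 het, 0 hom, NA missing)
.hetMatrix <- function(table) {
  h <- (table@allele1 != table@allele2) * 1L
  dimnames(h) <- list(table@individualIds, table@locusNames)
  h
}

# per-individual typed-locus counts L_i
.typedCounts <- function(table) {
  rowSums(!is.na(table@allele1))
}
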