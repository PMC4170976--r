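# Diploid genotype tables.
#
# A "genotype_table" holds allele sizes in bp for one population:
#   individuals  character vector
#   loci         character vector
#   a1, a2       numeric matrices (individuals x loci); unordered pairs are
#                normalised so a1 <= a2; NA marks missing data
# The native text format is TSV (columns: individual, optional colony, one
# column per locus with "size/size" entries, "0/0" or blank = missing).  A
# GenePop dialect is read and written as well; GenePop's fixed-width allele
# codes cannot carry sizes above 999, so export falls back to rank codes with
# a logged mapping.

new_genotype_table <- function(individuals, loci, a1, a2, colony = NULL) {
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]
  a1[swap] <- a2[swap]
  a2[swap] <- tmp
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2,
                 colony = colony),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individual(s) x %d locus/loci\n",
              length(x$individuals), length(x$loci)))
  invisible(x)
}

parse_genotype_cell <- function(cell, individual, locus) {
  cell <- trimws(cell)
  if (cell == "" || cell == "0/0" || cell == "NA") return(c(NA_real_, NA_real_))
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    msat_error("msat_genotype_error",
               sprintf("genotype '%s' for individual '%s' at locus '%s' is not diploid",
                       cell, individual, locus))
  }
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals)) {
    msat_error("msat_genotype_error",
               sprintf("non-numeric allele '%s' for individual '%s' at locus '%s'",
                       cell, individual, locus))
  }
  if (any(vals == 0)) return(c(NA_real_, NA_real_))
  vals
}

#' Read a diploid genotype table
#'
#' @param path input file.
#' @param dialect `"tsv"` (native; individual, optional colony, then one
#'   column per locus holding `"a/b"` allele sizes in bp) or `"genepop"`.
#' @return a `genotype_table`.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    msat_error("msat_io_error", sprintf("genotype file not found: %s", path))
  }
  if (dialect == "tsv") read_genotypes_tsv(path) else read_genepop(path)
}

read_genotypes_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (!"individual" %in% names(df)) {
    msat_error("msat_io_error", "TSV dialect requires an 'individual' column")
  }
  colony <- if ("colony" %in% names(df)) df$colony else NULL
  loci <- setdiff(names(df), c("individual", "colony"))
  if (length(loci) == 0) {
    msat_error("msat_io_error", "no locus columns found")
  }
  inds <- df$individual
  a1 <- a2 <- matrix(NA_real_, nrow(df), length(loci))
  for (j in seq_along(loci)) {
    for (i in seq_len(nrow(df))) {
      g <- parse_genotype_cell(df[[loci[j]]][i], inds[i], loci[j])
      a1[i, j] <- g[1]
      a2[i, j] <- g[2]
    }
  }
  new_genotype_table(inds, loci, a1, a2, colony)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) {
    msat_error("msat_io_error", "GenePop file too short")
  }
  # line 1: title; locus names until the first POP line (one per line or
  # comma-separated on one line)
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (length(pop_idx) == 0) {
    msat_error("msat_io_error", "GenePop file has no POP line")
  }
  loci <- unlist(strsplit(lines[2:(pop_idx[1] - 1)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  body <- lines[(pop_idx[1] + 1):length(lines)]
  body <- body[toupper(trimws(body)) != "POP"]
  inds <- character(0)
  rows1 <- rows2 <- list()
  for (ln in body) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      msat_error("msat_io_error", sprintf("malformed GenePop line: %s", ln))
    }
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gts) != length(loci)) {
      msat_error("msat_genotype_error",
                 sprintf("individual '%s' has %d genotypes for %d loci", id,
                         length(gts), length(loci)))
    }
    w <- nchar(gts)
    if (any(!w %in% c(4L, 6L))) {
      msat_error("msat_genotype_error",
                 sprintf("individual '%s': allele codes must be 2 or 3 digits", id))
    }
    half <- w / 2
    v1 <- as.numeric(substr(gts, 1, half))
    v2 <- as.numeric(substr(gts, half + 1, w))
    v1[v1 == 0] <- NA
    v2[v2 == 0] <- NA
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- v2[miss] <- NA
    inds <- c(inds, id)
    rows1[[length(rows1) + 1]] <- v1
    rows2[[length(rows2) + 1]] <- v2
  }
  new_genotype_table(inds, loci, do.call(rbind, rows1), do.call(rbind, rows2))
}

#' Write a genotype table
#'
#' @param table a `genotype_table`.
#' @param path output file.
#' @param dialect `"tsv"` or `"genepop"`. GenePop allele codes are 3 digits;
#'   when any allele size exceeds 999 the alleles of each locus are re-coded
#'   by rank and the mapping is logged.
#' @param title GenePop title line.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path, dialect = c("tsv", "genepop"),
                            title = "conmsat genotypes") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "genotype_table"))
  if (dialect == "tsv") {
    cell <- function(x, y) ifelse(is.na(x), "0/0", paste0(x, "/", y))
    df <- data.frame(individual = table$individuals,
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(table$colony)) df$colony <- table$colony
    for (j in seq_along(table$loci)) {
      df[[table$loci[j]]] <- cell(table$a1[, j], table$a2[, j])
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  a1 <- table$a1
  a2 <- table$a2
  if (any(c(a1, a2) > 999, na.rm = TRUE)) {
    msat_log("allele sizes exceed 3 digits; re-coding alleles by rank for GenePop export")
    for (j in seq_along(table$loci)) {
      sizes <- sort(unique(c(a1[, j], a2[, j])))
      sizes <- sizes[!is.na(sizes)]
      msat_log(sprintf("  %s: %s", table$loci[j],
                       paste(sprintf("%d->%03d", sizes, seq_along(sizes)),
                             collapse = " ")))
      a1[, j] <- match(a1[, j], sizes)
      a2[, j] <- match(a2[, j], sizes)
    }
  }
  fmt <- function(x, y) {
    ifelse(is.na(x), "000000", sprintf("%03d%03d", x, y))
  }
  lines <- c(title, table$loci, "POP")
  for (i in seq_along(table$individuals)) {
    lines <- c(lines, paste0(table$individuals[i], " , ",
                             paste(fmt(a1[i, ], a2[i, ]), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}
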