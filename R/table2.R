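# Packaged marker-panel characterisation table: 24 loci genotyped in single
# populations of six ant species (n, number of alleles, allele size range,
# observed/expected heterozygosity, Hardy-Weinberg deviation flag,
# amplification status).  Shipped as a plain TSV transcription; two size
# ranges are printed reversed in the source and are preserved verbatim with
# a flag plus corrected bounds, never silently fixed.

#' Load the packaged 24-locus, six-species marker characterisation table
#'
#' Returns one row per (locus, species) cell: 24 loci x 6 species = 144 rows.
#' Non-amplified cells carry NA statistics.  Size ranges printed in reversed
#' order in the source table are kept verbatim in `size_range` and flagged in
#' `size_range_flipped`; `size_min`/`size_max` hold the ordered bounds.
#'
#' @return a `data.frame` with columns locus, species, amplified, n, A,
#'   size_range, size_min, size_max, size_range_flipped, ho, he,
#'   hwe_deviates.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_loci.tsv", package = "conmsat",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                   na.strings = c("NA", ""))
  stopifnot(nrow(df) == 144)
  amp <- df$status == "amplified"
  bounds <- t(vapply(df$size_range, function(sr) {
    if (is.na(sr)) return(c(NA_real_, NA_real_))
    v <- as.numeric(strsplit(sr, "-", fixed = TRUE)[[1]])
    if (length(v) == 1) c(v, v) else v
  }, numeric(2)))
  out <- data.frame(
    locus = df$locus,
    species = df$species,
    amplified = amp,
    n = df$n,
    A = df$A,
    size_range = df$size_range,
    size_min = pmin(bounds[, 1], bounds[, 2]),
    size_max = pmax(bounds[, 1], bounds[, 2]),
    size_range_flipped = !is.na(bounds[, 1]) & bounds[, 1] > bounds[, 2],
    ho = df$ho,
    he = df$he,
    hwe_deviates = ifelse(is.na(df$hwe_deviates), NA, df$hwe_deviates == "yes"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("table2_fixture", "data.frame")
  out
}

#' Load the published cross-species primer pairs
#'
#' The 45 primer pairs designed from consensus flanks of the eight ant
#' genomes (21 screened with unlabelled primers only, 24 characterised in
#' depth).  Degenerate IUPAC codes in the sequences reflect variable
#' consensus positions.
#'
#' @return a `data.frame` with columns locus, forward, reverse, panel
#'   (`"screened"` or `"characterised"`).
#' @export
load_published_primers <- function() {
  path <- system.file("extdata", "published_primers.tsv", package = "conmsat",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
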