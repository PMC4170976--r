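# Genome input/output.
#
# A "genome" is a named list with fields:
#   genome_id  character scalar
#   contigs    named character vector, uppercase sequences over {A,C,G,T,N}
#   softmask   named list (per contig) of integer vectors: 0-based positions
#              that were lowercase (soft-masked) in the input
# A "genome_set" is a named list of genomes keyed by genome_id.

#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased; lowercase input positions are recorded as a
#' soft-mask. IUPAC ambiguity codes other than N are converted to N (with a
#' logged count); any other character is rejected with an error naming the
#' contig and 0-based offset.
#'
#' @param path path to a FASTA file.
#' @param genome_id identifier for the genome; defaults to the file base name.
#' @return an object of class `msat_genome`.
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    msat_error("msat_io_error", sprintf("FASTA file not found: %s", path))
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) {
    msat_error("msat_io_error", sprintf("empty FASTA file: %s", path))
  }
  nm <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(nm)) {
    msat_error("msat_io_error",
               sprintf("duplicate contig name in %s: %s", path,
                       nm[duplicated(nm)][1]))
  }
  raw <- as.character(recs)
  softmask <- lapply(raw, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] %in% letters) - 1L
  })
  seqs <- toupper(raw)
  n_amb <- 0L
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% names(IUPAC_SETS))
    if (length(bad)) {
      msat_error("msat_alphabet_error",
                 sprintf("illegal character '%s' in contig '%s' at offset %d",
                         chars[bad[1]], nm[i], bad[1] - 1L))
    }
    amb <- which(!chars %in% c(DNA_BASES, "N"))
    if (length(amb)) {
      n_amb <- n_amb + length(amb)
      chars[amb] <- "N"
      seqs[[i]] <- paste(chars, collapse = "")
    }
  }
  if (n_amb > 0) {
    msat_log(sprintf("%s: converted %d IUPAC ambiguity base(s) to N",
                     basename(path), n_amb))
  }
  names(seqs) <- nm
  names(softmask) <- nm
  if (is.null(genome_id)) {
    genome_id <- tools::file_path_sans_ext(basename(path))
  }
  structure(list(genome_id = genome_id, contigs = seqs, softmask = softmask),
            class = "msat_genome")
}

#' Write a genome to FASTA
#'
#' @param genome an `msat_genome`.
#' @param path output path.
#' @param width line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 60L) {
  stopifnot(inherits(genome, "msat_genome"))
  x <- Biostrings::BStringSet(genome$contigs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Bundle genomes into a genome set
#'
#' @param ... `msat_genome` objects (or a single list of them).
#' @return an object of class `msat_genome_set`: a named list of genomes.
#' @export
genome_set <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && !inherits(gs[[1]], "msat_genome")) gs <- gs[[1]]
  ids <- vapply(gs, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) {
    msat_error("msat_io_error",
               sprintf("duplicate genome_id: %s", ids[duplicated(ids)][1]))
  }
  names(gs) <- ids
  structure(gs, class = "msat_genome_set")
}

#' @export
print.msat_genome <- function(x, ...) {
  cat(sprintf("<msat_genome> %s: %d contig(s), %s bp\n", x$genome_id,
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' @export
print.msat_genome_set <- function(x, ...) {
  cat(sprintf("<msat_genome_set> %d genome(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Total length of a genome in bases
#'
#' @param genome an `msat_genome`.
#' @return integer total number of bases across contigs.
#' @export
genome_length <- function(genome) sum(nchar(genome$contigs))
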