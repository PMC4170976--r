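# Shared helpers: alphabet handling, coordinate conventions, local RNG.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes -> base sets (N covered separately)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base set (sorted, collapsed) -> IUPAC code
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
             CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  unname(codes[key])
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x character vector of DNA strings (may contain IUPAC codes and `-`).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN-", "TGCAYRSWMKVHDBN-", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Run `expr` under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Typed condition constructor used by all modules.
msat_error <- function(class, message, ...) {
  stop(structure(class = c(class, "msat_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

msat_log <- function(...) message("[conmsat] ", ...)

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# i.i.d. substitution of a DNA string at the given per-base rate; substituted
# positions always change to a different base.
mutate_dna <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate & chars %in% DNA_BASES)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}
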