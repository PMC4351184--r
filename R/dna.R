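# DNA sequence normalization and FASTA I/O.
#
# Sequences are plain uppercase character strings over {A,C,G,T,N}. All
# coordinates taken or returned by this package are 0-based, half-open.

#' Normalize a DNA sequence
#'
#' Coerces input to the package's internal sequence representation:
#' uppercase over the alphabet `A`, `C`, `G`, `T`, `N`. `U` is converted to
#' `T` (RNA input), and IUPAC ambiguity codes (`R`, `Y`, `S`, `W`, `K`, `M`,
#' `B`, `D`, `H`, `V`) are collapsed to `N` with a warning. Any other
#' character is an error.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @examples
#' as_dna("acgu")        # "ACGT"
#' suppressWarnings(as_dna("ACGR"))  # "ACGN"
#' @export
as_dna <- function(x) {
  if (!is.character(x) || any(is.na(x))) {
    stop("sequence must be a non-NA character vector")
  }
  x <- toupper(x)
  if (any(!nzchar(x))) stop("empty sequence")
  x <- chartr("U", "T", x)
  amb <- grepl("[RYSWKMBDHV]", x)
  if (any(amb)) {
    warning("IUPAC ambiguity codes collapsed to N in ",
            sum(amb), " sequence(s)")
    x[amb] <- gsub("[RYSWKMBDHV]", "N", x[amb])
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("illegal characters in sequence: ",
         paste(unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad]), ""))),
               collapse = ", "))
  }
  x
}

#' Read a FASTA file
#'
#' Records are returned in file order as a named character vector of
#' normalized sequences (see [as_dna()]). Record ids are the first
#' whitespace-delimited token of each header line.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed or empty FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(as_dna(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  x <- as_dna(x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# substring in 0-based half-open coordinates
subseq0 <- function(s, from, to) substr(s, from + 1L, to)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
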