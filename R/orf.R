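# Reading-frame operations: stop stripping, in-frame tag fusion, translation.

#' Stop codons (standard genetic code)
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

# codons of a frame-0 sequence (trailing partial codon dropped)
codons_of <- function(seq, start = 0L) {
  n <- nchar(seq)
  k <- (n - start) %/% 3L
  if (k <= 0L) return(character())
  at <- start + 3L * (seq_len(k) - 1L)
  substring(seq, at + 1L, at + 3L)
}

#' Epitope-tag specification
#'
#' A tag is a coding sequence (length divisible by 3, no internal in-frame
#' stop) plus a default stop codon appended on fusion. Two V5 variants ship
#' with the package:
#' \describe{
#'   \item{`V5_methods`}{`GGTAAGCCTATCCCTAACCCTCTCCTCGGTCTCGATTCTAGC`
#'     (peptide GKPIPNPLLGLDSS), the 42-mer printed in the vendor-derived
#'     screening protocol; default stop `TAA`.}
#'   \item{`V5_canonical`}{`GGTAAGCCTATCCCTAACCCTCTCCTCGGTCTCGATTCTACG`
#'     (peptide GKPIPNPLLGLDST, the canonical V5 epitope); default stop
#'     `TGA`, which together with the terminal `ACG` forms the BsaAI
#'     recognition site `TACGTG` used for digest diagnostics.}
#' }
#' Both variants share the 5' end `GGTAAGCCT`, so junction splice-donor
#' behaviour is identical.
#'
#' @param name built-in tag name (`"V5_methods"`, `"V5_canonical"`), or any
#'   name when `coding` is supplied.
#' @param coding tag coding sequence; may be `""` for a bare stop "tag".
#' @param stop default stop codon (one of `TAA`, `TAG`, `TGA`).
#' @return a `tag_spec` list with fields `name`, `coding`, `default_stop`.
#' @export
tag_spec <- function(name, coding = NULL, stop = NULL) {
  builtin <- list(
    V5_methods = list(coding = "GGTAAGCCTATCCCTAACCCTCTCCTCGGTCTCGATTCTAGC",
                      stop = "TAA"),
    V5_canonical = list(coding = "GGTAAGCCTATCCCTAACCCTCTCCTCGGTCTCGATTCTACG",
                        stop = "TGA"))
  if (is.null(coding)) {
    if (!name %in% names(builtin)) {
      stop("unknown built-in tag '", name, "'; supply `coding`")
    }
    coding <- builtin[[name]]$coding
    if (is.null(stop)) stop <- builtin[[name]]$stop
  }
  if (is.null(stop)) stop <- "TAA"
  if (nzchar(coding)) coding <- as_dna(coding)
  if (nchar(coding) %% 3L != 0L) stop("tag coding length not divisible by 3")
  if (any(codons_of(coding) %in% STOP_CODONS)) {
    stop("tag coding sequence contains an internal stop codon")
  }
  if (!stop %in% STOP_CODONS) stop("tag stop must be one of TAA, TAG, TGA")
  structure(list(name = name, coding = coding, default_stop = stop),
            class = "tag_spec")
}

#' Read tag specifications from TSV
#'
#' Columns: `name`, `coding`, `stop`.
#'
#' @param path path to a TSV file.
#' @return named list of `tag_spec`s.
#' @export
read_tag_spec <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("name", "coding", "stop") %in% names(tab))) {
    stop("tag spec needs columns name, coding, stop")
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    tag_spec(tab$name[i], tab$coding[i], tab$stop[i])
  })
  setNames(out, tab$name)
}

#' Remove the terminal stop codon from a CDS
#'
#' @param cds CDS sequence: length divisible by 3, ending in a stop codon,
#'   with no internal in-frame stop.
#' @return `cds` minus its final 3 nucleotides.
#' @export
strip_stop <- function(cds) {
  cds <- as_dna(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  cod <- codons_of(cds)
  k <- length(cod)
  if (!cod[k] %in% STOP_CODONS) {
    stop("no terminal stop codon (found '", cod[k], "' at codon index ",
         k - 1L, ")")
  }
  internal <- which(cod[-k] %in% STOP_CODONS)
  if (length(internal)) {
    stop("internal stop codon at codon index ", internal[1L] - 1L)
  }
  substr(cds, 1L, nchar(cds) - 3L)
}

#' Fuse an epitope tag in frame to a stop-stripped CDS
#'
#' The fused CDS is `cds_nostop + tag$coding + tag$default_stop`, followed by
#' `linker` (as trailing UTR) when given. The junction window spans the last
#' `exon_nt` CDS nucleotides and the first `tag_nt` downstream nucleotides
#' (default 3 + 7 = 10, matching both the 8-mer donor definition and 10-mer
#' junction search strings).
#'
#' @param cds_nostop stop-stripped CDS (length divisible by 3).
#' @param tag a [tag_spec()].
#' @param linker optional linker/UTR sequence appended after the stop.
#' @param exon_nt,tag_nt junction-window geometry.
#' @return a `fusion` list: `fused_cds`, `junction_offset` (0-based offset of
#'   the first tag nucleotide), `window`.
#' @export
fuse_tag <- function(cds_nostop, tag, linker = "", exon_nt = 3L, tag_nt = 7L) {
  cds_nostop <- as_dna(cds_nostop)
  stopifnot(inherits(tag, "tag_spec"))
  if (nchar(cds_nostop) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (nzchar(linker)) linker <- as_dna(linker)
  downstream <- paste0(tag$coding, tag$default_stop, linker)
  fused <- paste0(cds_nostop, downstream)
  j <- nchar(cds_nostop)
  window <- paste0(subseq0(cds_nostop, max(0L, j - exon_nt), j),
                   substr(downstream, 1L, tag_nt))
  structure(list(fused_cds = fused, junction_offset = j, window = window,
                 tag = tag$name),
            class = "fusion")
}

#' @export
print.fusion <- function(x, ...) {
  cat("<fusion> tag ", x$tag, ", ", nchar(x$fused_cds),
      " nt, junction at ", x$junction_offset,
      " (1-based ", x$junction_offset + 1L, "), window ", x$window,
      "\n", sep = "")
  invisible(x)
}

#' Translate from an offset to the first in-frame stop
#'
#' Standard genetic code only. Translation runs from `start` to the first
#' in-frame stop codon (excluded). If no stop is reached, `stopped` is
#' `FALSE` and any trailing partial codon is ignored. `N` within the
#' translated span is an error.
#'
#' @param seq DNA sequence.
#' @param start 0-based offset of the first codon.
#' @return list with `protein` (single-letter amino acids) and `stopped`.
#' @export
translate_cds <- function(seq, start = 0L) {
  seq <- as_dna(seq)
  start <- as.integer(start)
  if (start < 0L || start >= nchar(seq)) stop("start out of range")
  cod <- codons_of(seq, start)
  hit <- which(cod %in% STOP_CODONS)
  stopped <- length(hit) > 0L
  span <- if (stopped) cod[seq_len(hit[1L] - 1L)] else cod
  if (any(grepl("N", span, fixed = TRUE))) {
    stop("N within translated span")
  }
  code <- Biostrings::GENETIC_CODE
  protein <- if (length(span)) paste(code[span], collapse = "") else ""
  list(protein = protein, stopped = stopped)
}
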