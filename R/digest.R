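# Restriction-digest prediction for mis-splicing diagnostics.
#
# A recognition site present only in the excisable region (e.g. the BsaAI
# site associated with the V5 tag) turns a restriction digest of an RT-PCR
# product into a splice diagnostic: the correctly spliced product cuts, the
# tag-deleted mis-spliced product is resistant.

#' Restriction recognition site
#'
#' Built-ins:
#' \describe{
#'   \item{`BsaAI_paper`}{`TACGTG`, the literal site printed for the V5
#'     digest assay.}
#'   \item{`BsaAI_iupac`}{`YACGTR`, the enzyme's accepted degenerate site.}
#' }
#' Both cut blunt at the midpoint (`cut_offset = 3`).
#'
#' @param name built-in name, or any name when `pattern` is supplied.
#' @param pattern IUPAC recognition pattern.
#' @param cut_offset nucleotides from pattern start to the cleavage point;
#'   defaults to the pattern midpoint (blunt cutter).
#' @return a `recognition_site` list.
#' @export
restriction_site <- function(name, pattern = NULL, cut_offset = NULL) {
  builtin <- list(BsaAI_paper = list(pattern = "TACGTG", cut_offset = 3L),
                  BsaAI_iupac = list(pattern = "YACGTR", cut_offset = 3L))
  if (is.null(pattern)) {
    if (!name %in% names(builtin)) {
      stop("unknown built-in enzyme '", name, "'; supply `pattern`")
    }
    pattern <- builtin[[name]]$pattern
    if (is.null(cut_offset)) cut_offset <- builtin[[name]]$cut_offset
  }
  pattern <- toupper(pattern)
  if (grepl("[^ACGTRYSWKMBDHVN]", pattern)) {
    stop("pattern must be over the IUPAC nucleotide alphabet")
  }
  if (is.null(cut_offset)) cut_offset <- nchar(pattern) %/% 2L
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(pattern)) {
    stop("cut_offset must lie within [0, pattern length]")
  }
  structure(list(name = name, pattern = pattern, cut_offset = cut_offset),
            class = "recognition_site")
}

#' Read enzyme definitions from TSV
#'
#' Columns: `name`, `pattern`, `cut_offset`.
#'
#' @param path path to a TSV file.
#' @return named list of `recognition_site`s.
#' @export
read_enzyme_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern", "cut_offset") %in% names(tab))) {
    stop("enzyme table needs columns name, pattern, cut_offset")
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    restriction_site(tab$name[i], tab$pattern[i], tab$cut_offset[i])
  })
  setNames(out, tab$name)
}

#' Find recognition-site matches on the sense strand
#'
#' IUPAC codes in the pattern are expanded; ambiguity codes in the subject
#' are not (an `N` in the sequence never satisfies a pattern letter).
#' Overlapping matches are all reported.
#'
#' @param seq DNA sequence.
#' @param site a [restriction_site()].
#' @return sorted integer vector of 0-based match start offsets.
#' @export
find_sites <- function(seq, site) {
  seq <- as_dna(seq)
  stopifnot(inherits(site, "recognition_site"))
  if (nchar(seq) < nchar(site$pattern)) return(integer())
  m <- Biostrings::matchPattern(site$pattern, Biostrings::DNAString(seq),
                                fixed = "subject")
  sort(as.integer(start(m)) - 1L)
}

#' Digest a linear sequence
#'
#' Cleaves at every recognition site's cut point (cut points falling on the
#' molecule ends are no-ops) and returns fragments in 5' to 3' order.
#'
#' @param seq DNA sequence.
#' @param site a [restriction_site()].
#' @return a `digest` list: `enzyme`, `cut_positions` (sorted, 0-based,
#'   strictly inside the molecule), `fragment_lengths` (5' to 3'; sums to
#'   the input length).
#' @export
digest_linear <- function(seq, site) {
  seq <- as_dna(seq)
  n <- nchar(seq)
  cuts <- find_sites(seq, site) + site$cut_offset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  structure(list(enzyme = site$name, cut_positions = cuts,
                 fragment_lengths = diff(c(0L, cuts, n))),
            class = "digest")
}

#' @export
print.digest <- function(x, ...) {
  cat("<digest> ", x$enzyme, ": ", length(x$cut_positions), " cut(s), ",
      "fragments ", paste(x$fragment_lengths, collapse = " + "),
      " nt\n", sep = "")
  invisible(x)
}

#' Text rendering of digest fragments ("virtual gel")
#'
#' Fragment sizes sorted descending, one lane per digest.
#'
#' @param ... `digest` objects (named arguments become lane labels).
#' @return character vector of gel lines.
#' @export
virtual_gel <- function(...) {
  lanes <- list(...)
  labels <- names(lanes)
  if (is.null(labels)) labels <- rep("", length(lanes))
  labels[!nzchar(labels)] <- paste0("lane", which(!nzchar(labels)))
  unlist(lapply(seq_along(lanes), function(i) {
    sizes <- sort(lanes[[i]]$fragment_lengths, decreasing = TRUE)
    c(sprintf("%-12s %s", labels[i],
              paste(sprintf("%5d bp", sizes), collapse = "  ")))
  }))
}
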