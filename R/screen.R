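# Library-wide tag-fusion junction screen.
#
# For every CDS in a library (e.g. a CCDS-style multi-FASTA), strip the stop
# codon, fuse the tag in frame, and ask whether the fusion junction creates
# a splice donor. Two classification modes ship because the source protocol
# is ambiguous about how many CDS-contributed nucleotides the search strings
# used:
#
#   "methods-10mer" (default): exact 10-mer search, CONSENSUS_JUNCTION iff
#     the junction 10-mer is AGGTAAGCCT and DUX4_LIKE_JUNCTION iff it is
#     TGGTAAGCCT. With a V5-type tag this depends only on the final CDS
#     nucleotide (A -> consensus, T -> DUX4-like).
#
#   "minimal-8mer": the donor 8-mer is classified with classify_window();
#     CONSENSUS_JUNCTION iff the terminal CDS dinucleotide is AA or CA
#     ((A/C)AGGTAAG), DUX4_LIKE_JUNCTION iff it is TT (the literal
#     TTGGTAAG site).

SCREEN_MODES <- c("methods-10mer", "minimal-8mer")

screen_klass <- function(dinuc, tag, mode) {
  tag6 <- substr(tag$coding, 1L, 6L)
  last1 <- substr(dinuc, 2L, 2L)
  if (mode == "methods-10mer") {
    junction10 <- paste0(last1, substr(tag$coding, 1L, 9L))
    if (junction10 == "AGGTAAGCCT") return("CONSENSUS_JUNCTION")
    if (junction10 == "TGGTAAGCCT") return("DUX4_LIKE_JUNCTION")
    return("NONE")
  }
  w8 <- paste0(dinuc, tag6)
  tier <- classify_window(w8)
  if (!is.na(tier) && tier == "CONSENSUS") return("CONSENSUS_JUNCTION")
  if (!is.na(tier) && tier == "GGTAAG_CLASS" && dinuc == "TT") {
    return("DUX4_LIKE_JUNCTION")
  }
  "NONE"
}

#' Classify a single tag-fusion junction
#'
#' @param cds a CDS (with its stop codon). Invalid CDSs (non-ACGT
#'   characters, length not a codon multiple, no terminal stop, internal
#'   stop) are returned with a `skipped_reason` instead of a class.
#' @param tag a [tag_spec()]; a warning is issued if its coding sequence
#'   does not begin `GGTAAGCCT`, since the 10-mer search strings assume the
#'   V5 5' end.
#' @param mode `"methods-10mer"` (default) or `"minimal-8mer"`.
#' @param id transcript id for the record.
#' @return one-row data frame: `transcript_id`, `terminal_dinucleotide`,
#'   `junction10`, `klass`, `skipped_reason`.
#' @export
classify_junction <- function(cds, tag = tag_spec("V5_methods"),
                              mode = c("methods-10mer", "minimal-8mer"),
                              id = "cds") {
  mode <- match.arg(mode)
  stopifnot(inherits(tag, "tag_spec"))
  if (mode == "methods-10mer" && !startsWith(tag$coding, "GGTAAGCCT")) {
    warning("tag coding does not begin GGTAAGCCT; 10-mer search strings ",
            "assume the V5 5' end")
  }
  rec <- function(dinuc, j10, klass, skip) {
    data.frame(transcript_id = id, terminal_dinucleotide = dinuc,
               junction10 = j10, klass = klass, skipped_reason = skip,
               stringsAsFactors = FALSE)
  }
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    return(rec(NA, NA, NA, "non_acgt"))
  }
  if (nchar(cds) %% 3L != 0L || nchar(cds) < 6L) {
    return(rec(NA, NA, NA, "length_not_codon_multiple"))
  }
  cod <- codons_of(cds)
  k <- length(cod)
  if (!cod[k] %in% STOP_CODONS) {
    return(rec(NA, NA, NA, "no_terminal_stop"))
  }
  if (any(cod[-k] %in% STOP_CODONS)) {
    return(rec(NA, NA, NA, "internal_stop"))
  }
  stripped <- substr(cds, 1L, nchar(cds) - 3L)
  dinuc <- substr(stripped, nchar(stripped) - 1L, nchar(stripped))
  j10 <- paste0(substr(dinuc, 2L, 2L), substr(tag$coding, 1L, 9L))
  rec(dinuc, j10, screen_klass(dinuc, tag, mode), NA_character_)
}

#' Run the tag-fusion junction screen on a CDS library
#'
#' @param cds a multi-FASTA path or a named character vector of CDSs.
#' @param tag a [tag_spec()].
#' @param mode see [classify_junction()].
#' @return list with `records` (one row per input CDS, in input order) and
#'   `summary` (a `screen_summary`: totals, per-class counts and fractions
#'   over the screened records).
#' @export
run_screen <- function(cds, tag = tag_spec("V5_methods"),
                       mode = c("methods-10mer", "minimal-8mer")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tag, "tag_spec"))
  if (is.character(cds) && length(cds) == 1L && file.exists(cds) &&
      is.null(names(cds))) {
    cds <- read_fasta(cds)
  }
  if (length(cds) == 0L) stop("empty CDS input")
  if (is.null(names(cds))) names(cds) <- sprintf("cds_%d", seq_along(cds))
  if (mode == "methods-10mer" && !startsWith(tag$coding, "GGTAAGCCT")) {
    warning("tag coding does not begin GGTAAGCCT; 10-mer search strings ",
            "assume the V5 5' end")
  }

  # vectorized screen (classify_junction is its per-record twin)
  s <- toupper(unname(cds))
  n <- nchar(s)
  skip <- rep(NA_character_, length(s))
  skip[grepl("[^ACGT]", s)] <- "non_acgt"
  bad_len <- is.na(skip) & (n %% 3L != 0L | n < 6L)
  skip[bad_len] <- "length_not_codon_multiple"
  ok <- is.na(skip)
  last_cod <- substring(s, n - 2L, n)
  no_stop <- ok & !last_cod %in% STOP_CODONS
  skip[no_stop] <- "no_terminal_stop"
  ok <- is.na(skip)
  internal <- vapply(which(ok), function(i) {
    cod <- codons_of(s[i])
    any(cod[-length(cod)] %in% STOP_CODONS)
  }, NA)
  skip[which(ok)[internal]] <- "internal_stop"
  ok <- is.na(skip)

  dinuc <- rep(NA_character_, length(s))
  dinuc[ok] <- substring(s[ok], n[ok] - 4L, n[ok] - 3L)
  j10 <- rep(NA_character_, length(s))
  j10[ok] <- paste0(substring(dinuc[ok], 2L, 2L),
                    substr(tag$coding, 1L, 9L))
  klass <- rep(NA_character_, length(s))
  klass[ok] <- vapply(dinuc[ok], screen_klass, "", tag = tag, mode = mode,
                      USE.NAMES = FALSE)

  records <- data.frame(transcript_id = names(cds),
                        terminal_dinucleotide = dinuc,
                        junction10 = j10, klass = klass,
                        skipped_reason = skip, stringsAsFactors = FALSE)

  classes <- c("CONSENSUS_JUNCTION", "DUX4_LIKE_JUNCTION", "NONE")
  counts <- setNames(vapply(classes, function(k) sum(klass == k, na.rm = TRUE),
                            0L), classes)
  n_screened <- sum(ok)
  summary <- structure(list(
    mode = mode, tag = tag$name,
    n_total = length(s), n_screened = n_screened,
    n_skipped = length(s) - n_screened,
    counts = counts,
    fractions = if (n_screened > 0L) counts / n_screened else counts * NA_real_),
    class = "screen_summary")
  list(records = records, summary = summary)
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary> mode ", x$mode, ", tag ", x$tag, "\n",
      "  screened ", x$n_screened, " of ", x$n_total,
      " (", x$n_skipped, " skipped)\n", sep = "")
  for (k in names(x$counts)) {
    cat(sprintf("  %-20s %8d  (%.2f%%)\n", k, x$counts[[k]],
                100 * x$fractions[[k]]))
  }
  invisible(x)
}

#' Write screen outputs
#'
#' Writes the per-record table and a summary (TSV and JSON).
#'
#' @param screen result of [run_screen()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(screen$records, file.path(dir, "records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- screen$summary
  tab <- data.frame(klass = names(s$counts), count = as.integer(s$counts),
                    fraction = as.numeric(s$fractions))
  write.table(tab, file.path(dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mode = s$mode, tag = s$tag, n_total = s$n_total,
                            n_screened = s$n_screened,
                            n_skipped = s$n_skipped,
                            counts = as.list(s$counts),
                            fractions = as.list(s$fractions)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
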