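# Tiered splice-donor detection.
#
# The donor model is exact tiered pattern matching on the 8-mer window
# [cut-3, cut+5) around the exon|intron boundary (`cut` = 0-based offset of
# the first intronic nucleotide, the G of GT):
#
#   CONSENSUS     (A/C)AGGTAAG   minimal consensus donor
#   GGTAAG_CLASS  NNGGTAAG       e.g. the TTGGTAAG site created by a
#                                CDS...CTT + V5 fusion
#   MINIMAL       NNNGTAAG
#   CORE          NNNGT          bare GT; reported only on request
#
# Tiers are nested by pattern containment. An N in the sequence never
# satisfies a constrained pattern position.

#' Donor tiers, weakest to strongest
#' @export
DONOR_TIERS <- c("CORE", "MINIMAL", "GGTAAG_CLASS", "CONSENSUS")

tier_rank <- function(tier) {
  r <- match(tier, DONOR_TIERS)
  r[is.na(tier)] <- 0L
  r
}

#' Classify an 8-mer splice-donor window
#'
#' Vectorized. Returns the strongest tier matched by each window, or `NA`
#' for windows with no GT at the intron positions (offsets 3-4 within the
#' window, 0-based).
#'
#' @param w character vector of 8-mers over `ACGTN`.
#' @return character vector over [DONOR_TIERS] with `NA` for non-donors.
#' @examples
#' classify_window(c("CAGGTAAG", "TTGGTAAG", "AAGCTAAG"))
#' @export
classify_window <- function(w) {
  if (any(nchar(w) != 8L)) stop("windows must be exactly 8 nt")
  if (any(grepl("[^ACGTN]", w))) stop("windows must be over ACGTN")
  out <- rep(NA_character_, length(w))
  core <- substr(w, 4L, 5L) == "GT"
  minimal <- substr(w, 4L, 8L) == "GTAAG"
  ggtaag <- minimal & substr(w, 3L, 3L) == "G"
  consensus <- ggtaag & substr(w, 2L, 2L) == "A" &
    substr(w, 1L, 1L) %in% c("A", "C")
  out[core] <- "CORE"
  out[minimal] <- "MINIMAL"
  out[ggtaag] <- "GGTAAG_CLASS"
  out[consensus] <- "CONSENSUS"
  out
}

#' Scan a sequence for splice-donor sites
#'
#' Reports every position whose 8-mer window classifies at or above
#' `min_tier`. Windows truncated by the sequence ends never match.
#'
#' @param seq DNA sequence.
#' @param min_tier weakest tier to report (default `"MINIMAL"`; use
#'   `"CORE"` explicitly to flood the report with bare GT dinucleotides).
#' @param region optional 0-based half-open interval `c(start, end)`
#'   restricting reported cut positions.
#' @return data frame of donor sites: `cut` (0-based offset of the G of GT),
#'   `tier`, `context8`, sorted by `cut`.
#' @export
scan_donors <- function(seq, min_tier = "MINIMAL", region = NULL) {
  seq <- as_dna(seq)
  min_tier <- match.arg(min_tier, DONOR_TIERS)
  n <- nchar(seq)
  empty <- data.frame(cut = integer(), tier = character(),
                      context8 = character(), stringsAsFactors = FALSE)
  if (n < 8L) return(empty)
  cuts <- 3L:(n - 5L)
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] <= region[2L])
    cuts <- cuts[cuts >= region[1L] & cuts < region[2L]]
    if (!length(cuts)) return(empty)
  }
  win <- substring(seq, cuts - 2L, cuts + 5L)
  tier <- classify_window(win)
  keep <- tier_rank(tier) >= tier_rank(min_tier)
  data.frame(cut = cuts[keep], tier = tier[keep], context8 = win[keep],
             stringsAsFactors = FALSE)
}

#' Scan for heuristic splice acceptors
#'
#' Reports AG dinucleotides preceded by a pyrimidine-rich tract: at least
#' `min_pyrimidines` C/T within the `window` nucleotides upstream of the AG.
#' This heuristic scanner is a convenience for sequences lacking annotation;
#' construct vetting normally uses annotated acceptors only.
#'
#' @param seq DNA sequence.
#' @param min_pyrimidines minimum C/T count in the upstream window.
#' @param window size (nt) of the upstream tract examined.
#' @return data frame of acceptor sites: `cut` (0-based offset of the first
#'   exonic nucleotide after the AG), `pyrimidines`, `source = "scanned"`.
#' @export
scan_acceptors <- function(seq, min_pyrimidines = 8L, window = 14L) {
  seq <- as_dna(seq)
  n <- nchar(seq)
  empty <- data.frame(cut = integer(), pyrimidines = integer(),
                      source = character(), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  # AG at [i, i+2), cut = i+2, needing at least one exonic nt after
  i <- 0L:(n - 3L)
  is_ag <- substring(seq, i + 1L, i + 2L) == "AG"
  i <- i[is_ag]
  if (!length(i)) return(empty)
  py <- vapply(i, function(k) {
    tract <- subseq0(seq, max(0L, k - window), k)
    sum(strsplit(tract, "")[[1]] %in% c("C", "T"))
  }, 0L)
  keep <- py >= min_pyrimidines
  data.frame(cut = i[keep] + 2L, pyrimidines = py[keep],
             source = rep("scanned", sum(keep)), stringsAsFactors = FALSE)
}

#' Donor report as TSV
#'
#' Writes donor sites with both 0-based and 1-based coordinates and, when a
#' construct is supplied, the overlapping segment label.
#'
#' @param sites data frame from [scan_donors()].
#' @param path output path.
#' @param construct optional `construct` for segment labels.
#' @param name sequence/construct name for the first column.
#' @return the report data frame, invisibly.
#' @export
write_donor_report <- function(sites, path, construct = NULL,
                               name = if (!is.null(construct))
                                 construct$name else "seq") {
  rep <- data.frame(construct = rep(name, nrow(sites)),
                    cut0 = sites$cut, cut1 = sites$cut + 1L,
                    tier = sites$tier, context8 = sites$context8,
                    stringsAsFactors = FALSE)
  rep$segment <- if (!is.null(construct) && nrow(sites)) {
    locate(construct, sites$cut)$label
  } else character(nrow(sites))
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
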