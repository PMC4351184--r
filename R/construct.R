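# Construct model: ordered, role-labelled DNA segments with an assembled
# sequence, a coordinate map, and annotated splice signals.

SEGMENT_ROLES <- c("promoter", "orf", "tag", "linker", "utr", "intron",
                   "exon", "polyA", "itr", "other")

#' Create a construct segment
#'
#' @param label segment label, unique within a construct.
#' @param role one of `"promoter"`, `"orf"`, `"tag"`, `"linker"`, `"utr"`,
#'   `"intron"`, `"exon"`, `"polyA"`, `"itr"`, `"other"`.
#' @param seq segment sequence (normalized via [as_dna()]).
#' @param canonical for introns: assert the GT...AG rule and derive an
#'   annotated donor/acceptor pair at the segment boundaries.
#' @return a `segment` list.
#' @export
segment <- function(label, role, seq, canonical = FALSE) {
  role <- match.arg(role, SEGMENT_ROLES)
  seq <- as_dna(seq)
  if (canonical && role != "intron") {
    stop("only introns can be flagged canonical (segment '", label, "')")
  }
  if (canonical) {
    if (nchar(seq) < 4L || substr(seq, 1L, 2L) != "GT" ||
        substr(seq, nchar(seq) - 1L, nchar(seq)) != "AG") {
      stop("canonical intron '", label, "' must start GT and end AG")
    }
  }
  structure(list(label = label, role = role, seq = seq,
                 canonical = isTRUE(canonical)),
            class = "segment")
}

#' Create a construct
#'
#' A construct is an ordered list of segments plus reading-frame and splice
#' annotations on the assembled sequence. Annotated donors/acceptors are the
#' union of canonical-intron boundaries and any explicitly supplied offsets.
#'
#' @param name construct name.
#' @param segments list of [segment()]s with unique labels.
#' @param orf_start 0-based offset of the first ORF nucleotide in the
#'   assembled sequence; defaults to the start of the first `role = "orf"`
#'   segment.
#' @param intended_stop 0-based offset of the first nucleotide of the
#'   intended stop codon. `(intended_stop - orf_start)` must be divisible
#'   by 3 and the codon at that offset must be a stop codon.
#' @param donors,acceptors optional extra annotated donor/acceptor offsets
#'   (0-based: donors point at the G of a GT; acceptors at the first exonic
#'   nucleotide after an intronic AG).
#' @return a `construct` object.
#' @export
construct <- function(name, segments, orf_start = NULL, intended_stop,
                      donors = integer(), acceptors = integer()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(segments) == 0L) stop("construct needs at least one segment")
  labels <- vapply(segments, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("duplicate segment labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  lens <- vapply(segments, function(s) nchar(s$seq), 0L)
  ends <- cumsum(lens)
  starts <- ends - lens
  map <- data.frame(label = labels,
                    role = vapply(segments, `[[`, "", "role"),
                    start = starts, end = ends,
                    stringsAsFactors = FALSE)
  seq <- paste(vapply(segments, `[[`, "", "seq"), collapse = "")
  total <- nchar(seq)

  if (is.null(orf_start)) {
    i <- which(map$role == "orf")
    if (length(i) == 0L) stop("no 'orf' segment and no explicit orf_start")
    orf_start <- map$start[i[1L]]
  }
  orf_start <- as.integer(orf_start)
  intended_stop <- as.integer(intended_stop)
  if (!(orf_start >= 0L && orf_start < intended_stop &&
        intended_stop + 3L <= total)) {
    stop("require 0 <= orf_start < intended_stop <= length - 3")
  }
  if ((intended_stop - orf_start) %% 3L != 0L) {
    stop("ORF length (orf_start to intended_stop) not divisible by 3")
  }
  if (!subseq0(seq, intended_stop, intended_stop + 3L) %in% STOP_CODONS) {
    stop("no stop codon at intended_stop offset ", intended_stop)
  }

  donors <- as.integer(donors)
  acceptors <- as.integer(acceptors)
  for (s in segments) {
    if (isTRUE(s$canonical)) {
      st <- map$start[match(s$label, map$label)]
      en <- map$end[match(s$label, map$label)]
      donors <- c(donors, st)
      acceptors <- c(acceptors, en)
    }
  }
  donors <- sort(unique(donors))
  acceptors <- sort(unique(acceptors))
  if (any(donors < 0L | donors + 2L > total) ||
      any(acceptors < 2L | acceptors > total)) {
    stop("annotated splice-site offset out of bounds")
  }
  if (length(donors)) {
    bad_d <- donors[substring(seq, donors + 1L, donors + 2L) != "GT"]
    if (length(bad_d)) {
      stop("annotated donor offset(s) not at a GT dinucleotide: ",
           paste(bad_d, collapse = ", "))
    }
  }
  if (length(acceptors)) {
    bad_a <- acceptors[substring(seq, acceptors - 1L, acceptors) != "AG"]
    if (length(bad_a)) {
      stop("annotated acceptor offset(s) not preceded by AG: ",
           paste(bad_a, collapse = ", "))
    }
  }

  structure(list(name = name, segments = segments, seq = seq, map = map,
                 orf_start = orf_start, intended_stop = intended_stop,
                 annotated_donors = donors, annotated_acceptors = acceptors),
            class = "construct")
}

#' Assemble a construct
#'
#' @param x a `construct`.
#' @return list with `seq` (the assembled sequence) and `map` (a data frame
#'   of per-segment 0-based half-open intervals tiling `[0, total)`).
#' @export
assemble <- function(x) {
  stopifnot(inherits(x, "construct"))
  list(seq = x$seq, map = x$map)
}

#' Locate an assembled position in its segment
#'
#' @param x a `construct`.
#' @param pos 0-based position(s) in the assembled sequence.
#' @return data frame with `label` and `offset` (0-based within the segment).
#' @export
locate <- function(x, pos) {
  stopifnot(inherits(x, "construct"))
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= nchar(x$seq))) stop("position out of bounds")
  i <- findInterval(pos, x$map$start)
  data.frame(label = x$map$label[i], offset = pos - x$map$start[i],
             stringsAsFactors = FALSE)
}

#' @export
print.construct <- function(x, ...) {
  cat("<construct> ", x$name, ": ", nchar(x$seq), " nt, ",
      nrow(x$map), " segments\n", sep = "")
  m <- x$map
  m$length <- m$end - m$start
  print(m, row.names = FALSE)
  cat("orf_start: ", x$orf_start,
      "  intended_stop: ", x$intended_stop, "\n", sep = "")
  cat("annotated donors: ", paste(x$annotated_donors, collapse = ", "),
      "\nannotated acceptors: ", paste(x$annotated_acceptors, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

parse_flags <- function(flags) {
  flags[is.na(flags)] <- ""
  lapply(flags, function(f) {
    toks <- trimws(strsplit(f, ",", fixed = TRUE)[[1]])
    toks[nzchar(toks)]
  })
}

#' Read a construct specification (TSV)
#'
#' The spec is a tab-separated file with a header row and columns `label`,
#' `role`, `sequence`, `flags`. `sequence` is either an inline sequence or a
#' FASTA reference of the form `@file.fasta:id` (resolved relative to the
#' spec file). `flags` is a comma-separated list of tokens:
#' \describe{
#'   \item{`canonical`}{intron obeys the GT...AG rule; a donor and acceptor
#'     are derived at its boundaries.}
#'   \item{`stop=K`}{the intended stop codon starts at 0-based offset K
#'     within this segment (required on exactly one segment).}
#'   \item{`orf_start=K`}{the ORF starts at offset K within this segment
#'     (default: start of the first `orf` segment).}
#'   \item{`donor=K` / `acceptor=K`}{extra annotated splice sites at offset
#'     K within this segment.}
#' }
#' A comment line `# construct: NAME` names the construct.
#'
#' @param path path to the spec TSV.
#' @return a `construct`.
#' @export
read_construct_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  name <- "construct"
  nm <- grep("^#\\s*construct:", lines, value = TRUE)
  if (length(nm)) name <- trimws(sub("^#\\s*construct:", "", nm[1L]))
  tab <- read.delim(text = lines, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("label", "role", "sequence", "flags")
  if (!all(need %in% names(tab))) {
    stop("construct spec needs columns: ", paste(need, collapse = ", "))
  }
  bad_role <- setdiff(tab$role, SEGMENT_ROLES)
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))

  flags <- parse_flags(tab$flags)
  segs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sq <- tab$sequence[i]
    if (startsWith(sq, "@")) {
      ref <- strsplit(sub("^@", "", sq), ":", fixed = TRUE)[[1]]
      if (length(ref) != 2L) stop("bad FASTA reference: ", sq)
      fa <- read_fasta(file.path(dirname(path), ref[1L]))
      if (!ref[2L] %in% names(fa)) {
        stop("id '", ref[2L], "' not found in ", ref[1L])
      }
      sq <- fa[[ref[2L]]]
    }
    segs[[i]] <- segment(tab$label[i], tab$role[i], sq,
                         canonical = "canonical" %in% flags[[i]])
  }

  lens <- vapply(segs, function(s) nchar(s$seq), 0L)
  starts <- cumsum(lens) - lens
  flag_val <- function(key) {
    out <- NULL
    for (i in seq_along(flags)) {
      hit <- grep(paste0("^", key, "="), flags[[i]], value = TRUE)
      for (h in hit) {
        out <- rbind(out, c(i, as.integer(sub(paste0("^", key, "="), "", h))))
      }
    }
    out
  }
  sv <- flag_val("stop")
  if (is.null(sv) || nrow(sv) != 1L) {
    stop("construct spec must carry exactly one 'stop=K' flag")
  }
  intended_stop <- starts[sv[1L, 1L]] + sv[1L, 2L]
  ov <- flag_val("orf_start")
  orf_start <- if (is.null(ov)) NULL else starts[ov[1L, 1L]] + ov[1L, 2L]
  dv <- flag_val("donor")
  av <- flag_val("acceptor")
  donors <- if (is.null(dv)) integer() else starts[dv[, 1L]] + dv[, 2L]
  acceptors <- if (is.null(av)) integer() else starts[av[, 1L]] + av[, 2L]

  construct(name, segs, orf_start = orf_start, intended_stop = intended_stop,
            donors = donors, acceptors = acceptors)
}

#' Write a construct specification (TSV)
#'
#' Inverse of [read_construct_spec()] (sequences are inlined).
#'
#' @param x a `construct`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_construct_spec <- function(x, path) {
  stopifnot(inherits(x, "construct"))
  starts <- x$map$start
  ends <- x$map$end
  derived_d <- integer(); derived_a <- integer()
  flags <- character(nrow(x$map))
  for (i in seq_along(x$segments)) {
    f <- character()
    if (isTRUE(x$segments[[i]]$canonical)) {
      f <- "canonical"
      derived_d <- c(derived_d, starts[i])
      derived_a <- c(derived_a, ends[i])
    }
    flags[i] <- paste(f, collapse = ",")
  }
  add_flag <- function(flags, pos, key) {
    i <- findInterval(pos, starts)
    tok <- paste0(key, "=", pos - starts[i])
    flags[i] <- if (nzchar(flags[i])) paste(flags[i], tok, sep = ",") else tok
    flags
  }
  flags <- add_flag(flags, x$intended_stop, "stop")
  default_orf <- {
    j <- which(x$map$role == "orf")
    if (length(j)) starts[j[1L]] else -1L
  }
  if (x$orf_start != default_orf) {
    flags <- add_flag(flags, x$orf_start, "orf_start")
  }
  for (d in setdiff(x$annotated_donors, derived_d)) {
    flags <- add_flag(flags, d, "donor")
  }
  for (a in setdiff(x$annotated_acceptors, derived_a)) {
    flags <- add_flag(flags, a, "acceptor")
  }
  tab <- data.frame(label = x$map$label, role = x$map$role,
                    sequence = vapply(x$segments, `[[`, "", "seq"),
                    flags = flags, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# construct: ", x$name), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Segment intervals as BED
#'
#' 0-based half-open intervals, one per segment, for genome-browser-style
#' inspection of the assembled construct.
#'
#' @param x a `construct`.
#' @param path optional output path; when `NULL` the BED data frame is
#'   returned instead.
#' @return data frame (invisibly when written to `path`).
#' @export
construct_bed <- function(x, path = NULL) {
  stopifnot(inherits(x, "construct"))
  bed <- data.frame(chrom = x$name, chromStart = x$map$start,
                    chromEnd = x$map$end, name = x$map$label,
                    stringsAsFactors = FALSE)
  if (is.null(path)) return(bed)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
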