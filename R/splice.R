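# Splice simulation: apply donor->acceptor events to a construct sequence,
# enumerate all donor/acceptor-consistent isoforms, and classify the protein
# consequence of each isoform relative to the intended fusion protein.

#' Build a table of splice events
#'
#' An event removes the half-open interval `[donor, acceptor)` from the
#' pre-mRNA.
#'
#' @param donor 0-based donor cut(s) (the G of GT, first intronic nt).
#' @param acceptor 0-based acceptor cut(s) (first exonic nt after the AG).
#' @param tier optional donor tier(s), used to soften GT...AG validation for
#'   bare-GT (`CORE`) donors.
#' @return data frame of events sorted by donor.
#' @export
splice_events <- function(donor, acceptor, tier = NA_character_) {
  ev <- data.frame(donor = as.integer(donor), acceptor = as.integer(acceptor),
                   tier = rep_len(as.character(tier), length(donor)),
                   stringsAsFactors = FALSE)
  if (any(ev$donor >= ev$acceptor)) stop("donor cut must precede acceptor cut")
  ev[order(ev$donor), , drop = FALSE]
}

#' Apply splice events to a sequence
#'
#' @param seq pre-mRNA sequence (or a `construct`).
#' @param events data frame from [splice_events()] (or `NULL` for the
#'   unspliced isoform). Events must be pairwise non-overlapping.
#' @return an `isoform`: list with `events`, `mature` (the spliced
#'   sequence), and `provenance` (data frame of retained 0-based half-open
#'   intervals on the input, which concatenate to `mature`).
#' @export
apply_splice <- function(seq, events = NULL) {
  if (inherits(seq, "construct")) seq <- seq$seq
  seq <- as_dna(seq)
  n <- nchar(seq)
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(donor = integer(), acceptor = integer(),
                         tier = character(), stringsAsFactors = FALSE)
  } else {
    events <- events[order(events$donor), , drop = FALSE]
    if (any(events$donor < 0L) || any(events$acceptor > n)) {
      stop("event interval out of bounds")
    }
    if (any(events$donor >= events$acceptor)) {
      stop("donor cut must precede acceptor cut")
    }
    k <- nrow(events)
    if (k > 1L && any(events$donor[-1L] < events$acceptor[-k])) {
      stop("overlapping splice events")
    }
    first2 <- substring(seq, events$donor + 1L, events$donor + 2L)
    last2 <- substring(seq, events$acceptor - 1L, events$acceptor)
    bad <- first2 != "GT" | last2 != "AG"
    if (any(bad)) {
      core <- !is.na(events$tier) & events$tier == "CORE"
      msg <- paste0("removed interval [", events$donor[bad], ",",
                    events$acceptor[bad], ") is not GT...AG",
                    collapse = "; ")
      if (all(core[bad])) warning(msg) else stop(msg)
    }
  }
  starts <- c(0L, events$acceptor)
  ends <- c(events$donor, n)
  keep <- starts < ends
  prov <- data.frame(start = starts[keep], end = ends[keep])
  mature <- paste(substring(seq, prov$start + 1L, prov$end), collapse = "")
  structure(list(events = events, mature = mature, provenance = prov),
            class = "isoform")
}

#' @export
print.isoform <- function(x, ...) {
  cat("<isoform> ", nchar(x$mature), " nt, ", nrow(x$events),
      " splice event(s)\n", sep = "")
  if (nrow(x$events)) {
    cat(paste0("  removed [", x$events$donor, ",", x$events$acceptor, ")",
               ifelse(is.na(x$events$tier), "",
                      paste0(" (", x$events$tier, " donor)")),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

# map a pre-mRNA position onto the mature sequence; NA if spliced out
mature_position <- function(provenance, pos) {
  off <- cumsum(c(0L, provenance$end - provenance$start))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(provenance))) {
    hit <- pos >= provenance$start[i] & pos < provenance$end[i]
    out[hit] <- off[i] + pos[hit] - provenance$start[i]
  }
  out
}

#' Enumerate donor/acceptor-consistent splice isoforms
#'
#' Generates every set of at most `max_events` pairwise-compatible splice
#' events (donor before acceptor, removed intervals non-overlapping, each
#' donor and acceptor used at most once), always including the unspliced
#' isoform, deduplicated by mature sequence. The enumeration over-reports by
#' design: no splice-strength model decides which donor a cell would prefer,
#' so isoforms are ranked deterministically by event count, then by leftmost
#' removed interval.
#'
#' @param x a `construct` or a plain sequence.
#' @param donors donor sites: data frame from [scan_donors()] or integer cut
#'   offsets. Default: scan `x` at tier `MINIMAL`.
#' @param acceptors acceptor cut offsets (integer vector or data frame with
#'   a `cut` column). Default: the construct's annotated acceptors.
#' @param max_events maximum events per isoform.
#' @param cap hard cap on the number of enumerated isoforms; exceeding it is
#'   an error, never silent truncation.
#' @return list of `isoform`s.
#' @export
enumerate_isoforms <- function(x, donors = NULL, acceptors = NULL,
                               max_events = 3L, cap = 10000L) {
  seq <- if (inherits(x, "construct")) x$seq else as_dna(x)
  if (is.null(donors)) donors <- scan_donors(seq, "MINIMAL")
  if (is.null(acceptors)) {
    if (!inherits(x, "construct")) {
      stop("acceptors required when x is not a construct")
    }
    acceptors <- x$annotated_acceptors
  }
  if (is.data.frame(donors)) {
    d_cut <- as.integer(donors$cut)
    d_tier <- as.character(donors$tier)
  } else {
    d_cut <- as.integer(donors)
    d_tier <- rep(NA_character_, length(d_cut))
  }
  a_cut <- if (is.data.frame(acceptors)) as.integer(acceptors$cut)
           else as.integer(acceptors)

  pairs <- expand.grid(di = seq_along(d_cut), ai = seq_along(a_cut))
  if (nrow(pairs)) {
    pairs <- pairs[d_cut[pairs$di] < a_cut[pairs$ai], , drop = FALSE]
    pairs <- pairs[order(d_cut[pairs$di], a_cut[pairs$ai]), , drop = FALSE]
  }
  pd <- d_cut[pairs$di]; pa <- a_cut[pairs$ai]; pt <- d_tier[pairs$di]
  np <- nrow(pairs)

  sets <- list(integer())
  count <- 1L
  dfs <- function(chosen, max_a, from) {
    if (length(chosen) >= max_events) return()
    for (i in seq_len(np)[seq_len(np) >= from]) {
      if (pd[i] < max_a) next
      count <<- count + 1L
      if (count > cap) {
        stop("isoform enumeration exceeded cap of ", cap,
             "; raise `cap` or restrict donors/acceptors")
      }
      sets[[count]] <<- c(chosen, i)
      dfs(c(chosen, i), max(max_a, pa[i]), i + 1L)
    }
  }
  if (np > 0L) dfs(integer(), -1L, 1L)

  isoforms <- lapply(sets, function(idx) {
    ev <- if (length(idx)) {
      splice_events(pd[idx], pa[idx], pt[idx])
    } else NULL
    apply_splice(seq, ev)
  })

  nev <- vapply(isoforms, function(iso) nrow(iso$events), 0L)
  key <- vapply(isoforms, function(iso) {
    if (nrow(iso$events) == 0L) return("")
    paste(sprintf("%012d", iso$events$donor), collapse = ",")
  }, "")
  ord <- order(nev, key)
  isoforms <- isoforms[ord]
  mat <- vapply(isoforms, `[[`, "", "mature")
  isoforms[!duplicated(mat)]
}

#' Classify the protein consequence of an isoform
#'
#' Translates the mature mRNA from the (mapped) ORF start and compares the
#' result to the intended fusion protein, i.e. the translation of the
#' isoform carrying exactly the construct's annotated intron events.
#'
#' Classes:
#' \describe{
#'   \item{`INTENDED`}{mature sequence identical to the intended isoform.}
#'   \item{`UTR_ONLY`}{protein identical, mature sequence differs only
#'     downstream of the stop codon (e.g. a splice within the 3' UTR).}
#'   \item{`TAG_LOST_EXTENDED`}{the native ORF (tag excluded) is intact, the
#'     tag peptide is absent, and a missense extension is appended -- the
#'     tag-excision mis-splicing signature.}
#'   \item{`EXTENDED`}{the full intended protein (tag included) plus an
#'     appended extension.}
#'   \item{`TRUNCATED`}{the protein diverges from or stops short of the
#'     intended protein.}
#'   \item{`NO_STOP`}{translation runs off the end of the mature mRNA.}
#'   \item{`ORF_START_LOST`}{the ORF start itself was spliced out (reported
#'     distinctly; nothing is translated).}
#' }
#'
#' @param isoform an `isoform` from [apply_splice()]/[enumerate_isoforms()].
#' @param construct the `construct` the isoform derives from.
#' @param tag the [tag_spec()] fused into the construct's ORF.
#' @return a `protein_consequence` list: `klass`, `native_retained`,
#'   `appended_missense`, `total_length`, `tag_retained`, `protein`.
#' @export
call_consequence <- function(isoform, construct, tag) {
  stopifnot(inherits(isoform, "isoform"), inherits(construct, "construct"),
            inherits(tag, "tag_spec"))
  intended_ev <- if (length(construct$annotated_donors)) {
    splice_events(construct$annotated_donors, construct$annotated_acceptors)
  } else NULL
  intended <- apply_splice(construct$seq, intended_ev)
  orf_i <- mature_position(intended$provenance, construct$orf_start)
  intended_tr <- translate_cds(intended$mature, orf_i)
  intended_prot <- intended_tr$protein
  tag_pep <- if (nzchar(tag$coding)) translate_cds(
    paste0(tag$coding, tag$default_stop))$protein else ""
  native_prefix <- if (nzchar(tag_pep) && endsWith(intended_prot, tag_pep)) {
    substr(intended_prot, 1L, nchar(intended_prot) - nchar(tag_pep))
  } else {
    intended_prot
  }

  out <- function(klass, native, appended, total, tag_ret, protein) {
    structure(list(klass = klass, native_retained = native,
                   appended_missense = appended, total_length = total,
                   tag_retained = tag_ret, protein = protein),
              class = "protein_consequence")
  }

  orf_m <- mature_position(isoform$provenance, construct$orf_start)
  if (is.na(orf_m)) {
    return(out("ORF_START_LOST", 0L, 0L, 0L, FALSE, ""))
  }
  tr <- translate_cds(isoform$mature, orf_m)
  prot <- tr$protein
  total <- nchar(prot)
  tag_ret <- !nzchar(tag_pep) || grepl(tag_pep, prot, fixed = TRUE)
  lcp <- function(a, b) {
    k <- min(nchar(a), nchar(b))
    i <- 0L
    while (i < k && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L)) {
      i <- i + 1L
    }
    i
  }

  if (!tr$stopped) {
    nat <- lcp(prot, intended_prot)
    return(out("NO_STOP", nat, total - nat, total, tag_ret, prot))
  }
  if (prot == intended_prot) {
    klass <- if (isoform$mature == intended$mature) "INTENDED" else "UTR_ONLY"
    return(out(klass, nchar(native_prefix), 0L, total, tag_ret, prot))
  }
  if (startsWith(prot, intended_prot)) {
    return(out("EXTENDED", nchar(intended_prot), total - nchar(intended_prot),
               total, tag_ret, prot))
  }
  if (startsWith(prot, native_prefix) && !tag_ret &&
      total > nchar(native_prefix)) {
    return(out("TAG_LOST_EXTENDED", nchar(native_prefix),
               total - nchar(native_prefix), total, FALSE, prot))
  }
  nat <- lcp(prot, intended_prot)
  out("TRUNCATED", nat, total - nat, total, tag_ret, prot)
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence> ", x$klass, ": ", x$total_length,
      " aa total (", x$native_retained, " native + ", x$appended_missense,
      " missense), tag ", if (x$tag_retained) "retained" else "lost",
      "\n", sep = "")
  invisible(x)
}
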