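# Internal: logical vector over the codon parse of one sequence at a given
# offset; TRUE where the codon is a sense codon in both aligned frames.
.ambig_ok <- function(seq, frame_offset) {
  s <- substring(seq, frame_offset + 1L)
  n3 <- (nchar(s) %/% 3L) * 3L
  if (n3 < 3L) return(logical(0))
  cods <- substring(s, seq(1L, n3 - 2L, 3L), seq(3L, n3, 3L))
  ok <- grepl("^[ACGU]{3}$", cods)
  tb <- .code()
  ok[ok] <- tb$translate[cods[ok]] != "STOP" &
    tb$comp_translate[cods[ok]] != "STOP"
  ok
}

#' Ambigrammatic spans of a sequence in one frame
#'
#' Parses a sequence into codons from a given frame offset and reports the
#' maximal runs of codons that are sense codons in both the forward frame
#' and the codon-aligned reverse-complement frame (no stop in either
#' direction).  Codons containing gaps or ambiguity codes break a run.
#'
#' @param seq a single nucleotide string (DNA or RNA).
#' @param frame_offset integer 0-2.
#' @return data frame ordered by decreasing span length: `start`, `end`
#'   (1-based nucleotide coordinates, inclusive), `n_codons`,
#'   `span_length`, `ambig_fraction` (= span_length / sequence length).
#' @export
ambig_spans <- function(seq, frame_offset = 0L) {
  seq <- as_rna(seq)
  stopifnot(length(seq) == 1L, nchar(seq) >= 3L)
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset >= 0L, frame_offset <= 2L)
  ok <- .ambig_ok(seq, frame_offset)
  out <- data.frame(start = integer(0), end = integer(0),
                    n_codons = integer(0), span_length = integer(0),
                    ambig_fraction = numeric(0))
  if (length(ok) && any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    out <- data.frame(
      start = frame_offset + 3L * (starts[keep] - 1L) + 1L,
      end = frame_offset + 3L * ends[keep],
      n_codons = r$lengths[keep])
    out$span_length <- out$end - out$start + 1L
    out$ambig_fraction <- out$span_length / nchar(seq)
    out <- out[order(-out$span_length, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Internal: strict reverse complement of whole sequences.
.revcomp_seq <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan sequences for ambigrammatic regions
#'
#' For each record, all three frame offsets and both input orientations are
#' parsed and the largest stop-free span in both aligned frames is taken as
#' the record's best span.  Records whose best span passes the length and
#' fraction thresholds are reported.  Coordinates are always given on the
#' input (forward) strand; ties between orientations prefer `+`.
#'
#' @param x FASTA file path, `Biostrings::XStringSet`, or (named) character
#'   vector of sequences.
#' @param min_len minimum span length in nucleotides (default 200).
#' @param min_frac minimum `span_length / sequence length` (default 0.90).
#' @return BED-like data frame: `id`, `start`, `end`, `strand`, `frame`,
#'   `span_length`, `ambig_fraction`.  Zero rows when nothing passes.
#' @export
scan_ambigrams <- function(x, min_len = 200L, min_frac = 0.90) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readBStringSet(x)
  }
  if (inherits(x, "XStringSet")) {
    x <- structure(as.character(x), names = names(x))
  }
  seqs <- as_rna(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  hits <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    L <- nchar(s)
    if (L < 3L) return(NULL)
    best <- NULL
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else .revcomp_seq(s)
      for (off in 0:2) {
        sp <- ambig_spans(ss, off)
        if (nrow(sp) == 0L) next
        top <- sp[1L, ]
        if (is.null(best) || top$span_length > best$span_length) {
          best <- cbind(top, strand = strand, frame = off)
        }
      }
    }
    if (is.null(best)) return(NULL)
    if (best$strand == "-") {         # map back to forward coordinates
      st <- L - best$end + 1L
      en <- L - best$start + 1L
      best$start <- st; best$end <- en
    }
    data.frame(id = names(seqs)[i], start = best$start, end = best$end,
               strand = best$strand, frame = best$frame,
               span_length = best$span_length,
               ambig_fraction = best$ambig_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), span_length = integer(0),
                      ambig_fraction = numeric(0))
  }
  out <- out[out$span_length >= min_len & out$ambig_fraction >= min_frac, ,
             drop = FALSE]
  rownames(out) <- NULL
  # self-check: every reported span must be stop-free in both aligned frames
  for (i in seq_len(nrow(out))) {
    s <- seqs[[out$id[i]]]
    sub <- substr(s, out$start[i], out$end[i])
    if (out$strand[i] == "-") sub <- .revcomp_seq(sub)
    cods <- substring(sub, seq(1L, nchar(sub) - 2L, 3L),
                      seq(3L, nchar(sub), 3L))
    tb <- .code()
    stopifnot(all(tb$translate[cods] != "STOP"),
              all(tb$comp_translate[cods] != "STOP"))
  }
  out
}
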