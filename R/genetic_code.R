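# Internal cache for code tables, built on first use.
.ambi <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE
.build_code_tables <- function() {
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  gc1 <- Biostrings::GENETIC_CODE            # standard code, DNA-keyed
  names(gc1) <- chartr("T", "U", names(gc1))
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
           "*" = "STOP")
  codons <- names(gc1)
  translate <- unname(aa3[gc1])
  names(translate) <- codons

  # aligned-frame reverse complement of every codon
  rc <- vapply(codons, function(cd) {
    paste(rev(comp[strsplit(cd, "")[[1]]]), collapse = "")
  }, character(1))

  # the 9 single-nucleotide neighbors of each codon, with substitution class
  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "U") | (a == "U" & b == "C")
  }
  nb <- lapply(codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    out <- character(0); cls <- character(0); pos <- integer(0)
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        mut <- ch
        mut[p] <- b
        out <- c(out, paste(mut, collapse = ""))
        cls <- c(cls, if (is_transition(ch[p], b)) "transition" else "transversion")
        pos <- c(pos, p)
      }
    }
    data.frame(codon = out, class = cls, position = pos,
               stringsAsFactors = FALSE)
  })
  names(nb) <- codons

  .ambi$bases <- bases
  .ambi$comp <- comp
  .ambi$codons <- codons
  .ambi$translate <- translate
  .ambi$rc <- rc
  .ambi$comp_translate <- translate[rc]        # aa coded by aligned revcomp
  names(.ambi$comp_translate) <- codons
  .ambi$neighbors <- nb

  # Per-codon synonym profile: single and double synonymous single-nucleotide
  # mutations, split transition/transversion.  Synonyms leading to a codon
  # whose aligned reverse complement is a stop are excluded (they cannot occur
  # in an ambigrammatic gene); mutations to a forward stop are never
  # synonymous.  Valid only for codons that are non-stop in both frames.
  prof <- do.call(rbind, lapply(codons, function(cd) {
    n <- nb[[cd]]
    aa <- translate[cd]
    caa <- .ambi$comp_translate[cd]
    n_aa <- translate[n$codon]
    n_caa <- .ambi$comp_translate[n$codon]
    syn <- n_aa == aa & n_caa != "STOP"
    dbl <- syn & n_caa == caa
    ts <- n$class == "transition"
    data.frame(codon = cd, aa = unname(aa), comp_aa = unname(caa),
               s_n = sum(syn & ts), s_v = sum(syn & !ts),
               d_n = sum(dbl & ts), d_v = sum(dbl & !ts),
               stringsAsFactors = FALSE)
  }))
  prof$is_double <- prof$d_n + prof$d_v >= 1
  rownames(prof) <- prof$codon
  .ambi$profile <- prof
  .ambi$double_syn <- prof$codon[prof$is_double &
                                   prof$aa != "STOP" & prof$comp_aa != "STOP"]

  # Per-codon mutational opportunity among the 9 neighbors, by direction.
  # A neighbor is synonymous in the forward direction if it codes the same
  # amino acid (a forward stop is non-synonymous); in the complement
  # direction if its aligned reverse complement codes the same amino acid
  # (a reverse-frame stop is non-synonymous).  s + n = 9 in each direction.
  opp <- function(dir) {
    do.call(rbind, lapply(codons, function(cd) {
      n <- nb[[cd]]
      same <- if (dir == "forward") {
        translate[n$codon] == translate[cd] & translate[n$codon] != "STOP"
      } else {
        .ambi$comp_translate[n$codon] == .ambi$comp_translate[cd] &
          .ambi$comp_translate[n$codon] != "STOP"
      }
      ts <- n$class == "transition"
      c(s_n = sum(same & ts), s_v = sum(same & !ts),
        n_n = sum(!same & ts), n_v = sum(!same & !ts))
    }))
  }
  .ambi$opp <- list(forward = opp("forward"), complement = opp("complement"))
  rownames(.ambi$opp$forward) <- rownames(.ambi$opp$complement) <- codons
  invisible(NULL)
}

.code <- function() {
  if (is.null(.ambi$codons)) .build_code_tables()
  .ambi
}

#' Normalize nucleotide text to the RNA alphabet
#'
#' Upper-cases and converts T to U.  Used at every ingestion point so that
#' all internal codons are RNA.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over the RNA alphabet.
#' @export
as_rna <- function(x) {
  out <- chartr("Tt", "Uu", toupper(as.character(x)))
  names(out) <- names(x)
  out
}

.check_codons <- function(x) {
  x <- as_rna(x)
  bad <- !grepl("^[ACGU]{3}$", x)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected 3 bases over A/C/G/U, T accepted as U)")
  }
  x
}

#' Aligned-frame reverse complement of a codon
#'
#' Reverses the read direction and takes the pairing complement, i.e. the
#' codon read at the same position on the complementary strand in the
#' reading frame whose codons are aligned with the forward frame.
#'
#' @param codon character vector of codons (DNA or RNA; T is read as U).
#' @return character vector of RNA codons.  The operation is an involution.
#' @examples
#' revcomp_codon("AGG")  # "CCU"
#' revcomp_codon("UAA")  # "UUA"
#' @export
revcomp_codon <- function(codon) {
  codon <- .check_codons(codon)
  unname(.code()$rc[codon])
}

#' Translate a codon under the standard genetic code
#'
#' @param codon character vector of codons (DNA or RNA).
#' @return character vector of three-letter amino acid names, or `"STOP"`.
#' @examples
#' translate_codon(c("UUA", "CCU", "UAA"))
#' @export
translate_codon <- function(codon) {
  codon <- .check_codons(codon)
  unname(.code()$translate[codon])
}

#' Classify the substitution between two codons
#'
#' A single-base change is a transition if it is A<->G or C<->U, otherwise a
#' transversion; codons differing at 2-3 positions are `"multi"`; identical
#' codons are `"identity"`.
#'
#' @param a,b character vectors of codons (recycled to common length).
#' @return character vector over
#'   `c("identity", "transition", "transversion", "multi")`.
#' @export
mutation_class <- function(a, b) {
  a <- .check_codons(a); b <- .check_codons(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- character(n)
  for (i in seq_len(n)) {
    ca <- substring(a[i], 1:3, 1:3)
    cb <- substring(b[i], 1:3, 1:3)
    d <- which(ca != cb)
    out[i] <- if (length(d) == 0) "identity"
    else if (length(d) > 1) "multi"
    else {
      pair <- sort(c(ca[d], cb[d]))
      if (identical(pair, c("A", "G")) || identical(pair, c("C", "U")))
        "transition" else "transversion"
    }
  }
  out
}

#' Single- and double-synonym profile of a codon
#'
#' For a codon that is a sense codon in both the forward frame and the
#' aligned reverse-complement frame, counts its single-nucleotide synonymous
#' mutations split into transitions (`s_n`) and transversions (`s_v`),
#' excluding mutations to codons whose aligned reverse complement is a stop,
#' and the subset of those that are *doubly* synonymous (`d_n`, `d_v`):
#' mutations that also preserve the amino acid coded by the aligned reverse
#' complement.  Double synonyms are included in the single-synonym counts.
#'
#' @param codon character vector of codons; each must be non-stop in both
#'   aligned frames.
#' @return a data frame of class `"synonym_profile"` with one row per codon
#'   and columns `codon`, `aa`, `comp_aa`, `s_n`, `s_v`, `d_n`, `d_v`,
#'   `is_double`.
#' @examples
#' synonym_profile("AGG")  # 1 + 1 single synonyms, 0 + 1 double, comp Pro
#' @export
synonym_profile <- function(codon) {
  codon <- .check_codons(codon)
  tb <- .code()
  fwd_stop <- tb$translate[codon] == "STOP"
  rev_stop <- tb$comp_translate[codon] == "STOP"
  if (any(fwd_stop | rev_stop)) {
    stop("codon(s) ", paste(unique(codon[fwd_stop | rev_stop]), collapse = ", "),
         " are stop codons in the forward or aligned reverse frame; ",
         "such codons do not occur in ambigrammatic genes")
  }
  out <- tb$profile[codon, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synonym_profile", "data.frame")
  out
}

#' @export
print.synonym_profile <- function(x, ...) {
  df <- data.frame(AA = x$aa, Codon = paste0(x$codon, ifelse(x$is_double, "*", "")),
                   `S(n)+S(v)` = paste(x$s_n, "+", x$s_v),
                   `D(n)+D(v)` = paste(x$d_n, "+", x$d_v),
                   Comp.AA = x$comp_aa, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' The twelve double-synonym codons
#'
#' Codons admitting at least one single-nucleotide mutation that is
#' synonymous in both the forward frame and the aligned reverse-complement
#' frame.
#'
#' @return character vector of 12 RNA codons.
#' @export
double_synonym_codons <- function() {
  .code()$double_syn
}

#' Synonym-profile table for the double-synonym amino acids
#'
#' Tabulates, for every amino acid that admits a double synonym, all of its
#' codons whose aligned reverse complement is not a stop, with their single-
#' and double-synonym counts.
#'
#' @return a `"synonym_profile"` data frame (21 rows for the standard code:
#'   Leu, Pro, Gln, Arg and Ser codons).
#' @export
synonym_table <- function() {
  tb <- .code()
  prof <- tb$profile
  aas <- unique(prof$aa[prof$is_double & prof$aa != "STOP"])
  keep <- prof$aa %in% aas & prof$comp_aa != "STOP" & prof$aa != "STOP"
  out <- prof[keep, , drop = FALSE]
  out <- out[order(match(out$aa, aas), out$codon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synonym_profile", "data.frame")
  out
}

#' Synonymous repairs of a reverse-frame stop codon
#'
#' For a codon whose aligned reverse complement is a stop codon, returns all
#' single-nucleotide mutations that preserve the forward amino acid and
#' remove the reverse-frame stop.  Such a repair always exists, which is why
#' an ambigrammatic version of any gene can evolve through synonymous
#' substitutions alone.
#'
#' @param codon a single codon with `translate_codon(revcomp_codon(codon))
#'   == "STOP"` (UUA, CUA or UCA in the standard code).
#' @return character vector of repaired codons (never empty).
#' @examples
#' stop_fixes("UUA")  # "UUG"
#' @export
stop_fixes <- function(codon) {
  codon <- .check_codons(codon)
  stopifnot(length(codon) == 1L)
  tb <- .code()
  if (tb$comp_translate[codon] != "STOP") {
    stop("aligned reverse complement of ", codon, " is not a stop codon")
  }
  n <- tb$neighbors[[codon]]
  keep <- tb$translate[n$codon] == tb$translate[codon] &
    tb$comp_translate[n$codon] != "STOP"
  sort(n$codon[keep])
}

# Internal: 9-neighbor table of a codon (codon, class, position).
.neighbors <- function(codon) .code()$neighbors[[codon]]
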