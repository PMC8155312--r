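# Independent oracle for the codon algebra, built on seqinr's translation
# and explicit loops.  Deliberately avoids every code path of the package
# implementation (which derives its tables from Biostrings::GENETIC_CODE
# and precomputed neighbor lists).

o_bases <- c("A", "C", "G", "U")

o_translate1 <- function(codon) {
  # one-letter amino acid, "*" for stop, via seqinr on the DNA alphabet
  seqinr::translate(tolower(strsplit(chartr("U", "T", codon), "")[[1]]))
}

o_revcomp <- function(codon) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(codon, "")[[1]]]), collapse = "")
}

o_is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "U") && b %in% c("C", "U"))
}

# all 9 single-nucleotide neighbors with their substitution class
o_neighbors <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- NULL
  for (p in 1:3) {
    for (b in setdiff(o_bases, ch[p])) {
      mut <- ch; mut[p] <- b
      out <- rbind(out, data.frame(
        codon = paste(mut, collapse = ""),
        ts = o_is_transition(ch[p], b)))
    }
  }
  out
}

# single/double synonym counts of one codon (exclusion of reverse-stop
# targets applied), computed by brute-force loops
o_profile <- function(codon) {
  aa <- o_translate1(codon)
  caa <- o_translate1(o_revcomp(codon))
  nb <- o_neighbors(codon)
  s_n <- s_v <- d_n <- d_v <- 0L
  for (i in seq_len(nrow(nb))) {
    b <- nb$codon[i]
    if (o_translate1(b) != aa) next
    if (o_translate1(o_revcomp(b)) == "*") next
    if (nb$ts[i]) s_n <- s_n + 1L else s_v <- s_v + 1L
    if (o_translate1(o_revcomp(b)) == caa) {
      if (nb$ts[i]) d_n <- d_n + 1L else d_v <- d_v + 1L
    }
  }
  c(s_n = s_n, s_v = s_v, d_n = d_n, d_v = d_v)
}

# synonymous / non-synonymous opportunity of one codon among its 9
# neighbors, in a read direction ("forward" or "complement")
o_opportunity <- function(codon, direction) {
  nb <- o_neighbors(codon)
  s_n <- s_v <- n_n <- n_v <- 0L
  ref <- if (direction == "forward") o_translate1(codon)
  else o_translate1(o_revcomp(codon))
  for (i in seq_len(nrow(nb))) {
    b <- nb$codon[i]
    aa <- if (direction == "forward") o_translate1(b)
    else o_translate1(o_revcomp(b))
    syn <- aa == ref && aa != "*"
    if (syn && nb$ts[i]) s_n <- s_n + 1L
    else if (syn) s_v <- s_v + 1L
    else if (nb$ts[i]) n_n <- n_n + 1L
    else n_v <- n_v + 1L
  }
  c(s_n = s_n, s_v = s_v, n_n = n_n, n_v = n_v)
}

o_all_codons <- apply(expand.grid(o_bases, o_bases, o_bases)[, 3:1], 1,
                      paste, collapse = "")

# Eq.-8-style null ratio over a consensus codon vector, brute force
o_Rexp <- function(codons, alpha, direction) {
  num <- den <- 0
  for (cd in codons) {
    op <- o_opportunity(cd, direction)
    num <- num + alpha * op["n_n"] + op["n_v"]
    den <- den + alpha * op["s_n"] + op["s_v"]
  }
  unname(num / den)
}

# Kimura null for the single/double synonym ratio, brute force
o_R0 <- function(codons, alpha) {
  num <- den <- 0
  for (cd in codons) {
    pr <- o_profile(cd)
    num <- num + alpha * pr["s_n"] + pr["s_v"]
    den <- den + alpha * pr["d_n"] + pr["d_v"]
  }
  unname(num / den)
}

# enumerate all doubly synonymous ordered codon pairs by brute force
o_dsyn_pairs <- function() {
  out <- NULL
  for (cd in o_all_codons) {
    if (o_translate1(cd) == "*" || o_translate1(o_revcomp(cd)) == "*") next
    nb <- o_neighbors(cd)
    for (b in nb$codon) {
      if (o_translate1(b) == "*" || o_translate1(o_revcomp(b)) == "*") next
      if (o_translate1(b) == o_translate1(cd) &&
          o_translate1(o_revcomp(b)) == o_translate1(o_revcomp(cd))) {
        out <- rbind(out, data.frame(from = cd, to = b))
      }
    }
  }
  out
}

# small helpers for building fixture alignments from codon rows:
# seqs_from_codons(list(c("AGG","CAA"), c("AGG","CAA"))) -> 2 sequences
seqs_from_codons <- function(rows) {
  vapply(rows, paste, character(1), collapse = "")
}

random_rna <- function(n) paste(sample(o_bases, n, TRUE), collapse = "")
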