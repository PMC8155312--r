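#' Construct a codon alignment
#'
#' Holds M codon-aligned nucleotide sequences of identical length.  Input is
#' normalized to RNA (T read as U, case folded); a leading `frame_offset`
#' (0-2) and any trailing remainder are trimmed so the stored length is a
#' multiple of three.  Non-ACGU symbols (gaps, ambiguity codes) are retained
#' and cause the containing codon of that sequence to be skipped by the
#' statistics.
#'
#' @param sequences character vector of nucleotide strings, all the same
#'   length, or a `Biostrings::XStringSet`.
#' @param ids sequence labels; defaults to names of `sequences` or `seq_1..`.
#' @param frame_offset integer 0-2, number of leading bases to discard
#'   before parsing codons.
#' @return an object of class `"codon_alignment"` with elements `mat`
#'   (M x 3N character matrix), `ids`, `M`, `N`, `frame_offset`.
#' @export
codon_alignment <- function(sequences, ids = NULL, frame_offset = 0L) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  nm <- names(sequences)
  sequences <- as.character(sequences)
  if (is.null(ids)) {
    ids <- if (!is.null(nm)) nm else paste0("seq_", seq_along(sequences))
  }
  if (length(sequences) < 2L) {
    stop("a codon alignment needs at least 2 sequences (got ",
         length(sequences), ")")
  }
  len <- nchar(sequences)
  if (length(unique(len)) != 1L) {
    # reference = modal length, ties resolved to the first sequence's length
    tb <- table(len)
    cand <- as.integer(names(tb)[tb == max(tb)])
    ref <- if (len[1] %in% cand) len[1] else cand[1]
    stop("sequences have unequal lengths; offending ids: ",
         paste(ids[len != ref], collapse = ", "))
  }
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset >= 0L, frame_offset <= 2L)
  seqs <- as_rna(sequences)
  if (frame_offset > 0L) seqs <- substring(seqs, frame_offset + 1L)
  n3 <- (nchar(seqs[1]) %/% 3L) * 3L
  if (n3 < 3L) stop("alignment shorter than one codon after trimming")
  seqs <- substr(seqs, 1L, n3)
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(seqs), ncol = n3, byrow = TRUE)
  rownames(mat) <- ids
  structure(list(mat = mat, ids = ids, M = nrow(mat), N = n3 %/% 3L,
                 frame_offset = frame_offset),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: M =", x$M, "sequences, N =", x$N,
      "codons (", 3L * x$N, "nt ), frame offset", x$frame_offset, "\n")
  invisible(x)
}

#' Read a codon alignment from a multi-FASTA file
#'
#' All records must have equal length (pre-aligned input); gaps are
#' permitted.  Plain or gzip-compressed FASTA is accepted.
#'
#' @param path FASTA file of aligned sequences.
#' @inheritParams codon_alignment
#' @return a [codon_alignment] object.
#' @export
read_alignment <- function(path, frame_offset = 0L) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  codon_alignment(as.character(x), ids = names(x), frame_offset = frame_offset)
}

# Internal: M x N matrix of codon strings.
.codon_matrix <- function(aln) {
  m <- aln$mat
  i <- seq(1L, ncol(m), by = 3L)
  matrix(paste0(m[, i], m[, i + 1L], m[, i + 2L]),
         nrow = nrow(m), dimnames = list(aln$ids, NULL))
}

#' Choose the reading frame of a sequence
#'
#' Returns the frame offset (0-2) whose forward codon parse contains the
#' fewest internal stop codons (the final codon of each parse is not counted
#' as internal).  Ties go to the smallest offset.  The complement direction
#' always uses the codon-aligned reverse frame of the chosen forward frame.
#'
#' @param seq a single nucleotide string (length >= 3).
#' @return integer offset in `0:2`.
#' @export
select_frame <- function(seq) {
  seq <- as_rna(seq)
  stopifnot(length(seq) == 1L, nchar(seq) >= 3L)
  n_stop <- vapply(0:2, function(off) {
    s <- substring(seq, off + 1L)
    n3 <- (nchar(s) %/% 3L) * 3L
    if (n3 < 3L) return(Inf)
    cods <- substring(s, seq(1L, n3 - 2L, 3L), seq(3L, n3, 3L))
    cods <- cods[-length(cods)]                      # terminal codon excluded
    cods <- cods[grepl("^[ACGU]{3}$", cods)]
    sum(.code()$translate[cods] == "STOP")
  }, numeric(1))
  as.integer(which.min(n_stop) - 1L)
}

#' Consensus sequence of a codon alignment
#'
#' The consensus base at each nucleotide column is the modal base among
#' A/C/G/U symbols; ties are broken by the fixed order A < C < G < U.  The
#' consensus codon at locus k is the triple of modal bases.
#'
#' @param aln a [codon_alignment].
#' @return an object of class `"ambigram_consensus"`: list with `bases`
#'   (character vector, 3N), `codons` (character vector, N), `counts`
#'   (4 x 3N base-count matrix), `N`, `M`.
#' @export
build_consensus <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  m <- aln$mat
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(factor(m[, j], levels = c("A", "C", "G", "U")), nbins = 4L)
  }, integer(4))
  rownames(counts) <- c("A", "C", "G", "U")
  empty <- colSums(counts) == 0L
  if (any(empty)) {
    stop("no unambiguous base in alignment column(s): ",
         paste(which(empty), collapse = ", "))
  }
  bases <- rownames(counts)[apply(counts, 2L, which.max)]
  i <- seq(1L, length(bases), by = 3L)
  codons <- paste0(bases[i], bases[i + 1L], bases[i + 2L])
  structure(list(bases = bases, codons = codons, counts = counts,
                 N = length(codons), M = aln$M),
            class = "ambigram_consensus")
}

#' @export
print.ambigram_consensus <- function(x, ...) {
  cat("Consensus of", x$M, "sequences,", x$N, "codons\n")
  invisible(x)
}

# Internal: per-cell comparison of the alignment against the consensus.
# Returns list(cod, cons, valid, ndiff, pos1_diff, pos2_diff, pos3_diff)
# where cod is the M x N codon matrix.
.cell_diffs <- function(aln, consensus) {
  cod <- .codon_matrix(aln)
  M <- nrow(cod); N <- ncol(cod)
  consm <- matrix(consensus$codons, nrow = M, ncol = N, byrow = TRUE)
  valid <- matrix(grepl("^[ACGU]{3}$", cod), M, N)
  d <- lapply(1:3, function(p) {
    matrix(substring(cod, p, p) != substring(consm, p, p), M, N) & valid
  })
  ndiff <- d[[1]] + d[[2]] + d[[3]]
  list(cod = cod, consm = consm, valid = valid, ndiff = ndiff, d = d)
}

#' Nucleotide-level polymorphism statistics
#'
#' Counts, over all M sequences and N codon loci, the codon cells that
#' differ from the consensus codon by exactly one base, split into
#' transitions (`N_n`) and transversions (`N_v`) and by codon position
#' (`n1`, `n2`, `n3`).  The overall mutation rate is
#' `r = (n1 + n2 + n3) / (3 N M)` and the transition/transversion rate
#' ratio is estimated as `alpha = 2 N_n / N_v`, the factor two accounting
#' for the two possible transversions per site.  The normalized positional
#' triplet is `(z1 : z2 : z3) = 3 (n1 : n2 : n3) / (n1 + n2 + n3)`.
#'
#' @param aln a [codon_alignment].
#' @param consensus an [build_consensus()] result (computed if missing).
#' @return object of class `"nucleotide_stats"`: list with `N`, `M`, `N_n`,
#'   `N_v`, `r`, `alpha`, `n1`, `n2`, `n3`, `z1`, `z2`, `z3`.  `alpha` is
#'   `NA` when no transversions are observed, `z*` are `NA` when no
#'   mutations are observed.
#' @export
nucleotide_stats <- function(aln, consensus = build_consensus(aln)) {
  cd <- .cell_diffs(aln, consensus)
  single <- cd$ndiff == 1L
  n_pos <- vapply(1:3, function(p) sum(cd$d[[p]] & single), integer(1))
  N_n <- 0L; N_v <- 0L
  if (any(single)) {
    idx <- which(single)
    cls <- mutation_class(cd$consm[idx], cd$cod[idx])
    N_n <- sum(cls == "transition")
    N_v <- sum(cls == "transversion")
  }
  tot <- sum(n_pos)
  structure(list(
    N = consensus$N, M = aln$M, N_n = N_n, N_v = N_v,
    r = tot / (3 * consensus$N * aln$M),
    alpha = if (N_v > 0L) 2 * N_n / N_v else NA_real_,
    n1 = n_pos[1], n2 = n_pos[2], n3 = n_pos[3],
    z1 = if (tot > 0L) 3 * n_pos[1] / tot else NA_real_,
    z2 = if (tot > 0L) 3 * n_pos[2] / tot else NA_real_,
    z3 = if (tot > 0L) 3 * n_pos[3] / tot else NA_real_),
    class = "nucleotide_stats")
}

#' @export
print.nucleotide_stats <- function(x, digits = 3, ...) {
  cat("Nucleotide-level polymorphism: N =", x$N, ", M =", x$M, "\n")
  cat("  transitions Nn =", x$N_n, ", transversions Nv =", x$N_v, "\n")
  cat("  r =", signif(x$r, digits), ", alpha = 2Nn/Nv =",
      signif(x$alpha, digits), "\n")
  cat("  (n1,n2,n3) = (", x$n1, ",", x$n2, ",", x$n3, "),  (z1:z2:z3) = (",
      paste(signif(c(x$z1, x$z2, x$z3), digits), collapse = ":"), ")\n")
  invisible(x)
}

#' Per-locus variant sets
#'
#' For each codon locus, the set of distinct codons observed that differ
#' from the consensus codon, with the number of carrier sequences, the
#' substitution class, and synonymy flags in both read directions.  A
#' sequence whose codon at a locus contains a non-ACGU symbol contributes
#' nothing at that locus (the denominator of `f` stays `M`).
#'
#' @inheritParams nucleotide_stats
#' @return object of class `"locus_variants"`: list with
#'   \describe{
#'     \item{summary}{data frame, one row per locus: `locus`, `consensus`,
#'       `n` (distinct variants), `f` (fraction of sequences off-consensus),
#'       `skipped` (sequences skipped for ambiguity/gaps).}
#'     \item{variants}{data frame, one row per distinct variant:
#'       `locus`, `consensus`, `codon`, `carriers`, `ndiff`, `class`,
#'       `syn_fwd`, `syn_comp`, `rev_stop`, `dsyn`.}
#'     \item{M, N}{alignment dimensions.}
#'   }
#' @export
codon_variant_sets <- function(aln, consensus = build_consensus(aln)) {
  cd <- .cell_diffs(aln, consensus)
  M <- nrow(cd$cod); N <- ncol(cd$cod)
  is_var <- cd$ndiff >= 1L
  f <- colSums(is_var) / M
  skipped <- colSums(!cd$valid)

  idx <- which(is_var)
  if (length(idx)) {
    locus <- ((idx - 1L) %/% M) + 1L
    vcod <- cd$cod[idx]
    key <- paste(locus, vcod)
    agg <- tapply(rep(1L, length(key)), key, sum)
    first <- !duplicated(key)
    vdf <- data.frame(locus = locus[first], codon = vcod[first],
                      carriers = as.integer(agg[key[first]]),
                      stringsAsFactors = FALSE)
    vdf <- vdf[order(vdf$locus, vdf$codon), , drop = FALSE]
    vdf$consensus <- consensus$codons[vdf$locus]
    vdf$class <- mutation_class(vdf$consensus, vdf$codon)
    vdf$ndiff <- ifelse(vdf$class == "multi", NA_integer_, 1L)
    # exact ndiff for multi rows
    multi <- which(vdf$class == "multi")
    if (length(multi)) {
      vdf$ndiff[multi] <- vapply(multi, function(i) {
        sum(substring(vdf$consensus[i], 1:3, 1:3) !=
              substring(vdf$codon[i], 1:3, 1:3))
      }, integer(1))
    }
    tb <- .code()
    vdf$syn_fwd <- tb$translate[vdf$codon] == tb$translate[vdf$consensus] &
      tb$translate[vdf$codon] != "STOP"
    vdf$syn_comp <- tb$comp_translate[vdf$codon] ==
      tb$comp_translate[vdf$consensus] & tb$comp_translate[vdf$codon] != "STOP"
    vdf$rev_stop <- tb$comp_translate[vdf$codon] == "STOP"
    vdf$dsyn <- vdf$ndiff == 1L & vdf$syn_fwd & vdf$syn_comp
    rownames(vdf) <- NULL
    vdf <- vdf[, c("locus", "consensus", "codon", "carriers", "ndiff",
                   "class", "syn_fwd", "syn_comp", "rev_stop", "dsyn")]
    n_k <- tabulate(vdf$locus, nbins = N)
  } else {
    vdf <- data.frame(locus = integer(0), consensus = character(0),
                      codon = character(0), carriers = integer(0),
                      ndiff = integer(0), class = character(0),
                      syn_fwd = logical(0), syn_comp = logical(0),
                      rev_stop = logical(0), dsyn = logical(0))
    n_k <- integer(N)
  }
  structure(list(
    summary = data.frame(locus = seq_len(N), consensus = consensus$codons,
                         n = n_k, f = f, skipped = as.integer(skipped)),
    variants = vdf, M = M, N = N), class = "locus_variants")
}

#' @export
print.locus_variants <- function(x, ...) {
  cat("Variant sets over", x$N, "codon loci (M =", x$M, "):",
      sum(x$summary$n > 0), "variable loci,", nrow(x$variants),
      "distinct variants\n")
  invisible(x)
}

# Internal: kappa-weighted synonymous / non-synonymous opportunity sums over
# a set of consensus codons, in a given direction.  Each codon contributes
# its 9 single-nucleotide neighbors; s + n = 9.
.opportunity_sums <- function(codons, direction, kappa) {
  opp <- .code()$opp[[direction]][codons, , drop = FALSE]
  c(syn = sum(kappa * opp[, "s_n"] + opp[, "s_v"]),
    nsyn = sum(kappa * opp[, "n_n"] + opp[, "n_v"]))
}

#' Codon-level polymorphism statistics
#'
#' Counts synonymous (`N_sy`) and non-synonymous (`N_ns`) single-nucleotide
#' variants in the stated read direction, and multi-base variants
#' (`N_mult`), from the per-locus variant sets.  The observed ratio
#' `R = N_ns / N_sy` is compared with its expectation under the null
#' hypothesis that the sequence is non-coding in that direction,
#' `R_exp = sum_k (alpha n_k(n) + n_k(v)) / sum_k (alpha s_k(n) + s_k(v))`,
#' where `s_k`/`n_k` are the synonymous / non-synonymous single-nucleotide
#' mutational opportunities of consensus codon k (9 per codon) and `alpha`
#' weights transitions.
#'
#' @param vs a [codon_variant_sets()] result.
#' @param direction `"forward"` or `"complement"`; synonymy is judged on
#'   the amino acid coded in that direction (a stop is never synonymous).
#' @param alpha transition/transversion rate ratio used in `R_exp`
#'   (typically the estimate from [nucleotide_stats()]).
#' @param counting `"distinct"` counts each variant codon once per locus;
#'   `"occurrence"` weights each variant by its number of carrier sequences.
#' @return object of class `"codon_stats"`: list with `direction`, `N_sy`,
#'   `N_ns`, `N_mult`, `R`, `R_exp`, `R_over_Rexp`, `f_mult`, `alpha`,
#'   `counting`.  `R` is `NA` (undefined) when `N_sy` is zero.
#' @export
codon_stats <- function(vs, direction = c("forward", "complement"),
                        alpha, counting = c("distinct", "occurrence")) {
  stopifnot(inherits(vs, "locus_variants"))
  direction <- match.arg(direction)
  counting <- match.arg(counting)
  stopifnot(is.numeric(alpha), alpha > 0)
  v <- vs$variants
  w <- if (counting == "occurrence") v$carriers else rep(1L, nrow(v))
  syn <- if (direction == "forward") v$syn_fwd else v$syn_comp
  single <- !is.na(v$ndiff) & v$ndiff == 1L
  N_sy <- sum(w[single & syn])
  N_ns <- sum(w[single & !syn])
  N_mult <- sum(w[!single])
  opp <- .opportunity_sums(vs$summary$consensus, direction, alpha)
  if (opp[["syn"]] == 0) {
    stop("zero synonymous mutational opportunity in the ", direction,
         " direction; R_exp undefined")
  }
  R_exp <- opp[["nsyn"]] / opp[["syn"]]
  R <- if (N_sy > 0) N_ns / N_sy else NA_real_
  structure(list(direction = direction, N_sy = N_sy, N_ns = N_ns,
                 N_mult = N_mult, R = R, R_exp = R_exp,
                 R_over_Rexp = R / R_exp, f_mult = N_mult / vs$N,
                 alpha = alpha, counting = counting),
            class = "codon_stats")
}

#' @export
print.codon_stats <- function(x, digits = 3, ...) {
  cat("Codon-level polymorphism (", x$direction, " direction, ",
      x$counting, " counting)\n", sep = "")
  cat("  Nsy =", x$N_sy, ", Nns =", x$N_ns, ", Nmult =", x$N_mult, "\n")
  cat("  R = Nns/Nsy =", signif(x$R, digits), ", R_exp =",
      signif(x$R_exp, digits), ", R/R_exp =", signif(x$R_over_Rexp, digits),
      ", fmult =", signif(x$f_mult, digits), "\n")
  invisible(x)
}

#' ORF-wide dN/dS
#'
#' A conservative ORF-wide dN/dS that assumes every mutation in the
#' alignment occurred only once: each distinct variant codon is counted a
#' single time (multi-base variants included) and classified by amino-acid
#' identity with the consensus in the stated direction.  The observed
#' non-synonymous and synonymous counts are normalized by the kappa-weighted
#' single-nucleotide opportunity sums of the consensus sequence.
#'
#' @inheritParams codon_stats
#' @param kappa transition/transversion ratio used to weight the mutational
#'   opportunities (default 2).
#' @return object of class `"ambigram_dnds"`: list with `dnds`, `N_ns_obs`,
#'   `N_sy_obs`, `opp_nsyn`, `opp_syn`, `direction`, `kappa`.  `dnds` is
#'   `NA` when no synonymous mutation is observed.
#' @export
dnds_orfwide <- function(vs, direction = c("forward", "complement"),
                         kappa = 2) {
  stopifnot(inherits(vs, "locus_variants"))
  direction <- match.arg(direction)
  v <- vs$variants
  syn <- if (direction == "forward") v$syn_fwd else v$syn_comp
  N_sy <- sum(syn)
  N_ns <- sum(!syn)
  opp <- .opportunity_sums(vs$summary$consensus, direction, kappa)
  dnds <- if (N_sy > 0 && opp[["syn"]] > 0) {
    (N_ns / opp[["nsyn"]]) / (N_sy / opp[["syn"]])
  } else NA_real_
  structure(list(dnds = dnds, N_ns_obs = N_ns, N_sy_obs = N_sy,
                 opp_nsyn = unname(opp[["nsyn"]]), opp_syn = unname(opp[["syn"]]),
                 direction = direction, kappa = kappa),
            class = "ambigram_dnds")
}

#' @export
print.ambigram_dnds <- function(x, digits = 3, ...) {
  cat("ORF-wide dN/dS (", x$direction, " direction, kappa = ", x$kappa,
      "): ", signif(x$dnds, digits), "\n", sep = "")
  cat("  observed: ", x$N_ns_obs, " non-synonymous, ", x$N_sy_obs,
      " synonymous distinct mutations\n", sep = "")
  invisible(x)
}
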