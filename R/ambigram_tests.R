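#' Doubly synonymous loci of a consensus sequence
#'
#' Loci whose consensus codon is one of the twelve double-synonym codons,
#' i.e. codons admitting a single-nucleotide mutation that is synonymous in
#' both the forward and the aligned reverse-complement frames.
#'
#' @param consensus an [build_consensus()] result, or a character vector of
#'   consensus codons.
#' @return integer vector of 1-based codon loci.
#' @export
ds_loci <- function(consensus) {
  codons <- if (inherits(consensus, "ambigram_consensus")) consensus$codons
  else .check_codons(consensus)
  which(codons %in% double_synonym_codons())
}

.fit_parts <- function(object) {
  if (inherits(object, "ambigram_polymorphism")) {
    list(vs = object$variant_sets, consensus = object$consensus,
         alpha = object$alpha)
  } else if (inherits(object, "locus_variants")) {
    list(vs = object, consensus = NULL, alpha = NULL)
  } else {
    stop("expected an 'ambigram_polymorphism' fit or 'locus_variants'")
  }
}

#' Mutational-hotspot test for reverse-strand coding
#'
#' If the reverse open reading frame codes for a protein, the only
#' assuredly non-deleterious mutations are the doubly synonymous ones, so
#' the doubly synonymous loci should be mutational hotspots.  The test
#' compares the average number of distinct variant codons `<n(k)>` and the
#' average off-consensus fraction `<f(k)>` between doubly synonymous loci
#' and all other loci:
#' `R_n = <n(k)>|ds / <n(k)>|other`, `R_f = <f(k)>|ds / <f(k)>|other`.
#' Ratios close to one are consistent with a non-coding reverse strand;
#' ratios well above one indicate reverse-strand coding.
#'
#' An optional label-permutation resample (not part of the original
#' procedure; provided as plumbing for judging "close to one") permutes the
#' doubly-synonymous labels over loci to give a null interval for the
#' ratios.
#'
#' @param object an [ambigram_polymorphism()] fit, or a
#'   [codon_variant_sets()] result (then `consensus` is required).
#' @param consensus consensus object when `object` is a `locus_variants`.
#' @param n_perm number of label permutations (0 = none).
#' @param seed optional RNG seed for the permutation.
#' @return object of class `"ambigram_hotspot"`: list with `N`, `N_ds`,
#'   `mean_n_ds`, `mean_n_other`, `mean_f_ds`, `mean_f_other`, `R_n`,
#'   `R_f`, and (if resampled) `perm_interval`, a 2x2 matrix of central
#'   95% null intervals.
#' @export
hotspot_test <- function(object, consensus = NULL, n_perm = 0L,
                         seed = NULL) {
  p <- .fit_parts(object)
  if (!is.null(consensus)) p$consensus <- consensus
  if (is.null(p$consensus)) stop("consensus required")
  s <- p$vs$summary
  ds <- ds_loci(p$consensus)
  if (length(ds) == 0L) stop("no doubly synonymous locus in the consensus")
  if (length(ds) == nrow(s)) stop("no non-doubly-synonymous locus")
  is_ds <- seq_len(nrow(s)) %in% ds
  ratio <- function(num, den) {
    if (den > 0) num / den
    else if (num > 0) Inf                    # hotspots with silent background
    else NA_real_                            # undefined: no signal either side
  }
  mean_n_ds <- mean(s$n[is_ds]); mean_n_other <- mean(s$n[!is_ds])
  mean_f_ds <- mean(s$f[is_ds]); mean_f_other <- mean(s$f[!is_ds])
  out <- list(N = nrow(s), N_ds = length(ds),
              mean_n_ds = mean_n_ds, mean_n_other = mean_n_other,
              mean_f_ds = mean_f_ds, mean_f_other = mean_f_other,
              R_n = ratio(mean_n_ds, mean_n_other),
              R_f = ratio(mean_f_ds, mean_f_other))
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    perm <- replicate(n_perm, {
      lab <- sample(is_ds)
      c(ratio(mean(s$n[lab]), mean(s$n[!lab])),
        ratio(mean(s$f[lab]), mean(s$f[!lab])))
    })
    out$perm_interval <- t(apply(perm, 1L, stats::quantile,
                                 probs = c(0.025, 0.975), na.rm = TRUE))
    rownames(out$perm_interval) <- c("R_n", "R_f")
  }
  structure(out, class = "ambigram_hotspot")
}

#' @export
print.ambigram_hotspot <- function(x, digits = 3, ...) {
  cat("Mutational-hotspot test over doubly synonymous loci\n")
  cat("  N =", x$N, "loci, N_ds =", x$N_ds, "doubly synonymous\n")
  cat("  <n(k)>: ds =", signif(x$mean_n_ds, digits), ", other =",
      signif(x$mean_n_other, digits), " ->  R_n =", signif(x$R_n, digits), "\n")
  cat("  <f(k)>: ds =", signif(x$mean_f_ds, digits), ", other =",
      signif(x$mean_f_other, digits), " ->  R_f =", signif(x$R_f, digits), "\n")
  if (!is.null(x$perm_interval)) {
    cat("  95% label-permutation null intervals:\n")
    print(signif(x$perm_interval, digits))
  }
  cat("  Ratios close to 1 are consistent with a non-coding reverse ORF.\n")
  invisible(x)
}

#' Kimura null for the single/double synonym ratio
#'
#' Expected value `R0` of the single-to-double synonym mutation ratio under
#' the null hypothesis that the complementary strand is non-coding, from the
#' synonym profile of the consensus codons at the variable doubly
#' synonymous loci:
#' `R0 = sum_k (alpha S_k(n) + S_k(v)) / sum_k (alpha D_k(n) + D_k(v))`,
#' with transitions weighted by the rate ratio `alpha`.
#'
#' @param codons character vector of the consensus codons at the variable
#'   doubly synonymous loci (repeats allowed; all must be double-synonym
#'   codons).
#' @param alpha transition/transversion rate ratio.
#' @return the null ratio `R0` (numeric scalar).
#' @examples
#' null_ratio_r0("CAA", alpha = 1)  # 1
#' null_ratio_r0("CGA", alpha = 2)  # 5
#' @export
null_ratio_r0 <- function(codons, alpha) {
  stopifnot(length(codons) >= 1L, is.numeric(alpha), alpha > 0)
  prof <- synonym_profile(codons)
  num <- sum(alpha * prof$s_n + prof$s_v)
  den <- sum(alpha * prof$d_n + prof$d_v)
  if (den == 0) {
    stop("no double-synonym opportunity at the supplied codons; ",
         "R0 requires loci whose consensus is a double-synonym codon")
  }
  num / den
}

#' Doubly-synonymous mutation-frequency test
#'
#' At the variable doubly synonymous loci `{k*}` (consensus codon in the
#' twelve-codon double-synonym set, at least `min_variants` distinct
#' variants), counts for each locus the distinct single-nucleotide variants
#' that are synonymous in the forward direction and not reverse-frame stops,
#' `n_s(k)`, and the subset that also preserve the complementary-strand
#' amino acid, `n_d(k)`.  The sums give `R = N_s / N_d`; if the complement
#' strand is coding, `R` should be close to one, while under the non-coding
#' null it should be close to the Kimura expectation `R0`
#' ([null_ratio_r0()]).
#'
#' @inheritParams hotspot_test
#' @param alpha transition/transversion rate ratio for `R0`; defaults to
#'   the fit's estimate.
#' @param min_variants minimum `n(k)` for a doubly synonymous locus to be
#'   counted as variable (default 1).
#' @param counting `"distinct"` (default) or `"occurrence"` weighting of
#'   variants, as in [codon_stats()].
#' @return object of class `"ambigram_dsyn"`: list with `N`, `N_ds`, `N_a`,
#'   `per_locus` (data frame `locus`, `consensus`, `n`, `n_s`, `n_d`),
#'   `N_s`, `N_d`, `R`, `R0`, `R_over_R0`, `alpha`.  `R` is `NA` (flagged
#'   `undefined = TRUE`) when `N_d` is zero.
#' @export
dsyn_test <- function(object, consensus = NULL, alpha = NULL,
                      min_variants = 1L,
                      counting = c("distinct", "occurrence")) {
  counting <- match.arg(counting)
  p <- .fit_parts(object)
  if (!is.null(consensus)) p$consensus <- consensus
  if (!is.null(alpha)) p$alpha <- alpha
  if (is.null(p$consensus)) stop("consensus required")
  if (is.null(p$alpha)) stop("alpha required")
  s <- p$vs$summary
  v <- p$vs$variants
  ds <- ds_loci(p$consensus)
  kstar <- intersect(ds, s$locus[s$n >= min_variants])
  if (length(kstar) == 0L) {
    stop("no variable doubly synonymous locus (n(k) >= ", min_variants, ")")
  }
  vv <- v[v$locus %in% kstar, , drop = FALSE]
  w <- if (counting == "occurrence") vv$carriers else rep(1L, nrow(vv))
  is_s <- !is.na(vv$ndiff) & vv$ndiff == 1L & vv$syn_fwd & !vv$rev_stop
  is_d <- is_s & vv$syn_comp
  per_locus <- data.frame(
    locus = kstar,
    consensus = s$consensus[kstar],
    n = s$n[kstar],
    n_s = vapply(kstar, function(k) sum(w[vv$locus == k & is_s]), numeric(1)),
    n_d = vapply(kstar, function(k) sum(w[vv$locus == k & is_d]), numeric(1)))
  N_s <- sum(per_locus$n_s); N_d <- sum(per_locus$n_d)
  R0 <- null_ratio_r0(per_locus$consensus, p$alpha)
  R <- if (N_d > 0) N_s / N_d else NA_real_
  structure(list(N = nrow(s), N_ds = length(ds), N_a = length(kstar),
                 per_locus = per_locus, N_s = N_s, N_d = N_d, R = R,
                 R0 = R0, R_over_R0 = R / R0, undefined = N_d == 0,
                 alpha = p$alpha, counting = counting),
            class = "ambigram_dsyn")
}

#' @export
print.ambigram_dsyn <- function(x, digits = 3, ...) {
  cat("Doubly-synonymous mutation-frequency test\n")
  cat("  N =", x$N, "loci, N_ds =", x$N_ds,
      "doubly synonymous, N_a =", x$N_a, "variable\n")
  cat("  Ns =", x$N_s, ", Nd =", x$N_d, "\n")
  if (x$undefined) {
    cat("  R = Ns/Nd undefined (no doubly synonymous mutation observed);",
        "R0 =", signif(x$R0, digits), "\n")
  } else {
    cat("  R = Ns/Nd =", signif(x$R, digits), ", R0 =", signif(x$R0, digits),
        ", R/R0 =", signif(x$R_over_R0, digits), "\n")
    cat("  R close to 1 indicates a coding reverse ORF;",
        "R close to R0 indicates non-coding.\n")
  }
  invisible(x)
}
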