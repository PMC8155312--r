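#' Fit the full polymorphism summary of an ambigrammatic alignment
#'
#' The central entry point: builds the consensus, enumerates per-locus
#' variant sets, and computes the nucleotide-level statistics and the
#' codon-level statistics and ORF-wide dN/dS for both read directions.
#'
#' @inheritParams nucleotide_stats
#' @param alpha transition/transversion rate ratio used in the codon-level
#'   null expectations; defaults to the `2 N_n / N_v` estimate from the
#'   alignment itself.
#' @param kappa transition/transversion ratio for the dN/dS opportunity
#'   weighting (default 2).
#' @param counting variant counting convention, see [codon_stats()].
#' @return object of class `"ambigram_polymorphism"`: list with elements
#'   `alignment`, `consensus`, `variant_sets`, `nucleotide`
#'   (a `"nucleotide_stats"`), `codon` (list `forward`/`complement` of
#'   `"codon_stats"`), `dnds` (list `forward`/`complement`), `alpha`,
#'   `kappa`, `counting`.
#' @seealso [hotspot_test()], [dsyn_test()] which consume the fitted object.
#' @examples
#' sim <- evolve_alignment(simulation_config(M = 10, N = 60, mu = 0.02,
#'                                           seed = 1))
#' fit <- ambigram_polymorphism(sim$alignment)
#' fit
#' @export
ambigram_polymorphism <- function(aln, alpha = NULL, kappa = 2,
                                  counting = c("distinct", "occurrence")) {
  stopifnot(inherits(aln, "codon_alignment"))
  counting <- match.arg(counting)
  consensus <- build_consensus(aln)
  nuc <- nucleotide_stats(aln, consensus)
  if (is.null(alpha)) {
    alpha <- nuc$alpha
    if (is.na(alpha) || alpha <= 0) {
      stop("alpha cannot be estimated from this alignment (Nv = ", nuc$N_v,
           "); supply alpha explicitly")
    }
  }
  vs <- codon_variant_sets(aln, consensus)
  cs <- lapply(c(forward = "forward", complement = "complement"),
               function(d) codon_stats(vs, d, alpha = alpha,
                                       counting = counting))
  dd <- lapply(c(forward = "forward", complement = "complement"),
               function(d) dnds_orfwide(vs, d, kappa = kappa))
  structure(list(alignment = aln, consensus = consensus, variant_sets = vs,
                 nucleotide = nuc, codon = cs, dnds = dd, alpha = alpha,
                 kappa = kappa, counting = counting),
            class = "ambigram_polymorphism")
}

#' @export
print.ambigram_polymorphism <- function(x, digits = 3, ...) {
  cat("Ambigrammatic-gene polymorphism fit\n")
  print(x$nucleotide, digits = digits)
  for (d in c("forward", "complement")) {
    cs <- x$codon[[d]]
    cat(sprintf("  %-10s Nsy=%d Nns=%d Nmult=%d R=%s R_exp=%s R/R_exp=%s dN/dS=%s\n",
                d, cs$N_sy, cs$N_ns, cs$N_mult, signif(cs$R, digits),
                signif(cs$R_exp, digits), signif(cs$R_over_Rexp, digits),
                signif(x$dnds[[d]]$dnds, digits)))
  }
  invisible(x)
}

#' @export
summary.ambigram_polymorphism <- function(object, ...) {
  ds <- ds_loci(object$consensus)
  out <- list(fit = object, n_ds_loci = length(ds),
              n_variable_loci = sum(object$variant_sets$summary$n > 0))
  class(out) <- "summary.ambigram_polymorphism"
  out
}

#' @export
print.summary.ambigram_polymorphism <- function(x, ...) {
  print(x$fit)
  cat("  doubly synonymous loci:", x$n_ds_loci, "of", x$fit$consensus$N,
      "; variable loci:", x$n_variable_loci, "\n")
  invisible(x)
}

#' @export
coef.ambigram_polymorphism <- function(object, ...) {
  n <- object$nucleotide
  c(r = n$r, alpha = n$alpha,
    R_fwd = object$codon$forward$R,
    R_exp_fwd = object$codon$forward$R_exp,
    R_over_Rexp_fwd = object$codon$forward$R_over_Rexp,
    R_comp = object$codon$complement$R,
    R_exp_comp = object$codon$complement$R_exp,
    R_over_Rexp_comp = object$codon$complement$R_over_Rexp,
    dnds_fwd = object$dnds$forward$dnds,
    dnds_comp = object$dnds$complement$dnds)
}

#' Tabulate a polymorphism fit
#'
#' @param x an `"ambigram_polymorphism"` fit.
#' @param row.names,optional,... ignored (S3 signature).
#' @return one-row data frame in nucleotide-table column order
#'   (`N, M, Nn, Nv, r, alpha, n1, n2, n3, z1, z2, z3`) followed by the
#'   per-direction codon statistics.
#' @export
as.data.frame.ambigram_polymorphism <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  n <- x$nucleotide
  base <- data.frame(N = n$N, M = n$M, Nn = n$N_n, Nv = n$N_v, r = n$r,
                     alpha = n$alpha, n1 = n$n1, n2 = n$n2, n3 = n$n3,
                     z1 = n$z1, z2 = n$z2, z3 = n$z3)
  for (d in c("forward", "complement")) {
    cs <- x$codon[[d]]
    sfx <- if (d == "forward") "fwd" else "comp"
    add <- data.frame(cs$N_sy, cs$N_ns, cs$N_mult, cs$R, cs$R_exp,
                      cs$R_over_Rexp, cs$f_mult, x$dnds[[d]]$dnds)
    names(add) <- paste0(c("Nsy_", "Nns_", "Nmult_", "R_", "Rexp_",
                           "R_over_Rexp_", "fmult_", "dnds_"), sfx)
    base <- cbind(base, add)
  }
  base
}
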