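#' Random ambigrammatic sequence
#'
#' Draws N random sense codons and repairs any codon whose aligned reverse
#' complement is a stop by a random synonymous single-nucleotide fix
#' ([stop_fixes()]), so the result has no stop codon in either aligned
#' frame.
#'
#' @param N number of codons.
#' @param seed optional RNG seed (omit to use the current RNG stream).
#' @return a single RNA string of length `3N`.
#' @export
random_ambigram <- function(N, seed = NULL) {
  stopifnot(N >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tb <- .code()
  sense <- tb$codons[tb$translate != "STOP"]
  cods <- sample(sense, N, replace = TRUE)
  bad <- which(tb$comp_translate[cods] == "STOP")
  for (i in bad) {
    fx <- stop_fixes(cods[i])
    cods[i] <- if (length(fx) == 1L) fx else sample(fx, 1L)
  }
  paste(cods, collapse = "")
}

#' Simulation configuration
#'
#' Parameters of the star-phylogeny sequence-evolution simulator.  `mu` is
#' the expected number of *proposed* single-base substitutions per site per
#' lineage (the accepted rate is lower under selective regimes, since
#' selection is applied by proposal rejection).  The default divergence
#' `mu = 0.01` corresponds to the low within-species divergence
#' (`r ~ 0.005-0.015`) typical of sampled ambigrammatic narnavirus genomes.
#'
#' @param M number of descendant sequences (>= 2).
#' @param N number of codons.
#' @param mu expected proposed substitutions per site per lineage.
#' @param kappa transition/transversion rate ratio of the Kimura model
#'   (a proposal is a transition with probability `kappa / (kappa + 2)`).
#' @param regime `"neutral"` (all proposals accepted), `"forward_purifying"`
#'   (only proposals preserving the forward amino acid accepted) or
#'   `"dual_purifying"` (only proposals preserving the amino acid in both
#'   aligned frames accepted).
#' @param keep_ambigrammatic reject proposals creating a stop codon in
#'   either aligned frame (default TRUE, matching the observation that
#'   sampled genomes carry no internal stops in either direction).
#' @param seed optional integer seed.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(M = 50L, N = 500L, mu = 0.01, kappa = 2,
                              regime = c("neutral", "forward_purifying",
                                         "dual_purifying"),
                              keep_ambigrammatic = TRUE, seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(M >= 2L, N >= 1L, mu >= 0, kappa > 0)
  structure(list(M = as.integer(M), N = as.integer(N), mu = mu,
                 kappa = kappa, regime = regime,
                 keep_ambigrammatic = isTRUE(keep_ambigrammatic),
                 seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config: M =", x$M, ", N =", x$N, ", mu =", x$mu,
      ", kappa =", x$kappa, ", regime =", x$regime,
      ", keep_ambigrammatic =", x$keep_ambigrammatic,
      if (!is.null(x$seed)) paste(", seed =", x$seed) else "", "\n")
  invisible(x)
}

#' Evolve an alignment from a common ambigrammatic ancestor
#'
#' Generates a random ambigrammatic ancestor and `M` independent
#' descendants (star phylogeny).  Each descendant accumulates
#' `Poisson(mu * 3N)` proposed single-base mutations; a proposal picks a
#' site uniformly, draws a transition with probability
#' `kappa / (kappa + 2)` and otherwise one of the two transversions, and is
#' accepted according to the selection regime (and, if
#' `keep_ambigrammatic`, only if it creates no stop in either aligned
#' frame).  Selection always compares against the *current* codon, so a
#' descendant's accepted mutations compose within codons.
#'
#' @param config a [simulation_config()].
#' @return object of class `"simulated_alignment"`: list with `ancestor`
#'   (RNA string), `alignment` (a [codon_alignment]), `log` (per-sequence
#'   data frames of accepted mutations: `site`, `locus`, `from`, `to`,
#'   `class`), `n_proposed`, `n_accepted`, `config`.
#' @export
evolve_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tb <- .code()
  anc <- random_ambigram(config$N)
  L <- 3L * config$N
  anc_chars <- strsplit(anc, "")[[1]]
  ts_partner <- c(A = "G", G = "A", C = "U", U = "C")
  p_ts <- config$kappa / (config$kappa + 2)
  seqs <- character(config$M)
  logs <- vector("list", config$M)
  n_prop <- integer(config$M); n_acc <- integer(config$M)

  for (m in seq_len(config$M)) {
    x <- anc_chars
    nmut <- stats::rpois(1L, config$mu * L)
    n_prop[m] <- nmut
    lg <- list()
    for (j in seq_len(nmut)) {
      site <- sample.int(L, 1L)
      cur <- x[site]
      new <- if (stats::runif(1L) < p_ts) ts_partner[[cur]]
      else sample(setdiff(tb$bases, c(cur, ts_partner[[cur]])), 1L)
      locus <- ((site - 1L) %/% 3L) + 1L
      pos <- site - 3L * (locus - 1L)
      old_codon <- paste(x[(3L * locus - 2L):(3L * locus)], collapse = "")
      new_chars <- x[(3L * locus - 2L):(3L * locus)]
      new_chars[pos] <- new
      new_codon <- paste(new_chars, collapse = "")
      if (config$keep_ambigrammatic &&
          (tb$translate[new_codon] == "STOP" ||
           tb$comp_translate[new_codon] == "STOP")) next
      ok <- switch(config$regime,
        neutral = TRUE,
        forward_purifying =
          tb$translate[new_codon] == tb$translate[old_codon],
        dual_purifying =
          tb$translate[new_codon] == tb$translate[old_codon] &&
          tb$comp_translate[new_codon] == tb$comp_translate[old_codon])
      if (!ok) next
      x[site] <- new
      lg[[length(lg) + 1L]] <- data.frame(
        site = site, locus = locus, from = cur, to = new,
        class = if (new == ts_partner[[cur]]) "transition" else "transversion",
        stringsAsFactors = FALSE)
    }
    seqs[m] <- paste(x, collapse = "")
    logs[[m]] <- if (length(lg)) do.call(rbind, lg)
    else data.frame(site = integer(0), locus = integer(0),
                    from = character(0), to = character(0),
                    class = character(0))
    n_acc[m] <- nrow(logs[[m]])
  }
  ids <- paste0("sim_", seq_len(config$M))
  names(seqs) <- ids; names(logs) <- ids
  structure(list(ancestor = anc,
                 alignment = codon_alignment(seqs, ids = ids),
                 log = logs, n_proposed = n_prop, n_accepted = n_acc,
                 config = config),
            class = "simulated_alignment")
}

#' @export
print.simulated_alignment <- function(x, ...) {
  cat("Simulated alignment (", x$config$regime, " regime): M =",
      x$config$M, ", N =", x$config$N, "\n")
  cat("  proposed mutations:", sum(x$n_proposed),
      ", accepted:", sum(x$n_accepted), "\n")
  invisible(x)
}
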