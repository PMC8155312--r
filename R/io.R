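#' Write an analysis result to TSV or JSON
#'
#' TSV output uses fixed column orders mirroring the package's report
#' tables (nucleotide statistics: `N, M, Nn, Nv, r, alpha, n1, n2, n3, z1,
#' z2, z3`; mutation-frequency test: `N, Na, Ns, Nd, R, R0, R_over_R0`).
#' JSON output round-trips all fields.
#'
#' @param x a result object (`nucleotide_stats`, `codon_stats`,
#'   `ambigram_polymorphism`, `ambigram_hotspot`, `ambigram_dsyn`,
#'   `ambigram_dnds`, or a scanner hit data frame).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- report_row(x)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(.report_fields(x), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Internal: full field list for JSON serialization.
.report_fields <- function(x) {
  if (is.data.frame(x)) return(x)
  out <- unclass(x)
  out$alignment <- NULL            # containers are not serialized
  drop <- vapply(out, function(e) is.environment(e) ||
                   inherits(e, "codon_alignment"), logical(1))
  out[!drop]
}

#' Tabular row(s) of a result object
#'
#' @param x a result object accepted by [write_report()].
#' @return a data frame with the fixed report column order for that result
#'   type.
#' @export
report_row <- function(x) UseMethod("report_row")

#' @export
report_row.data.frame <- function(x) x

#' @export
report_row.nucleotide_stats <- function(x) {
  data.frame(N = x$N, M = x$M, Nn = x$N_n, Nv = x$N_v, r = x$r,
             alpha = x$alpha, n1 = x$n1, n2 = x$n2, n3 = x$n3,
             z1 = x$z1, z2 = x$z2, z3 = x$z3)
}

#' @export
report_row.codon_stats <- function(x) {
  data.frame(direction = x$direction, Nsy = x$N_sy, Nns = x$N_ns,
             Nmult = x$N_mult, R = x$R, R_exp = x$R_exp,
             R_over_Rexp = x$R_over_Rexp, fmult = x$f_mult)
}

#' @export
report_row.ambigram_polymorphism <- function(x) as.data.frame(x)

#' @export
report_row.ambigram_hotspot <- function(x) {
  data.frame(N = x$N, Nds = x$N_ds, mean_n_ds = x$mean_n_ds,
             mean_n_other = x$mean_n_other, mean_f_ds = x$mean_f_ds,
             mean_f_other = x$mean_f_other, Rn = x$R_n, Rf = x$R_f)
}

#' @export
report_row.ambigram_dsyn <- function(x) {
  data.frame(N = x$N, Na = x$N_a, Ns = x$N_s, Nd = x$N_d, R = x$R,
             R0 = x$R0, R_over_R0 = x$R_over_R0)
}

#' @export
report_row.ambigram_dnds <- function(x) {
  data.frame(direction = x$direction, kappa = x$kappa, dnds = x$dnds,
             Nns_obs = x$N_ns_obs, Nsy_obs = x$N_sy_obs)
}

#' @export
report_row.synonym_profile <- function(x) as.data.frame(unclass(x))

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector (or a `simulated_alignment`,
#'   whose descendant sequences are written).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "simulated_alignment")) {
    aln <- sequences$alignment
    sequences <- structure(apply(aln$mat, 1L, paste, collapse = ""),
                           names = aln$ids)
  }
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
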