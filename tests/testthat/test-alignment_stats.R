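# Consensus construction, variant sets, and polymorphism statistics.

test_that("codon_alignment normalizes, trims, and validates input", {
  a <- codon_alignment(c("acgtacg", "ACGTACG"), frame_offset = 1)
  expect_equal(a$M, 2)
  expect_equal(a$N, 2)                      # 6 usable nt after offset 1
  expect_equal(a$mat[1, ], c("C", "G", "U", "A", "C", "G"))
  expect_error(codon_alignment("ACG"), "at least 2")
  expect_error(codon_alignment(c(x = "ACGACG", y = "ACGAC")), "y")
})

test_that("consensus takes the modal base with A<C<G<U tie-break", {
  a <- codon_alignment(rep("AUGCCA", 3))
  cons <- build_consensus(a)
  expect_equal(cons$codons, c("AUG", "CCA"))
  # columns (A,A,G), (C,C,C), (U,G,U) -> ACU
  a2 <- codon_alignment(c("ACU", "ACG", "GCU"))
  expect_equal(build_consensus(a2)$codons, "ACU")
  # tie (A,G) with M = 2 resolves to A
  a3 <- codon_alignment(c("AAA", "GAA"))
  expect_equal(build_consensus(a3)$codons, "AAA")
  # a column of only gaps is an error naming the column
  a4 <- codon_alignment(c("A-G", "A-G"))
  expect_error(build_consensus(a4), "2")
})

test_that("select_frame minimizes internal stops with smallest-offset ties", {
  expect_equal(select_frame("AUGGCU"), 0L)
  # frame 0 is stop-free while frames 1 and 2 each hit an internal UAA
  s <- "GUAAGUAAGUAAG"
  expect_equal(select_frame(s), 0L)
  # prepending one base makes frame 1 the clean parse
  expect_equal(select_frame(paste0("G", s)), 1L)
  # a tie goes to the smallest offset
  expect_equal(select_frame("AAAAAAAAA"), 0L)
})

test_that("nucleotide stats count single-base codon differences", {
  # identical sequences: everything zero, alpha undefined
  a0 <- codon_alignment(rep("AUGCGA", 4))
  n0 <- nucleotide_stats(a0)
  expect_equal(n0$N_n + n0$N_v, 0)
  expect_equal(n0$r, 0)
  expect_true(is.na(n0$alpha))
  expect_true(is.na(n0$z1))

  # 3 sequences x 2 codons with one transition at codon position 3
  a <- codon_alignment(c("AAACCC", "AAACCC", "AAACCU"))
  ns <- nucleotide_stats(a)
  expect_equal(ns$N_n, 1)
  expect_equal(ns$N_v, 0)
  expect_equal(c(ns$n1, ns$n2, ns$n3), c(0, 0, 1))
  expect_equal(c(ns$z1, ns$z2, ns$z3), c(0, 0, 3))
  expect_equal(ns$r, 1 / (3 * 2 * 3))
  expect_true(is.na(ns$alpha))               # no transversions observed

  # z normalization holds whenever defined
  set.seed(7)
  sim <- evolve_alignment(simulation_config(M = 12, N = 80, mu = 0.02,
                                            seed = 7))
  nz <- nucleotide_stats(sim$alignment)
  expect_equal(nz$z1 + nz$z2 + nz$z3, 3)
  expect_equal(nz$alpha, 2 * nz$N_n / nz$N_v)
})

test_that("codon variant sets enumerate distinct non-consensus codons", {
  a0 <- codon_alignment(rep("AUGCGA", 4))
  vs0 <- codon_variant_sets(a0)
  expect_equal(vs0$summary$n, c(0, 0))
  expect_equal(vs0$summary$f, c(0, 0))

  # locus column {AGG x4, CGG, AGA} plus a constant locus
  rows <- list(c("AGG", "AAA"), c("AGG", "AAA"), c("AGG", "AAA"),
               c("AGG", "AAA"), c("CGG", "AAA"), c("AGA", "AAA"))
  a <- codon_alignment(seqs_from_codons(rows))
  vs <- codon_variant_sets(a)
  expect_equal(vs$summary$consensus, c("AGG", "AAA"))
  expect_equal(vs$summary$n, c(2, 0))
  expect_equal(vs$summary$f, c(2 / 6, 0))
  v <- vs$variants
  expect_setequal(v$codon, c("CGG", "AGA"))
  expect_true(all(v$syn_fwd))                # both are Arg
  expect_equal(v$class[v$codon == "CGG"], "transversion")
  expect_equal(v$class[v$codon == "AGA"], "transition")
  expect_true(all(vs$summary$f <= 1))
})

test_that("ambiguous codons are skipped without shrinking the denominator", {
  rows <- list(c("AGG", "CAA"), c("AGG", "CAA"), c("A-G", "CAA"),
               c("CGG", "CAA"))
  a <- codon_alignment(seqs_from_codons(rows))
  vs <- codon_variant_sets(a)
  expect_equal(vs$summary$skipped, c(1L, 0L))
  expect_equal(vs$summary$n, c(1, 0))        # the gapped sequence contributes nothing
  expect_equal(vs$summary$f, c(1 / 4, 0))    # denominator stays M = 4
  ns <- nucleotide_stats(a)
  expect_equal(ns$N_n + ns$N_v, 1)           # only the CGG cell counts
})

test_that("codon stats split synonymy by direction and reproduce R_exp", {
  rows <- list(c("AGG", "AAA", "GGG"), c("AGG", "AAA", "GGG"),
               c("AGA", "AAA", "GGG"), c("AGG", "AAG", "GGG"))
  a <- codon_alignment(seqs_from_codons(rows))
  vs <- codon_variant_sets(a)
  cs <- codon_stats(vs, "forward", alpha = 2)
  # AGA is synonymous (Arg), AAG synonymous (Lys)
  expect_equal(cs$N_sy, 2); expect_equal(cs$N_ns, 0)
  expect_equal(cs$N_mult, 0); expect_equal(cs$f_mult, 0)
  expect_equal(cs$R, 0)
  # complement direction: AGA -> UCU (Ser) vs consensus AGG -> CCU (Pro):
  # non-synonymous; AAG -> CUU (Leu) vs AAA -> UUU (Phe): non-synonymous
  cc <- codon_stats(vs, "complement", alpha = 2)
  expect_equal(cc$N_sy, 0); expect_equal(cc$N_ns, 2)
  expect_true(is.na(cc$R))

  # R_exp equals the brute-force 9-neighbor enumeration, both directions
  for (alpha in c(0.5, 1, 2)) {
    for (dir in c("forward", "complement")) {
      got <- codon_stats(vs, dir, alpha = alpha)$R_exp
      expect_equal(got, o_Rexp(vs$summary$consensus, alpha, dir),
                   tolerance = 1e-12)
    }
  }
  # with alpha = 1 R_exp is simply (total nonsyn)/(total syn) neighbors
  ops <- sapply(vs$summary$consensus, o_opportunity, direction = "forward")
  expect_equal(codon_stats(vs, "forward", alpha = 1)$R_exp,
               sum(ops["n_n", ] + ops["n_v", ]) / sum(ops["s_n", ] + ops["s_v", ]))
})

test_that("a consensus without synonymous opportunity is an error", {
  a <- codon_alignment(c("AUG", "AUG", "AUG"))    # Met has no synonym
  vs <- codon_variant_sets(a)
  expect_error(codon_stats(vs, "forward", alpha = 2), "opportunity")
})

test_that("occurrence counting weights variants by carriers", {
  a <- codon_alignment(c("AGG", "AGG", "AGG", "AGA", "AGA"))
  vs <- codon_variant_sets(a)
  expect_equal(vs$summary$consensus, "AGG")
  expect_equal(codon_stats(vs, "forward", alpha = 2)$N_sy, 1)
  expect_equal(codon_stats(vs, "forward", alpha = 2,
                           counting = "occurrence")$N_sy, 2)
})

test_that("ORF-wide dN/dS matches R/R_exp on single-nucleotide-only data", {
  rows <- list(c("CAA", "AAA", "CGA", "GGG"),
               c("CAA", "AAA", "CGA", "GGG"),
               c("CAG", "AAC", "CGA", "GGG"),
               c("CAA", "AAA", "AGA", "GGG"))
  a <- codon_alignment(seqs_from_codons(rows))
  vs <- codon_variant_sets(a)
  expect_true(all(vs$variants$ndiff == 1))
  for (dir in c("forward", "complement")) {
    cs <- codon_stats(vs, dir, alpha = 3)
    dd <- dnds_orfwide(vs, dir, kappa = 3)
    expect_equal(dd$dnds, cs$R_over_Rexp, tolerance = 1e-12)
  }
  # no mutations at all: undefined
  a0 <- codon_alignment(rep("CAACGA", 3))
  expect_true(is.na(dnds_orfwide(codon_variant_sets(a0), "forward")$dnds))
  # purely synonymous variants: dN/dS = 0
  a1 <- codon_alignment(c("CAAAAA", "CAGAAA", "CAAAAA"))
  expect_equal(dnds_orfwide(codon_variant_sets(a1), "forward")$dnds, 0)
})

test_that("counting is consistent between nucleotide and codon levels", {
  set.seed(5)
  for (seed in 1:3) {
    sim <- evolve_alignment(simulation_config(M = 15, N = 100, mu = 0.02,
                                              seed = seed))
    cons <- build_consensus(sim$alignment)
    ns <- nucleotide_stats(sim$alignment, cons)
    vs <- codon_variant_sets(sim$alignment, cons)
    cod <- ambigram:::.codon_matrix(sim$alignment)
    consm <- matrix(cons$codons, nrow = nrow(cod), ncol = ncol(cod),
                    byrow = TRUE)
    nd <- mapply(function(a, b) sum(substring(a, 1:3, 1:3) !=
                                      substring(b, 1:3, 1:3)), cod, consm)
    expect_equal(ns$N_n + ns$N_v, sum(nd == 1))
    cs <- codon_stats(vs, "forward", alpha = 2)
    single <- vs$variants$ndiff == 1
    expect_equal(cs$N_sy + cs$N_ns, sum(single))
    expect_equal(cs$N_mult, sum(!single))
  }
})

test_that("the polymorphism fit assembles all statistics coherently", {
  sim <- evolve_alignment(simulation_config(M = 20, N = 150, mu = 0.015,
                                            seed = 99))
  fit <- ambigram_polymorphism(sim$alignment)
  expect_s3_class(fit, "ambigram_polymorphism")
  expect_equal(fit$alpha, fit$nucleotide$alpha)
  expect_equal(fit$codon$forward$R_exp,
               o_Rexp(fit$consensus$codons, fit$alpha, "forward"),
               tolerance = 1e-10)
  cf <- coef(fit)
  expect_equal(unname(cf["alpha"]), fit$alpha)
  df <- as.data.frame(fit)
  expect_equal(df$Nsy_fwd, fit$codon$forward$N_sy)
  expect_output(print(fit), "polymorphism fit")
})
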