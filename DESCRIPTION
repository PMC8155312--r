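Package: ambigram
Title: Polymorphism Tests for Ambigrammatic Viral Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of codon-aligned sequence sets from ambigrammatic
    viral genes, i.e. genes carrying an open reading frame on both the
    forward strand and the codon-aligned reverse complement, as found in
    narnaviruses.  Enumerates the single and double synonyms of the
    standard genetic code, computes nucleotide- and codon-level
    polymorphism statistics (transition/transversion ratio, synonymous
    versus non-synonymous variant counts, ORF-wide dN/dS), and provides
    two tests of whether the reverse open reading frame is under
    protein-level purifying selection: a mutational-hotspot test over
    doubly synonymous loci and a doubly-synonymous mutation-frequency
    test compared against a Kimura two-parameter null.  Also includes a
    scanner for ambigrammatic regions in contigs and a star-phylogeny
    sequence-evolution simulator with explicit selection regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
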