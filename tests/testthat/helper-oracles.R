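## Independent brute-force codon enumerator: expands all 64 codons and
## filters by an IUPAC letter table written out by hand here, translating
## with the standard genetic code table from Biostrings.
brute_force_codon <- function(letters) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  all64 <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                             b2 = c("A", "C", "G", "T"),
                             b3 = c("A", "C", "G", "T"),
                             stringsAsFactors = FALSE),
                 1, paste, collapse = "")
  ls <- strsplit(letters, "")[[1]]
  keep <- vapply(all64, function(cd) {
    b <- strsplit(cd, "")[[1]]
    b[1] %in% iupac[[ls[1]]] && b[2] %in% iupac[[ls[2]]] &&
      b[3] %in% iupac[[ls[3]]]
  }, logical(1))
  codons <- all64[keep]
  aa <- Biostrings::GENETIC_CODE[codons]
  list(n = length(codons), aas = sort(unique(aa[aa != "*"])),
       stops = sum(aa == "*"), codons = sort(unname(codons)))
}
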