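## Degenerate-codon focused-library mathematics: codon expansion against the
## standard genetic code, exact diversity products, stop fractions, coverage
## probabilities, site-saturation panels and oligo emission.
##
## Diversity products are computed in double precision, which represents
## integers exactly up to 2^53 -- far beyond any codon-library diversity
## (6 NNS positions: 32^6 ~ 1.07e9).

#' Expand a degenerate codon against the standard genetic code
#'
#' @param letters 3-character string of IUPAC nucleotide codes (e.g. "NNS").
#' @return a `DegenerateCodon`: letters, `expansion` (concrete codons),
#'   `aa_multiplicity` (named integer vector, amino acid -> codon count),
#'   `stop_count`.
#' @export
expand_degenerate_codon <- function(letters) {
  letters <- toupper(letters)
  if (nchar(letters) != 3L) stop("a codon has 3 letters, got: ", letters)
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(letters, "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  per_letter <- lapply(chars, function(ch) strsplit(map[[ch]], "")[[1]])
  grid <- expand.grid(per_letter[[3]], per_letter[[2]], per_letter[[1]],
                      stringsAsFactors = FALSE)
  codons <- paste0(grid[[3]], grid[[2]], grid[[1]])
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_count <- sum(aa == "*")
  aa_mult <- table(aa[aa != "*"])
  out <- list(letters = letters, expansion = codons,
              aa_multiplicity = stats::setNames(as.integer(aa_mult),
                                                names(aa_mult)),
              stop_count = as.integer(stop_count))
  stopifnot(length(out$expansion) ==
              prod(vapply(per_letter, length, integer(1))),
            sum(out$aa_multiplicity) + out$stop_count ==
              length(out$expansion))
  class(out) <- "DegenerateCodon"
  out
}

#' Design a focused degenerate-codon library
#'
#' @param positions character vector of randomized position labels (residue
#'   keys), or a data.frame with columns `key` and `native_aa`.
#' @param scheme degenerate codon applied at every position (default "NNS":
#'   32 codons, all 20 amino acids, one stop).
#' @param target_size intended number of transformants/phages (the reference
#'   campaign used 1e6-1e7 for 6 positions).
#' @return a `LibraryDesign`: positions, per-position codon scheme,
#'   `dna_diversity`, `protein_diversity`, `stop_free_dna_fraction`,
#'   `target_library_size`, and a coverage summary under the uniform
#'   sampling model.
#' @export
design_library <- function(positions, scheme = "NNS", target_size = 1e6) {
  if (is.data.frame(positions)) {
    keys <- positions$key
    natives <- positions$native_aa
  } else {
    keys <- positions
    natives <- rep(NA_character_, length(positions))
  }
  if (!length(keys)) stop("zero positions")
  codon <- expand_degenerate_codon(scheme)
  n <- length(keys)
  dna_div <- length(codon$expansion)^n
  prot_div <- length(codon$aa_multiplicity)^n
  stop_free <- (1 - codon$stop_count / length(codon$expansion))^n
  cov <- coverage_probability(dna_div, target_size)
  out <- list(
    positions = data.frame(key = keys, native_aa = natives,
                           scheme = scheme, stringsAsFactors = FALSE),
    codon = codon,
    dna_diversity = dna_div,
    protein_diversity = prot_div,
    stop_free_dna_fraction = stop_free,
    target_library_size = target_size,
    coverage = cov)
  class(out) <- "LibraryDesign"
  out
}

#' @export
print.LibraryDesign <- function(x, ...) {
  cat("LibraryDesign:", nrow(x$positions), "positions x", x$codon$letters,
      "\n  DNA diversity:", format(x$dna_diversity, big.mark = ","),
      "| protein diversity:", format(x$protein_diversity, big.mark = ","),
      sprintf("| stop-free fraction: %.4f", x$stop_free_dna_fraction),
      "\n  target size:", format(x$target_library_size, big.mark = ","),
      sprintf("| P(specific DNA variant sampled): %.4g",
              x$coverage["p_specific_variant_present"]), "\n")
  invisible(x)
}

#' Library coverage under uniform sampling
#'
#' Probability that a specific variant is present among `N` uniform draws
#' from `D` equiprobable variants: `p = 1 - (1 - 1/D)^N`; under uniformity
#' this also equals the expected fraction of the diversity covered. The
#' Poisson approximation `1 - exp(-N/D)` is reported alongside, flagged as
#' such.
#'
#' @param D diversity (>= 1).
#' @param N number of transformants (>= 0).
#' @return named numeric vector: `p_specific_variant_present`,
#'   `expected_fraction_covered`, `p_poisson_approx`.
#' @export
coverage_probability <- function(D, N) {
  if (D < 1) stop("D must be >= 1")
  if (N < 0) stop("N must be >= 0")
  p <- 1 - (1 - 1 / D)^N
  c(p_specific_variant_present = p,
    expected_fraction_covered = p,
    p_poisson_approx = 1 - exp(-N / D))
}

#' Site-saturation variant panel for one position
#'
#' @param position residue key or label of the saturated position.
#' @param native_aa native amino acid (1- or 3-letter).
#' @param include_native include the native amino acid (20 specs) or not
#'   (19 specs).
#' @return data.frame of variant specs ordered alphabetically by one-letter
#'   code: position, native_aa, substitution_aa (3-letter), substitution_1.
#' @export
saturation_panel <- function(position, native_aa, include_native = TRUE) {
  native3 <- aa_three(native_aa)
  aas <- unname(AA_STANDARD)  # already alphabetical by 1-letter code
  if (!include_native) aas <- setdiff(aas, native3)
  data.frame(position = position, native_aa = native3,
             substitution_aa = aas, substitution_1 = aa_one(aas),
             stringsAsFactors = FALSE)
}

#' Substitute degenerate codons into an oligonucleotide template
#'
#' @param template_dna nucleotide string (A/C/G/T), in frame from
#'   `frame_offset`.
#' @param positions integer vector of randomized codon numbers (1-based,
#'   counted from the reading frame start; all user-facing coordinates in
#'   this package are 1-based).
#' @param scheme degenerate codon to substitute (default "NNS").
#' @param frame_offset 0-based offset of the reading frame start within the
#'   template (default 0).
#' @return an `OligoTemplate`: template_dna, substituted_oligo, positions,
#'   scheme, frame_offset.
#' @export
emit_oligos <- function(template_dna, positions, scheme = "NNS",
                        frame_offset = 0L) {
  template_dna <- toupper(template_dna)
  if (!grepl("^[ACGT]+$", template_dna))
    stop("template must contain only A/C/G/T")
  n_codons <- (nchar(template_dna) - frame_offset) %/% 3L
  if (n_codons < 1L) stop("template shorter than one codon after frame offset")
  bad <- positions[positions < 1L | positions > n_codons]
  if (length(bad))
    stop("codon position(s) outside template frame: ",
         paste(bad, collapse = ", "))
  oligo <- strsplit(template_dna, "")[[1]]
  for (p in positions) {
    start <- frame_offset + (p - 1L) * 3L + 1L
    oligo[start:(start + 2L)] <- strsplit(scheme, "")[[1]]
  }
  out <- list(template_dna = template_dna,
              substituted_oligo = paste(oligo, collapse = ""),
              positions = sort(unique(as.integer(positions))),
              scheme = scheme, frame_offset = as.integer(frame_offset))
  class(out) <- "OligoTemplate"
  out
}
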