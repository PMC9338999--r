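## Rotamer library: modal chi-angle tuples with prior frequencies, shipped as
## a plain-text table and validated on load.

#' Load the packaged rotamer library
#'
#' Backbone-independent library of modal side-chain chi angles. Every
#' flexible standard amino acid has at least one entry and per-amino-acid
#' frequencies sum to 1.
#'
#' @param path optional path to an alternative library table (same columns:
#'   aa3, chi1..chi4, freq, tab-separated, `#` comments).
#' @return a `RotamerLibrary`: data.frame with one row per rotamer.
#' @export
default_rotlib <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rotamers.tsv", package = "abrescue",
                        mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("aa3", "chi1", "chi2", "chi3", "chi4", "freq") %in%
                  names(tab)))
  flexible <- setdiff(AA_STANDARD, AA_INFLEXIBLE)
  missing_aa <- setdiff(flexible, tab$aa3)
  if (length(missing_aa))
    stop("rotamer library lacks entries for: ",
         paste(missing_aa, collapse = ", "))
  sums <- tapply(tab$freq, tab$aa3, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("rotamer frequencies do not sum to 1 for: ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  class(tab) <- c("RotamerLibrary", "data.frame")
  tab
}

## Chi tuples for one amino acid as a list of numeric vectors (trimmed to the
## amino acid's chi count).
rotamer_chis <- function(rotlib, aa3) {
  aa3 <- aa_three(aa3)
  ## proline's ring is built with one fixed pucker, never chi-searched
  if (aa3 == "PRO") return(list(c(-26, 37)))
  nch <- n_chi(aa3)
  if (nch == 0L) return(list(numeric(0)))
  rows <- rotlib[rotlib$aa3 == aa3, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i)
    as.numeric(rows[i, paste0("chi", seq_len(nch))]))
}
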