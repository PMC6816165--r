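# Internal helpers shared across modules.

#' Reverse complement of nucleotide strings
#'
#' Complements IUPAC nucleotide codes and reverses each string. Case is
#' preserved, so soft-masked (lowercase) bases stay lowercase.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp("ACGTn")
revcomp <- function(x) {
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  stringi::stri_reverse(comp)
}

# Width of the union of 0-based half-open intervals.
union_width <- function(start, end) {
  if (!length(start)) return(0)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1, end))))
}

# Per-reference-sequence union widths (named, sorted by reference id).
ref_union_widths <- function(aln) {
  if (!nrow(aln)) return(setNames(numeric(0), character(0)))
  vapply(split(aln, aln$rname), function(a) union_width(a$rstart, a$rend),
         numeric(1))
}

# Total overlap (bp) between one 0-based half-open interval and a set of
# intervals on the same sequence.
interval_overlap <- function(start, end, set_start, set_end) {
  if (!length(set_start)) return(0)
  sum(pmax(0, pmin(end, set_end) - pmax(start, set_start)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
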