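# Alignment production and filtering: minimap2 wrapper, reference-coverage
# computation, unique-anchor filtering, and primary-alignment selection.
# All tie-breaks are deterministic so repeated runs are bit-identical.

#' Aligner configuration
#'
#' Defaults follow the scaffolding setup: k-mer size and minimizer window
#' size both 19 bp, single thread. A minimap2 preset may be layered first
#' (`-x` is emitted before `-k`/`-w`, so the explicit sizes win).
#'
#' @param kmer_size Minimizer k-mer size in bp (default 19).
#' @param window_size Minimizer window size in bp (default 19).
#' @param threads Worker threads (default 1).
#' @param preset Optional minimap2 preset name (e.g. `"asm5"`).
#' @param extra Additional command-line arguments, verbatim.
#' @return List of class `aligner_config`.
#' @export
aligner_config <- function(kmer_size = 19L, window_size = 19L, threads = 1L,
                           preset = NULL, extra = character()) {
  stopifnot(kmer_size >= 1, window_size >= 1, threads >= 1)
  structure(list(kmer_size = as.integer(kmer_size),
                 window_size = as.integer(window_size),
                 threads = as.integer(threads),
                 preset = preset, extra = extra),
            class = "aligner_config")
}

minimap2_args <- function(reference, query, config = aligner_config(),
                          cigar = TRUE) {
  c(if (!is.null(config$preset)) c("-x", config$preset),
    "-k", config$kmer_size, "-w", config$window_size,
    if (cigar) "-c",
    "-t", config$threads,
    config$extra, reference, query)
}

#' Align a query assembly to a reference with minimap2
#'
#' Thin wrapper around the external `minimap2` binary. The whole pipeline
#' also accepts a user-supplied PAF file (see [read_paf()] and the `paf`
#' argument of [align_to_reference()]), so an aligner binary is never a
#' hard requirement.
#'
#' @param reference,query Paths to FASTA files.
#' @param out_paf Output PAF path (default: a temporary file).
#' @param config [aligner_config()].
#' @param cigar Request base-level alignments (`-c`, emits the `cg:Z` tag
#'   needed for within-alignment variant calling). Default `TRUE`.
#' @param binary Name or path of the aligner executable.
#' @return Path of the PAF file produced.
#' @export
run_minimap2 <- function(reference, query, out_paf = tempfile(fileext = ".paf"),
                         config = aligner_config(), cigar = TRUE,
                         binary = "minimap2") {
  exe <- Sys.which(binary)
  if (!nzchar(exe))
    stop("aligner binary '", binary, "' was not found on PATH; either ",
         "install it or supply precomputed alignments as a PAF file ",
         "(read_paf() / the 'paf' argument of the pipeline functions)")
  if (!file.exists(reference)) stop("no such file: ", reference)
  if (!file.exists(query)) stop("no such file: ", query)
  status <- system2(exe, minimap2_args(reference, query, config, cigar),
                    stdout = out_paf, stderr = FALSE)
  if (status != 0) stop("minimap2 exited with status ", status)
  out_paf
}

#' Obtain alignments from a PAF file or by running the aligner
#'
#' Canonical entry point used by the pipeline: if `paf` is given the file
#' is read as-is, otherwise `reference` and `query` (paths or named
#' sequence vectors) are aligned with minimap2.
#'
#' @param reference,query FASTA paths or named character vectors of
#'   sequences (written to temporary files when needed).
#' @param paf Optional path to a precomputed PAF file; when supplied the
#'   aligner is not invoked.
#' @param config [aligner_config()].
#' @param min_len Minimum alignment block length retained (default 1000).
#' @param cigar Request base-level alignments when invoking the aligner.
#' @return Alignment data.frame (see [read_paf()]).
#' @export
align_to_reference <- function(reference, query, paf = NULL,
                               config = aligner_config(), min_len = 1000,
                               cigar = TRUE) {
  if (!is.null(paf)) return(read_paf(paf, min_len = min_len))
  as_path <- function(x, what) {
    if (length(x) == 1 && is.character(x) && is.null(names(x)) &&
        file.exists(x)) return(x)
    p <- tempfile(pattern = what, fileext = ".fa")
    write_fasta(x, p)
    p
  }
  rp <- as_path(reference, "ref")
  qp <- as_path(query, "qry")
  read_paf(run_minimap2(rp, qp, config = config, cigar = cigar),
           min_len = min_len)
}

#' Reference coverage of an alignment set
#'
#' Coverage is the number of reference base pairs covered by at least one
#' alignment, i.e. the size of the union of the reference intervals, per
#' reference sequence.
#'
#' @param aln Alignment data.frame.
#' @param restrict Optional character vector of reference ids to restrict
#'   to before computing.
#' @return List with `per_ref` (named numeric, sorted by reference id) and
#'   `total` (sum over reference sequences).
#' @export
alignment_coverage <- function(aln, restrict = NULL) {
  if (!is.null(restrict)) aln <- aln[aln$rname %in% restrict, , drop = FALSE]
  per <- ref_union_widths(aln)
  list(per_ref = per, total = sum(per))
}

#' Unique-anchor filtering of a contig's alignments
#'
#' Alignments are visited in decreasing order of block length (ties broken
#' by query start, reference id, reference start); each is accepted iff at
#' least `min_unique` of its query positions are not covered by the union
#' of the query intervals of previously accepted alignments. With
#' `min_unique = 0` the filter is the identity.
#'
#' @param aln Alignment data.frame; multiple contigs are filtered
#'   independently per `qname`.
#' @param min_unique Minimum novel query bp an alignment must contribute.
#' @return The accepted alignments, sorted by (`qname`, `qstart`, `qend`).
#' @export
unique_anchor_filter <- function(aln, min_unique) {
  stopifnot(min_unique >= 0)
  if (!nrow(aln)) return(aln)
  one <- function(a) {
    ord <- order(-a$alen, a$qstart, a$rname, a$rstart)
    covered <- IRanges::IRanges()
    keep <- logical(nrow(a))
    for (i in ord) {
      ir <- IRanges::IRanges(a$qstart[i] + 1, a$qend[i])
      novel <- (a$qend[i] - a$qstart[i]) -
        sum(IRanges::width(IRanges::intersect(ir, covered)))
      if (novel >= min_unique) {
        keep[i] <- TRUE
        covered <- IRanges::reduce(c(covered, ir))
      }
    }
    a[keep, , drop = FALSE]
  }
  parts <- lapply(split(aln, aln$qname), one)
  out <- do.call(rbind, parts)
  out <- out[order(out$qname, out$qstart, out$qend), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Primary alignment of a contig to its assigned chromosome
#'
#' The longest alignment (by block length) between the contig and the
#' assigned reference chromosome; ties broken by larger match count, then
#' smaller reference start.
#'
#' @param aln Alignment data.frame for one contig.
#' @param assigned_chromosome Reference id the contig was clustered to.
#' @return A single-row alignment data.frame.
#' @export
primary_alignment <- function(aln, assigned_chromosome) {
  sub <- aln[aln$rname == assigned_chromosome, , drop = FALSE]
  if (!nrow(sub))
    stop("contig ", aln$qname[1] %||% "?",
         " has no alignments to assigned chromosome ", assigned_chromosome)
  sub[order(-sub$alen, -sub$nmatch, sub$rstart), , drop = FALSE][1, ]
}
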