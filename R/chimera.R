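# Chimeric-contig detection and correction. A contig joining sequence
# from two reference chromosomes (interchromosomal) or from distant loci
# of one chromosome (intrachromosomal) is broken at the discordance; the
# fragments concatenate back to the original sequence exactly, so no
# sequence content is ever added or removed. Breakpoints falling inside
# protected intervals (e.g. gene models from a GFF3) suppress the break.

#' Chimera-detection configuration
#'
#' Interchromosomal detection keeps alignments of at least `min_aln_len`
#' (default 10 kbp), unique-anchor filters them at `unique_anchor_min`,
#' and declares a chimera when at least two reference chromosomes each
#' hold at least `cluster_fraction` (default 5%) of the total alignment
#' length while covering at least `min_ref_span` (default 100 kbp) of
#' that chromosome. Intrachromosomal detection breaks when consecutive
#' alignments (in reference order) are separated by more than
#' `intra_ref_dist` on the reference or `intra_qry_dist` on the contig;
#' these distance cutoffs are deliberately large (2 Mbp) so that ordinary
#' structural variants do not trigger breaks.
#'
#' @param min_aln_len Minimum alignment block length in bp (default 10000).
#' @param cluster_fraction Minimum fraction of total alignment length a
#'   chromosome must hold to qualify (default 0.05).
#' @param min_ref_span Minimum covered bp on a qualifying chromosome
#'   (default 1e5).
#' @param intra_ref_dist,intra_qry_dist Distance thresholds in bp for
#'   intrachromosomal breaks (default 2e6 each).
#' @param unique_anchor_min Unique-anchor threshold in bp (default 10000).
#' @return List of class `chimera_config`.
#' @export
chimera_config <- function(min_aln_len = 10000, cluster_fraction = 0.05,
                           min_ref_span = 1e5, intra_ref_dist = 2e6,
                           intra_qry_dist = 2e6, unique_anchor_min = 10000) {
  stopifnot(min_aln_len >= 0, cluster_fraction > 0, cluster_fraction <= 1,
            min_ref_span >= 0, intra_ref_dist >= 0, intra_qry_dist >= 0,
            unique_anchor_min >= 0)
  structure(list(min_aln_len = min_aln_len,
                 cluster_fraction = cluster_fraction,
                 min_ref_span = min_ref_span,
                 intra_ref_dist = intra_ref_dist,
                 intra_qry_dist = intra_qry_dist,
                 unique_anchor_min = unique_anchor_min),
            class = "chimera_config")
}

chimera_prefilter <- function(aln, config) {
  aln <- aln[aln$alen >= config$min_aln_len, , drop = FALSE]
  if (!nrow(aln)) return(aln)
  unique_anchor_filter(aln, config$unique_anchor_min)
}

#' Detect an interchromosomal chimera in one contig
#'
#' @param aln Alignment data.frame holding all alignments of one contig.
#' @param config [chimera_config()].
#' @return `NULL`, or a one-row data.frame `contig, position, kind` with
#'   the 0-based breakpoint placed at the end of the query interval of
#'   the last alignment before the chromosome transition.
#' @export
detect_interchromosomal <- function(aln, config = chimera_config()) {
  f <- chimera_prefilter(aln, config)
  if (nrow(f) < 2) return(NULL)
  tot <- sum(f$alen)
  alen_by_ref <- vapply(split(f$alen, f$rname), sum, numeric(1))
  cov_by_ref <- ref_union_widths(f)
  qual <- names(alen_by_ref)[alen_by_ref >= config$cluster_fraction * tot &
                               cov_by_ref[names(alen_by_ref)] >=
                                 config$min_ref_span]
  if (length(qual) < 2) return(NULL)
  q <- f[f$rname %in% qual, , drop = FALSE]
  q <- q[order(q$qstart, q$qend), , drop = FALSE]
  trans <- which(q$rname[-1] != q$rname[-nrow(q)])
  if (!length(trans)) return(NULL)
  pos <- q$qend[trans[1]]
  qlen <- q$qlen[1]
  if (pos <= 0 || pos >= qlen) return(NULL)
  data.frame(contig = q$qname[1], position = pos,
             kind = "interchromosomal", stringsAsFactors = FALSE)
}

#' Detect an intrachromosomal chimera in one contig
#'
#' Alignments to the dominant (most covered) chromosome are sorted by
#' reference start then end; the contig is broken between the first
#' consecutive pair whose reference gap exceeds `intra_ref_dist` or whose
#' absolute query gap exceeds `intra_qry_dist`, at the midpoint of the
#' unaligned query interval.
#'
#' @inheritParams detect_interchromosomal
#' @return `NULL` or a one-row breakpoint data.frame.
#' @export
detect_intrachromosomal <- function(aln, config = chimera_config()) {
  f <- chimera_prefilter(aln, config)
  if (nrow(f) < 2) return(NULL)
  cov <- ref_union_widths(f)
  dom <- names(cov)[order(-cov, names(cov))][1]
  d <- f[f$rname == dom, , drop = FALSE]
  if (nrow(d) < 2) return(NULL)
  d <- d[order(d$rstart, d$rend), , drop = FALSE]
  rgap <- d$rstart[-1] - d$rend[-nrow(d)]
  qgap <- abs(d$qstart[-1] - d$qend[-nrow(d)])
  hit <- which(rgap > config$intra_ref_dist | qgap > config$intra_qry_dist)
  if (!length(hit)) return(NULL)
  i <- hit[1]
  lo <- min(d$qend[i], d$qstart[i + 1])
  hi <- max(d$qend[i], d$qstart[i + 1])
  pos <- (lo + hi) %/% 2
  qlen <- d$qlen[1]
  pos <- max(1, min(qlen - 1, pos))
  data.frame(contig = d$qname[1], position = pos,
             kind = "intrachromosomal", stringsAsFactors = FALSE)
}

in_protected <- function(contig, position, protected) {
  if (is.null(protected) || !nrow(protected)) return(FALSE)
  p <- protected[protected$seqid == contig, , drop = FALSE]
  any(position >= p$start & position < p$end)
}

#' Break contigs at chimera breakpoints
#'
#' Fragments are named `<id>_chimera_broken:<start>-<end>` and their
#' in-order concatenation equals the original contig exactly. Breakpoints
#' inside a protected interval are discarded (the contig is left intact)
#' and reported.
#'
#' @param contig_seqs Named character vector of contigs.
#' @param breaks data.frame `contig, position, kind` (0-based positions,
#'   strictly inside the contig).
#' @param protected Optional data.frame `seqid, start, end` of 0-based
#'   half-open intervals that must not contain a breakpoint (e.g. from
#'   [read_gff_intervals()] after lifting to contig coordinates).
#' @return List with `seqs` (new contig set, broken contigs replaced in
#'   place), `applied` (breaks that were made, with fragment names), and
#'   `suppressed` (breaks discarded by protection).
#' @export
apply_breaks <- function(contig_seqs, breaks, protected = NULL) {
  if (is.null(breaks) || !nrow(breaks))
    return(list(seqs = contig_seqs,
                applied = data.frame(contig = character(0),
                                     position = numeric(0),
                                     kind = character(0)),
                suppressed = breaks))
  unknown <- setdiff(breaks$contig, names(contig_seqs))
  if (length(unknown)) stop("breakpoint for unknown contig ", unknown[1])
  lens <- nchar(contig_seqs)[breaks$contig]
  if (any(breaks$position <= 0 | breaks$position >= lens))
    stop("breakpoint out of range for contig ",
         breaks$contig[which(breaks$position <= 0 |
                               breaks$position >= lens)[1]])
  prot <- vapply(seq_len(nrow(breaks)), function(i)
    in_protected(breaks$contig[i], breaks$position[i], protected),
    logical(1))
  suppressed <- breaks[prot, , drop = FALSE]
  if (nrow(suppressed))
    message("suppressed ", nrow(suppressed),
            " breakpoint(s) inside protected intervals")
  breaks <- breaks[!prot, , drop = FALSE]
  out <- list()
  for (id in names(contig_seqs)) {
    b <- breaks[breaks$contig == id, , drop = FALSE]
    if (!nrow(b)) {
      out[[id]] <- contig_seqs[[id]]
      next
    }
    cuts <- sort(unique(b$position))
    bounds <- c(0, cuts, nchar(contig_seqs[[id]]))
    for (j in seq_len(length(bounds) - 1)) {
      nm <- sprintf("%s_chimera_broken:%d-%d", id, bounds[j], bounds[j + 1])
      out[[nm]] <- substr(contig_seqs[[id]], bounds[j] + 1, bounds[j + 1])
    }
  }
  list(seqs = unlist(out), applied = breaks, suppressed = suppressed)
}

# alignments of a contig restricted to a fragment [lo, hi), rebased to
# fragment coordinates; alignments straddling the cut are dropped.
fragment_alignments <- function(aln, lo, hi) {
  a <- aln[aln$qstart >= lo & aln$qend <= hi, , drop = FALSE]
  if (!nrow(a)) return(a)
  a$qstart <- a$qstart - lo
  a$qend <- a$qend - lo
  a$qlen <- hi - lo
  a
}

#' One round of chimeric-contig correction
#'
#' For every contig, interchromosomal detection runs first; the
#' intrachromosomal detector then runs on the (putative) fragments'
#' alignments. At most one break of each kind is made per contig per
#' round, so nested chimeras may require additional rounds (with
#' realignment in between). The pass is a fixed point on chimera-free
#' assemblies.
#'
#' @param contig_seqs Named character vector of contigs.
#' @param aln Alignment data.frame for all contigs.
#' @param config [chimera_config()].
#' @param protected Optional protected intervals (see [apply_breaks()]).
#' @param realign Optional function `(seqs) -> alignment data.frame` used
#'   to realign the corrected contigs and report the mean clustering
#'   confidence before/after correction.
#' @return List with `seqs`, `breaks` (applied), `suppressed`, and
#'   `confidence` (`NULL` unless `realign` is supplied: a data.frame with
#'   mean clustering confidence before and after).
#' @export
correction_round <- function(contig_seqs, aln, config = chimera_config(),
                             protected = NULL, realign = NULL) {
  by_q <- split(aln, aln$qname)
  breaks <- list()
  for (id in intersect(names(contig_seqs), names(by_q))) {
    a <- by_q[[id]]
    inter <- detect_interchromosomal(a, config)
    if (!is.null(inter) && in_protected(id, inter$position, protected))
      inter <- NULL   # suppressed later by apply_breaks for reporting
    frag_bounds <- if (!is.null(inter))
      list(c(0, inter$position), c(inter$position, nchar(contig_seqs[[id]])))
    else list(c(0, nchar(contig_seqs[[id]])))
    intra <- NULL
    for (fb in frag_bounds) {
      fa <- fragment_alignments(a, fb[1], fb[2])
      hit <- detect_intrachromosomal(fa, config)
      if (!is.null(hit)) {
        hit$position <- hit$position + fb[1]
        intra <- hit
        break
      }
    }
    found <- do.call(rbind, Filter(Negate(is.null),
                                   list(detect_interchromosomal(a, config),
                                        intra)))
    if (!is.null(found)) breaks[[id]] <- found
  }
  breaks <- if (length(breaks)) do.call(rbind, breaks) else NULL
  res <- apply_breaks(contig_seqs, breaks, protected)
  confidence <- NULL
  if (!is.null(realign)) {
    before <- cluster_contigs(aln, names(contig_seqs))
    after <- cluster_contigs(realign(res$seqs), names(res$seqs))
    confidence <- data.frame(
      stage = c("before", "after"),
      mean_clustering_confidence = c(mean(before$clustering_confidence),
                                     mean(after$clustering_confidence)))
  }
  list(seqs = res$seqs, breaks = res$applied, suppressed = res$suppressed,
       confidence = confidence)
}
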