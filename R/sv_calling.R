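# Assembly-based structural-variant calling from query-to-reference
# alignments: indels read off base-level alignment operations
# (within-alignment calls) and gap-discrepancy events between consecutive
# alignments of the same query (between-alignment calls), followed by
# gap-overlap annotation, multi-sample merging by breakpoint proximity,
# and presence/absence summaries.

sv_types_expansion <- c("Insertion", "Tandem_expansion", "Repeat_expansion")

#' Structural-variant calling configuration
#'
#' @param min_size Minimum variant size in bp (default 20).
#' @param max_size Maximum variant size in bp (default 1e5).
#' @param unique_anchor_min Unique-anchor threshold in bp applied to the
#'   alignments before between-alignment calling (default 10000).
#' @param max_gap_fraction Variants whose span overlaps gaps by more than
#'   this fraction are removed by [filter_gap_svs()] (default 0.10).
#' @param excluded_refs Reference ids whose variants are dropped before
#'   merging (e.g. "Chr0" and organellar sequences).
#' @return List of class `sv_config`.
#' @export
sv_config <- function(min_size = 20, max_size = 1e5,
                      unique_anchor_min = 10000, max_gap_fraction = 0.10,
                      excluded_refs = character()) {
  stopifnot(min_size > 0, min_size <= max_size, unique_anchor_min >= 0,
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  structure(list(min_size = min_size, max_size = max_size,
                 unique_anchor_min = unique_anchor_min,
                 max_gap_fraction = max_gap_fraction,
                 excluded_refs = excluded_refs),
            class = "sv_config")
}

empty_sv <- function() {
  data.frame(reference = character(0), ref_start = numeric(0),
             ref_end = numeric(0), query = character(0),
             query_start = numeric(0), query_end = numeric(0),
             size = numeric(0), strand = character(0), type = character(0),
             source = character(0), gap_overlap_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

parse_cigar <- function(tags) {
  m <- regmatches(tags, regexpr("cg:Z:[0-9MIDNSHP=X]+", tags))
  if (!length(m)) return(NULL)
  body <- sub("^cg:Z:", "", m)
  ops <- regmatches(body, gregexpr("[0-9]+[MIDNSHP=X]", body))[[1]]
  list(len = as.numeric(sub("[A-Z=]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

#' Call structural variants within alignments
#'
#' Reads insertion/deletion operations of size `min_size`..`max_size`
#' directly off the base-level alignment (the `cg:Z` CIGAR tag of each
#' PAF record). Reference coordinates walk forward from `rstart`; query
#' coordinates walk forward from `qstart` on plus-strand alignments and
#' backward from `qend` on minus-strand alignments.
#'
#' @param aln Alignment data.frame whose `tags` carry `cg:Z` CIGARs.
#' @param config [sv_config()].
#' @return SV data.frame (see [call_svs()]); alignments without base-level
#'   operations are skipped with a single warning.
#' @export
call_within_alignments <- function(aln, config = sv_config()) {
  if (!nrow(aln)) return(empty_sv())
  out <- list()
  missing_cg <- 0L
  for (i in seq_len(nrow(aln))) {
    cg <- parse_cigar(aln$tags[i])
    if (is.null(cg)) {
      missing_cg <- missing_cg + 1L
      next
    }
    rconsume <- cg$op %in% c("M", "=", "X", "D", "N")
    qconsume <- cg$op %in% c("M", "=", "X", "I")
    rpos <- aln$rstart[i] + cumsum(cg$len * rconsume) - cg$len * rconsume
    qoff <- cumsum(cg$len * qconsume) - cg$len * qconsume
    plus <- aln$strand[i] == "+"
    qpos <- if (plus) aln$qstart[i] + qoff else aln$qend[i] - qoff
    sel <- which((cg$op == "I" | cg$op == "D") &
                   cg$len >= config$min_size & cg$len <= config$max_size)
    if (!length(sel)) next
    ins <- cg$op[sel] == "I"
    len <- cg$len[sel]
    qs <- ifelse(ins, if (plus) qpos[sel] else qpos[sel] - len, qpos[sel])
    qe <- ifelse(ins, if (plus) qpos[sel] + len else qpos[sel], qpos[sel])
    out[[length(out) + 1]] <- data.frame(
      reference = aln$rname[i], ref_start = rpos[sel],
      ref_end = ifelse(ins, rpos[sel], rpos[sel] + len),
      query = aln$qname[i],
      query_start = pmin(qs, qe), query_end = pmax(qs, qe),
      size = len, strand = aln$strand[i],
      type = ifelse(ins, "Insertion", "Deletion"),
      source = "within_alignment", gap_overlap_fraction = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (missing_cg == nrow(aln) && nrow(aln))
    warning("no alignments carry base-level operations (cg:Z tag); ",
            "within-alignment SV calling skipped")
  if (!length(out)) return(empty_sv())
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

classify_between <- function(query_gap, ref_gap) {
  if (ref_gap >= 0 && query_gap >= 0) {
    if (query_gap > ref_gap) "Insertion" else "Deletion"
  } else if (ref_gap < 0 && query_gap >= 0) {
    "Tandem_expansion"
  } else if (query_gap < 0 && ref_gap >= 0) {
    "Tandem_contraction"
  } else {
    if (query_gap > ref_gap) "Repeat_expansion" else "Repeat_contraction"
  }
}

#' Call structural variants between consecutive alignments
#'
#' Alignments of each query are unique-anchor filtered and sorted by
#' query position; every consecutive pair on the same reference sequence
#' and strand defines a query gap and a (strand-adjusted) reference gap.
#' The absolute gap discrepancy is the variant size; the sign pattern of
#' the two gaps determines the type (insertion/deletion when neither
#' coordinate system overlaps, tandem expansion/contraction when exactly
#' one does, repeat expansion/contraction when both do).
#'
#' @inheritParams call_within_alignments
#' @return SV data.frame with `source == "between_alignments"`.
#' @export
call_between_alignments <- function(aln, config = sv_config()) {
  if (!nrow(aln)) return(empty_sv())
  f <- unique_anchor_filter(aln, config$unique_anchor_min)
  out <- list()
  for (a in split(f, f$qname)) {
    if (nrow(a) < 2) next
    a <- a[order(a$qstart, a$qend), , drop = FALSE]
    for (i in seq_len(nrow(a) - 1)) {
      p <- a[i, ]; nx <- a[i + 1, ]
      if (p$rname != nx$rname || p$strand != nx$strand) next
      query_gap <- nx$qstart - p$qend
      ref_gap <- if (p$strand == "+") nx$rstart - p$rend
                 else p$rstart - nx$rend
      size <- abs(query_gap - ref_gap)
      if (size < config$min_size || size > config$max_size) next
      rb <- if (p$strand == "+") c(p$rend, nx$rstart) else c(nx$rend, p$rstart)
      out[[length(out) + 1]] <- data.frame(
        reference = p$rname, ref_start = min(rb), ref_end = max(rb),
        query = p$qname, query_start = min(p$qend, nx$qstart),
        query_end = max(p$qend, nx$qstart), size = size,
        strand = p$strand, type = classify_between(query_gap, ref_gap),
        source = "between_alignments", gap_overlap_fraction = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_sv())
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotate variants with their fractional overlap against gaps
#'
#' Alignments may traverse sequencing gaps in either assembly, so each
#' variant reports the fraction of its span made of `N` gap sequence:
#' deletions and contractions use their reference span against the
#' reference gaps; insertions and expansions use their query span against
#' the query gaps. Zero-width spans get fraction 0.
#'
#' @param svs SV data.frame.
#' @param ref_gaps,query_gaps Gap tables from [find_gaps()] on the
#'   reference and query sequences (either may be `NULL` for none).
#' @return `svs` with `gap_overlap_fraction` filled in.
#' @export
annotate_gap_overlap <- function(svs, ref_gaps = NULL, query_gaps = NULL) {
  if (!nrow(svs)) return(svs)
  svs$gap_overlap_fraction <- vapply(seq_len(nrow(svs)), function(i) {
    expansion <- svs$type[i] %in% sv_types_expansion
    if (expansion) {
      span <- c(svs$query_start[i], svs$query_end[i])
      g <- query_gaps[query_gaps$seqid == svs$query[i], , drop = FALSE]
    } else {
      span <- c(svs$ref_start[i], svs$ref_end[i])
      g <- ref_gaps[ref_gaps$seqid == svs$reference[i], , drop = FALSE]
    }
    w <- span[2] - span[1]
    if (w <= 0 || is.null(g) || !nrow(g)) return(0)
    interval_overlap(span[1], span[2], g$start, g$end) / w
  }, numeric(1))
  svs
}

#' Drop variants spanning too much gap sequence
#'
#' @param svs SV data.frame with `gap_overlap_fraction` annotated.
#' @param max_fraction Maximum tolerated gap-overlap fraction (default
#'   0.10).
#' @return Filtered SV data.frame.
#' @export
filter_gap_svs <- function(svs, max_fraction = 0.10) {
  svs[is.na(svs$gap_overlap_fraction) |
        svs$gap_overlap_fraction <= max_fraction, , drop = FALSE]
}

#' Call, annotate, and filter structural variants
#'
#' Combines within- and between-alignment calling, gap-overlap
#' annotation, and the optional gap filter; variants on excluded
#' reference sequences are dropped.
#'
#' @param aln Alignment data.frame (CIGARs required for within-alignment
#'   calls).
#' @param config [sv_config()].
#' @param ref_gaps,query_gaps Optional gap tables (see
#'   [annotate_gap_overlap()]).
#' @param apply_gap_filter Drop variants exceeding
#'   `config$max_gap_fraction` (default `TRUE`).
#' @return SV data.frame sorted by reference position.
#' @export
call_svs <- function(aln, config = sv_config(), ref_gaps = NULL,
                     query_gaps = NULL, apply_gap_filter = TRUE) {
  svs <- rbind(call_within_alignments(aln, config),
               call_between_alignments(aln, config))
  svs <- svs[!(svs$reference %in% config$excluded_refs), , drop = FALSE]
  svs <- annotate_gap_overlap(svs, ref_gaps, query_gaps)
  if (apply_gap_filter) svs <- filter_gap_svs(svs, config$max_gap_fraction)
  svs <- svs[order(svs$reference, svs$ref_start, svs$ref_end, svs$type), ,
             drop = FALSE]
  rownames(svs) <- NULL
  svs
}

#' Merge structural variants across samples
#'
#' Variants of the same type and reference sequence (and strand, when
#' `strand_aware`) are linked whenever both their start and end
#' breakpoints lie within `max_dist` of each other; merged variants are
#' the connected components of that relation (transitive chains allowed).
#' Size similarity is not required. The representative coordinates of a
#' merged variant are those of its largest member (ties: smallest start,
#' then sample id). With `min_support = 1` the result is the union of the
#' call sets; with `min_support` equal to the number of samples, their
#' intersection.
#'
#' @param sv_tables Named list of per-sample SV data.frames.
#' @param max_dist Maximum distance between breakpoints in bp (default
#'   1000).
#' @param min_support Minimum number of supporting samples (default 1).
#' @param strand_aware Separate merge groups by strand (default `TRUE`).
#' @param excluded_refs Reference ids dropped before merging.
#' @return data.frame of merged variants: `variant_id, reference,
#'   ref_start, ref_end, size, type, strand, n_support, samples`
#'   (comma-separated sample ids), with the member rows in
#'   `attr(, "members")`.
#' @export
merge_svs <- function(sv_tables, max_dist = 1000, min_support = 1,
                      strand_aware = TRUE, excluded_refs = character()) {
  stopifnot(length(names(sv_tables)) == length(sv_tables))
  all <- do.call(rbind, lapply(names(sv_tables), function(s) {
    x <- sv_tables[[s]]
    if (!nrow(x)) return(NULL)
    x$sample <- s
    x
  }))
  if (is.null(all) || !nrow(all)) {
    out <- data.frame(variant_id = character(0), reference = character(0),
                      ref_start = numeric(0), ref_end = numeric(0),
                      size = numeric(0), type = character(0),
                      strand = character(0), n_support = numeric(0),
                      samples = character(0), stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  all <- all[!(all$reference %in% excluded_refs), , drop = FALSE]
  all$grp <- paste(all$type, all$reference,
                   if (strand_aware) all$strand else "", sep = "\r")
  merged <- list()
  members <- list()
  for (g in split(all, all$grp)) {
    g <- g[order(g$ref_start, g$ref_end, g$sample), , drop = FALSE]
    n <- nrow(g)
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(n)) {
      j <- i + 1
      while (j <= n && g$ref_start[j] - g$ref_start[i] <= max_dist) {
        if (abs(g$ref_end[j] - g$ref_end[i]) <= max_dist)
          comp[find(j)] <- find(i)
        j <- j + 1
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      m <- g[roots == r, , drop = FALSE]
      rep <- m[order(-m$size, m$ref_start, m$sample), , drop = FALSE][1, ]
      support <- sort(unique(m$sample))
      if (length(support) < min_support) next
      merged[[length(merged) + 1]] <- data.frame(
        reference = rep$reference, ref_start = rep$ref_start,
        ref_end = rep$ref_end, size = rep$size, type = rep$type,
        strand = rep$strand, n_support = length(support),
        samples = paste(support, collapse = ","), stringsAsFactors = FALSE)
      m$grp <- NULL
      members[[length(members) + 1]] <- m
    }
  }
  if (!length(merged)) {
    out <- data.frame(variant_id = character(0), reference = character(0),
                      ref_start = numeric(0), ref_end = numeric(0),
                      size = numeric(0), type = character(0),
                      strand = character(0), n_support = numeric(0),
                      samples = character(0), stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  out <- do.call(rbind, merged)
  ord <- order(out$reference, out$ref_start, out$ref_end, out$type)
  out <- out[ord, , drop = FALSE]
  members <- members[ord]
  out <- cbind(variant_id = sprintf("sv_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Presence/absence matrix of merged variants
#'
#' @param merged Output of [merge_svs()].
#' @param samples Optional character vector fixing the column set and
#'   order; defaults to the union of supporting samples.
#' @return Binary integer matrix, rows = merged variants (named by
#'   `variant_id`), columns = samples. Row sums equal the support counts.
#' @export
presence_matrix <- function(merged, samples = NULL) {
  sup <- strsplit(merged$samples, ",", fixed = TRUE)
  if (is.null(samples)) samples <- sort(unique(unlist(sup)))
  mat <- matrix(0L, nrow = nrow(merged), ncol = length(samples),
                dimnames = list(merged$variant_id, samples))
  for (i in seq_len(nrow(merged))) mat[i, sup[[i]]] <- 1L
  mat
}

#' Count merged variants intersecting genes
#'
#' A merged variant counts for a gene when its reference span (insertion
#' points widened to 1 bp) intersects the gene interval extended by
#' `flank` on both sides. The normalized count divides by gene length.
#'
#' @param merged Output of [merge_svs()].
#' @param genes data.frame `id, seqid, start, end` (0-based half-open),
#'   e.g. from [read_gff_intervals()].
#' @param flank Flank size in bp added both upstream and downstream
#'   (default 2000).
#' @return `genes` with `n_variants` and `normalized_n_variants` columns,
#'   sorted by decreasing count.
#' @export
intersect_genes <- function(merged, genes, flank = 2000) {
  vs <- merged$ref_start
  ve <- pmax(merged$ref_end, merged$ref_start + 1)
  genes$n_variants <- vapply(seq_len(nrow(genes)), function(i) {
    lo <- genes$start[i] - flank
    hi <- genes$end[i] + flank
    sum(merged$reference == genes$seqid[i] & vs < hi & ve > lo)
  }, numeric(1))
  genes$normalized_n_variants <- genes$n_variants /
    (genes$end - genes$start)
  genes[order(-genes$n_variants, genes$id), , drop = FALSE]
}
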