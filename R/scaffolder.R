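# The core method: cluster contigs to reference chromosomes, order and
# orient them, score each placement, and build pseudomolecule sequences.
#
# Contigs that cannot be placed (no alignments, clustering confidence
# below the floor, or explicitly skipped) are pooled in the "Chr0" group
# and emitted unmodified.

CHR0 <- "Chr0"

#' Scaffolding configuration
#'
#' @param min_aln_len Minimum alignment block length in bp used for
#'   clustering/ordering/orienting (default 1000).
#' @param pad_size Number of `N` characters placed between adjacent
#'   contigs in a pseudomolecule (default 100).
#' @param min_cluster_confidence Contigs whose clustering confidence falls
#'   below this floor are left unlocalized in Chr0 (default 0.2).
#' @param excluded_refs Reference ids never used for clustering (e.g. an
#'   unplaced "chromosome 0" in the reference).
#' @param skipped_contigs Contig ids forced into Chr0.
#' @return List of class `scaffold_config`.
#' @export
scaffold_config <- function(min_aln_len = 1000, pad_size = 100,
                            min_cluster_confidence = 0.2,
                            excluded_refs = character(),
                            skipped_contigs = character()) {
  stopifnot(pad_size >= 0, min_cluster_confidence >= 0,
            min_cluster_confidence <= 1, min_aln_len >= 0)
  structure(list(min_aln_len = min_aln_len, pad_size = pad_size,
                 min_cluster_confidence = min_cluster_confidence,
                 excluded_refs = excluded_refs,
                 skipped_contigs = skipped_contigs),
            class = "scaffold_config")
}

filter_alignments <- function(aln, config) {
  aln[aln$alen >= config$min_aln_len &
        !(aln$rname %in% config$excluded_refs), , drop = FALSE]
}

#' Cluster contigs into chromosome groups
#'
#' Each contig is assigned to the reference chromosome it covers the most,
#' where coverage is the number of reference bp covered by at least one
#' alignment. The clustering confidence is the coverage of the assigned
#' chromosome divided by the total covered bp across the whole reference.
#' Ties are broken by the lexicographically smallest reference id.
#'
#' @param aln Alignment data.frame for the whole assembly.
#' @param contig_ids Character vector of all contig ids (contigs without
#'   alignments are reported in Chr0 with confidence 0).
#' @param config [scaffold_config()].
#' @return data.frame with columns `contig, chromosome,
#'   clustering_confidence`.
#' @export
cluster_contigs <- function(aln, contig_ids, config = scaffold_config()) {
  aln <- filter_alignments(aln, config)
  by_q <- split(aln, aln$qname)
  rows <- lapply(contig_ids, function(id) {
    a <- by_q[[id]]
    if (is.null(a) || !nrow(a) || id %in% config$skipped_contigs)
      return(data.frame(contig = id, chromosome = CHR0,
                        clustering_confidence = 0,
                        stringsAsFactors = FALSE))
    cov <- ref_union_widths(a)
    best <- names(cov)[order(-cov, names(cov))][1]
    conf <- unname(cov[best] / sum(cov))
    data.frame(contig = id,
               chromosome = if (conf < config$min_cluster_confidence) CHR0
                            else best,
               clustering_confidence = conf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# location confidence: covered bp within [min rstart, max rend) of the
# contig's alignments to its assigned chromosome, divided by that range.
location_confidence <- function(a) {
  lo <- min(a$rstart); hi <- max(a$rend)
  union_width(a$rstart, a$rend) / (hi - lo)
}

# orientation by a base-pair-weighted strand vote over the alignments to
# the assigned chromosome; exact tie defaults to '+'.
orientation_vote <- function(a) {
  plus <- sum(a$alen[a$strand == "+"])
  minus <- sum(a$alen[a$strand == "-"])
  if (plus >= minus) list(orientation = "+",
                          confidence = plus / (plus + minus))
  else list(orientation = "-", confidence = minus / (plus + minus))
}

#' Order and orient clustered contigs
#'
#' Within each chromosome group contigs are sorted by the reference start,
#' then end, of their primary (longest) alignment, with residual ties
#' broken by contig id. Orientation is the majority of a bp-weighted
#' strand vote. Location and orientation confidences are computed from all
#' alignments to the assigned chromosome.
#'
#' @param aln Alignment data.frame.
#' @param clusters Output of [cluster_contigs()].
#' @param config [scaffold_config()].
#' @return data.frame with one row per contig: `contig, chromosome,
#'   order_index, orientation, clustering_confidence, location_confidence,
#'   orientation_confidence`. Chr0 contigs have `NA` order and orientation
#'   and zero location/orientation confidence.
#' @export
place_contigs <- function(aln, clusters, config = scaffold_config()) {
  aln <- filter_alignments(aln, config)
  by_q <- split(aln, aln$qname)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    id <- clusters$contig[i]
    chrom <- clusters$chromosome[i]
    base <- data.frame(contig = id, chromosome = chrom,
                       order_index = NA_real_, orientation = NA_character_,
                       clustering_confidence = clusters$clustering_confidence[i],
                       location_confidence = 0, orientation_confidence = 0,
                       primary_rstart = NA_real_, primary_rend = NA_real_,
                       stringsAsFactors = FALSE)
    if (chrom == CHR0) return(base)
    a <- by_q[[id]]
    a <- a[a$rname == chrom, , drop = FALSE]
    prim <- primary_alignment(a, chrom)
    vote <- orientation_vote(a)
    base$orientation <- vote$orientation
    base$orientation_confidence <- vote$confidence
    base$location_confidence <- location_confidence(a)
    base$primary_rstart <- prim$rstart
    base$primary_rend <- prim$rend
    base
  })
  out <- do.call(rbind, rows)
  out$order_index <- NA_real_
  for (chrom in setdiff(unique(out$chromosome), CHR0)) {
    sel <- which(out$chromosome == chrom)
    ord <- sel[order(out$primary_rstart[sel], out$primary_rend[sel],
                     out$contig[sel])]
    out$order_index[ord] <- seq_along(ord)
  }
  out$primary_rstart <- NULL
  out$primary_rend <- NULL
  rownames(out) <- NULL
  out
}

#' Build pseudomolecule sequences from contig placements
#'
#' Contigs are concatenated in order with `pad_size` `N` characters
#' between adjacent contigs; minus-oriented contigs are
#' reverse-complemented. No input base is altered, added, or removed.
#' Chr0 contigs are returned individually and unmodified; optionally a
#' single concatenated Chr0 record is built as well.
#'
#' @param contig_seqs Named character vector with every placed contig.
#' @param placements Output of [place_contigs()].
#' @param pad_size Gap padding in bp (default 100).
#' @param chr0_concat Also emit one concatenated `Chr0` record with
#'   `pad_size` gaps (default `FALSE`).
#' @return List with `pseudomolecules` (named character vector, one
#'   `<chromosome>_pseudomolecule` per chromosome with at least one
#'   contig), `chr0` (named character vector of unplaced contigs), and
#'   `agp` (placement table covering the pseudomolecules).
#' @export
build_pseudomolecules <- function(contig_seqs, placements, pad_size = 100,
                                  chr0_concat = FALSE) {
  missing <- setdiff(placements$contig, names(contig_seqs))
  if (length(missing))
    stop("contig ", missing[1], " is present in placements but missing ",
         "from the assembly sequences")
  chroms <- sort(setdiff(unique(placements$chromosome), CHR0))
  pad <- strrep("N", pad_size)
  seqs <- character(0)
  agp <- list()
  for (chrom in chroms) {
    p <- placements[placements$chromosome == chrom, , drop = FALSE]
    p <- p[order(p$order_index), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(p)), function(i) {
      s <- contig_seqs[[p$contig[i]]]
      if (p$orientation[i] == "-") revcomp(s) else s
    }, character(1))
    obj <- paste0(chrom, "_pseudomolecule")
    seqs[obj] <- paste(pieces, collapse = pad)
    pos <- 0
    part <- 0
    for (i in seq_len(nrow(p))) {
      len <- nchar(pieces[i])
      part <- part + 1
      agp[[length(agp) + 1]] <- data.frame(
        object = obj, object_beg = pos + 1, object_end = pos + len,
        part_number = part, component_type = "W",
        component_id = p$contig[i], component_beg = 1, component_end = len,
        orientation = p$orientation[i], gap_length = NA_real_,
        stringsAsFactors = FALSE)
      pos <- pos + len
      if (i < nrow(p) && pad_size > 0) {
        part <- part + 1
        agp[[length(agp) + 1]] <- data.frame(
          object = obj, object_beg = pos + 1, object_end = pos + pad_size,
          part_number = part, component_type = "N",
          component_id = NA_character_, component_beg = NA_real_,
          component_end = NA_real_, orientation = NA_character_,
          gap_length = pad_size, stringsAsFactors = FALSE)
        pos <- pos + pad_size
      }
    }
  }
  agp <- if (length(agp)) do.call(rbind, agp) else empty_placement_table()
  chr0_ids <- placements$contig[placements$chromosome == CHR0]
  chr0 <- contig_seqs[chr0_ids]
  if (chr0_concat && length(chr0))
    seqs[CHR0] <- paste(unname(chr0), collapse = pad)
  list(pseudomolecules = seqs, chr0 = chr0, agp = agp)
}

empty_placement_table <- function() {
  data.frame(object = character(0), object_beg = numeric(0),
             object_end = numeric(0), part_number = numeric(0),
             component_type = character(0), component_id = character(0),
             component_beg = numeric(0), component_end = numeric(0),
             orientation = character(0), gap_length = numeric(0),
             stringsAsFactors = FALSE)
}

#' Scaffold an assembly against a reference
#'
#' End-to-end driver for the core method: cluster, order, orient, score,
#' and build pseudomolecules from an assembly and its alignments.
#'
#' @param contig_seqs Named character vector of assembly contigs.
#' @param aln Alignment data.frame (from [read_paf()] or
#'   [align_to_reference()]).
#' @param config [scaffold_config()].
#' @param chr0_concat Passed to [build_pseudomolecules()].
#' @return List with `placements` (per-contig table incl. the three
#'   confidence scores), `pseudomolecules`, `chr0`, and `agp`.
#' @export
scaffold_assembly <- function(contig_seqs, aln, config = scaffold_config(),
                              chr0_concat = FALSE) {
  clusters <- cluster_contigs(aln, names(contig_seqs), config)
  placements <- place_contigs(aln, clusters, config)
  built <- build_pseudomolecules(contig_seqs, placements,
                                 pad_size = config$pad_size,
                                 chr0_concat = chr0_concat)
  c(list(placements = placements), built)
}
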