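# File formats: FASTA, PAF, AGP, SV tables, GFF3 gene intervals, plus
# gap-interval extraction. Sequences are plain named character vectors so
# that case is preserved verbatim; Biostrings handles the actual FASTA
# parsing and 60-column serialization.

#' Read a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences. Ids are the header text up
#'   to the first whitespace; case of the bases is preserved.
#' @details Duplicate ids are an error; an empty file yields an empty
#'   vector. Multi-line sequence bodies are joined.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate id ", dup[1])
  setNames(as.character(set), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) && length(seqs))
    stop("sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

empty_paf <- function() {
  data.frame(qname = character(0), qlen = numeric(0), qstart = numeric(0),
             qend = numeric(0), strand = character(0), rname = character(0),
             rlen = numeric(0), rstart = numeric(0), rend = numeric(0),
             nmatch = numeric(0), alen = numeric(0), mapq = numeric(0),
             tags = character(0), stringsAsFactors = FALSE)
}

#' Read whole-genome alignments from a PAF file
#'
#' Parses the 12 mandatory PAF columns; any further columns (e.g. the
#' `cg:Z` CIGAR tag used for within-alignment variant calling) are retained
#' verbatim in a `tags` column. Alignments whose block length (column 11)
#' is below `min_len` are removed, matching the default 1 kbp alignment
#' length filter applied before scaffolding.
#'
#' @param path Path to a PAF file.
#' @param min_len Minimum alignment block length in bp (default 1000).
#'   Use 0 to keep everything.
#' @return A data.frame with columns `qname, qlen, qstart, qend, strand,
#'   rname, rlen, rstart, rend, nmatch, alen, mapq, tags`. Coordinates are
#'   0-based half-open exactly as stored in the file.
#' @export
read_paf <- function(path, min_len = 1000) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    i <- which(nf < 12L)[1]
    stop("malformed PAF line ", lineno[i],
         ": expected at least 12 tab-separated fields, found ", nf[i])
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)
  numcol <- function(k, what) {
    v <- suppressWarnings(as.numeric(col(k)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("malformed PAF line ", lineno[i], ": non-numeric ", what)
    }
    v
  }
  paf <- data.frame(
    qname = col(1), qlen = numcol(2, "query length"),
    qstart = numcol(3, "query start"), qend = numcol(4, "query end"),
    strand = col(5), rname = col(6), rlen = numcol(7, "reference length"),
    rstart = numcol(8, "reference start"), rend = numcol(9, "reference end"),
    nmatch = numcol(10, "residue matches"), alen = numcol(11, "block length"),
    mapq = numcol(12, "mapping quality"),
    tags = vapply(fields, function(f)
      if (length(f) > 12L) paste(f[-(1:12)], collapse = "\t") else "",
      character(1)),
    stringsAsFactors = FALSE)
  neg <- paf$qstart < 0 | paf$rstart < 0 | paf$qend < 0 | paf$rend < 0
  if (any(neg))
    stop("malformed PAF line ", lineno[which(neg)[1]], ": negative coordinate")
  bad <- paf$qstart >= paf$qend | paf$rstart >= paf$rend |
    paf$qend > paf$qlen | paf$rend > paf$rlen
  if (any(bad))
    stop("malformed PAF line ", lineno[which(bad)[1]],
         ": invalid interval (need 0 <= start < end <= length)")
  if (!all(paf$strand %in% c("+", "-")))
    stop("malformed PAF line ", lineno[which(!paf$strand %in% c("+", "-"))[1]],
         ": strand must be '+' or '-'")
  if (any(paf$alen <= 0))
    stop("malformed PAF line ", lineno[which(paf$alen <= 0)[1]],
         ": alignment block length must be positive")
  out <- paf[paf$alen >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find gap (N-run) intervals in sequences
#'
#' Locates maximal runs of `N`/`n` characters of length at least `min_run`
#' (default 20 bp, the conventional threshold for a sequencing gap).
#'
#' @param seqs Named character vector of sequences.
#' @param min_run Minimum run length in bp (default 20).
#' @return A data.frame with columns `seqid, start, end` (0-based
#'   half-open), sorted by seqid then start.
#' @export
find_gaps <- function(seqs, min_run = 20L) {
  stopifnot(min_run >= 1)
  if (length(seqs) && is.null(names(seqs))) stop("sequences must be named")
  pat <- sprintf("[Nn]{%d,}", as.integer(min_run))
  out <- lapply(names(seqs), function(id) {
    m <- gregexpr(pat, seqs[[id]], perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(seqid = id, start = as.numeric(m) - 1,
               end = as.numeric(m) - 1 + attr(m, "match.length"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate a placement (AGP) table
#'
#' Checks the tiling invariant: within every object the parts, sorted by
#' part number, start at 1, abut exactly (no overlap, no holes), never put
#' two gap rows next to each other, and have component spans consistent
#' with the object span.
#'
#' @param placements A placement data.frame as produced by
#'   [build_pseudomolecules()] or [read_agp()].
#' @return `placements`, invisibly; errors describe the first violation.
#' @export
validate_placement_table <- function(placements) {
  req <- c("object", "object_beg", "object_end", "part_number",
           "component_type", "component_id", "component_beg",
           "component_end", "orientation", "gap_length")
  if (!all(req %in% names(placements)))
    stop("placement table lacks columns: ",
         paste(setdiff(req, names(placements)), collapse = ", "))
  for (obj in unique(placements$object)) {
    p <- placements[placements$object == obj, , drop = FALSE]
    p <- p[order(p$part_number), , drop = FALSE]
    if (p$object_beg[1] != 1)
      stop("object ", obj, " does not start at position 1")
    if (any(p$object_end < p$object_beg))
      stop("object ", obj, " has an empty or inverted part")
    if (nrow(p) > 1) {
      if (any(p$object_beg[-1] != p$object_end[-nrow(p)] + 1))
        stop("object ", obj, " parts do not tile (hole or overlap)")
      gap <- p$component_type %in% c("N", "U")
      if (any(gap[-1] & gap[-nrow(p)]))
        stop("object ", obj, " has two adjacent gap parts")
    }
    w <- p$component_type == "W"
    span <- p$object_end - p$object_beg + 1
    if (any(w & (p$component_end - p$component_beg + 1 != span)))
      stop("object ", obj, " has a contig part whose component span ",
           "disagrees with its object span")
    if (any(!w & (p$gap_length != span)))
      stop("object ", obj, " has a gap part whose gap length ",
           "disagrees with its object span")
  }
  invisible(placements)
}

#' Write a placement table as AGP v2.1
#'
#' Contig parts are written as component type `W` with 1-based inclusive
#' component coordinates and orientation; gap parts as type `N` (known
#' size, scaffold gap, linkage `yes`). The tiling invariant is validated
#' before anything is written.
#'
#' @param placements Placement data.frame (see
#'   [validate_placement_table()] for the required columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(placements, path) {
  validate_placement_table(placements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(placements)) {
    p <- placements[order(placements$object, placements$part_number), ]
    rows <- vapply(seq_len(nrow(p)), function(i) {
      r <- p[i, ]
      if (r$component_type == "W")
        paste(r$object, r$object_beg, r$object_end, r$part_number, "W",
              r$component_id, r$component_beg, r$component_end,
              r$orientation, sep = "\t")
      else
        paste(r$object, r$object_beg, r$object_end, r$part_number,
              r$component_type, r$gap_length, "scaffold", "yes",
              "align_genus", sep = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an AGP file back into a placement table
#'
#' @param path Path to an AGP v2.1 file written by [write_agp()].
#' @return Placement data.frame (0 rows for a header-only file).
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(object = character(0), object_beg = numeric(0),
                      object_end = numeric(0), part_number = numeric(0),
                      component_type = character(0),
                      component_id = character(0), component_beg = numeric(0),
                      component_end = numeric(0), orientation = character(0),
                      gap_length = numeric(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9))
    stop("malformed AGP line: fewer than 9 columns")
  gap <- vapply(f, `[[`, character(1), 5) %in% c("N", "U")
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  data.frame(
    object = vapply(f, `[[`, character(1), 1),
    object_beg = as.numeric(vapply(f, `[[`, character(1), 2)),
    object_end = as.numeric(vapply(f, `[[`, character(1), 3)),
    part_number = as.numeric(vapply(f, `[[`, character(1), 4)),
    component_type = vapply(f, `[[`, character(1), 5),
    component_id = ifelse(gap, NA_character_,
                          vapply(f, `[[`, character(1), 6)),
    component_beg = ifelse(gap, NA_real_,
                           num_or_na(vapply(f, `[[`, character(1), 7))),
    component_end = ifelse(gap, NA_real_,
                           num_or_na(vapply(f, `[[`, character(1), 8))),
    orientation = ifelse(gap, NA_character_,
                         vapply(f, `[[`, character(1), 9)),
    gap_length = ifelse(gap, num_or_na(vapply(f, `[[`, character(1), 6)),
                        NA_real_),
    stringsAsFactors = FALSE)
}

sv_columns <- c("reference", "ref_start", "ref_end", "query", "query_start",
                "query_end", "size", "strand", "type", "source",
                "gap_overlap_fraction")

#' Write / read a structural-variant table
#'
#' Tab-separated with a header line; coordinates stay 0-based half-open.
#'
#' @param svs Structural-variant data.frame (see [call_svs()]).
#' @param path File path.
#' @return `write_sv_tsv` returns `path` invisibly; `read_sv_tsv` returns
#'   the data.frame.
#' @export
write_sv_tsv <- function(svs, path) {
  missing <- setdiff(sv_columns, names(svs))
  if (length(missing))
    stop("SV table lacks columns: ", paste(missing, collapse = ", "))
  write.table(svs[, sv_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sv_tsv
#' @export
read_sv_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read intervals from a GFF3 (or BED) annotation
#'
#' Only the coordinates are used: the result is suitable for protecting
#' gene loci from chimera breaking and for gene/variant intersection. Full
#' feature-model parsing is out of scope.
#'
#' @param path Path to a GFF3 or BED file (format detected by
#'   `rtracklayer` from the extension).
#' @param feature Optional feature type filter (e.g. `"gene"`); `NULL`
#'   keeps every record.
#' @return data.frame with columns `id, seqid, start, end` (0-based
#'   half-open).
#' @export
read_gff_intervals <- function(path, feature = NULL) {
  gr <- rtracklayer::import(path)
  if (!is.null(feature) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) %in% feature]
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
        else if ("Name" %in% names(mc)) as.character(mc$Name)
        else paste0("feature_", seq_along(gr))
  id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  data.frame(id = id,
             seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}
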