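# Shared fixtures: all synthetic data is generated in code at test time.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One alignment record in the internal PAF representation.
paf_row <- function(qname, qlen, qstart, qend, strand, rname, rlen,
                    rstart, rend, nmatch = NULL, alen = NULL, mapq = 60,
                    tags = "") {
  alen <- alen %||% max(qend - qstart, rend - rstart)
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, rname = rname, rlen = rlen, rstart = rstart,
             rend = rend, nmatch = nmatch %||% alen, alen = alen,
             mapq = mapq, tags = tags, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact alignments reconstructed from a simulation truth table: each
# contig maps end-to-end onto its source interval. Used to test the
# scaffolder independently of any aligner.
truth_to_paf <- function(truth, contig_lengths, chrom_lengths) {
  do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    len <- contig_lengths[[t$id]]
    paf_row(t$id, len, 0, len, t$orientation, t$chromosome,
            chrom_lengths[[t$chromosome]], t$ref_start, t$ref_end,
            tags = sprintf("cg:Z:%dM", len))
  }))
}

# Align sequences with minimap2 (present in the environment), keeping all
# alignments regardless of length.
align_mm2 <- function(genome, query, min_len = 0, cigar = TRUE) {
  rf <- tempfile(fileext = ".fa")
  qf <- tempfile(fileext = ".fa")
  write_fasta(genome, rf)
  write_fasta(query, qf)
  on.exit(unlink(c(rf, qf)))
  read_paf(run_minimap2(rf, qf, cigar = cigar), min_len = min_len)
}

# Per-base boolean-array coverage oracle.
coverage_oracle <- function(aln) {
  refs <- sort(unique(aln$rname))
  per <- vapply(refs, function(r) {
    a <- aln[aln$rname == r, ]
    hit <- logical(max(a$rend))
    for (i in seq_len(nrow(a))) hit[(a$rstart[i] + 1):a$rend[i]] <- TRUE
    sum(hit)
  }, numeric(1))
  list(per_ref = per, total = sum(per))
}

# Brute-force unique-anchor oracle: enumerate acceptance in decreasing
# block-length order using an explicit per-position set.
uaf_oracle <- function(aln, min_unique) {
  ord <- order(-aln$alen, aln$qstart, aln$rname, aln$rstart)
  covered <- integer(0)
  keep <- logical(nrow(aln))
  for (i in ord) {
    pos <- (aln$qstart[i] + 1):aln$qend[i]
    if (length(setdiff(pos, covered)) >= min_unique) {
      keep[i] <- TRUE
      covered <- union(covered, pos)
    }
  }
  out <- aln[keep, , drop = FALSE]
  out <- out[order(out$qname, out$qstart, out$qend), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Full-matrix dynamic-programming edit-distance oracle.
edit_distance_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  d <- matrix(0, m + 1, n + 1)
  d[, 1] <- 0:m
  d[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1, j + 1] <- min(d[i, j] + (a[i] != b[j]), d[i, j + 1] + 1,
                           d[i + 1, j] + 1)
  d[m + 1, n + 1]
}

# Brute-force merge oracle: connected components of the pairwise
# "both breakpoints within max_dist, same type/ref(/strand)" relation.
merge_oracle_components <- function(df, max_dist, strand_aware = TRUE) {
  n <- nrow(df)
  link <- function(i, j) {
    df$type[i] == df$type[j] && df$reference[i] == df$reference[j] &&
      (!strand_aware || df$strand[i] == df$strand[j]) &&
      abs(df$ref_start[i] - df$ref_start[j]) <= max_dist &&
      abs(df$ref_end[i] - df$ref_end[j]) <= max_dist
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && link(i, j)) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}
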