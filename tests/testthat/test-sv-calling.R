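# Structural-variant calling, gap-overlap annotation, multi-sample
# merging, presence/absence matrix, and gene intersection.

cigar_aln <- function(cigar, strand = "+", rstart = 0, qstart = 0,
                      qlen = NULL, rlen_ref = 1e6) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDX=]", cigar))[[1]]
  len <- as.numeric(sub(".$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  qspan <- sum(len[op %in% c("M", "=", "X", "I")])
  rspan <- sum(len[op %in% c("M", "=", "X", "D")])
  qlen <- qlen %||% (qstart + qspan)
  paf_row("q", qlen, qstart, qstart + qspan, strand, "chr1", rlen_ref,
          rstart, rstart + rspan, alen = max(qspan, rspan),
          tags = paste0("cg:Z:", cigar))
}

test_that("within-alignment calls read indels off the CIGAR", {
  svs <- call_within_alignments(cigar_aln("10000M100I10000M"))
  expect_equal(nrow(svs), 1)
  expect_equal(svs$type, "Insertion")
  expect_equal(svs$size, 100)
  expect_equal(svs$ref_start, 10000)
  expect_equal(svs$query_start, 10000)
  expect_equal(svs$query_end, 10100)

  expect_equal(nrow(call_within_alignments(cigar_aln("10000M10I10000M"))), 0)

  del <- call_within_alignments(cigar_aln("5000M300D5000M", rstart = 100))
  expect_equal(del$type, "Deletion")
  expect_equal(del$ref_start, 5100)
  expect_equal(del$ref_end, 5400)

  expect_warning(call_within_alignments(
    paf_row("q", 1e4, 0, 1e4, "+", "chr1", 1e6, 0, 1e4)), "cg:Z")
})

test_that("minus-strand query coordinates match a coordinate-walking oracle", {
  aln <- cigar_aln("4000M250D3000M80I3000M", strand = "-", rstart = 500)
  svs <- call_within_alignments(aln)
  # naive per-op walk: ref forward from rstart, query backward from qend
  rpos <- 500; qpos <- aln$qend
  oracle <- list()
  for (tok in regmatches("4000M250D3000M80I3000M",
                         gregexpr("[0-9]+[MID]", "4000M250D3000M80I3000M"))[[1]]) {
    len <- as.numeric(sub(".$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    if (op == "M") { rpos <- rpos + len; qpos <- qpos - len }
    if (op == "D") {
      oracle[[length(oracle) + 1]] <-
        c(type = "Deletion", ref_start = rpos, q_lo = qpos, q_hi = qpos)
      rpos <- rpos + len
    }
    if (op == "I") {
      oracle[[length(oracle) + 1]] <-
        c(type = "Insertion", ref_start = rpos, q_lo = qpos - len,
          q_hi = qpos)
      qpos <- qpos - len
    }
  }
  oracle <- as.data.frame(do.call(rbind, oracle), stringsAsFactors = FALSE)
  expect_equal(svs$type, oracle$type)
  expect_equal(svs$ref_start, as.numeric(oracle$ref_start))
  expect_equal(svs$query_start, as.numeric(oracle$q_lo))
  expect_equal(svs$query_end, as.numeric(oracle$q_hi))
})

between_pair <- function(query_gap, ref_gap, strand = "+") {
  # two 20 kbp anchors separated by the requested gaps
  q1 <- c(0, 20000)
  q2 <- c(20000 + query_gap, 40000 + query_gap)
  if (strand == "+") {
    r1 <- c(100000, 120000)
    r2 <- c(120000 + ref_gap, 140000 + ref_gap)
  } else {
    r2 <- c(100000, 120000)
    r1 <- c(120000 + ref_gap, 140000 + ref_gap)
  }
  rbind(paf_row("q", 6e4, q1[1], q1[2], strand, "chr1", 1e6, r1[1], r1[2]),
        paf_row("q", 6e4, q2[1], q2[2], strand, "chr1", 1e6, r2[1], r2[2]))
}

test_that("between-alignment classification follows the gap sign table", {
  cases <- list(
    list(qg = 0, rg = 1000, type = "Deletion", size = 1000),
    list(qg = 1000, rg = 0, type = "Insertion", size = 1000),
    list(qg = 500, rg = -500, type = "Tandem_expansion", size = 1000),
    list(qg = -500, rg = 500, type = "Tandem_contraction", size = 1000),
    list(qg = -200, rg = -800, type = "Repeat_expansion", size = 600),
    list(qg = -800, rg = -200, type = "Repeat_contraction", size = 600))
  for (cs in cases) {
    for (strand in c("+", "-")) {
      svs <- call_between_alignments(between_pair(cs$qg, cs$rg, strand))
      expect_equal(svs$type, cs$type,
                   label = sprintf("qg=%d rg=%d %s", cs$qg, cs$rg, strand))
      expect_equal(svs$size, cs$size)
      expect_equal(svs$strand, strand)
    }
  }
})

test_that("the classification table is total over in-range gap pairs", {
  set.seed(51)
  for (rep in 1:50) {
    qg <- sample(-2000:2000, 1)
    rg <- sample(-2000:2000, 1)
    size <- abs(qg - rg)
    svs <- call_between_alignments(between_pair(qg, rg))
    if (size >= 20 && size <= 1e5) {
      expect_equal(nrow(svs), 1)
      expect_true(svs$type %in% c("Insertion", "Deletion",
                                  "Tandem_expansion", "Tandem_contraction",
                                  "Repeat_expansion", "Repeat_contraction"))
    } else {
      expect_equal(nrow(svs), 0)
    }
  }
})

test_that("gap-overlap fractions are exact and drive the 10% filter", {
  svs <- data.frame(reference = "chr1", ref_start = c(100, 500, 700),
                    ref_end = c(200, 600, 800), query = "q",
                    query_start = 0, query_end = 0,
                    size = 100, strand = "+",
                    type = "Deletion", source = "between_alignments",
                    gap_overlap_fraction = NA_real_,
                    stringsAsFactors = FALSE)
  gaps <- data.frame(seqid = "chr1", start = c(150, 700), end = c(250, 800))
  got <- annotate_gap_overlap(svs, ref_gaps = gaps)
  expect_equal(got$gap_overlap_fraction, c(0.5, 0, 1))
  expect_equal(filter_gap_svs(got, 0.10)$ref_start, 500)

  # insertions measure their overlap on the query span
  ins <- data.frame(reference = "chr1", ref_start = 100, ref_end = 100,
                    query = "q", query_start = 1000, query_end = 1200,
                    size = 200, strand = "+", type = "Insertion",
                    source = "within_alignment",
                    gap_overlap_fraction = NA_real_,
                    stringsAsFactors = FALSE)
  qgaps <- data.frame(seqid = "q", start = 1100, end = 1300)
  expect_equal(annotate_gap_overlap(ins, query_gaps = qgaps)$gap_overlap_fraction,
               0.5)
})

mk_sv <- function(ref_start, ref_end, type = "Deletion", strand = "+",
                  size = ref_end - ref_start, reference = "chr1") {
  data.frame(reference = reference, ref_start = ref_start,
             ref_end = ref_end, query = "q", query_start = 0,
             query_end = 0, size = size, strand = strand, type = type,
             source = "between_alignments", gap_overlap_fraction = 0,
             stringsAsFactors = FALSE)
}

test_that("merging links breakpoints within 1 kbp, strand-aware", {
  a <- mk_sv(1000, 1200)
  b <- mk_sv(1500, 1700)
  m <- merge_svs(list(A = a, B = b), max_dist = 1000)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_support, 1L + 1L)
  expect_equal(m$samples, "A,B")

  b_minus <- mk_sv(1500, 1700, strand = "-")
  m2 <- merge_svs(list(A = a, B = b_minus), max_dist = 1000,
                  strand_aware = TRUE)
  expect_equal(nrow(m2), 2)

  # intersection semantics: variant in 2 of 3 samples disappears
  m3 <- merge_svs(list(A = a, B = b, C = mk_sv(9e5, 9.1e5)),
                  max_dist = 1000, min_support = 3)
  expect_equal(nrow(m3), 0)
})

test_that("merge with max_dist 0 deduplicates identical calls", {
  a <- rbind(mk_sv(100, 300), mk_sv(5000, 5200, type = "Insertion"))
  m <- merge_svs(list(s1 = a, s2 = a, s3 = a), max_dist = 0)
  expect_equal(nrow(m), 2)
  expect_true(all(m$n_support == 3))
  pm <- presence_matrix(m)
  expect_equal(unname(rowSums(pm)), m$n_support)
  expect_equal(colnames(pm), c("s1", "s2", "s3"))
})

test_that("merge clustering matches the brute-force component oracle", {
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    starts <- sort(sample.int(20000, n))
    df <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_sv(starts[i], starts[i] + sample(c(50, 500, 3000), 1),
            type = sample(c("Deletion", "Insertion"), 1),
            strand = sample(c("+", "-"), 1))))
    df$sample <- paste0("s", sample(1:3, n, replace = TRUE))
    max_dist <- sample(c(0, 200, 1000), 1)
    comp <- merge_oracle_components(df, max_dist)
    tables <- split(df[, setdiff(names(df), "sample")], df$sample)
    m <- merge_svs(tables, max_dist = max_dist)
    expect_equal(nrow(m), length(unique(comp)))
    # row sums of the presence matrix equal the support sets
    pm <- presence_matrix(m, samples = paste0("s", 1:3))
    expect_equal(unname(rowSums(pm)), m$n_support)
  }
})

test_that("variants on excluded references are dropped before merging", {
  a <- rbind(mk_sv(100, 300), mk_sv(100, 300, reference = "Chr0_pseudomolecule"))
  m <- merge_svs(list(A = a), excluded_refs = "Chr0_pseudomolecule")
  expect_equal(unique(m$reference), "chr1")
})

test_that("gene intersection uses 2 kbp flanks and normalizes by length", {
  merged <- data.frame(variant_id = c("v1", "v2", "v3"),
                       reference = "chr1",
                       ref_start = c(5000, 30000, 60000),
                       ref_end = c(5100, 30100, 60100),
                       size = 100, type = "Deletion", strand = "+",
                       n_support = 1, samples = "A",
                       stringsAsFactors = FALSE)
  genes <- data.frame(id = "g1", seqid = "chr1", start = 7000, end = 17000)
  got <- intersect_genes(merged, genes, flank = 2000)
  expect_equal(got$n_variants, 1)   # v1 is 1.9 kbp upstream -> counted
  expect_equal(got$normalized_n_variants, 1e-4)
  got0 <- intersect_genes(merged, genes, flank = 0)
  expect_equal(got0$n_variants, 0)
})

test_that("planted indels are recovered from real alignments", {
  set.seed(53)
  ref <- random_genome(1, 8e5, prefix = "ref")
  mut <- mutate_scaffolds(ref, n_indels = 40, indel_min = 50,
                          indel_max = 3000, snp_rate = 0)
  qry <- setNames(mut$scaffolds, "asm")
  aln <- align_mm2(ref, qry, min_len = 1000)
  svs <- call_svs(aln, sv_config())
  log <- mut$log
  hit <- vapply(seq_len(nrow(log)), function(i) {
    want <- if (log$type[i] == "insertion") "Insertion" else "Deletion"
    any(svs$type == want &
          abs(svs$ref_start - log$pos[i]) <= 1000 &
          abs(svs$size - log$size[i]) <= 10)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
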