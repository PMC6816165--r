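# Benchmark harness: partition a reference into simulated scaffolds with
# lengths drawn from an empirical (or log-normal) distribution, add
# variation (indels + SNPs), derive gap-free contigs, and score any
# scaffolder output against the recorded ground truth.

#' Generate a random nuclear genome
#'
#' Uniform random A/C/G/T sequence, optionally interrupted by N-runs to
#' emulate sequencing gaps in a finished reference. Randomness comes from
#' the current RNG state (seed with [set.seed()]).
#'
#' @param n_chrom Number of chromosomes (default 5).
#' @param chrom_len Length of each chromosome in bp (default 2e6).
#' @param n_gaps N-runs injected per chromosome (default 0).
#' @param gap_len Length range of injected N-runs (default 100..1000).
#' @param prefix Chromosome name prefix (default "chr").
#' @return Named character vector of chromosome sequences.
#' @export
random_genome <- function(n_chrom = 5, chrom_len = 2e6, n_gaps = 0,
                          gap_len = c(100, 1000), prefix = "chr") {
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0(prefix, seq_len(n_chrom))
  if (n_gaps > 0) {
    for (i in seq_along(seqs)) {
      for (k in seq_len(n_gaps)) {
        len <- gap_len[1] + sample.int(gap_len[2] - gap_len[1] + 1, 1) - 1
        pos <- sample.int(chrom_len - len - 1, 1)
        substr(seqs[i], pos + 1, pos + len) <- strrep("N", len)
      }
    }
  }
  seqs
}

draw_lengths_fun <- function(lengths, meanlog, sdlog, min_len) {
  if (is.function(lengths)) return(lengths)
  if (!is.null(lengths)) {
    stopifnot(all(lengths > 0))
    return(function(n) lengths[sample.int(length(lengths), n, replace = TRUE)])
  }
  function(n) pmax(min_len, round(rlnorm(n, meanlog, sdlog)))
}

#' Simulate scaffolds by partitioning a reference
#'
#' Intervals are successively defined along each chromosome with lengths
#' drawn from an empirical length distribution (or a log-normal
#' fallback); the last interval is truncated at the chromosome end.
#' Scaffolds containing more than `max_n_frac` `N` characters are
#' removed, a random half of the rest is reverse complemented, and the
#' output order is shuffled. The truth table records every kept
#' scaffold's source chromosome, order, orientation, and interval before
#' shuffling.
#'
#' @param genome Named character vector of reference chromosomes.
#' @param lengths Empirical lengths to sample from (numeric vector), or a
#'   function `(n) -> lengths` for full control, or `NULL` to use the
#'   log-normal fallback.
#' @param meanlog,sdlog Log-normal fallback parameters (defaults
#'   `log(1e5)`, 1).
#' @param min_draw Lower clamp for log-normal draws (default 1000).
#' @param min_tail A terminal remainder shorter than this is merged into
#'   the previous interval instead of forming its own scaffold (default 0,
#'   i.e. plain truncation).
#' @param max_n_frac Scaffolds with a higher `N` fraction are dropped
#'   (default 0.5).
#' @param rc_frac Fraction of kept scaffolds reverse complemented
#'   (default 0.5).
#' @return List with `scaffolds` (named character vector, shuffled) and
#'   `truth` (data.frame `id, chromosome, order_index, orientation,
#'   ref_start, ref_end`).
#' @export
simulate_scaffolds <- function(genome, lengths = NULL, meanlog = log(1e5),
                               sdlog = 1, min_draw = 1000, min_tail = 0,
                               max_n_frac = 0.5, rc_frac = 0.5) {
  draw <- draw_lengths_fun(lengths, meanlog, sdlog, min_draw)
  truth <- list()
  seqs <- character(0)
  k <- 0
  for (chrom in names(genome)) {
    clen <- nchar(genome[[chrom]])
    pos <- 0
    while (pos < clen) {
      len <- draw(1)
      end <- min(pos + len, clen)
      if (clen - end < min_tail) end <- clen
      k <- k + 1
      id <- sprintf("sim_scaffold_%05d", k)
      seqs[id] <- substr(genome[[chrom]], pos + 1, end)
      truth[[k]] <- data.frame(id = id, chromosome = chrom,
                               order_index = NA_real_, orientation = "+",
                               ref_start = pos, ref_end = end,
                               stringsAsFactors = FALSE)
      pos <- end
    }
  }
  truth <- do.call(rbind, truth)
  n_frac <- vapply(seqs, function(s)
    nchar(gsub("[^Nn]", "", s)) / nchar(s), numeric(1))
  keep <- n_frac <= max_n_frac
  seqs <- seqs[keep]
  truth <- truth[keep, , drop = FALSE]
  for (chrom in unique(truth$chromosome)) {
    sel <- which(truth$chromosome == chrom)
    truth$order_index[sel[order(truth$ref_start[sel])]] <- seq_along(sel)
  }
  n <- length(seqs)
  if (n) {
    rc <- sample.int(n, floor(rc_frac * n))
    seqs[rc] <- revcomp(seqs[rc])
    truth$orientation[rc] <- "-"
    seqs <- seqs[sample.int(n)]
  }
  rownames(truth) <- NULL
  list(scaffolds = seqs, truth = truth)
}

#' Add indel and SNP variation to simulated scaffolds
#'
#' Plants `n_indels` insertion/deletion events (50/50, sizes uniform in
#' `indel_min..indel_max`, positions uniform over non-N bases, events
#' never overlapping so the log is invertible) and SNPs at `snp_rate`
#' per non-N base, each substituted by a different random base. Every
#' event is logged with its coordinates on the unmutated scaffold, so
#' planted variants can be cross-validated against an SV caller.
#'
#' @param scaffolds Named character vector.
#' @param n_indels Number of indel events across all scaffolds (default
#'   10000), apportioned by scaffold length.
#' @param indel_min,indel_max Indel size range in bp (defaults 20 and
#'   10000).
#' @param snp_rate Per-base substitution rate over non-N bases (default
#'   0.01).
#' @param max_retries Redraws allowed per event before it is skipped with
#'   a warning (default 50).
#' @return List with `scaffolds` (mutated) and `log` (data.frame
#'   `scaffold, pos, type, size, seq, orig`; positions are 0-based on the
#'   input scaffold; insertions insert before `pos`, deletions remove
#'   `[pos, pos + size)`).
#' @export
mutate_scaffolds <- function(scaffolds, n_indels = 10000, indel_min = 20,
                             indel_max = 10000, snp_rate = 0.01,
                             max_retries = 50) {
  stopifnot(indel_min <= indel_max, snp_rate >= 0, snp_rate <= 1,
            length(scaffolds) > 0)
  log <- list()
  out <- scaffolds
  bases <- c("A", "C", "G", "T")
  alt <- rbind(c("C", "A", "A", "A"),
               c("G", "G", "C", "C"),
               c("T", "T", "T", "G"))   # alternatives per original base
  # --- SNPs (original coordinates are unchanged by substitutions) ---
  if (snp_rate > 0) {
    for (id in names(out)) {
      chars <- strsplit(out[[id]], "", fixed = TRUE)[[1]]
      nonN <- which(toupper(chars) %in% bases)
      ns <- round(snp_rate * length(nonN))
      if (!ns) next
      idx <- nonN[sample.int(length(nonN), ns)]
      base_i <- match(toupper(chars[idx]), bases)
      pick <- sample.int(3, ns, replace = TRUE)
      new <- alt[cbind(pick, base_i)]
      log[[length(log) + 1]] <- data.frame(
        scaffold = id, pos = idx - 1, type = "snp", size = 1,
        seq = new, orig = chars[idx], stringsAsFactors = FALSE)
      chars[idx] <- new
      out[id] <- paste(chars, collapse = "")
    }
  }
  # --- indels ---
  if (n_indels > 0) {
    counts <- table(names(out)[sample.int(length(out), n_indels,
                                          replace = TRUE,
                                          prob = nchar(out))])
    for (id in names(counts)) {
      seq <- out[[id]]
      len <- nchar(seq)
      is_n <- strsplit(chartr("acgtACGT", "00000000", seq), "",
                       fixed = TRUE)[[1]] != "0"
      events <- list()
      taken_s <- numeric(0)
      taken_e <- numeric(0)
      skipped <- 0
      for (e in seq_len(counts[[id]])) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          type <- sample(c("insertion", "deletion"), 1)
          size <- indel_min + sample.int(indel_max - indel_min + 1, 1) - 1
          pos <- sample.int(len, 1) - 1       # 0-based
          span <- if (type == "deletion") size else 1
          if (pos + span > len) next
          if (any(is_n[(pos + 1):(pos + span)])) next
          if (interval_overlap(pos, pos + span, taken_s, taken_e) > 0) next
          ok <- TRUE
          break
        }
        if (!ok) {
          skipped <- skipped + 1
          next
        }
        taken_s <- c(taken_s, pos)
        taken_e <- c(taken_e, pos + span)
        events[[length(events) + 1]] <- data.frame(
          scaffold = id, pos = pos, type = type, size = size,
          seq = if (type == "insertion")
                  paste(sample(bases, size, replace = TRUE), collapse = "")
                else substr(seq, pos + 1, pos + size),
          orig = NA_character_, stringsAsFactors = FALSE)
      }
      if (skipped)
        warning("skipped ", skipped, " indel event(s) on ", id,
                " after ", max_retries, " redraws")
      if (!length(events)) next
      ev <- do.call(rbind, events)
      ev <- ev[order(ev$pos), , drop = FALSE]
      segs <- character(0)
      cur <- 0
      for (i in seq_len(nrow(ev))) {
        segs <- c(segs, substr(seq, cur + 1, ev$pos[i]))
        if (ev$type[i] == "insertion") {
          segs <- c(segs, ev$seq[i])
          cur <- ev$pos[i]
        } else {
          cur <- ev$pos[i] + ev$size[i]
        }
      }
      segs <- c(segs, substr(seq, cur + 1, len))
      out[id] <- paste(segs, collapse = "")
      log[[length(log) + 1]] <- ev
    }
  }
  log <- if (length(log)) do.call(rbind, log)
         else data.frame(scaffold = character(0), pos = numeric(0),
                         type = character(0), size = numeric(0),
                         seq = character(0), orig = character(0),
                         stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(scaffolds = out, log = log)
}

# Map an offset on a mutated scaffold back to the unmutated scaffold,
# using the indel events of the mutation log (sorted by position).
unshift_offset <- function(offset, ev) {
  if (!nrow(ev)) return(offset)
  shift <- 0
  for (i in seq_len(nrow(ev))) {
    mut_start <- ev$pos[i] + shift
    delta <- if (ev$type[i] == "insertion") ev$size[i] else -ev$size[i]
    mut_end <- if (delta > 0) mut_start + ev$size[i] else mut_start
    if (offset < mut_start) return(offset - shift)
    if (offset < mut_end) return(ev$pos[i])   # inside inserted sequence
    shift <- shift + delta
  }
  offset - shift
}

#' Derive gap-free contigs from simulated scaffolds
#'
#' Scaffolds are broken at every N-run of at least `min_n_run` bp, the
#' gap sequence is discarded, and resulting pieces shorter than `min_len`
#' are excluded from both the contigs and the truth. Order indices are
#' recomputed per chromosome; pieces of reverse-complemented scaffolds
#' map back to reference coordinates through the scaffold's source
#' interval.
#'
#' @param scaffolds Named character vector (possibly mutated).
#' @param truth Truth table from [simulate_scaffolds()].
#' @param min_n_run Minimum N-run length that splits (default 20).
#' @param min_len Minimum contig length kept (default 10000).
#' @param mutation_log Optional log from [mutate_scaffolds()], used to
#'   map mutated offsets back to reference coordinates.
#' @return List with `contigs` and updated `truth`.
#' @export
scaffolds_to_contigs <- function(scaffolds, truth, min_n_run = 20,
                                 min_len = 10000, mutation_log = NULL) {
  contigs <- character(0)
  rows <- list()
  for (sid in names(scaffolds)) {
    t <- truth[truth$id == sid, , drop = FALSE]
    if (!nrow(t)) stop("scaffold ", sid, " missing from truth")
    seq <- scaffolds[[sid]]
    gaps <- find_gaps(setNames(seq, sid), min_run = min_n_run)
    bounds_s <- c(0, gaps$end)
    bounds_e <- c(gaps$start, nchar(seq))
    ev <- NULL
    if (!is.null(mutation_log)) {
      ev <- mutation_log[mutation_log$scaffold == sid &
                           mutation_log$type != "snp", , drop = FALSE]
      ev <- ev[order(ev$pos), , drop = FALSE]
    }
    j <- 0
    for (p in seq_along(bounds_s)) {
      a <- bounds_s[p]; b <- bounds_e[p]
      if (b - a < min_len || b <= a) next
      j <- j + 1
      cid <- sprintf("%s_ctg%d", sid, j)
      contigs[cid] <- substr(seq, a + 1, b)
      a0 <- if (is.null(ev)) a else unshift_offset(a, ev)
      b0 <- if (is.null(ev)) b else unshift_offset(b, ev)
      if (t$orientation == "+") {
        rs <- t$ref_start + a0; re <- t$ref_start + b0
      } else {
        rs <- t$ref_end - b0; re <- t$ref_end - a0
      }
      rows[[length(rows) + 1]] <- data.frame(
        id = cid, chromosome = t$chromosome, order_index = NA_real_,
        orientation = t$orientation, ref_start = rs, ref_end = re,
        stringsAsFactors = FALSE)
    }
  }
  new_truth <- if (length(rows)) do.call(rbind, rows)
               else truth[0, , drop = FALSE]
  for (chrom in unique(new_truth$chromosome)) {
    sel <- which(new_truth$chromosome == chrom)
    new_truth$order_index[sel[order(new_truth$ref_start[sel])]] <-
      seq_along(sel)
  }
  rownames(new_truth) <- NULL
  list(contigs = contigs, truth = new_truth)
}

#' Token edit distance between two id sequences
#'
#' Standard Levenshtein distance over whole tokens (contig ids), computed
#' by dynamic programming.
#'
#' @param a,b Character vectors.
#' @return Non-negative integer distance.
#' @export
token_edit_distance <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0) return(n)
  if (n == 0) return(m)
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- numeric(n + 1)
    cur[1] <- i
    cost <- as.numeric(b != a[i])
    for (j in seq_len(n))
      cur[j + 1] <- min(prev[j] + cost[j], prev[j + 1] + 1, cur[j] + 1)
    prev <- cur
  }
  as.integer(prev[n + 1])
}

#' Score scaffolder placements against simulation truth
#'
#' Clustering and orientation accuracy are the fractions of localized
#' contigs assigned the correct chromosome and orientation. Ordering is
#' scored per chromosome: the token edit distance between true and
#' predicted contig order, normalized by the true contig count (capped at
#' 2), and the fraction of correct directed adjacent pairs. Localization
#' is reported over all contigs and, when lengths are supplied, over all
#' bases.
#'
#' @param placements Placement table from [place_contigs()] /
#'   [scaffold_assembly()].
#' @param truth Truth table covering every placed contig.
#' @param contig_lengths Optional named lengths for the sequence-level
#'   localization percentage.
#' @return List of class `scaffold_eval`: `clustering_accuracy`,
#'   `orientation_accuracy`, `per_chromosome` (data.frame),
#'   `mean_normalized_edit_distance`, `mean_adjacent_pair_accuracy`,
#'   `pct_contigs_localized`, `pct_sequence_localized`.
#' @export
evaluate_placements <- function(placements, truth, contig_lengths = NULL) {
  unknown <- setdiff(placements$contig, truth$id)
  if (length(unknown))
    stop("placement references unknown contig ", unknown[1])
  loc <- placements[placements$chromosome != CHR0 &
                      !is.na(placements$order_index), , drop = FALSE]
  m <- match(loc$contig, truth$id)
  clustering <- if (nrow(loc)) mean(loc$chromosome == truth$chromosome[m])
                else NA_real_
  orienting <- if (nrow(loc)) mean(loc$orientation == truth$orientation[m])
               else NA_real_
  per <- lapply(sort(unique(truth$chromosome)), function(chrom) {
    tr <- truth[truth$chromosome == chrom, , drop = FALSE]
    true_ids <- tr$id[order(tr$order_index)]
    pr <- loc[loc$chromosome == chrom, , drop = FALSE]
    pred_ids <- pr$contig[order(pr$order_index)]
    if (!length(pred_ids))
      return(data.frame(chromosome = chrom, n_true = length(true_ids),
                        n_predicted = 0,
                        normalized_edit_distance = NA_real_,
                        adjacent_pair_accuracy = NA_real_))
    ed <- token_edit_distance(true_ids, pred_ids)
    nd <- min(2, ed / length(true_ids))
    apa <- if (length(true_ids) >= 2) {
      tp <- paste(true_ids[-length(true_ids)], true_ids[-1], sep = "\r")
      pp <- if (length(pred_ids) >= 2)
        paste(pred_ids[-length(pred_ids)], pred_ids[-1], sep = "\r")
      else character(0)
      sum(tp %in% pp) / (length(true_ids) - 1)
    } else NA_real_
    data.frame(chromosome = chrom, n_true = length(true_ids),
               n_predicted = length(pred_ids),
               normalized_edit_distance = nd,
               adjacent_pair_accuracy = apa)
  })
  per <- do.call(rbind, per)
  pct_seq <- NA_real_
  if (!is.null(contig_lengths))
    pct_seq <- sum(contig_lengths[loc$contig]) /
      sum(contig_lengths[truth$id])
  structure(list(
    clustering_accuracy = clustering,
    orientation_accuracy = orienting,
    per_chromosome = per,
    mean_normalized_edit_distance =
      mean(per$normalized_edit_distance, na.rm = TRUE),
    mean_adjacent_pair_accuracy =
      mean(per$adjacent_pair_accuracy, na.rm = TRUE),
    pct_contigs_localized = nrow(loc) / nrow(truth),
    pct_sequence_localized = pct_seq), class = "scaffold_eval")
}

#' @export
print.scaffold_eval <- function(x, ...) {
  cat("Scaffolding evaluation\n")
  cat(sprintf("  clustering accuracy:        %.4f\n", x$clustering_accuracy))
  cat(sprintf("  orientation accuracy:       %.4f\n", x$orientation_accuracy))
  cat(sprintf("  mean norm. edit distance:   %.4f\n",
              x$mean_normalized_edit_distance))
  cat(sprintf("  mean adjacent-pair acc.:    %.4f\n",
              x$mean_adjacent_pair_accuracy))
  cat(sprintf("  contigs localized:          %.2f%%\n",
              100 * x$pct_contigs_localized))
  if (!is.na(x$pct_sequence_localized))
    cat(sprintf("  sequence localized:         %.2f%%\n",
                100 * x$pct_sequence_localized))
  invisible(x)
}
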