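# Interval-overlap statistics between QTL sets and hotspots.
#
# All intervals are 1-based and inclusive; [a,b] overlaps [c,d] iff
# a <= d and c <= b. Empirical significance comes from re-placing intervals
# of the same sizes uniformly at random (mutually non-overlapping) across
# the genome.

.check_intervals <- function(x, layout) {
  stopifnot(all(c("chrom", "ci_lo", "ci_hi") %in% names(x)))
  if (any(x$ci_lo > x$ci_hi)) stop("interval with ci_lo > ci_hi")
  if (!is.null(layout)) {
    len <- .chrom_length(layout, x$chrom)
    if (any(x$ci_lo < 1 | x$ci_hi > len)) stop("interval outside chromosome bounds")
  }
  invisible(x)
}

#' Count overlaps between two interval sets
#'
#' @param a,b data.frames with `chrom`, `ci_lo`, `ci_hi` (1-based inclusive).
#' @param layout Optional [genome_layout()] for bounds checking.
#' @return list with `counts` (per `a` interval, number of `b` intervals it
#'   overlaps) and `n_with_overlap` (number of `a` intervals overlapping at
#'   least one `b` interval).
#' @export
count_overlaps <- function(a, b, layout = NULL) {
  .check_intervals(a, layout); .check_intervals(b, layout)
  counts <- integer(nrow(a))
  for (cc in unique(a$chrom)) {
    ia <- which(a$chrom == cc)
    ib <- which(b$chrom == cc)
    if (!length(ib)) next
    counts[ia] <- vapply(ia, function(i) {
      sum(.int_overlaps(a$ci_lo[i], a$ci_hi[i], b$ci_lo[ib], b$ci_hi[ib]))
    }, integer(1L))
  }
  list(counts = counts, n_with_overlap = sum(counts > 0L))
}

# Place intervals of given lengths uniformly at random, each entirely on one
# chromosome (chromosome sampled with probability proportional to the number
# of valid start positions), mutually non-overlapping, by rejection sampling.
.place_random_intervals <- function(lens, layout, max_attempts = 10000L) {
  lens <- sort(lens, decreasing = TRUE)
  chrom <- character(length(lens)); lo <- numeric(length(lens))
  attempts <- 0L
  placed <- 0L
  while (placed < length(lens)) {
    len <- lens[placed + 1L]
    slots <- pmax(layout$length - len + 1, 0)
    if (all(slots == 0)) stop("interval longer than every chromosome")
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) stop("random interval placement infeasible")
      ci <- sample.int(nrow(layout), 1L, prob = slots)
      start <- sample.int(slots[ci], 1L)
      hi <- start + len - 1
      prev <- which(chrom[seq_len(placed)] == layout$chrom[ci])
      if (!length(prev) ||
          !any(.int_overlaps(start, hi, lo[prev], lo[prev] + lens[prev] - 1))) {
        placed <- placed + 1L
        chrom[placed] <- layout$chrom[ci]; lo[placed] <- start
        break
      }
    }
  }
  data.frame(chrom = chrom, ci_lo = lo, ci_hi = lo + lens - 1,
             stringsAsFactors = FALSE)
}

#' Random-placement null for interval overlap
#'
#' Re-places intervals of the same sizes as `intervals` uniformly at random
#' (mutually non-overlapping) `n_reps` times and counts, per replicate, how
#' many placed intervals overlap at least one interval of the `fixed` set.
#' The empirical p-value is the fraction of replicates matching or exceeding
#' the observed count.
#'
#' @param intervals data.frame of observed intervals (`chrom`, `ci_lo`,
#'   `ci_hi`).
#' @param layout A [genome_layout()].
#' @param fixed data.frame of fixed intervals to count overlaps against.
#' @param n_reps Number of random placements.
#' @param seed Integer seed.
#' @return list of class `overlap_null`: `observed`, `null_counts`, `p`,
#'   `n_reps`.
#' @export
random_interval_null <- function(intervals, layout, fixed, n_reps = 1000,
                                 seed = 1L) {
  .check_intervals(intervals, layout)
  if (nrow(fixed)) .check_intervals(fixed, layout)
  observed <- count_overlaps(intervals, fixed, layout)$n_with_overlap
  lens <- intervals$ci_hi - intervals$ci_lo + 1
  set.seed(seed)
  null_counts <- vapply(seq_len(n_reps), function(i) {
    rnd <- .place_random_intervals(lens, layout)
    count_overlaps(rnd, fixed)$n_with_overlap
  }, integer(1L))
  structure(list(observed = observed, null_counts = null_counts,
                 p = mean(null_counts >= observed), n_reps = n_reps),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf("overlap null: observed %d, null mean %.2f, p = %.4g (%d reps)\n",
              x$observed, mean(x$null_counts), x$p, x$n_reps))
  invisible(x)
}

#' Binned peak-marker co-occurrence
#'
#' Divides every chromosome into fixed-width bins, counts the peaks of each
#' set per bin, and correlates the two genome-wide count vectors by
#' Spearman's rank correlation.
#'
#' @param peaks_a,peaks_b data.frames with `chrom` and a position column
#'   (`peak_pos` or `pos`).
#' @param layout A [genome_layout()].
#' @param bin_bp Bin width in bp (bins are half-open `[k*bin, (k+1)*bin)`
#'   internally, covering each chromosome).
#' @return list with `rho`, `p`, `n_bins`.
#' @export
binned_cooccurrence <- function(peaks_a, peaks_b, layout, bin_bp = 10000) {
  get_pos <- function(x) if ("peak_pos" %in% names(x)) x$peak_pos else x$pos
  n_bins <- setNames(ceiling(layout$length / bin_bp), layout$chrom)
  offset <- setNames(cumsum(c(0, head(n_bins, -1L))), layout$chrom)
  idx <- function(p) {
    i <- match(p$chrom, layout$chrom)
    if (anyNA(i)) stop("unknown chromosome in peak table")
    offset[p$chrom] + floor((get_pos(p) - 1) / bin_bp) + 1
  }
  total <- sum(n_bins)
  ca <- tabulate(idx(peaks_a), nbins = total)
  cb <- tabulate(idx(peaks_b), nbins = total)
  ct <- suppressWarnings(cor.test(ca, cb, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_bins = total)
}
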