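# Two-pass clustering of labeled SNPs into ancestry blocks.
#
# Pass 1 is a run-length encoding of the label sequence along each
# chromosome with a minimum-span filter (the CLUSTER parameter). Pass 2
# smooths the block sequence: a short block of one ancestry sandwiched
# between two blocks of another is treated as a false positive, removed,
# and its flanks merged. "Length" always means nucleotide span
# (end - start + 1), never SNP count.

#' Cluster labeled SNPs into candidate ancestry blocks (pass 1)
#'
#' Scans SNPs sorted by `(chrom, pos)` and collapses maximal runs of
#' identical labels into clusters. Runs are broken at chromosome changes
#' and label changes. A candidate cluster is kept iff its nucleotide span
#' (`end - start + 1`, positions of the first and last member SNP) is at
#' least `min_cluster_len`; sub-threshold runs — including the trailing
#' run on each chromosome — are discarded and counted.
#'
#' @param snps Tibble with columns `chrom`, `pos`, `label` (values from
#'   [ancestry_levels()]), sorted by `(chrom, pos)`; an optional
#'   `individual` column is honored (runs never cross individuals).
#' @param min_cluster_len Minimum cluster span in nucleotides (the CLUSTER
#'   parameter). Default 10: single sporadic SNP calls and runs shorter
#'   than 10 nt are biologically insignificant at typical SNP densities.
#' @return An `ancestry_blocks` tibble with columns (`individual`,)
#'   `chrom`, `start`, `end`, `label`, `n_snps`, `span`, sorted and
#'   non-overlapping per chromosome. Attribute `"n_discarded_runs"` counts
#'   dropped sub-threshold runs.
#' @details Unsorted input is an error (sort by chromosome then position
#'   first); `Unknown`-labeled runs are clustered by the same rules as
#'   parental runs.
#' @seealso [merge_small_clusters()], [trace_ancestry()]
#' @export
#' @examples
#' snps <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
#'                        label = "Parent1")
#' cluster_pass1(snps, min_cluster_len = 10)
cluster_pass1 <- function(snps, min_cluster_len = 10) {
  check_cols(snps, c("chrom", "pos", "label"), "snps")
  check_labels(snps$label)
  if (!is.numeric(min_cluster_len) || min_cluster_len < 1) {
    stop("`min_cluster_len` must be >= 1.", call. = FALSE)
  }
  has_ind <- "individual" %in% names(snps)
  grp <- if (has_ind) {
    paste(snps$individual, snps$chrom, sep = "\r")
  } else {
    snps$chrom
  }
  check_sorted(grp, snps$pos,
               "`snps` must be sorted by (chrom, pos) within individual")

  n <- nrow(snps)
  if (n == 0L) {
    return(empty_blocks(has_ind, n_discarded = 0L))
  }
  new_run <- c(TRUE, grp[-1L] != grp[-n] | snps$label[-1L] != snps$label[-n])
  run <- cumsum(new_run)

  blocks <- snps |>
    dplyr::mutate(.run = run) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("individual", "chrom", "label")),
                    dplyr::first),
      start = min(.data$pos),
      end = max(.data$pos),
      n_snps = dplyr::n(),
      .by = ".run"
    ) |>
    dplyr::mutate(span = .data$end - .data$start + 1L) |>
    dplyr::select(dplyr::any_of("individual"), "chrom", "start", "end",
                  "label", "n_snps", "span")

  keep <- blocks$span >= min_cluster_len
  out <- blocks[keep, , drop = FALSE]
  out <- as_ancestry_blocks(out)
  attr(out, "n_discarded_runs") <- sum(!keep)
  out
}

#' Remove small intervening clusters and merge their flanks (pass 2)
#'
#' Left-to-right smoothing of the per-chromosome cluster sequence: any
#' cluster whose span is strictly below `max_gap_cluster_len` and which is
#' flanked (same chromosome, same individual) by two clusters sharing one
#' label different from its own is deleted, and the flanks are merged into
#' a single cluster running from the left flank's start to the right
#' flank's end with their SNP counts summed. The scan restarts after every
#' rewrite and stops at a fixpoint. Adjacent clusters that share a label
#' (possible when pass 1 discarded the run between them) are coalesced the
#' same way, so no two consecutive surviving clusters on a chromosome
#' share a label. Merging never relabels flanks; the operation is
#' idempotent.
#'
#' @param clusters An `ancestry_blocks` tibble (or any tibble with columns
#'   (`individual`,) `chrom`, `start`, `end`, `label`, `n_snps`), sorted
#'   and non-overlapping per chromosome.
#' @param max_gap_cluster_len Spans strictly below this threshold (in
#'   nucleotides) are removable. Default 1000: genuine recombination
#'   tracts of only a few hundred nucleotides are rare, so sub-kilobase
#'   intervening blocks are treated as call noise.
#' @return An `ancestry_blocks` tibble of the same shape.
#' @export
#' @examples
#' cl <- tibble::tibble(
#'   chrom = "chr1",
#'   start = c(1L, 10001L, 10101L), end = c(10000L, 10100L, 20100L),
#'   label = c("Parent1", "Parent2", "Parent1"), n_snps = c(50L, 2L, 50L)
#' )
#' merge_small_clusters(cl, max_gap_cluster_len = 1000)
merge_small_clusters <- function(clusters, max_gap_cluster_len = 1000) {
  check_cols(clusters, c("chrom", "start", "end", "label", "n_snps"),
             "clusters")
  check_labels(clusters$label)
  if (!is.numeric(max_gap_cluster_len) || max_gap_cluster_len < 1) {
    stop("`max_gap_cluster_len` must be >= 1.", call. = FALSE)
  }
  has_ind <- "individual" %in% names(clusters)
  if (nrow(clusters) == 0L) {
    return(as_ancestry_blocks(empty_blocks(has_ind)))
  }
  grp <- if (has_ind) {
    paste(clusters$individual, clusters$chrom, sep = "\r")
  } else {
    clusters$chrom
  }
  check_sorted(grp, clusters$start,
               "`clusters` must be sorted by (chrom, start)")

  pieces <- split(seq_len(nrow(clusters)), factor(grp, unique(grp)))
  out <- lapply(pieces, function(idx) {
    d <- clusters[idx, , drop = FALSE]
    if (any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("Overlapping clusters on chromosome '", d$chrom[[1]], "'.",
           call. = FALSE)
    }
    m <- merge_chain(d$start, d$end, d$label, d$n_snps,
                     max_gap_cluster_len)
    res <- tibble::tibble(
      chrom = d$chrom[[1]],
      start = m$start, end = m$end, label = m$label, n_snps = m$n_snps,
      span = m$end - m$start + 1L
    )
    if (has_ind) {
      res <- dplyr::mutate(res, individual = d$individual[[1]],
                           .before = 1L)
    }
    res
  })
  as_ancestry_blocks(dplyr::bind_rows(out))
}

# fixpoint rewrite on one chromosome chain, plain vectors for speed
merge_chain <- function(start, end, label, n_snps, thr) {
  repeat {
    n <- length(start)
    if (n >= 2L) {
      # coalesce leftmost adjacent same-label pair
      same <- which(label[-n] == label[-1L])
      if (length(same) > 0L) {
        i <- same[[1L]]
        end[i] <- end[i + 1L]
        n_snps[i] <- n_snps[i] + n_snps[i + 1L]
        start <- start[-(i + 1L)]; end <- end[-(i + 1L)]
        label <- label[-(i + 1L)]; n_snps <- n_snps[-(i + 1L)]
        next
      }
    }
    if (n >= 3L) {
      span <- end - start + 1L
      mid <- 2:(n - 1L)
      removable <- span[mid] < thr &
        label[mid - 1L] == label[mid + 1L] &
        label[mid - 1L] != label[mid]
      if (any(removable)) {
        i <- mid[which(removable)[[1L]]]
        # merge flanks i-1 and i+1; the small cluster's SNPs are dropped
        end[i - 1L] <- end[i + 1L]
        n_snps[i - 1L] <- n_snps[i - 1L] + n_snps[i + 1L]
        drop <- c(i, i + 1L)
        start <- start[-drop]; end <- end[-drop]
        label <- label[-drop]; n_snps <- n_snps[-drop]
        next
      }
    }
    break
  }
  list(start = start, end = end, label = label, n_snps = n_snps)
}

#' Run the full labeling-and-clustering pipeline for one offspring
#'
#' Composes [build_comparison_table()], [cluster_pass1()] and
#' [merge_small_clusters()]: offspring and parental SNP calls go in,
#' smoothed ancestry blocks come out.
#'
#' @inheritParams build_comparison_table
#' @inheritParams cluster_pass1
#' @inheritParams merge_small_clusters
#' @param individual Name recorded in the `individual` column of the
#'   result.
#' @return An `ancestry_blocks` tibble with columns `individual`, `chrom`,
#'   `start`, `end`, `label`, `n_snps`, `span`. Attributes:
#'   `"comparison"` (the labeled site table), `"params"` (the two
#'   thresholds), `"counts"` (sites labeled per category plus discarded
#'   runs). [tidy()] returns the plain block tibble, [glance()] a one-row
#'   summary, [autoplot()] the chromosome painting.
#' @export
#' @examples
#' sim <- simulate_cross_tables(cross_config(
#'   n_chroms = 1, chrom_len = 1e5, snp_density = 2, n_offspring = 1,
#'   crossovers_per_chrom = 1, seed = 7
#' ))
#' blocks <- trace_ancestry(sim$offspring_calls[[1]], sim$parent1,
#'                          sim$parent2, individual = "off_1")
#' glance(blocks)
trace_ancestry <- function(offspring, parent1, parent2,
                           individual = "offspring",
                           min_cluster_len = 10,
                           max_gap_cluster_len = 1000) {
  tab <- build_comparison_table(offspring, parent1, parent2)
  snps <- dplyr::select(tab, "chrom", "pos", "label")
  p1 <- cluster_pass1(snps, min_cluster_len = min_cluster_len)
  blocks <- merge_small_clusters(p1,
                                 max_gap_cluster_len = max_gap_cluster_len)
  blocks <- dplyr::mutate(blocks, individual = individual, .before = 1L)
  blocks <- as_ancestry_blocks(blocks)
  attr(blocks, "comparison") <- tab
  attr(blocks, "params") <- list(min_cluster_len = min_cluster_len,
                                 max_gap_cluster_len = max_gap_cluster_len)
  attr(blocks, "counts") <- c(
    table(factor(tab$label, ancestry_levels())),
    discarded_sites = attr(tab, "n_discarded"),
    discarded_runs = attr(p1, "n_discarded_runs")
  )
  blocks
}

as_ancestry_blocks <- function(x) {
  class(x) <- unique(c("ancestry_blocks", class(tibble::as_tibble(x))))
  x
}

empty_blocks <- function(has_ind, n_discarded = NULL) {
  out <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    label = character(), n_snps = integer(), span = integer()
  )
  if (has_ind) {
    out <- dplyr::mutate(out, individual = character(), .before = 1L)
  }
  out <- as_ancestry_blocks(out)
  if (!is.null(n_discarded)) attr(out, "n_discarded_runs") <- n_discarded
  out
}

check_labels <- function(label) {
  bad <- !label %in% ancestry_levels()
  if (any(bad)) {
    stop("Invalid ancestry label(s): ",
         paste(unique(label[bad]), collapse = ", "),
         " (allowed: ", paste(ancestry_levels(), collapse = ", "), ").",
         call. = FALSE)
  }
  invisible(label)
}

check_sorted <- function(grp, pos, msg) {
  r <- rle(grp)
  if (anyDuplicated(r$values) > 0L) {
    stop(msg, " (chromosome blocks are interleaved).", call. = FALSE)
  }
  n <- length(pos)
  if (n > 1L) {
    same <- grp[-1L] == grp[-n]
    if (any(same & diff(pos) < 0)) {
      stop(msg, " (positions decrease within a chromosome).",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
tidy.ancestry_blocks <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "comparison") <- NULL
  attr(out, "params") <- NULL
  attr(out, "counts") <- NULL
  attr(out, "n_discarded_runs") <- NULL
  out
}

#' @export
glance.ancestry_blocks <- function(x, ...) {
  total <- sum(x$span)
  pct <- function(l) {
    if (total == 0) return(NA_real_)
    100 * sum(x$span[x$label == l]) / total
  }
  tibble::tibble(
    n_clusters = nrow(x),
    n_chroms = dplyr::n_distinct(x$chrom),
    total_span = total,
    parent1_pct = pct("Parent1"),
    parent2_pct = pct("Parent2"),
    unknown_pct = pct("Unknown")
  )
}

#' @export
print.ancestry_blocks <- function(x, ...) {
  cat("# Ancestry blocks:", nrow(x), "cluster(s) on",
      dplyr::n_distinct(x$chrom), "chromosome(s)\n")
  NextMethod()
}
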