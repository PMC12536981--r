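# Independent oracles used to cross-check the pipeline. Each one is a
# deliberately naive re-derivation (frozen truth table, base-R rle,
# repeated rewrite on data.frame rows, literal per-base tallies) kept
# separate from the package's implementation.

# Exhaustive truth table for the labeling rule, written out by hand over
# offspring alleles {A,G} x parent alleles {A,G,absent} (at least one
# parent present).
label_truth_table <- function() {
  tibble::tribble(
    ~offspring, ~p1, ~p2, ~expected,
    "A", "A", "A", "Unknown",
    "A", "A", "G", "Parent1",
    "A", "A", NA,  "Parent1",
    "A", "G", "A", "Parent2",
    "A", "G", "G", "Unknown",
    "A", "G", NA,  "Unknown",
    "A", NA,  "A", "Parent2",
    "A", NA,  "G", "Unknown",
    "G", "A", "A", "Unknown",
    "G", "A", "G", "Parent2",
    "G", "A", NA,  "Unknown",
    "G", "G", "A", "Parent1",
    "G", "G", "G", "Unknown",
    "G", "G", NA,  "Parent1",
    "G", NA,  "A", "Unknown",
    "G", NA,  "G", "Parent2"
  )
}

# Run-length encode then filter, base R only.
oracle_rle_filter <- function(snps, min_len) {
  out <- list()
  for (ch in unique(snps$chrom)) {
    d <- snps[snps$chrom == ch, , drop = FALSE]
    r <- rle(d$label)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (k in seq_along(r$values)) {
      s <- d$pos[starts_i[k]]
      e <- d$pos[ends_i[k]]
      if (e - s + 1 >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e, label = r$values[k],
          n_snps = r$lengths[k], span = e - s + 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      n_snps = integer(), span = integer()))
  }
  do.call(rbind, out)
}

# Naive iterate-until-stable rewrite of the cluster chain: coalesce any
# adjacent same-label pair, remove any sub-threshold cluster between
# same-label flanks, leftmost first, until nothing changes.
oracle_merge_rewrite <- function(df, thr) {
  df <- as.data.frame(df)[, c("chrom", "start", "end", "label", "n_snps")]
  repeat {
    n <- nrow(df)
    changed <- FALSE
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        if (df$chrom[i] == df$chrom[i + 1L] &&
            df$label[i] == df$label[i + 1L]) {
          df$end[i] <- df$end[i + 1L]
          df$n_snps[i] <- df$n_snps[i] + df$n_snps[i + 1L]
          df <- df[-(i + 1L), , drop = FALSE]
          changed <- TRUE
          break
        }
      }
    }
    if (changed) next
    if (n >= 3L) {
      for (i in 2:(n - 1L)) {
        if (df$chrom[i - 1L] == df$chrom[i] &&
            df$chrom[i] == df$chrom[i + 1L] &&
            (df$end[i] - df$start[i] + 1L) < thr &&
            df$label[i - 1L] == df$label[i + 1L] &&
            df$label[i - 1L] != df$label[i]) {
          df$end[i - 1L] <- df$end[i + 1L]
          df$n_snps[i - 1L] <- df$n_snps[i - 1L] + df$n_snps[i + 1L]
          df <- df[-c(i, i + 1L), , drop = FALSE]
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  df$span <- df$end - df$start + 1L
  rownames(df) <- NULL
  df
}

# Literal per-base label tally over cluster spans for one chromosome.
oracle_basewise_pct <- function(clusters_one_chrom) {
  d <- clusters_one_chrom
  bases <- unlist(mapply(
    function(s, e, l) rep(l, e - s + 1L),
    d$start, d$end, d$label, SIMPLIFY = FALSE
  ))
  100 * table(factor(bases, pedpaint::ancestry_levels())) / length(bases)
}

# Per-base majority label over one gene interval; tie or no coverage is
# Unknown.
oracle_gene_label <- function(gene_start, gene_end, clusters_one_chrom) {
  v <- rep(NA_character_, gene_end - gene_start + 1L)
  d <- clusters_one_chrom
  for (k in seq_len(nrow(d))) {
    lo <- max(gene_start, d$start[k])
    hi <- min(gene_end, d$end[k])
    if (lo <= hi) v[(lo:hi) - gene_start + 1L] <- d$label[k]
  }
  counts <- table(v[!is.na(v)])
  if (length(counts) == 0L) return("Unknown")
  top <- max(counts)
  if (sum(counts == top) > 1L) "Unknown" else names(which.max(counts))
}
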