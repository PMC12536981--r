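# Parental contribution quantification.
#
# Percentages are computed over the informative regions only — the union
# of cluster spans, including Unknown clusters — never over the full
# chromosome length, which may be poorly defined (repeats, invariant
# regions) in non-model genomes.

#' Per-chromosome genome contribution percentages
#'
#' For each individual and chromosome, the percentage of each ancestry
#' label is the summed span of that label's clusters divided by the summed
#' span of all clusters on the chromosome, times 100. Pre-rounding, the
#' three percentages sum to exactly 100 per chromosome.
#'
#' @param clusters Post-merge `ancestry_blocks` (see
#'   [merge_small_clusters()]); an `individual` column is honored.
#' @param individual Individual name used when `clusters` has no
#'   `individual` column.
#' @return An `ancestry_contributions` tibble with columns `individual`,
#'   `chrom`, `parent1_pct`, `parent2_pct`, `unknown_pct`. Empty input
#'   yields an empty tibble with a warning.
#' @export
#' @examples
#' cl <- tibble::tibble(chrom = "chr1", start = c(1L, 301L),
#'                      end = c(300L, 400L),
#'                      label = c("Parent1", "Parent2"),
#'                      n_snps = c(3L, 1L))
#' genome_contributions(cl)
genome_contributions <- function(clusters, individual = "offspring") {
  check_cols(clusters, c("chrom", "start", "end", "label"), "clusters")
  check_labels(clusters$label)
  if (nrow(clusters) == 0L) {
    warning("No clusters: no contributions to quantify.", call. = FALSE)
    return(as_contributions(tibble::tibble(
      individual = character(), chrom = character(),
      parent1_pct = double(), parent2_pct = double(),
      unknown_pct = double()
    ), kind = "genome"))
  }
  d <- tibble::as_tibble(clusters)
  if (!"individual" %in% names(d)) {
    d <- dplyr::mutate(d, individual = individual)
  }
  out <- d |>
    dplyr::mutate(span = .data$end - .data$start + 1) |>
    dplyr::summarise(
      span = sum(.data$span),
      .by = c("individual", "chrom", "label")
    ) |>
    dplyr::mutate(pct = 100 * .data$span / sum(.data$span),
                  .by = c("individual", "chrom")) |>
    dplyr::select(-"span") |>
    tidyr::pivot_wider(names_from = "label", values_from = "pct",
                       values_fill = 0) |>
    add_missing_labels() |>
    dplyr::rename(parent1_pct = "Parent1", parent2_pct = "Parent2",
                  unknown_pct = "Unknown") |>
    dplyr::select("individual", "chrom", "parent1_pct", "parent2_pct",
                  "unknown_pct") |>
    dplyr::arrange(.data$individual, .data$chrom)
  as_contributions(out, kind = "genome")
}

#' Assign ancestry labels to genes by cluster overlap
#'
#' Each gene interval inherits the label of the cluster set with the
#' largest total overlapping span (overlap summed per label across
#' clusters, partial and nested overlaps included). A gene with no
#' overlapping cluster, or whose top two labels tie, is labeled `Unknown`.
#' Works with filtered annotations (e.g. a GTF restricted to genes of
#' interest).
#'
#' @param clusters Post-merge `ancestry_blocks`; an `individual` column is
#'   honored (genes are assigned independently per individual).
#' @param genes Gene tibble with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based closed), deduplicated on `gene_id`; see
#'   [read_gtf_genes()].
#' @param individual Individual name used when `clusters` has no
#'   `individual` column.
#' @return A tibble with columns `individual`, `gene_id`, `chrom`,
#'   `start`, `end`, `label`, `overlap_bp` (total overlap supporting the
#'   winning label; 0 for genes with no overlap). Strand is ignored —
#'   ancestry is strand-agnostic.
#' @seealso [gene_percentages()]
#' @export
gene_contributions <- function(clusters, genes, individual = "offspring") {
  check_cols(clusters, c("chrom", "start", "end", "label"), "clusters")
  check_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  check_labels(clusters$label)
  if (anyDuplicated(genes$gene_id) > 0L) {
    stop("`genes` has duplicate gene_id values.", call. = FALSE)
  }
  d <- tibble::as_tibble(clusters)
  if (!"individual" %in% names(d)) {
    d <- dplyr::mutate(d, individual = individual)
  }
  inds <- unique(d$individual)
  out <- lapply(inds, function(ind) {
    assign_genes_one(d[d$individual == ind, , drop = FALSE], genes) |>
      dplyr::mutate(individual = ind, .before = 1L)
  })
  dplyr::bind_rows(out)
}

# overlap bookkeeping for one individual's clusters, via GenomicRanges
assign_genes_one <- function(clusters, genes) {
  g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  cl <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(clusters$start, clusters$end)
  )
  hits <- GenomicRanges::findOverlaps(g, cl)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(g)[qi], IRanges::ranges(cl)[si]
  ))

  per_label <- tibble::tibble(
    gene_idx = qi,
    label = clusters$label[si],
    overlap = ov
  ) |>
    dplyr::summarise(overlap = sum(.data$overlap),
                     .by = c("gene_idx", "label"))

  winners <- per_label |>
    dplyr::mutate(
      top = max(.data$overlap),
      tied = sum(.data$overlap == max(.data$overlap)) > 1L,
      .by = "gene_idx"
    ) |>
    dplyr::filter(.data$overlap == .data$top) |>
    dplyr::distinct(.data$gene_idx, .keep_all = TRUE) |>
    dplyr::mutate(
      label = ifelse(.data$tied, "Unknown", .data$label),
      overlap_bp = .data$top
    ) |>
    dplyr::select("gene_idx", "label", "overlap_bp")

  genes |>
    dplyr::mutate(gene_idx = dplyr::row_number()) |>
    dplyr::left_join(winners, by = "gene_idx") |>
    dplyr::mutate(
      label = dplyr::coalesce(.data$label, "Unknown"),
      overlap_bp = dplyr::coalesce(.data$overlap_bp, 0L)
    ) |>
    dplyr::select("gene_id", "chrom", "start", "end", "label",
                  "overlap_bp")
}

#' Per-chromosome gene-level contribution percentages
#'
#' Counts gene labels per chromosome (and individual) and converts them to
#' percentages of the genes annotated on that chromosome.
#'
#' @param assignments Output of [gene_contributions()].
#' @return An `ancestry_contributions` tibble with columns `individual`,
#'   `chrom`, `n_genes`, `parent1_pct`, `parent2_pct`, `unknown_pct`.
#' @export
gene_percentages <- function(assignments) {
  check_cols(assignments, c("gene_id", "chrom", "label"), "assignments")
  d <- tibble::as_tibble(assignments)
  if (!"individual" %in% names(d)) {
    d <- dplyr::mutate(d, individual = "offspring")
  }
  out <- d |>
    dplyr::summarise(n = dplyr::n(),
                     .by = c("individual", "chrom", "label")) |>
    dplyr::mutate(n_genes = sum(.data$n),
                  pct = 100 * .data$n / sum(.data$n),
                  .by = c("individual", "chrom")) |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "label", values_from = "pct",
                       values_fill = 0) |>
    add_missing_labels() |>
    dplyr::rename(parent1_pct = "Parent1", parent2_pct = "Parent2",
                  unknown_pct = "Unknown") |>
    dplyr::select("individual", "chrom", "n_genes", "parent1_pct",
                  "parent2_pct", "unknown_pct") |>
    dplyr::arrange(.data$individual, .data$chrom)
  as_contributions(out, kind = "gene")
}

#' Read gene intervals from a GTF annotation
#'
#' Imports a GTF via `rtracklayer` and reduces it to one interval per
#' `gene_id`: rows with feature type `gene` when present, otherwise the
#' union (range) of each gene's `exon` rows — so minimal or filtered GTFs
#' that carry only exon features still work. Records without a parseable
#' `gene_id` attribute are skipped with a counted warning; duplicate
#' `gene` rows for one `gene_id` keep the first with a warning. GTF
#' coordinates are 1-based closed and kept that way.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   sorted by `(chrom, start)`.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) {
    stop("GTF file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  d <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    type = as.character(gr$type),
    gene_id = if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$gene_id)
    } else {
      NA_character_
    }
  )
  n_noid <- sum(is.na(d$gene_id) | d$gene_id == "")
  if (n_noid > 0L) {
    warning(n_noid, " GTF record(s) without a gene_id attribute skipped.",
            call. = FALSE)
    d <- d[!(is.na(d$gene_id) | d$gene_id == ""), , drop = FALSE]
  }
  genes <- if (any(d$type == "gene")) {
    g <- d[d$type == "gene", , drop = FALSE]
    if (anyDuplicated(g$gene_id) > 0L) {
      warning("Duplicate gene rows for some gene_id values; keeping the ",
              "first occurrence.", call. = FALSE)
      g <- g[!duplicated(g$gene_id), , drop = FALSE]
    }
    g
  } else {
    d[d$type == "exon", , drop = FALSE] |>
      dplyr::summarise(
        chrom = dplyr::first(.data$chrom),
        start = min(.data$start),
        end = max(.data$end),
        .by = "gene_id"
      )
  }
  if (nrow(genes) == 0L) {
    stop("No usable 'gene' or 'exon' records in GTF '", path, "'.",
         call. = FALSE)
  }
  genes |>
    dplyr::select("gene_id", "chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write contribution percentages as a tidy TSV
#'
#' Long format (`individual`, `chrom`, `label`, `pct`), percentages to one
#' decimal place — ready for downstream ggplot2 use.
#'
#' @param contributions An `ancestry_contributions` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contributions <- function(contributions, path) {
  long <- contributions_long(contributions) |>
    dplyr::mutate(pct = round(.data$pct, 1))
  readr::write_tsv(long[, c("individual", "chrom", "label", "pct")], path)
  invisible(path)
}

# wide percentages -> long (individual, chrom, label, pct)
contributions_long <- function(x) {
  check_cols(x, c("individual", "chrom", "parent1_pct", "parent2_pct",
                  "unknown_pct"), "contributions")
  x |>
    tibble::as_tibble() |>
    dplyr::select("individual", "chrom", Parent1 = "parent1_pct",
                  Parent2 = "parent2_pct", Unknown = "unknown_pct") |>
    tidyr::pivot_longer(dplyr::all_of(ancestry_levels()),
                        names_to = "label", values_to = "pct")
}

add_missing_labels <- function(x) {
  for (l in ancestry_levels()) {
    if (!l %in% names(x)) x[[l]] <- 0
  }
  x
}

as_contributions <- function(x, kind) {
  class(x) <- unique(c("ancestry_contributions",
                       class(tibble::as_tibble(x))))
  attr(x, "kind") <- kind
  x
}
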