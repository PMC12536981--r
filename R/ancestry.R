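# Ancestry assignment: match each homozygous offspring SNP against the two
# parental alleles at the same site. Purely deterministic — exact allele
# matches, no statistical inference.

#' Assign a parent-of-origin label to offspring alleles
#'
#' Vectorized labeling rule for a site where the offspring allele is known
#' and at least one parental allele is known (`NA` marks a parent that
#' lacks the site):
#' * `Parent1` — the offspring allele equals the Parent1 allele and does
#'   not equal the Parent2 allele (including Parent2 absent);
#' * `Parent2` — symmetric;
#' * `Unknown` — the allele matches both parents (uninformative site) or
#'   matches neither, including a mismatch against the only parent that
#'   carries the site.
#'
#' @param offspring_allele Character vector of offspring alleles.
#' @param parent1_allele,parent2_allele Character vectors of parental
#'   alleles; `NA` where the parent does not carry the site.
#' @return Character vector over [ancestry_levels()].
#' @details Swapping the two parent arguments swaps every
#'   `Parent1`/`Parent2` label and changes nothing else.
#' @export
#' @examples
#' assign_label(c("G", "G", "G"), c("G", "A", "G"), c("A", "G", "G"))
assign_label <- function(offspring_allele, parent1_allele, parent2_allele) {
  n <- length(offspring_allele)
  if (length(parent1_allele) != n || length(parent2_allele) != n) {
    stop("Allele vectors must have equal length.", call. = FALSE)
  }
  both_absent <- is.na(parent1_allele) & is.na(parent2_allele)
  if (any(both_absent)) {
    stop("Both parental alleles absent at ", sum(both_absent),
         " site(s); such sites must be discarded upstream.", call. = FALSE)
  }
  m1 <- !is.na(parent1_allele) & offspring_allele == parent1_allele
  m2 <- !is.na(parent2_allele) & offspring_allele == parent2_allele
  dplyr::case_when(
    m1 & !m2 ~ "Parent1",
    m2 & !m1 ~ "Parent2",
    .default = "Unknown"
  )
}

#' Build the offspring-vs-parents comparison table
#'
#' Joins one offspring SNP-call set against the two parental call sets on
#' `(chrom, pos)` and labels every retained site. Only sites present in at
#' least one parent are kept; sites absent from both parents are discarded
#' and counted. The result is sorted by `(chrom, pos)` — the order the
#' clustering pass consumes.
#'
#' @param offspring,parent1,parent2 SNP-call tibbles with columns `chrom`,
#'   `pos`, `allele`, deduplicated on `(chrom, pos)` (as produced by
#'   [read_snp_calls()]).
#' @return A tibble with columns `chrom`, `pos`, `offspring`, `parent1`,
#'   `parent2` (allele characters, `NA` where a parent lacks the site) and
#'   `label`. Attribute `"n_discarded"` counts offspring sites dropped
#'   because neither parent carries them.
#' @export
#' @examples
#' off <- tibble::tibble(chrom = "chr1", pos = 100L, allele = "G")
#' p1  <- tibble::tibble(chrom = "chr1", pos = 100L, allele = "G")
#' p2  <- tibble::tibble(chrom = "chr1", pos = 100L, allele = "A")
#' build_comparison_table(off, p1, p2)
build_comparison_table <- function(offspring, parent1, parent2) {
  off <- check_snp_calls(offspring, "offspring")
  p1 <- check_snp_calls(parent1, "parent1")
  p2 <- check_snp_calls(parent2, "parent2")

  parents <- dplyr::full_join(
    dplyr::select(p1, "chrom", "pos", parent1 = "allele"),
    dplyr::select(p2, "chrom", "pos", parent2 = "allele"),
    by = c("chrom", "pos")
  )
  tab <- off |>
    dplyr::select("chrom", "pos", offspring = "allele") |>
    dplyr::inner_join(parents, by = c("chrom", "pos")) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(label = assign_label(.data$offspring, .data$parent1,
                                       .data$parent2))
  attr(tab, "n_discarded") <- nrow(off) - nrow(tab)
  tab
}

#' Write a comparison table as TSV
#'
#' Human-readable per-individual output: tab-separated with a header row,
#' columns `chrom`, `pos`, `offspring`, `parent1`, `parent2`, `label`.
#'
#' @param tab Comparison table from [build_comparison_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(tab, path) {
  check_cols(tab, c("chrom", "pos", "offspring", "parent1", "parent2",
                    "label"), "tab")
  readr::write_tsv(tab[, c("chrom", "pos", "offspring", "parent1",
                           "parent2", "label")], path)
  invisible(path)
}

check_snp_calls <- function(x, what) {
  check_cols(x, c("chrom", "pos", "allele"), what)
  dup <- duplicated(paste(x$chrom, x$pos, sep = "\r"))
  if (any(dup)) {
    stop("`", what, "` has duplicate (chrom, pos) entries, e.g. ",
         paste(sprintf("%s:%d", x$chrom[dup], x$pos[dup])[
           seq_len(min(3L, sum(dup)))], collapse = ", "),
         call. = FALSE)
  }
  x
}
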