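#' Marker quality-control filter
#'
#' Removes monomorphic markers and markers with a heterozygote proportion
#' strictly above `max_het`, a missing proportion strictly above
#' `max_missing`, or a minor-allele frequency below `min_maf` (MAF equal to
#' the threshold is retained). The line set is never changed. The missing
#' threshold defaults to the permissive 80% used in array panels of inbred
#' lines; tighten it for denser platforms.
#'
#' @param geno A [geno_matrix()].
#' @param max_het Maximum heterozygote proportion (strict `>` removes).
#' @param max_missing Maximum missing proportion (strict `>` removes).
#' @param min_maf Minimum minor-allele frequency (`<` removes).
#' @return The filtered [geno_matrix()].
#' @export
marker_qc <- function(geno, max_het = 0.10, max_missing = 0.80,
                      min_maf = 0.05) {
  assert_scalar_prob(max_het, "max_het")
  assert_scalar_prob(max_missing, "max_missing")
  assert_scalar_prob(min_maf, "min_maf")
  st <- marker_stats(geno)
  keep <- !is.na(st$maf) & st$maf >= min_maf & st$maf > 0 &
    st$het <= max_het & st$missing <= max_missing
  if (!any(keep)) abort("no markers survive QC")
  geno[, keep]
}

#' Pairwise linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of coded calls across lines with complete,
#' homozygous data at both markers: heterozygous (`0`) and missing calls
#' are dropped pairwise, treating near-inbred lines as haplotypes.
#'
#' @param geno A [geno_matrix()].
#' @param marker_i,marker_j Marker ids.
#' @return A single r-squared value in `[0, 1]`.
#' @export
pairwise_r2 <- function(geno, marker_i, marker_j) {
  m <- geno_calls(select_markers(geno, c(marker_i, marker_j)))
  x <- m[, marker_i]
  y <- m[, marker_j]
  ok <- !is.na(x) & !is.na(y) & x != 0 & y != 0
  if (sum(ok) < 2) abort("fewer than 2 complete homozygous pairs: LD undefined")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("marker monomorphic on the complete-pair subset: LD undefined")
  }
  cor(x[ok], y[ok])^2
}

# full pairwise r^2 matrix on the homozygous-complete convention; NA where
# undefined (monomorphic on the shared subset)
ld_r2_matrix <- function(geno) {
  m <- geno_calls(geno)
  m[m == 0] <- NA_real_  # hets dropped pairwise, like missing
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  r^2
}

#' Greedy tag-SNP selection
#'
#' Selects a set of tag SNPs such that every non-tag marker is in LD
#' (`r^2 >= r2_threshold`) with at least one tag. Greedy rule: repeatedly
#' pick the marker covering the largest number of still-uncovered markers
#' (itself included); ties break to the lowest genome-order index. Markers
#' whose pairwise LD is undefined with everything tag themselves.
#'
#' @param geno A QC-filtered [geno_matrix()].
#' @param r2_threshold LD threshold defining coverage.
#' @return A tibble `marker`, `chrom`, `pos_cm`, `n_covered` (markers the
#'   tag covered at selection time), in genome order.
#' @export
tag_snps <- function(geno, r2_threshold = 0.8) {
  assert_scalar_prob(r2_threshold, "r2_threshold")
  r2 <- ld_r2_matrix(geno)
  p <- ncol(r2)
  cover <- !is.na(r2) & r2 >= r2_threshold
  diag(cover) <- TRUE
  uncovered <- rep(TRUE, p)
  picked <- integer(0)
  n_cov <- integer(0)
  gain <- colSums(cover)
  while (any(uncovered)) {
    best <- which.max(gain)  # ties -> lowest index = genome order
    picked <- c(picked, best)
    n_cov <- c(n_cov, gain[best])
    newly <- which(uncovered & cover[, best])
    uncovered[newly] <- FALSE
    # incremental gain update: markers covering a newly covered marker
    # lose one unit each
    gain <- gain - colSums(cover[newly, , drop = FALSE])
  }
  ord <- order(picked)
  map <- marker_map(geno)[picked[ord], ]
  mutate(map, n_covered = n_cov[ord])
}

#' Thin a tag-SNP set into half, fourth, and eighth densities
#'
#' From the genome-ordered tag list, every other marker forms the half-tag
#' set, every fourth the 4th-tag set, and every eighth the 8th-tag set,
#' always anchored at the first tag (sizes `ceiling(n/2)`, `ceiling(n/4)`,
#' `ceiling(n/8)`).
#'
#' @param tags Tibble from [tag_snps()] (or any tibble with `marker`,
#'   `chrom`, `pos_cm`), assumed/re-sorted in genome order.
#' @return A named list of marker-id character vectors: `half_tag`,
#'   `4th_tag`, `8th_tag`.
#' @export
thin_marker_sets <- function(tags) {
  tags <- arrange(tags, .data$chrom, .data$pos_cm)
  ids <- tags$marker
  n <- length(ids)
  list(
    half_tag = ids[seq(1, n, by = 2)],
    `4th_tag` = ids[seq(1, n, by = 4)],
    `8th_tag` = ids[seq(1, n, by = 8)]
  )
}

#' Build the five standard marker sets
#'
#' Convenience wrapper returning `all`, `tag`, `half_tag`, `4th_tag`,
#' `8th_tag` marker-id vectors for a QC-filtered panel.
#'
#' @inheritParams tag_snps
#' @return Named list of marker-id character vectors.
#' @export
marker_density_sets <- function(geno, r2_threshold = 0.8) {
  tags <- tag_snps(geno, r2_threshold)
  c(list(all = marker_map(geno)$marker, tag = tags$marker),
    thin_marker_sets(tags))
}
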