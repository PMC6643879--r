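#' Simulate a genetic map
#'
#' Builds a marker map over `n_chrom` chromosomes of `chrom_length_cm`
#' centiMorgans each. Positions are evenly spaced by default or drawn
#' uniformly (then sorted) when `positions = "random"`; positions are always
#' strictly increasing within a chromosome. The default genome (20
#' chromosomes x 130 markers x 100 cM) mirrors a ~2,600-SNP soybean array
#' panel at roughly 130 SNPs per chromosome.
#'
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome.
#' @param chrom_length_cm Map length per chromosome in centiMorgans.
#' @param positions `"even"` or `"random"`.
#' @param seed Integer seed (used only for `positions = "random"`).
#' @return A tibble with columns `marker`, `chrom`, `pos_cm`.
#' @export
#' @examples
#' sim_genetic_map(n_chrom = 2, markers_per_chrom = 5)
sim_genetic_map <- function(n_chrom = 20, markers_per_chrom = 130,
                            chrom_length_cm = 100,
                            positions = c("even", "random"), seed = 1L) {
  positions <- match.arg(positions)
  stopifnot(n_chrom >= 1, markers_per_chrom >= 1, chrom_length_cm > 0)
  pos_one <- function(chrom) {
    if (positions == "even") {
      seq(0, chrom_length_cm, length.out = markers_per_chrom + 1L)[-1L]
    } else {
      with_seed(derive_seed(seed, "map", chrom), {
        p <- sort(runif(markers_per_chrom, 0, chrom_length_cm))
        # enforce strict increase at double precision
        p + seq_along(p) * 1e-9
      })
    }
  }
  purrr::map(seq_len(n_chrom), function(cc) {
    tibble(
      marker = sprintf("chr%02d_m%03d", cc, seq_len(markers_per_chrom)),
      chrom = cc,
      pos_cm = pos_one(cc)
    )
  }) |> list_rbind()
}

#' Sample a pool of fully inbred founders
#'
#' Each founder is fully homozygous. With `n_ancestors = 0` the marker
#' allele (0 or 1) is drawn independently per founder from a per-marker
#' base frequency taken from `maf_spectrum` (linkage equilibrium). The
#' default instead makes each founder a mosaic of a small pool of
#' ancestral haplotypes (ancestor switches between adjacent markers with
#' probability `1 - exp(-d / segment_cm)`), emulating the shared ancestry
#' of breeding-program parents: founders then carry long common haplotypes,
#' which is what produces realistic panel-wide linkage disequilibrium and
#' family structure downstream.
#'
#' @param n_founders Number of founder lines (>= 2).
#' @param map A genetic map from [sim_genetic_map()].
#' @param maf_spectrum Either a numeric range `c(lo, hi)` from which base
#'   frequencies of the `1` allele are drawn uniformly, or a function
#'   `f(n)` returning `n` frequencies. Frequencies must lie strictly inside
#'   `(0, 1)`.
#' @param n_ancestors Size of the ancestral haplotype pool (0 = draw
#'   founders in linkage equilibrium).
#' @param segment_cm Mean ancestral segment length in cM.
#' @param seed Integer seed.
#' @return A `founder_pool`: list with `alleles` (founders x markers 0/1
#'   matrix), `base_freq`, and `map`.
#' @export
sim_founders <- function(n_founders, map, maf_spectrum = c(0.2, 0.5),
                         n_ancestors = 4, segment_cm = 40, seed = 1L) {
  stopifnot(n_founders >= 2)
  m <- nrow(map)
  freq <- with_seed(derive_seed(seed, "basefreq"), {
    if (is.function(maf_spectrum)) {
      maf_spectrum(m)
    } else {
      stopifnot(length(maf_spectrum) == 2L)
      runif(m, maf_spectrum[1], maf_spectrum[2])
    }
  })
  if (length(freq) != m || any(!is.finite(freq)) ||
      any(freq <= 0) || any(freq >= 1)) {
    abort("maf_spectrum must yield one frequency per marker, strictly inside (0, 1)")
  }
  alleles <- with_seed(derive_seed(seed, "founders"), {
    if (n_ancestors == 0) {
      matrix(rbinom(n_founders * m, 1L, rep(freq, each = n_founders)),
             nrow = n_founders, ncol = m)
    } else {
      # allele counts per marker: binomial draw clipped so every marker is
      # polymorphic within the ancestral pool (markers can still go
      # monomorphic in any given panel; QC handles those)
      k1 <- pmin(pmax(rbinom(m, n_ancestors, freq), 1L), n_ancestors - 1L)
      anc <- matrix(0L, n_ancestors, m)
      for (j in seq_len(m)) anc[sample.int(n_ancestors, k1[j]), j] <- 1L
      # per-interval ancestor-switch probabilities, chromosome breaks = 1
      p_switch <- 1 - exp(-diff(map$pos_cm) / segment_cm)
      p_switch[diff(map$chrom) != 0] <- 1
      t(vapply(seq_len(n_founders), function(f) {
        sw <- c(TRUE, runif(m - 1) < p_switch)
        idx <- sample.int(n_ancestors, sum(sw), replace = TRUE)
        anc[cbind(idx[cumsum(sw)], seq_len(m))]
      }, integer(m)))
    }
  })
  rownames(alleles) <- sprintf("F%03d", seq_len(n_founders))
  colnames(alleles) <- map$marker
  structure(list(alleles = alleles, base_freq = freq, map = as_tibble(map)),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf("<founder_pool> %d founders x %d markers\n",
              nrow(x$alleles), ncol(x$alleles)))
  invisible(x)
}
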