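# Heterozygote-excess testing at structural-variant loci: PCA + k-means
# assignment of individuals to the six structural genotype clusters,
# genotype-to-allele frequency arithmetic, and the binomial Monte-Carlo
# test for an excess of green/striped heterozygotes.

#' Assign individuals to genotype clusters by PCA + k-means
#'
#' Principal components analysis of the column-mean-centred (unscaled)
#' genotype dosage matrix, followed by k-means on the first two PC
#' scores with multiple starts; the best within-cluster sum of squares
#' over starts is retained. Deterministic under a fixed seed.
#'
#' @param genotypes Individual-by-SNP numeric matrix (dosages 0/1/2).
#' @param k Number of clusters (default 6: three structural homozygotes
#'   and three heterozygotes).
#' @param n_starts k-means restarts.
#' @param max_iter Maximum k-means iterations per start.
#' @param seed Integer seed.
#' @return Object of class `cluster_assignment`: `assignments` (tibble:
#'   `individual`, `PC1`, `PC2`, `cluster`), plus the `kmeans` object
#'   and the PCA variance profile.
#' @export
assign_clusters <- function(genotypes, k = 6, n_starts = 20, max_iter = 500,
                            seed = 1) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < k) {
    stop("need at least k = ", k, " individuals", call. = FALSE)
  }
  pca <- stats::prcomp(genotypes, center = TRUE, scale. = FALSE)
  scores <- pca$x[, 1:2, drop = FALSE]
  if (nrow(unique(scores)) < k) {
    stop("fewer than k = ", k, " distinct points in PC space", call. = FALSE)
  }
  withr::local_seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = n_starts,
                      iter.max = max_iter)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(genotypes)))
  structure(
    list(
      assignments = tibble::tibble(
        individual = ids,
        PC1 = scores[, 1], PC2 = scores[, 2],
        cluster = km$cluster
      ),
      kmeans = km,
      pca_sdev = pca$sdev
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", nrow(x$assignments), "individuals in",
      length(unique(x$assignments$cluster)), "clusters; sizes:",
      paste(x$kmeans$size, collapse = ", "), "\n")
  invisible(x)
}

#' Designate structural genotypes for numeric clusters
#'
#' Clusters are anonymous; their genotype identity (which unordered
#' allele pair over green/striped/melanic each represents) comes from an
#' external designation table built from the phenotypes of the
#' individuals in each cluster. Designation is pure relabelling:
#' frequencies are invariant to it.
#'
#' @param assignment A `cluster_assignment`.
#' @param designation Tibble with columns `cluster` and `genotype`
#'   (values from [genotype_cluster_levels()]).
#' @return The assignments tibble with a `genotype` column.
#' @export
designate_genotypes <- function(assignment, designation) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  bad <- setdiff(designation$genotype, genotype_cluster_levels())
  if (length(bad) > 0) {
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::left_join(assignment$assignments, designation, by = "cluster")
}

#' Allele frequencies from six genotype-class frequencies
#'
#' Each allele's frequency is its homozygote frequency plus half of each
#' heterozygote frequency involving it. Mass is conserved exactly.
#'
#' @param genotype_freqs Numeric vector of the six genotype-class
#'   frequencies, named by [genotype_cluster_levels()] or given in that
#'   order; non-negative, summing to 1 (tolerance 1e-6).
#' @return Named numeric vector `c(green, striped, melanic)`.
#' @examples
#' genotype_to_allele_frequencies(
#'   c(0.005, 0.272, 0.088, 0.095, 0.038, 0.502)
#' )
#' @export
genotype_to_allele_frequencies <- function(genotype_freqs) {
  lev <- genotype_cluster_levels()
  if (!is.null(names(genotype_freqs))) {
    if (!setequal(names(genotype_freqs), lev)) {
      stop("names must be exactly the six genotype classes", call. = FALSE)
    }
    genotype_freqs <- genotype_freqs[lev]
  }
  if (length(genotype_freqs) != 6) {
    stop("need six genotype-class frequencies", call. = FALSE)
  }
  if (any(genotype_freqs < 0)) {
    stop("genotype frequencies must be non-negative", call. = FALSE)
  }
  if (abs(sum(genotype_freqs) - 1) > 1e-6) {
    stop("genotype frequencies must sum to 1", call. = FALSE)
  }
  g <- stats::setNames(as.numeric(genotype_freqs), lev)
  c(
    green = unname(g["green/green"] +
                     (g["green/striped"] + g["green/melanic"]) / 2),
    striped = unname(g["striped/striped"] +
                       (g["green/striped"] + g["striped/melanic"]) / 2),
    melanic = unname(g["melanic/melanic"] +
                       (g["green/melanic"] + g["striped/melanic"]) / 2)
  )
}

#' Binomial Monte-Carlo test for heterozygote excess
#'
#' Draws `reps` samples of `n` individuals from
#' `Binomial(n, expected_het_freq)` and reports the one-sided p-value
#' for an excess: the fraction of null draws at or above the observed
#' heterozygote count (with the add-one correction by default). The
#' exact binomial upper-tail probability is reported alongside as a
#' closed-form cross-check.
#'
#' @param observed_het Observed heterozygote count.
#' @param n Sample size.
#' @param expected_het_freq Expected heterozygote frequency under
#'   Hardy-Weinberg (e.g. `2 * p_green * p_striped`), in (0, 1).
#' @param reps Number of null draws (>= 1).
#' @param seed Integer seed.
#' @param ties Count null draws `">="` (default) or `">"` the observed.
#' @param add_one Apply the add-one Monte-Carlo correction.
#' @return Object of class `het_test`: tibble with `observed`,
#'   `expected_count`, `p_mc`, `p_exact`, `reps`.
#' @export
het_excess_test <- function(observed_het, n, expected_het_freq, reps = 1000,
                            seed = 1, ties = c("geq", "gt"), add_one = TRUE) {
  ties <- match.arg(ties)
  stopifnot(observed_het >= 0, observed_het <= n,
            expected_het_freq > 0, expected_het_freq < 1)
  if (reps < 1) {
    stop("`reps` must be >= 1", call. = FALSE)
  }
  withr::local_seed(seed)
  draws <- stats::rbinom(reps, n, expected_het_freq)
  hits <- if (ties == "geq") sum(draws >= observed_het) else sum(draws > observed_het)
  p_mc <- if (add_one) (hits + 1) / (reps + 1) else hits / reps
  out <- tibble::tibble(
    observed = observed_het,
    n = n,
    expected_het_freq = expected_het_freq,
    expected_count = n * expected_het_freq,
    p_mc = p_mc,
    p_exact = stats::pbinom(observed_het - 1, n, expected_het_freq,
                            lower.tail = FALSE),
    reps = reps
  )
  class(out) <- c("het_test", class(out))
  out
}

#' Heterozygote-excess test from genotype-class frequencies
#'
#' Convenience wrapper: derives allele frequencies from the six
#' genotype-class frequencies, forms the Hardy-Weinberg expected
#' green/striped heterozygote frequency `2 * p_green * p_striped`, and
#' runs [het_excess_test()] against the observed green/striped count.
#'
#' @param genotype_freqs Six genotype-class frequencies (see
#'   [genotype_to_allele_frequencies()]).
#' @param n Sample size.
#' @param observed_het Observed green/striped heterozygote count;
#'   defaults to `round(n * freq(green/striped))`.
#' @inheritParams het_excess_test
#' @return A `het_test` tibble with the allele frequencies attached as
#'   the `allele_freqs` attribute.
#' @export
het_excess_from_genotypes <- function(genotype_freqs, n, observed_het = NULL,
                                      reps = 1000, seed = 1) {
  af <- genotype_to_allele_frequencies(genotype_freqs)
  het_freq <- 2 * af["green"] * af["striped"]
  if (is.null(observed_het)) {
    g <- genotype_freqs
    if (!is.null(names(g))) g <- g[genotype_cluster_levels()]
    g <- stats::setNames(as.numeric(g), genotype_cluster_levels())
    observed_het <- unname(round(n * g["green/striped"]))
  }
  out <- het_excess_test(observed_het, n, unname(het_freq), reps = reps,
                         seed = seed)
  attr(out, "allele_freqs") <- af
  out
}
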