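#' Identity-by-state distance matrix
#'
#' For each pair of samples, over the sites where both calls are non-missing,
#' the number of shared alleles (counting multiplicity) is 2 for identical
#' genotypes, 1 for one shared allele (e.g. `0/0` vs `0/1`) and 0 for
#' opposite homozygotes. IBS is the summed shared alleles over twice the
#' number of jointly non-missing sites, and the reported distance is
#' `d = 1 - IBS`. Missing data are handled pairwise-complete: each pair uses
#' its own site set.
#'
#' @param table A biallelic [variant_table()] with at least 2 samples.
#' @return An `ibs_dist` object: `samples`, symmetric matrix `d` in
#'   `[0, 1]` and `n_sites_used` (per-pair jointly non-missing site counts).
#' @details A pair with zero jointly non-missing sites is an error naming
#'   the pair.
#' @export
ibs_distance <- function(table) {
  m <- n_samples(table)
  if (m < 2) stop("need at least 2 samples")
  dos <- geno_dosage(table)
  if (any(is.na(dos) & !is.na(table$geno))) {
    stop("ibs_distance requires a biallelic table")
  }
  d <- matrix(0, m, m, dimnames = list(table$samples, table$samples))
  n_used <- matrix(0L, m, m, dimnames = dimnames(d))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      both <- !is.na(dos[, i]) & !is.na(dos[, j])
      n <- sum(both)
      if (n == 0) {
        stop("no jointly non-missing sites for pair ",
             table$samples[i], " / ", table$samples[j])
      }
      shared <- 2 - abs(dos[both, i] - dos[both, j])
      ibs <- sum(shared) / (2 * n)
      d[i, j] <- d[j, i] <- 1 - ibs
      n_used[i, j] <- n_used[j, i] <- n
    }
  }
  structure(list(samples = table$samples, d = d, n_sites_used = n_used),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat(sprintf("ibs_dist: %d samples, distances %.4f-%.4f\n",
              length(x$samples), min(x$d[upper.tri(x$d)]),
              max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Hierarchical ascendant clustering of an IBS distance matrix
#'
#' Agglomerative (bottom-up) clustering of the samples, the standard way to
#' visualize population structure from genetic distances. Samples are
#' reordered lexicographically before clustering so that ties break
#' deterministically by sample id.
#'
#' @param dist An `ibs_dist` from [ibs_distance()].
#' @param linkage Agglomeration method: `"average"` (UPGMA, default),
#'   `"complete"` or `"single"`.
#' @return An `snp_dendrogram`: the `hclust` object, a Newick string with
#'   branch lengths, and a `merges` data frame (merge pairs and heights).
#' @export
hierarchical_clustering <- function(dist,
                                    linkage = c("average", "complete", "single")) {
  stopifnot(inherits(dist, "ibs_dist"))
  linkage <- match.arg(linkage)
  if (length(dist$samples) < 2) stop("need at least 2 samples to cluster")
  ord <- order(dist$samples)
  d <- dist$d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  merges <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height)
  structure(list(hclust = hc, newick = newick, merges = merges,
                 linkage = linkage),
            class = "snp_dendrogram")
}

#' @export
print.snp_dendrogram <- function(x, ...) {
  cat(sprintf("snp_dendrogram (%s linkage): %d samples\n", x$linkage,
              length(x$hclust$labels)))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Cut a dendrogram into k clusters
#' @param dendrogram An `snp_dendrogram`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "snp_dendrogram"))
  stats::cutree(dendrogram$hclust, k = k)
}

#' Write a distance matrix as square TSV
#' @param dist An `ibs_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path) {
  d <- as.data.frame(dist$d)
  d <- cbind(sample = rownames(dist$d), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
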