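#' Hypergeometric down-projection of one site
#'
#' Probability vector of observing `0..n` copies of the allele when drawing
#' `n` chromosomes without replacement from `D` genotyped chromosomes of
#' which `d` carry it. This is how sites with missing genotypes still
#' contribute to the SFS.
#'
#' @param d observed allele count (0 <= d <= D).
#' @param D genotyped haploid (chromosome) count at the site.
#' @param n target haploid sample size (n <= D, else an error the caller
#'   turns into dropping the site).
#' @return numeric vector of length `n + 1`, summing to 1.
#' @export
project_site <- function(d, D, n) {
  if (d < 0 || d > D) stop("need 0 <= d <= D", call. = FALSE)
  if (n > D) stop("projection size exceeds genotyped chromosomes", call. = FALSE)
  dhyper(0:n, d, D - d, n)
}

unmasked_entries <- function(dims) {
  m <- matrix(TRUE, dims[1], dims[2])
  m[1, 1] <- FALSE
  m[dims[1], dims[2]] <- FALSE
  m
}

# fold an unfolded (n1+1) x (n2+1) spectrum by pooled minor-allele count;
# boundary mass (i + j == (n1 + n2)/2) is split half-half with its mirror
fold_joint_sfs <- function(u) {
  n1 <- nrow(u) - 1L; n2 <- ncol(u) - 1L
  half <- (n1 + n2) / 2
  f <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) for (j in 0:n2) {
    tot <- i + j
    if (tot < half) {
      f[i + 1, j + 1] <- f[i + 1, j + 1] + u[i + 1, j + 1]
    } else if (tot > half) {
      f[n1 - i + 1, n2 - j + 1] <- f[n1 - i + 1, n2 - j + 1] + u[i + 1, j + 1]
    } else {
      f[i + 1, j + 1] <- f[i + 1, j + 1] + u[i + 1, j + 1] / 2
      f[n1 - i + 1, n2 - j + 1] <- f[n1 - i + 1, n2 - j + 1] + u[i + 1, j + 1] / 2
    }
  }
  f
}

#' Joint folded site-frequency spectrum container
#'
#' @param counts `(n1+1) x (n2+1)` non-negative matrix (deme A allele count
#'   by row, deme B by column).
#' @param projection haploid projection sizes `(n1, n2)`.
#' @param folded logical.
#' @param n_sites_used,n_sites_dropped bookkeeping from construction.
#' @return a `joint_sfs`; the monomorphic corners `(0,0)` and `(n1,n2)` are
#'   always flagged masked and excluded from likelihoods.
#' @export
joint_sfs <- function(counts, projection, folded = TRUE,
                      n_sites_used = NA_integer_, n_sites_dropped = 0L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == projection[1] + 1,
            ncol(counts) == projection[2] + 1, all(counts >= 0))
  structure(list(counts = counts, projection = as.integer(projection),
                 folded = folded, masked_corners = TRUE,
                 n_sites_used = n_sites_used,
                 n_sites_dropped = n_sites_dropped),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("<joint_sfs> projection (%d, %d), %s, unmasked mass %.4g\n",
              x$projection[1], x$projection[2],
              if (x$folded) "folded" else "unfolded", sfs_total(x)))
  invisible(x)
}

#' Total mass over unmasked entries
#' @param sfs a [joint_sfs()].
#' @return numeric scalar.
#' @export
sfs_total <- function(sfs) sum(sfs$counts[unmasked_entries(dim(sfs$counts))])

#' Build the folded joint SFS with down-projection
#'
#' For every site, the per-deme allele-count distributions at the projection
#' sizes are combined as an outer product and accumulated into an unfolded
#' spectrum (oriented by the ALT allele), which is then folded by pooled
#' minor-allele count. Sites with fewer genotyped chromosomes than the
#' projection in either deme are dropped (with a warning above 50%).
#'
#' @param gm a [geno_matrix()] that has *not* been MAF-filtered (the SFS
#'   must retain rare variants; an error enforces this provenance).
#' @param projection haploid sizes `(n1, n2)`; default is per deme the
#'   largest size that keeps at least 80% of sites usable.
#' @return a [joint_sfs()] of per-site probability mass (counts sum to the
#'   number of used sites, up to corner masking).
#' @export
build_joint_folded_sfs <- function(gm, projection = NULL) {
  if (isTRUE(gm$maf_filtered))
    stop("SFS input must not be MAF-filtered", call. = FALSE)
  idx <- species_index(gm)
  if (length(idx) != 2) stop("exactly two species required", call. = FALSE)
  a <- site_allele_counts(gm, idx[[1]])
  b <- site_allele_counts(gm, idx[[2]])
  if (is.null(projection)) {
    projection <- c(quantile(a$chroms, 0.2, type = 1),
                    quantile(b$chroms, 0.2, type = 1))
  }
  projection <- as.integer(projection)
  n1 <- projection[1]; n2 <- projection[2]
  usable <- a$chroms >= n1 & b$chroms >= n2
  if (mean(usable) < 0.5)
    warning(sprintf("%.0f%% of sites dropped by the projection",
                    100 * mean(!usable)))
  u <- matrix(0, n1 + 1L, n2 + 1L)
  for (s in which(usable)) {
    v1 <- dhyper(0:n1, a$alt[s], a$chroms[s] - a$alt[s], n1)
    v2 <- dhyper(0:n2, b$alt[s], b$chroms[s] - b$alt[s], n2)
    u <- u + outer(v1, v2)
  }
  joint_sfs(fold_joint_sfs(u), projection, folded = TRUE,
            n_sites_used = sum(usable), n_sites_dropped = sum(!usable))
}
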