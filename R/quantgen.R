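#' Define an infinitesimal quantitative trait
#'
#' A trait assigns every mapped locus an additive effect `a` and a dominance
#' effect `d` around an intercept `m`, in the classical genotypic-value
#' parameterization: the homozygote for the bit-1 allele contributes `+a`,
#' the heterozygote `d`, and the homozygote for the bit-0 allele `-a`.
#' Scalars are broadcast to all loci, so `trait_infty(spp, m = 0, a = 1,
#' d = 0)` is the usual infinitesimal additive trait.
#'
#' @param specie a [make_specie()] object.
#' @param m trait intercept.
#' @param a additive effect, scalar or one value per locus.
#' @param d dominance effect, scalar or one value per locus.
#' @return a `trait`.
#' @export
trait_infty <- function(specie, m = 0, a = 1, d = 0) {
  if (!is_specie(specie)) stop_input("not a specie")
  n <- sum(specie$n_loci)
  bc <- function(v, what) {
    if (length(v) == 1L) v <- rep(as.numeric(v), n)
    if (length(v) != n)
      stop_input(paste0(what, " effects must be scalar or length ", n))
    if (anyNA(v)) stop_input(paste0(what, " effects must not be NA"))
    v
  }
  structure(list(specie = specie, m = as.numeric(m),
                 a = bc(a, "additive"), d = bc(d, "dominance")),
            class = "trait")
}

#' @export
print.trait <- function(x, ...) {
  cat("<trait> ", length(x$a), " loci; m = ", x$m,
      "; mean |a| = ", signif(mean(abs(x$a)), 3),
      "; mean |d| = ", signif(mean(abs(x$d)), 3), "\n", sep = "")
  invisible(x)
}

#' Genetic value of individuals
#'
#' The genotypic value under a trait: `m + sum_j g_j` with `g_j = +a_j` for
#' dosage-2 loci, `d_j` for heterozygous loci and `-a_j` for dosage-0 loci.
#' This is the true breeding value ("alpha") used as the phenotype mean in
#' simulation studies.
#'
#' @param population a `population`, `individual`, or list of individuals.
#' @param trait a [trait_infty()] object of the same specie.
#' @return numeric vector, one value per individual.
#' @export
genetic_value <- function(population, trait) {
  if (!inherits(trait, "trait")) stop_input("not a trait")
  inds <- as_individual_list(population)
  if (!identical(inds[[1]]$specie, trait$specie))
    stop_incompatible("trait and individuals belong to different species")
  M <- genotype_numeric(inds)
  # dosage - 1 in {-1,0,1} weights a; indicator of dosage 1 weights d
  drop(crossprod(M - 1, trait$a) + crossprod(M == 1L, trait$d)) + trait$m
}

#' Standardize a numeric vector
#'
#' Centers to sample mean zero and scales to sample standard deviation one.
#'
#' @param values numeric vector with at least two distinct values.
#' @return standardized vector.
#' @export
standardize <- function(values) {
  if (anyNA(values) || any(!is.finite(values)))
    stop_input("values must be finite")
  s <- sd(values)
  if (length(values) < 2L || s == 0)
    stop_degenerate("cannot standardize a constant vector")
  (values - mean(values)) / s
}

#' Simulate phenotypes at a target heritability
#'
#' Adds independent Gaussian noise to standardized genetic values:
#' `phenotype_i = alpha_i + e_i` with `e_i ~ N(0, (1 - h2)/h2)`. Because the
#' genetic values have unit variance, the realized narrow-sense heritability
#' `Var(alpha) / (Var(alpha) + Var(e))` targets `h2`.
#'
#' @param alphas_std standardized genetic values (see [standardize()]).
#' @param h2 target heritability in `(0, 1]`; `h2 = 1` returns the genetic
#'   values unchanged.
#' @return a `phenotype_set` tibble with columns `alpha` and `phenotype` and
#'   attribute `h2`.
#' @export
simulate_phenotypes <- function(alphas_std, h2) {
  if (length(h2) != 1L || !is.finite(h2) || h2 <= 0 || h2 > 1)
    stop_input("h2 must lie in (0, 1]")
  if (anyNA(alphas_std)) stop_input("alphas must be finite")
  e_sd <- sqrt((1 - h2) / h2)
  out <- tibble::tibble(
    alpha = as.numeric(alphas_std),
    phenotype = as.numeric(alphas_std) + rnorm(length(alphas_std), 0, e_sd))
  structure(out, h2 = h2, class = c("phenotype_set", class(out)))
}

#' VanRaden realized genomic relationship matrix
#'
#' G = Z'Z / (2 * sum p_j (1 - p_j)) where Z is the dosage matrix with each
#' locus (row) centered by twice its allele frequency. Frequencies default to
#' the observed ones in the analyzed population; a known base-population
#' frequency (0.5 for an F2 from contrasting inbreds) can be supplied
#' instead. Monomorphic loci (under observed frequencies) carry no
#' information and are dropped with a notice.
#'
#' @param M dosage matrix in `{0,1,2}`, loci in rows, individuals in columns
#'   (as returned by [genotype_numeric()]).
#' @param p allele frequencies: `NULL` (observed, default), a single value
#'   applied to all loci, or one value per locus.
#' @return a symmetric `kinship` matrix (flavor `"G"`) over the individuals.
#' @export
kinship_vanraden <- function(M, p = NULL) {
  M <- as.matrix(M)
  if (ncol(M) < 2L) stop_input("need at least two individuals")
  if (anyNA(M) || !all(M %in% 0:2)) stop_input("dosages must be in {0,1,2}")
  obs <- rowMeans(M) / 2
  if (is.null(p)) p <- obs
  else if (length(p) == 1L) p <- rep(p, nrow(M))
  if (length(p) != nrow(M)) stop_input("p must be scalar or one per locus")
  keep <- obs > 0 & obs < 1
  if (!any(keep)) stop_degenerate("all loci are monomorphic")
  if (!all(keep))
    inform(sprintf("dropping %d monomorphic locus/loci", sum(!keep)))
  Mk <- M[keep, , drop = FALSE]
  pk <- p[keep]
  Z <- Mk - 2 * pk
  denom <- 2 * sum(pk * (1 - pk))
  G <- crossprod(Z) / denom
  G <- (G + t(G)) / 2
  new_kinship(G, "G")
}

new_kinship <- function(K, flavor) {
  structure(K, flavor = flavor, class = c("kinship", "matrix", "array"))
}

#' @export
print.kinship <- function(x, ...) {
  cat("<kinship ", attr(x, "flavor"), "> ", nrow(x), " x ", ncol(x),
      "; mean diagonal ", signif(mean(diag(x)), 4), "\n", sep = "")
  invisible(x)
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' Numerator relationship matrix A over a pedigree sorted parents-first:
#' `A_ii = 1 + A_(m,f)/2` and `A_ij = (A_(j,m) + A_(j,f))/2`, with unknown
#' parents treated as unrelated non-inbred founders.
#'
#' @param ped data frame with columns `id`, `mother`, `father` (NA for
#'   unknown), each parent appearing as an id before its offspring.
#' @return a symmetric `kinship` matrix (flavor `"A"`) over the ids.
#' @export
kinship_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  if (!all(c("id", "mother", "father") %in% names(ped)))
    stop_input("pedigree needs columns id, mother, father")
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop_input("duplicated pedigree ids")
  n <- length(ids)
  mi <- match(as.character(ped$mother), ids)
  fi <- match(as.character(ped$father), ids)
  known_m <- !is.na(ped$mother)
  known_f <- !is.na(ped$father)
  if (any(known_m & is.na(mi)) || any(known_f & is.na(fi)))
    stop_input("pedigree refers to parents absent from the id column")
  if (any(stats::na.omit(mi >= seq_len(n))) ||
      any(stats::na.omit(fi >= seq_len(n))))
    stop_input("parents must precede offspring (no cycles)")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m <- mi[i]; f <- fi[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      am <- if (is.na(m)) rep(0, i - 1L) else A[j, m]
      af <- if (is.na(f)) rep(0, i - 1L) else A[j, f]
      A[j, i] <- A[i, j] <- (am + af) / 2
    }
    A[i, i] <- 1 + (if (is.na(m) || is.na(f)) 0 else A[m, f] / 2)
  }
  new_kinship(A, "A")
}

#' Single-kernel REML variance components
#'
#' Fits `y = 1*mu + g + e` with `g ~ N(0, vA * K)` and `e ~ N(0, vE * I)` by
#' restricted maximum likelihood. K is spectrally decomposed once; the REML
#' log-likelihood is profiled down to the variance ratio `lambda = vA / vE`
#' and maximized by Brent search over `log(lambda)` in `[-10, 10]`
#' (convergence tolerance 1e-8; deterministic). Eigenvalues of K below
#' -1e-8 are an error; small negative values are clipped to zero.
#'
#' @param y numeric phenotype vector.
#' @param K kinship matrix (positive semidefinite) over the same
#'   individuals, in the same order.
#' @return a `vc_fit`: list with `vA`, `vE`, `h2` (= vA/(vA+vE)), `lambda`,
#'   `mu`, `loglik` (profiled REML, up to a constant), `converged` (FALSE
#'   when the ratio hits a search boundary, e.g. noise-free data), `n`.
#' @export
fit_variance_components <- function(y, K) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y) || any(!is.finite(y))) stop_input("phenotypes must be finite")
  K <- unclass(as.matrix(K))
  if (!isTRUE(all.equal(dim(K), c(n, n), check.attributes = FALSE)))
    stop_input("K must be n x n for n phenotypes")
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- eig$values
  if (any(d < -1e-8)) stop_input("K is not positive semidefinite")
  d[d < 0] <- 0
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  reml <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1
    w <- 1 / v
    xwx <- sum(xt^2 * w)
    beta <- sum(xt * w * yt) / xwx
    r <- yt - xt * beta
    rwr <- sum(r^2 * w)
    -0.5 * ((n - 1) * log(rwr / (n - 1)) + sum(log(v)) + log(xwx))
  }
  lo <- -10; hi <- 10
  opt <- optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-8)
  loglam <- opt$maximum
  lam <- exp(loglam)
  v <- lam * d + 1
  w <- 1 / v
  xwx <- sum(xt^2 * w)
  mu <- sum(xt * w * yt) / xwx
  r <- yt - xt * mu
  vE <- sum(r^2 * w) / (n - 1)
  converged <- loglam > lo + 1e-3 && loglam < hi - 1e-3
  structure(list(vA = lam * vE, vE = vE, h2 = lam / (lam + 1),
                 lambda = lam, mu = mu, loglik = opt$objective,
                 converged = converged, n = n),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> n = ", x$n,
      "; vA = ", signif(x$vA, 4), ", vE = ", signif(x$vE, 4),
      ", h2 = ", signif(x$h2, 3),
      if (!x$converged) " (ratio at search boundary)", "\n", sep = "")
  invisible(x)
}
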