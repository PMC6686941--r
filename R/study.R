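#' Replicated F2:3 variance-partitioning study
#'
#' End-to-end simulation comparing variance-component estimates obtained with
#' the realized genomic relationship matrix (VanRaden G, which captures
#' Mendelian sampling) against the pedigree expectation (tabular-method A).
#' Each replicate, on a fresh specie over `map`:
#'
#' 1. two contrasting homozygous founders and their F1 are created; the F1 is
#'    selfed to an F2 of size `N`, and each F2 plant is selfed to `P` F2:3
#'    progeny (`N * P` phenotyped individuals);
#' 2. true breeding values under an infinitesimal additive trait
#'    (`m = 0, a = 1, d = 0`) are standardized over all F2:3 and phenotypes
#'    are drawn with noise variance `(1 - h2)/h2`;
#' 3. the F2:3 are genotyped; G is computed from dosages and A from the
#'    recorded pedigree;
#' 4. both single-kernel REML models are fitted and the additive and residual
#'    variance estimates collected.
#'
#' @param N F2 population size.
#' @param P progeny per F2 plant.
#' @param h2 target heritability of the simulated phenotypes.
#' @param replicates number of independent replicates.
#' @param seed integer seed; the whole table is reproducible from it.
#' @param map genetic map; default the five-chromosome, 1000-loci-per-
#'   chromosome, two-Morgan fixture.
#' @return an `f23_study` tibble with one row per replicate and columns
#'   `replicate`, `vAP`, `vEP` (pedigree-A fit), `vAG`, `vEG` (realized-G
#'   fit), `h2P`, `h2G` (the per-fit `vA/(vA+vE)` ratios).
#' @examples
#' run_f23_study(N = 6, P = 2, h2 = 0.5, replicates = 1, seed = 1,
#'               map = fixture_map(2, 50, 1))
#' @export
run_f23_study <- function(N, P, h2, replicates = 100, seed = 1L,
                          map = fixture_map(5, 1000, 2)) {
  if (N < 2 || P < 1 || replicates < 1) stop_input("invalid study sizes")
  if (!inherits(map, "genetic_map")) map <- load_map(map)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, replicates)

  rows <- purrr::map(seq_len(replicates), function(r) {
    res <- f23_replicate(N, P, h2, rep_seeds[r], map)
    tibble::tibble(replicate = r,
                   vAP = res$fitA$vA, vEP = res$fitA$vE,
                   vAG = res$fitG$vA, vEG = res$fitG$vE,
                   h2P = res$fitA$h2, h2G = res$fitG$h2)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, N = N, P = P, h2 = h2, seed = seed,
            class = c("f23_study", class(out)))
}

# one replicate; also used directly by tests that need the intermediates
f23_replicate <- function(N, P, h2, seed, map) {
  spp <- make_specie(map, seed = seed)
  trait <- trait_infty(spp, m = 0, a = 1, d = 0)
  P1 <- founder(spp, "AA")
  P2 <- mirror(P1)
  F1 <- cross(1, P1, P2)[[1]]
  F2 <- selfcross(N, F1)
  fams <- lapply(seq_len(N), function(i) selfcross(P, F2[[i]]))
  F23 <- do.call(c, fams)

  alphas <- standardize(genetic_value(F23, trait))
  set.seed(seed %% 1000003L + 1L) # phenotype-noise stream, distinct from meiosis
  phen <- simulate_phenotypes(alphas, h2)

  G <- kinship_vanraden(genotype_numeric(F23))
  A_full <- kinship_pedigree(pedigree(F23))
  labs <- F23$labels
  A <- new_kinship(unclass(A_full)[labs, labs], "A")

  list(fitA = fit_variance_components(phen$phenotype, A),
       fitG = fit_variance_components(phen$phenotype, G),
       phen = phen, G = G, A = A, F2 = F2, F23 = F23, specie = spp)
}

#' @export
print.f23_study <- function(x, ...) {
  cat("<f23_study> ", nrow(x), " replicate(s); N = ", attr(x, "N"),
      ", P = ", attr(x, "P"), ", target h2 = ", attr(x, "h2"), "\n", sep = "")
  NextMethod()
}

#' Write the study results table
#'
#' One row per replicate with the collected statistics, column names
#' `VG.vAP`, `VG.vAG`, `Ve.vEP`, `Ve.vEG`, preceded by a reproducibility
#' header recording the seed and sizes.
#'
#' @param study an `f23_study` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  if (!inherits(study, "f23_study")) stop_input("not an f23_study")
  df <- data.frame(replicate = study$replicate,
                   VG.vAP = study$vAP, VG.vAG = study$vAG,
                   Ve.vEP = study$vEP, Ve.vEG = study$vEG)
  write_with_header(df, path, c(
    seed = attr(study, "seed"), N = attr(study, "N"), P = attr(study, "P"),
    h2 = attr(study, "h2"), model = "count_location"))
  invisible(path)
}
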