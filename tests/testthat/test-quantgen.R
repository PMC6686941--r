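test_that("traits broadcast scalar effects and validate vector lengths", {
  spp <- make_specie(fixture_map(2, 10, 1), seed = 1)
  tr <- trait_infty(spp, m = 0, a = 1, d = 0)
  expect_length(tr$a, 20)
  expect_true(all(tr$a == 1))
  expect_error(trait_infty(spp, a = c(1, 2)), class = "bitqg_error_input")
})

test_that("genetic values follow the -a / d / +a parameterization", {
  n_loci <- 20
  spp <- make_specie(fixture_map(2, n_loci / 2, 1), seed = 2)
  tr <- trait_infty(spp, m = 0, a = 1, d = 0)
  AA <- founder(spp, "AA")
  aa <- founder(spp, "aa")
  F1 <- cross(1, AA, aa)[[1]]
  expect_equal(unname(genetic_value(AA, tr)), n_loci)
  expect_equal(unname(genetic_value(aa, tr)), -n_loci)
  expect_equal(unname(genetic_value(F1, tr)), 0)
  # dominance moves only the heterozygote; intercept shifts everything
  trd <- trait_infty(spp, m = 3, a = 1, d = 0.5)
  expect_equal(unname(genetic_value(F1, trd)), 3 + 0.5 * n_loci)
  expect_equal(unname(genetic_value(AA, trd)), 3 + n_loci)
  # a null trait gives everyone the intercept
  tr0 <- trait_infty(spp, m = 10, a = 0, d = 0)
  expect_equal(unname(genetic_value(selfcross(5, F1), tr0)), rep(10, 5))
})

test_that("genetic value is linear in the effect vectors", {
  spp <- make_specie(fixture_map(1, 12, 1), seed = 3)
  F2 <- selfcross(8, cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]])
  set.seed(4)
  a1 <- rnorm(12); d1 <- rnorm(12)
  a2 <- rnorm(12); d2 <- rnorm(12)
  m <- 1.5
  v_sum <- genetic_value(F2, trait_infty(spp, m, a1 + a2, d1 + d2))
  v_parts <- genetic_value(F2, trait_infty(spp, m, a1, d1)) +
    genetic_value(F2, trait_infty(spp, m, a2, d2)) - m
  expect_equal(v_sum, v_parts)
})

test_that("standardize centers and scales, and rejects degenerate input", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 5, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), class = "bitqg_error_degenerate")
})

test_that("simulated phenotypes hit the target heritability", {
  set.seed(5)
  al <- standardize(rnorm(2000))
  exact <- simulate_phenotypes(al, h2 = 1)
  expect_equal(exact$phenotype, exact$alpha)
  ph <- simulate_phenotypes(al, h2 = 0.5)
  e <- ph$phenotype - ph$alpha
  expect_gt(var(e), 0.9) # (1-h2)/h2 = 1, chi-square 99% band at n = 2000
  expect_lt(var(e), 1.1)
  slope <- coef(lm(ph$phenotype ~ ph$alpha))[2]
  se <- sqrt(var(e) / (2000 * var(ph$alpha)))
  expect_lt(abs(slope - 1), 3 * se)
  expect_error(simulate_phenotypes(al, 0), class = "bitqg_error_input")
  expect_error(simulate_phenotypes(al, 1.2), class = "bitqg_error_input")
})

test_that("VanRaden G equals the brute-force double loop", {
  set.seed(6)
  for (rep in 1:5) {
    M <- matrix(sample(0:2, 20 * 30, replace = TRUE), nrow = 20)
    expect_lt(max(abs(unclass(kinship_vanraden(M)) - vanraden_loop(M))),
              1e-10)
  }
  # fixed base frequency flag
  M <- matrix(sample(0:2, 20 * 10, replace = TRUE), nrow = 20)
  expect_lt(max(abs(unclass(kinship_vanraden(M, p = 0.5)) -
                    vanraden_loop(M, p = 0.5))), 1e-10)
})

test_that("VanRaden G is symmetric and self-consistent for duplicates", {
  spp <- make_specie(fixture_map(1, 30, 1), seed = 7)
  F2 <- selfcross(12, cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]])
  M <- genotype_numeric(F2)
  M2 <- cbind(M, dup = M[, 3])
  G <- suppressMessages(kinship_vanraden(M2))
  expect_equal(unclass(G), t(unclass(G)))
  expect_equal(G[3, ncol(M2)], G[ncol(M2), ncol(M2)])
  expect_equal(G[3, 3], G[3, ncol(M2)])
})

test_that("monomorphic loci are dropped and all-monomorphic input errors", {
  M <- rbind(c(0, 1, 2, 1), c(2, 2, 2, 2), c(1, 0, 1, 2))
  expect_message(kinship_vanraden(M), "monomorphic")
  Gk <- suppressMessages(kinship_vanraden(M))
  expect_equal(unclass(Gk), vanraden_loop(M), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(kinship_vanraden(rbind(c(2, 2), c(0, 0))),
               class = "bitqg_error_degenerate")
})

test_that("F2 VanRaden diagonal is near one", {
  spp <- make_specie(fixture_map(5, 100, 2), seed = 8)
  F2 <- selfcross(200, cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]])
  G <- kinship_vanraden(genotype_numeric(F2))
  expect_gt(mean(diag(G)), 0.9)
  expect_lt(mean(diag(G)), 1.1)
})

test_that("pedigree A reproduces tabular-method closed forms", {
  founders <- data.frame(id = c("u", "v"), mother = NA, father = NA)
  expect_equal(unclass(kinship_pedigree(founders)),
               diag(2), ignore_attr = TRUE)

  sibs <- data.frame(id = c("u", "v", "s1", "s2"),
                     mother = c(NA, NA, "u", "u"),
                     father = c(NA, NA, "v", "v"))
  A <- kinship_pedigree(sibs)
  expect_equal(A["s1", "s2"], 0.5)
  expect_equal(A["s1", "s1"], 1)

  selfed <- data.frame(id = c("u", "s"), mother = c(NA, "u"),
                       father = c(NA, "u"))
  expect_equal(kinship_pedigree(selfed)["s", "s"], 1.5)
})

test_that("pedigree A matches hand-computed values on a 3-generation selfing pedigree", {
  # P1 x P2 -> F1; F1 selfed -> two F2; each F2 selfed -> one F3
  ped <- data.frame(
    id = c("P1", "P2", "F1", "F2a", "F2b", "F3a", "F3b"),
    mother = c(NA, NA, "P1", "F1", "F1", "F2a", "F2b"),
    father = c(NA, NA, "P2", "F1", "F1", "F2a", "F2b"))
  A <- kinship_pedigree(ped)
  expect_equal(A["F1", "F1"], 1)
  expect_equal(A["F2a", "F2a"], 1.5)    # F = 1/2 after one selfing
  expect_equal(A["F2a", "F2b"], 1)      # sibs from selfing share A(F2, F1) = 1
  expect_equal(A["F3a", "F3a"], 1.75)   # F = 3/4 after two selfings
  expect_equal(A["F2a", "F3a"], 1.5)    # parent-offspring equals A(F2a, F2a)
  expect_equal(A["F3a", "F3b"], 1)      # across families, through F1
  expect_error(kinship_pedigree(data.frame(id = "x", mother = "y",
                                           father = NA)),
               class = "bitqg_error_input")
  expect_error(kinship_pedigree(data.frame(id = c("a", "b"),
                                           mother = c("b", NA),
                                           father = c(NA, NA))),
               class = "bitqg_error_input")
})

test_that("REML recovers variance components under the generating model", {
  set.seed(9)
  spp <- make_specie(fixture_map(2, 100, 2), seed = 10)
  F2 <- selfcross(100, cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]])
  K <- unclass(kinship_vanraden(genotype_numeric(F2)))
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  draw_y <- function(vA, vE) {
    g <- eg$vectors %*% (sqrt(vA * d) * rnorm(100))
    drop(g) + rnorm(100, 0, sqrt(vE)) + 2
  }
  ratios <- replicate(50, {
    f <- fit_variance_components(draw_y(1, 1), K)
    f$h2
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.05)

  # heritability sweep under the correctly specified model
  for (h2 in c(0.2, 0.5, 0.8)) {
    vA <- h2 / (1 - h2)
    est <- replicate(20, fit_variance_components(draw_y(vA, 1), K)$h2)
    expect_lt(abs(mean(est) - h2), 0.1)
  }
})

test_that("REML degenerates gracefully on identity kinship and zero noise", {
  set.seed(11)
  n <- 200
  y <- rnorm(n, 3, sqrt(2))
  f <- fit_variance_components(y, diag(n))
  # vA and vE are not separately identifiable; their sum is the total variance
  expect_lt(abs((f$vA + f$vE) / var(y) - 1), 0.1)

  spp <- make_specie(fixture_map(1, 50, 1), seed = 12)
  F2 <- selfcross(80, cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]])
  K <- kinship_vanraden(genotype_numeric(F2))
  eg <- eigen(unclass(K), symmetric = TRUE)
  g <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(80))
  f0 <- fit_variance_components(drop(g), K)
  expect_lt(f0$vE, 0.01 * f0$vA)
  expect_false(f0$converged)
  expect_error(fit_variance_components(c(1, NA, 3), diag(3)),
               class = "bitqg_error_input")
})

test_that("the F2:3 study has the right shape and is reproducible", {
  map <- fixture_map(2, 30, 1)
  res <- run_f23_study(N = 10, P = 2, h2 = 0.5, replicates = 3, seed = 21,
                       map = map)
  expect_s3_class(res, "f23_study")
  expect_equal(nrow(res), 3)
  expect_true(all(c("vAP", "vAG", "vEP", "vEG") %in% names(res)))
  expect_true(all(is.finite(as.matrix(res))))
  expect_true(all(res$vAP >= 0 & res$vAG >= 0 & res$vEP >= 0 & res$vEG >= 0))
  res2 <- run_f23_study(N = 10, P = 2, h2 = 0.5, replicates = 3, seed = 21,
                        map = map)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("each replicate simulates N times P progeny", {
  rep1 <- bitqg:::f23_replicate(N = 5, P = 4, h2 = 0.5, seed = 31,
                                map = fixture_map(2, 20, 1))
  expect_length(rep1$F23, 20)
  expect_length(rep1$F2, 5)
  expect_equal(dim(unclass(rep1$G)), c(20, 20))
  expect_equal(dim(unclass(rep1$A)), c(20, 20))
})

test_that("tidiers and plots expose the fitted objects", {
  set.seed(41)
  f <- fit_variance_components(rnorm(30, 0, 1), diag(30))
  td <- tidy(f)
  expect_equal(td$term, c("vA", "vE"))
  expect_equal(td$estimate, c(f$vA, f$vE))
  gl <- glance(f)
  expect_equal(gl$h2, f$h2)

  res <- run_f23_study(N = 6, P = 2, h2 = 0.5, replicates = 2, seed = 51,
                       map = fixture_map(1, 20, 1))
  long <- tidy(res)
  expect_equal(nrow(long), 2 * 4)
  expect_setequal(unique(long$kinship), c("pedigree (A)", "realized (G)"))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")

  K <- kinship_pedigree(data.frame(id = c("a", "b", "k"),
                                   mother = c(NA, NA, "a"),
                                   father = c(NA, NA, "b")))
  tk <- tidy(K)
  expect_equal(nrow(tk), 9)
  expect_equal(tk$kinship[tk$id1 == "a" & tk$id2 == "k"], 0.5)
  expect_s3_class(autoplot(K), "ggplot")

  spp <- make_specie(fixture_map(1, 10, 1), seed = 61)
  F2 <- selfcross(20, cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]])
  expect_s3_class(plot_genotype_frequencies(F2), "ggplot")
})
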