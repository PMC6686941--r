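# shared fixtures and independent oracles, built in code

tiny_map <- function(positions, chr = "1") {
  load_map(data.frame(chr = chr, pos = positions,
                      snp = paste0("m", seq_along(positions))))
}

# contrasting founders and their hybrid on a given map
make_f1 <- function(map, seed = 1, meiosis = meiosis_count_location()) {
  spp <- make_specie(map, meiosis = meiosis, seed = seed)
  AA <- founder(spp, "AA")
  aa <- founder(spp, "aa")
  list(spp = spp, AA = AA, aa = aa, F1 = cross(1, AA, aa)[[1]])
}

# parity oracle for crossover masks: bit j = #{chiasmata <= pos_j} mod 2
parity_mask <- function(chiasmata, positions) {
  vapply(positions, function(x) sum(chiasmata <= x) %% 2L, integer(1)) == 1L
}

# per-bit conditional selection, the definition recombine must reproduce
select_bits <- function(alpha, beta, mask) {
  ifelse(mask, alpha, beta)
}

# brute-force VanRaden G by an explicit double loop over individual pairs
vanraden_loop <- function(M, p = NULL) {
  obs <- rowMeans(M) / 2
  keep <- obs > 0 & obs < 1
  M <- M[keep, , drop = FALSE]
  p <- if (is.null(p)) obs[keep] else rep(p, length.out = nrow(M))
  denom <- 2 * sum(p * (1 - p))
  n <- ncol(M)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- sum((M[, i] - 2 * p) * (M[, j] - 2 * p)) / denom
    }
  }
  G
}

# binomial 3-standard-error tolerance
tol3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
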