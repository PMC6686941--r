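#' Plot an F2:3 study
#'
#' Boxplots of the per-replicate heritability estimates `vA/(vA+vE)` under
#' the pedigree (A) and realized (G) kinship fits, with the simulation target
#' marked by a dashed line.
#'
#' @param object an `f23_study`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.f23_study <- function(object, ...) {
  d <- tibble::tibble(
    kinship = rep(c("pedigree (A)", "realized (G)"), each = nrow(object)),
    h2_hat = c(object$h2P, object$h2G))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kinship, y = .data$h2_hat)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = attr(object, "h2"), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(hat(h)^2),
                  title = "Variance partitioning across replicates") +
    ggplot2::theme_minimal()
}

#' Plot a kinship matrix
#'
#' Heatmap of pairwise relationship coefficients.
#'
#' @param object a `kinship` matrix.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kinship <- function(object, ...) {
  d <- tidy(object)
  d$id1 <- factor(d$id1, levels = unique(d$id1))
  d$id2 <- factor(d$id2, levels = unique(d$id2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id1, y = .data$id2,
                                  fill = .data$kinship)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Kinship (", attr(object, "flavor"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot per-locus genotype frequencies of a population
#'
#' @param population a `population`.
#' @return a ggplot of per-locus frequencies of the three dosage classes.
#' @export
plot_genotype_frequencies <- function(population) {
  M <- genotype_numeric(population)
  d <- tibble::tibble(
    locus = rep(seq_len(nrow(M)), 3L),
    dosage = factor(rep(0:2, each = nrow(M))),
    freq = c(rowMeans(M == 0L), rowMeans(M == 1L), rowMeans(M == 2L)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$freq,
                                  colour = .data$dosage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "locus index", y = "frequency") +
    ggplot2::theme_minimal()
}
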