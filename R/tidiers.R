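#' Tidy a variance-component fit
#'
#' @param x a `vc_fit`.
#' @param ... unused.
#' @return one row per estimated component (`vA`, `vE`) with its estimate.
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(term = c("vA", "vE"), estimate = c(x$vA, x$vE))
}

#' @rdname tidy.vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, lambda = x$lambda, mu = x$mu,
                 loglik = x$loglik, converged = x$converged, nobs = x$n)
}

#' Tidy a kinship matrix
#'
#' @param x a `kinship` matrix.
#' @param ... unused.
#' @return long tibble with columns `id1`, `id2`, `kinship`, `flavor`.
#' @export
tidy.kinship <- function(x, ...) {
  K <- unclass(x)
  ids <- rownames(K) %||% as.character(seq_len(nrow(K)))
  out <- tibble::tibble(
    id1 = rep(ids, times = ncol(K)),
    id2 = rep(ids, each = nrow(K)),
    kinship = as.vector(K))
  out$flavor <- attr(x, "flavor")
  out
}

#' Tidy / summarize an F2:3 study
#'
#' `tidy()` pivots the per-replicate variance estimates into long form;
#' `glance()` reports the study-level means, in particular the mean estimated
#' heritability `vA/(vA+vE)` under each kinship flavor.
#'
#' @param x an `f23_study` tibble.
#' @param ... unused.
#' @export
tidy.f23_study <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x),
                              cols = c("vAP", "vEP", "vAG", "vEG"),
                              names_to = "stat", values_to = "estimate")
  long$component <- ifelse(substr(long$stat, 1, 2) == "vA",
                           "additive", "residual")
  long$kinship <- ifelse(substr(long$stat, 3, 3) == "G",
                         "realized (G)", "pedigree (A)")
  long[, c("replicate", "kinship", "component", "estimate")]
}

#' @rdname tidy.f23_study
#' @export
glance.f23_study <- function(x, ...) {
  tibble::tibble(
    replicates = nrow(x),
    N = attr(x, "N"), P = attr(x, "P"), target_h2 = attr(x, "h2"),
    mean_vA_A = mean(x$vAP), mean_vE_A = mean(x$vEP),
    mean_vA_G = mean(x$vAG), mean_vE_G = mean(x$vEG),
    mean_h2_A = mean(x$h2P), mean_h2_G = mean(x$h2G))
}
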