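#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the adjusted reading-frame triplet
#' @param x A [frame_statistic()] result.
#' @param ... Unused.
#' @return Tibble `frame`, `count`, `expected`.
#' @export
tidy.frame_stat <- function(x, ...) {
  tibble(frame = 0:2, count = unname(x$triplet),
         expected = rep(sum(x$triplet) / 3, 3))
}

#' @rdname tidy.frame_stat
#' @return For `glance()`: one-row tibble `statistic`, `p_value`, `df`,
#'   `n_footprints`, `n_excluded`.
#' @export
glance.frame_stat <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = 2L,
         n_footprints = sum(x$triplet), n_excluded = x$n_excluded)
}

#' Tidy differential allelic engagement results
#' @param x An [differential_allelic_engagement()] result.
#' @param ... Unused.
#' @return The per-gene call table.
#' @export
tidy.allelic_engagement <- function(x, ...) x$calls

#' @rdname tidy.allelic_engagement
#' @export
glance.allelic_engagement <- function(x, ...) {
  tibble(stage = x$stage, n_genes = nrow(x$calls),
         n_tested = sum(x$calls$eligible), n_called = sum(x$calls$called),
         B = x$B, support_frac = x$support_frac, fdr = x$fdr)
}

#' Tidy allelic bias classifications
#' @param x A [classify_allelic_bias()] result.
#' @param ... Unused.
#' @return The per-gene classification table.
#' @export
tidy.allelic_calls <- function(x, ...) x$calls

#' @rdname tidy.allelic_calls
#' @export
glance.allelic_calls <- function(x, ...) {
  tab <- table(factor(x$calls$category,
                      c("biallelic", "maternal_biased", "paternal_biased")))
  tibble(n_genes = nrow(x$calls),
         n_biallelic = unname(tab[["biallelic"]]),
         n_maternal_biased = unname(tab[["maternal_biased"]]),
         n_paternal_biased = unname(tab[["paternal_biased"]]),
         n_monoallelic = sum(x$calls$monoallelic),
         n_high_confidence = sum(x$calls$high_confidence), B = x$B)
}

#' Tidy the poly(A)-bin association summary
#' @param x A [polya_te_association()] result.
#' @param ... Unused.
#' @return Per-bin boxplot statistics.
#' @export
tidy.polya_assoc <- function(x, ...) x$bins

#' @rdname tidy.polya_assoc
#' @export
glance.polya_assoc <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n, n_bins = nrow(x$bins))
}
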