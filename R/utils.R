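#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter select group_by ungroup summarise arrange
#'   left_join inner_join anti_join semi_join bind_rows distinct n rename
#'   row_number across pull count slice if_else first tibble
#' @importFrom tibble as_tibble is_tibble
#' @importFrom stats pchisq qnorm quantile median rbinom rpois runif rlnorm
#'   setNames cor cor.test wilcox.test p.adjust ks.test sd complete.cases
#' @importFrom utils head packageVersion
NULL

# Deterministic 32-bit sub-seed from a master seed and a character key.
# Keeps replicate / stage / modality RNG streams independent and stable
# under parallel or out-of-order execution.
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = "/", collapse = "/")
  codes <- utf8ToInt(key)
  h <- sum(as.numeric(codes) * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

BASES <- c("A", "C", "G", "T")

# Sample, for each element of `base`, one of the three other nucleotides.
other_base <- function(base, n = length(base)) {
  idx <- match(base, BASES)
  shift <- sample.int(3L, n, replace = TRUE)
  BASES[(idx - 1L + shift) %% 4L + 1L]
}

geometric_mean <- function(x) exp(mean(log(x)))

# uniform integer draw on [lo, hi]; safe for degenerate lo == hi
# (base sample() would treat a length-1 vector as 1:n)
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

sample_id_of <- function(stage, modality, replicate) {
  paste(stage, modality, paste0("rep", replicate), sep = "_")
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# region of a 0-based transcript position given region lengths
position_region <- function(pos, utr5_len, cds_len) {
  dplyr::case_when(
    pos < utr5_len ~ "5UTR",
    pos < utr5_len + cds_len ~ "CDS",
    TRUE ~ "3UTR"
  )
}
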