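# Alpha diversity and the Bray-Curtis dissimilarity.

#' Shannon diversity index (nats)
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the positive entries of an
#' abundance vector, \eqn{p_i = v_i / \sum v}.  Natural logarithm; zero
#' categories are excluded.
#'
#' @param v non-negative abundance vector (counts or relative
#'   abundances) with at least one positive entry, or a matrix /
#'   count-table object (samples in rows), in which case one index per
#'   sample is returned.
#' @return Shannon index (or named vector of indices) in nats.
#' @examples
#' shannonIndex(c(10, 10, 10, 10))  # log(4)
#' @export
shannonIndex <- function(v) {
  if (is.matrix(v) || is.data.frame(v) || is(v, "SummarizedExperiment")) {
    m <- .asSampleMatrix(v)
    return(apply(m, 1L, shannonIndex))
  }
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v < 0))
    .stopf("abundances must be finite and non-negative")
  tot <- sum(v)
  if (tot <= 0) .stopf("all-zero abundance vector")
  p <- v[v > 0] / tot
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' \eqn{J = H / \ln S}, with `sTotal` the total column richness of the
#' table (so evenness is comparable across samples of the same table).
#'
#' @param H Shannon indices in nats.
#' @param sTotal total number of columns (taxa) in the table; must be
#'   at least 2.
#' @export
pielouEvenness <- function(H, sTotal) {
  if (sTotal < 2) .stopf("evenness requires richness >= 2")
  H / log(sTotal)
}

#' Map diversity values into the open unit interval
#'
#' Beta regression requires responses strictly inside (0, 1).  Mode
#' `"evenness"` first rescales Shannon values to Pielou evenness
#' \eqn{H/\ln S_{total}} and then applies the boundary squeeze; mode
#' `"squeeze"` applies only the squeeze
#' \eqn{(y (n - 1) + 0.5)/n} to values already in `[0, 1]`.
#'
#' @param values finite numeric vector (Shannon indices for
#'   `"evenness"`, unit-interval values for `"squeeze"`).
#' @param mode `"evenness"` or `"squeeze"`.
#' @param sTotal total column richness (required for `"evenness"`).
#' @param n sample size used in the squeeze; defaults to
#'   `length(values)`.
#' @return Values strictly inside (0, 1).
#' @examples
#' squeezeToUnitInterval(c(0, 0.5, 1), mode = "squeeze", n = 10)
#' @export
squeezeToUnitInterval <- function(values, mode = c("squeeze", "evenness"),
                                  sTotal = NULL, n = length(values)) {
  mode <- match.arg(mode)
  if (any(!is.finite(values))) .stopf("values must be finite")
  if (mode == "evenness") {
    if (is.null(sTotal)) .stopf("sTotal is required for evenness mode")
    values <- pielouEvenness(values, sTotal)
  }
  if (any(values < -1e-9) || any(values > 1 + 1e-9))
    .stopf("values must lie in [0, 1] before squeezing")
  values <- pmin(pmax(values, 0), 1)
  (values * (n - 1) + 0.5) / n
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{d(i, j) = \sum_c |x_{ic} - x_{jc}| / \sum_c (x_{ic} + x_{jc})},
#' bounded in `[0, 1]` and invariant to joint rescaling of both rows.
#'
#' @param x matrix or count table with samples in rows; all row totals
#'   must be positive and at least 2 samples are required.
#' @return A `dist` object labelled with sample ids.
#' @examples
#' brayCurtis(rbind(a = c(2, 1), b = c(1, 3)))  # 3/7
#' @export
brayCurtis <- function(x) {
  m <- .asSampleMatrix(x)
  if (nrow(m) < 2L) .stopf("need at least 2 samples")
  rs <- rowSums(m)
  if (any(rs <= 0))
    .stopf("zero-total sample(s): %s",
           paste(utils::head(rownames(m)[rs <= 0], 5), collapse = ", "))
  num <- stats::dist(m, method = "manhattan")
  den <- stats::as.dist(outer(rs, rs, "+"))
  d <- num / den
  attr(d, "method") <- "bray"
  d
}
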