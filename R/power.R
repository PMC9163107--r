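# Detection-power model: given a mutation observed in RNA with x alternate
# and y reference reads, what is the probability of seeing at least k
# supporting reads at DNA coverage N?  The allele fraction is integrated out
# under its Beta(x+1, y+1) posterior, giving a beta-binomial tail.

#' Site error rate from the matched normal with Laplace correction
#'
#' The noise rate at a site is estimated from the matched-normal pileup as
#' the maximal alternate-allele count over the three possible alternate
#' bases, add-one (Laplace) corrected.  The default treats the correction
#' in the binomial success/failure view, (m + 1) / (N + 2); the 4-category
#' view (m + 1) / (N + 4) is available via \code{correction}.
#'
#' @param max_alt_count maximal alt count over the three alternate alleles.
#' @param coverage total coverage at the site in the normal (> 0).
#' @param correction "binomial" (default) or "categorical".
#' @return error rate in (0, 1).
#' @export
error_rate <- function(max_alt_count, coverage,
                       correction = c("binomial", "categorical")) {
  correction <- match.arg(correction)
  if (any(coverage <= 0)) stop("error_rate: coverage must be positive",
                               call. = FALSE)
  if (any(max_alt_count < 0) || any(max_alt_count > coverage)) {
    stop("error_rate: need 0 <= max_alt_count <= coverage", call. = FALSE)
  }
  denom_add <- if (correction == "binomial") 2 else 4
  (max_alt_count + 1) / (coverage + denom_add)
}

#' Minimal alternate read count not attributable to noise
#'
#' The smallest integer k whose binomial upper tail P(X >= k) under
#' X ~ Binomial(N, r) falls strictly below \code{noise_alpha} (reads with
#' probability < 1\% of being generated by noise, by default).
#'
#' @param N DNA coverage (>= 1).
#' @param r site error rate in (0, 1).
#' @param noise_alpha noise tail bound (default 0.01, strict).
#' @return integer k_min, at most N + 1.
#' @export
min_detectable_k <- function(N, r, noise_alpha = 0.01) {
  stopifnot(N >= 1, r > 0, r < 1)
  k <- 1:(N + 1)
  upper_tail <- pbinom(k - 1, N, r, lower.tail = FALSE)  # P(X >= k)
  as.integer(k[which(upper_tail < noise_alpha)[1]])
}

#' Beta-binomial power to detect a mutation in DNA
#'
#' Probability of observing at least \code{k_min} alternate reads at DNA
#' coverage N, when the allele fraction follows the Beta(x+1, y+1) posterior
#' implied by the RNA counts:
#' power = sum over k >= k_min of C(N,k) B(k+x+1, N-k+y+1) / B(x+1, y+1),
#' evaluated in log space so large N does not overflow.
#'
#' @param x,y alternate / reference read counts in RNA (>= 0).
#' @param N DNA coverage (>= 1).
#' @param k_min minimal alternate read count (from [min_detectable_k()]).
#' @return power in [0, 1].
#' @export
detection_power <- function(x, y, N, k_min) {
  stopifnot(x >= 0, y >= 0, N >= 1, k_min >= 0)
  if (k_min > N) return(0)
  k <- k_min:N
  log_terms <- lchoose(N, k) + lbeta(k + x + 1, N - k + y + 1) -
    lbeta(x + 1, y + 1)
  min(1, sum(exp(log_terms)))
}

#' Powered-mutation decision rule
#'
#' A mutation counts as powered when its detection power strictly exceeds
#' 0.95 and it is supported by at least 4 alternate reads.
#'
#' @param power detection power in [0, 1].
#' @param alt_count alternate read count.
#' @return logical vector.
#' @export
is_powered <- function(power, alt_count) {
  power > 0.95 & alt_count >= 4
}

#' Full per-site power computation
#'
#' Convenience wrapper chaining [error_rate()], [min_detectable_k()],
#' [detection_power()] and [is_powered()].
#'
#' @param x,y RNA alternate / reference read counts.
#' @param N DNA coverage.
#' @param normal_max_alt maximal alt count in the matched normal.
#' @param normal_coverage coverage in the matched normal.
#' @param noise_alpha noise tail bound.
#' @param correction Laplace correction mode, see [error_rate()].
#' @return list with r, k_min, power, is_powered.
#' @export
site_power <- function(x, y, N, normal_max_alt, normal_coverage,
                       noise_alpha = 0.01,
                       correction = c("binomial", "categorical")) {
  r <- error_rate(normal_max_alt, normal_coverage, match.arg(correction))
  k_min <- min_detectable_k(N, r, noise_alpha)
  power <- detection_power(x, y, N, k_min)
  list(r = r, k_min = k_min, power = power,
       is_powered = is_powered(power, x))
}
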