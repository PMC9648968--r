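#' Fluorescence-bin probabilities for a fixed number of bound Pol II
#'
#' Under the trapezoidal signal profile, a polymerase at normalized position
#' x on the gene contributes signal q(x) = x L / L1 for x <= L1/L and 1
#' afterwards. With polymerases independently uniform on the gene, each
#' per-polymerase signal is Uniform(0, 1) with probability L1/L and exactly 1
#' with probability L2/L. The total signal of k polymerases is therefore a
#' binomial mixture over the number j of uniform components of a shifted
#' Irwin-Hall (uniform-sum) variable, and the probability that a sum of j
#' uniforms falls in the unit bin (i-1, i] is the Eulerian number
#' A(j, i-1) / j!, evaluated here with the normalized stable recurrence.
#' Bins are right-closed; integer atoms belong to their own-numbered bin,
#' and k = 0 puts all mass in bin 0.
#'
#' @param k Number of bound polymerases (non-negative integer).
#' @param geometry A [gene_geometry].
#' @return Numeric vector of length k + 1: probabilities of bins 0..k.
#' @examples
#' signal_conditional_bin_probs(1, gene_geometry())        # all mass in bin 1
#' signal_conditional_bin_probs(2, gene_geometry())[2]     # (L1/L)^2 / 2
#' @export
signal_conditional_bin_probs <- function(k, geometry) {
  stopifnot(inherits(geometry, "gene_geometry"))
  if (length(k) != 1 || is.na(k) || k < 0 || k != round(k)) {
    stop("k must be a single non-negative integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (k == 0L) return(1)
  .signal_bin_matrix(k, geometry)[k + 1L, ]
}

# rows of normalized Eulerian numbers: E[[j]] is the j-vector of
# P(ceiling(U1 + ... + Uj) = i), i = 1..j
.eulerian_rows <- function(j_max) {
  rows <- vector("list", j_max)
  rows[[1]] <- 1
  if (j_max >= 2) {
    for (n in 2:j_max) {
      prev <- rows[[n - 1]]
      e <- numeric(n)
      for (kk in 0:(n - 1)) {
        left <- if (kk <= n - 2) (kk + 1) * prev[kk + 1] else 0
        right <- if (kk >= 1) (n - kk) * prev[kk] else 0
        e[kk + 1] <- (left + right) / n
      }
      rows[[n]] <- e
    }
  }
  rows
}

# conditional bin matrix C with C[k + 1, i + 1] = P(bin i | k bound Pol II),
# k = 0..k_max; cached per (k_max, geometry)
.signal_cache <- new.env(parent = emptyenv())

.signal_bin_matrix <- function(k_max, geometry) {
  key <- paste0("g", signif(geometry$L1, 12), "_", signif(geometry$L2, 12))
  cached <- .signal_cache[[key]]
  if (!is.null(cached) && nrow(cached) >= k_max + 1L) {
    return(cached[seq_len(k_max + 1L), seq_len(k_max + 1L), drop = FALSE])
  }
  a <- geometry$L1 / geometry$L   # P(uniform component)
  eu <- .eulerian_rows(max(1L, k_max))
  C <- matrix(0, k_max + 1L, k_max + 1L)
  C[1L, 1L] <- 1
  for (k in seq_len(k_max)) {
    wj <- stats::dbinom(0:k, k, a)  # number of uniform (non-plateau) components
    out <- numeric(k + 1L)
    out[k + 1L] <- out[k + 1L] + wj[1]          # j = 0: atom at k -> bin k
    for (j in seq_len(k)) {
      # j uniforms shifted by the k - j plateau signals: bins k - j + (1..j)
      bins <- (k - j) + seq_len(j)
      out[bins + 1L] <- out[bins + 1L] + wj[j + 1] * eu[[j]]
    }
    C[k + 1L, seq_len(k + 1L)] <- out
  }
  .signal_cache[[key]] <- C
  C
}

#' Steady-state distribution of discretized transcription-site signal
#'
#' Mixes the conditional bin probabilities of
#' [signal_conditional_bin_probs()] over the Pol II number distribution of
#' [delay_polii_pmf()]. Before binning, the mean of the underlying continuous
#' signal is checked against the analytic identity
#' `E[k] * (L1/2 + L2) / L` with `E[k] = rho * tau * fON`.
#'
#' @param spec A [nascent_model].
#' @param eps Tail-mass tolerance (default 1e-8).
#' @param min_K Optional lower bound on the bin support.
#' @return A [burst_pmf] of kind `"signal"`: bin 0 is zero signal, bin i >= 1
#'   covers signal in (i-1, i].
#' @examples
#' s <- signal_bin_pmf(nascent_model(rate_params(2, 3, 20), tau = 0.5))
#' sum(s$probs)
#' @export
signal_bin_pmf <- function(spec, eps = 1e-8, min_K = 0L) {
  stopifnot(inherits(spec, "nascent_model"))
  pk <- delay_polii_pmf(spec, eps = eps, min_K = min_K)
  K <- pk$K
  geom <- spec$geometry

  # analytic consistency of the continuous signal mean prior to binning
  r <- spec$rates
  if (r$sigma_on + r$sigma_off > 0) {
    mean_k <- r$rho * spec$tau * r$sigma_on / (r$sigma_on + r$sigma_off)
    per_pol <- (geom$L1 / 2 + geom$L2) / geom$L
    cont_mean <- pmf_mean(pk) * per_pol
    if (mean_k > 1e-3 && abs(cont_mean - mean_k * per_pol) / (mean_k * per_pol) > 1e-4) {
      stop("continuous signal mean deviates from rho*tau*fON*(L1/2+L2)/L; ",
           "increase the truncation (eps too large?)", call. = FALSE)
    }
  }

  C <- .signal_bin_matrix(K, geom)
  bins <- as.numeric(pk$probs %*% C)
  burst_pmf(bins, "signal", eps = eps, params = spec)
}
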