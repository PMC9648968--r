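#' Observed single-cell dataset for inference
#'
#' Wraps a vector of per-cell non-negative integers: mature mRNA spot counts
#' (`"mature-counts"`) or discretized transcription-site signal bins
#' (`"nascent-bins"`), together with the gene-copy model and any curation of
#' the low bins.
#'
#' @param values Non-negative integer vector, one value per cell.
#' @param kind `"mature-counts"` or `"nascent-bins"`.
#' @param copy_mode `"one-copy"` (default), `"two-copy-independent"`
#'   (likelihood uses the single-copy distribution convolved with itself) or
#'   `"two-copy-synchronized"` (one promoter trajectory at doubled initiation
#'   rate).
#' @param curation `"none"`, `"fusion"` or `"rejection"`.
#' @param curation_k Number of low bins fused/rejected (k >= 1 when curation
#'   is set; `k = 1` fusion is the identity).
#' @return An object of class `observed_dataset`.
#' @export
observed_dataset <- function(values,
                             kind = c("mature-counts", "nascent-bins"),
                             copy_mode = c("one-copy", "two-copy-independent",
                                           "two-copy-synchronized"),
                             curation = c("none", "fusion", "rejection"),
                             curation_k = 1L) {
  kind <- match.arg(kind)
  copy_mode <- match.arg(copy_mode)
  curation <- match.arg(curation)
  if (length(values) == 0) stop("dataset is empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) || any(values != round(values))) {
    stop("values must be non-negative integers", call. = FALSE)
  }
  if (curation != "none" && curation_k < 1) {
    stop("curation_k must be >= 1", call. = FALSE)
  }
  values <- as.integer(values)
  tab <- table(values)
  structure(list(values = values, kind = kind,
                 n_cells = length(values), copy_mode = copy_mode,
                 curation = curation, curation_k = as.integer(curation_k),
                 hist = list(value = as.integer(names(tab)),
                             count = as.numeric(tab))),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cur <- if (x$curation == "none") "none" else sprintf("%s(k=%d)", x$curation, x$curation_k)
  cat(sprintf("<observed_dataset> %s, %d cells, %s, curation %s\n",
              x$kind, x$n_cells, x$copy_mode, cur))
  invisible(x)
}

#' Scale configuration for inference
#'
#' The telegraph model only identifies rates relative to the degradation
#' rate, and the delay telegraph model relative to the elongation time, so
#' one of the two must be supplied and is never inferred.
#'
#' @param d Degradation rate (1/min) for mature-count data (default 1).
#' @param tau Elongation time (min) for nascent-bin data (default 0.5).
#' @param geometry A [gene_geometry] for the trapezoidal signal.
#' @return An object of class `scale_cfg`.
#' @export
scale_cfg <- function(d = 1, tau = 0.5, geometry = gene_geometry()) {
  stopifnot(inherits(geometry, "gene_geometry"))
  if (d <= 0 || tau <= 0) stop("d and tau must be positive", call. = FALSE)
  structure(list(d = d, tau = tau, geometry = geometry), class = "scale_cfg")
}

#' Search space for the transcriptional parameters
#'
#' Box bounds for the global optimization over (sigma_on, sigma_off, rho),
#' in 1/min.
#'
#' @param lower,upper Named numeric vectors with entries `sigma_on`,
#'   `sigma_off`, `rho`.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lower = c(sigma_on = 0, sigma_off = 0, rho = 0),
                         upper = c(sigma_on = 250, sigma_off = 250, rho = 300)) {
  nm <- c("sigma_on", "sigma_off", "rho")
  if (!all(nm %in% names(lower)) || !all(nm %in% names(upper))) {
    stop("lower and upper must name sigma_on, sigma_off, rho", call. = FALSE)
  }
  lower <- lower[nm]; upper <- upper[nm]
  if (any(lower < 0) || any(upper <= lower)) {
    stop("need 0 <= lower < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "search_space")
}
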