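#' Optimizer control settings
#'
#' The global search is a self-adaptive differential evolution (jDE,
#' rand/1/bin with per-individual F and CR): robust for the low-dimensional
#' but multimodal likelihood surfaces of the telegraph family. Defaults are
#' sized so a 10^4-cell fit completes in seconds to tens of seconds;
#' `restarts` independent runs are kept and the best final likelihood wins.
#'
#' @param pop Population size (default 40).
#' @param max_gen Generation cap (default 250).
#' @param patience Stop early after this many generations without an
#'   improvement larger than `tol` (default 60).
#' @param tol Improvement tolerance for early stopping (default 1e-8).
#' @param restarts Number of independent optimizer runs (default 2).
#' @param seed Base seed for the optimizer's randomness (default 1).
#' @param eps PMF tail tolerance used inside the objective (default 1e-8).
#' @param polish Refine the best population member with a bounded
#'   quasi-Newton (L-BFGS-B) local step (default TRUE); the global search
#'   locates the likelihood basin and the local step resolves the narrow
#'   ridge the telegraph likelihood has along correlated parameters.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(pop = 40L, max_gen = 250L, patience = 60L,
                        tol = 1e-8, restarts = 2L, seed = 1L, eps = 1e-8,
                        polish = TRUE) {
  stopifnot(pop >= 5, max_gen >= 1, patience >= 1, restarts >= 1)
  structure(list(pop = as.integer(pop), max_gen = as.integer(max_gen),
                 patience = as.integer(patience), tol = tol,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 eps = eps, polish = isTRUE(polish)),
            class = "fit_control")
}

# heuristic polish starts: match the sample mean at assumed fractions ON,
# with a moderate total switching rate; clipped into the search box
.moment_starts <- function(data, scale, space) {
  m <- mean(data$values)
  if (data$copy_mode != "one-copy") m <- m / 2
  per_obs <- if (data$kind == "mature-counts") {
    1 / scale$d
  } else {
    scale$tau * (scale$geometry$L1 / 2 + scale$geometry$L2) / scale$geometry$L
  }
  f_guess <- c(0.2, 0.5, 0.8)
  k_sw <- 10  # total switching rate (1/min) for the starting guesses
  t(vapply(f_guess, function(f) {
    pmin(pmax(c(k_sw * f, k_sw * (1 - f), m / (f * per_obs)),
              space$lower + 1e-4), space$upper - 1e-4)
  }, numeric(3)))
}

# jDE: self-adaptive differential evolution, rand/1/bin. obj takes a numeric
# parameter vector and returns a finite scalar (Inf allowed for invalid).
.de_optimize <- function(obj, lower, upper, control) {
  np <- control$pop
  d <- length(lower)
  pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  f_i <- rep(0.5, np)
  cr_i <- rep(0.9, np)
  fit <- apply(pop, 1, obj)
  n_eval <- np
  best_hist <- min(fit)
  stall <- 0L
  gen <- 0L
  while (gen < control$max_gen && stall < control$patience) {
    gen <- gen + 1L
    for (i in seq_len(np)) {
      # self-adaptation of F and CR (jDE rule)
      f_new <- if (stats::runif(1) < 0.1) stats::runif(1, 0.1, 1) else f_i[i]
      cr_new <- if (stats::runif(1) < 0.1) stats::runif(1) else cr_i[i]
      r <- sample.int(np, 3)
      while (any(r == i)) r <- sample.int(np, 3)
      v <- pop[r[1], ] + f_new * (pop[r[2], ] - pop[r[3], ])
      # reflect at the box bounds
      v <- ifelse(v < lower, pmin(upper, 2 * lower - v), v)
      v <- ifelse(v > upper, pmax(lower, 2 * upper - v), v)
      jr <- sample.int(d, 1)
      cross <- stats::runif(d) < cr_new
      cross[jr] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      ft <- obj(trial)
      n_eval <- n_eval + 1L
      if (ft <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ft
        f_i[i] <- f_new
        cr_i[i] <- cr_new
      }
    }
    b <- min(fit)
    if (best_hist - b > control$tol) {
      best_hist <- b
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  ord <- order(fit)
  i_best <- ord[1]
  list(par = pop[i_best, ], value = fit[i_best], generations = gen,
       evaluations = n_eval,
       top = pop[ord[seq_len(min(5L, np))], , drop = FALSE])
}

#' Fit transcriptional parameters by maximum likelihood
#'
#' Global stochastic search (differential evolution) over the box
#' `space` minimizing [negative_log_likelihood()]. Mature-count fits return
#' rates relative to the supplied degradation rate `d`; nascent-bin fits
#' return absolute rates given the elongation time `tau`.
#'
#' @param data An [observed_dataset].
#' @param scale A [scale_cfg].
#' @param space A [search_space].
#' @param control A [fit_control].
#' @return An object of class `fit_result` with elements `theta_star`
#'   ([rate_params]), `nll`, `iterations` (objective evaluations),
#'   `generations`, `seed`, `derived` (fraction ON, burst size, effective
#'   rate), `degenerate` (TRUE when the data are all zeros), and the echoed
#'   `scale`, `space`, `data_kind`, `copy_mode`, `curation`.
#' @examples
#' \donttest{
#' cells <- simulate_mature_cells(mature_model(rate_params(7.5, 7.5, 50)),
#'                                sim_config(2000, 1))
#' fit <- fit_kinetics(observed_dataset(cells, "mature-counts"),
#'                     control = fit_control(pop = 20, max_gen = 60))
#' fit$derived$fraction_on
#' }
#' @export
fit_kinetics <- function(data, scale = scale_cfg(), space = search_space(),
                         control = fit_control()) {
  stopifnot(inherits(data, "observed_dataset"), inherits(scale, "scale_cfg"),
            inherits(space, "search_space"), inherits(control, "fit_control"))
  degenerate <- all(data$values == 0L)

  obj <- function(theta) {
    p <- tryCatch(rate_params(theta[1], theta[2], theta[3]),
                  error = function(e) NULL)
    if (is.null(p)) return(Inf)
    val <- tryCatch(
      negative_log_likelihood(data, p, scale, eps = control$eps, warn = FALSE),
      error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }

  best <- NULL
  for (r in seq_len(control$restarts)) {
    set.seed(control$seed + 101L * (r - 1L))
    run <- .de_optimize(obj, space$lower, space$upper, control)
    if (is.null(best) || run$value < best$value) best <- run
  }
  if (control$polish && is.finite(best$value)) {
    # the likelihood surface can have a secondary low-fON/high-rho mode;
    # refine several distinct leaders of the final population plus
    # moment-matched starts spanning the fraction-ON range
    starts <- unique(rbind(best$par, best$top[1:2, , drop = FALSE],
                           .moment_starts(data, scale, space)))
    starts <- starts[seq_len(min(5L, nrow(starts))), , drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      pol <- tryCatch(
        stats::optim(pmax(starts[s, ], 1e-6), obj, method = "L-BFGS-B",
                     lower = pmax(space$lower, 1e-8), upper = space$upper,
                     control = list(maxit = 100)),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value) {
        best$par <- pol$par
        best$value <- pol$value
      }
      if (!is.null(pol)) best$evaluations <- best$evaluations + sum(pol$counts)
    }
  }
  if (!is.finite(best$value)) {
    stop("optimizer failed to find a finite negative log-likelihood; ",
         "check the data and search space", call. = FALSE)
  }
  theta <- rate_params(best$par[1], best$par[2], best$par[3])
  structure(list(
    theta_star = theta,
    nll = best$value,
    iterations = best$evaluations,
    generations = best$generations,
    seed = control$seed,
    derived = tryCatch(derived_quantities(theta), error = function(e) NULL),
    degenerate = degenerate,
    ci = NULL,
    scale = scale, space = space,
    data_kind = data$kind, copy_mode = data$copy_mode,
    curation = data$curation, curation_k = data$curation_k,
    n_cells = data$n_cells
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  t <- x$theta_star
  cat(sprintf("<fit_result> %s (%s)\n", x$data_kind, x$copy_mode))
  cat(sprintf("  sigma_on = %.4g, sigma_off = %.4g, rho = %.4g (1/min)\n",
              t$sigma_on, t$sigma_off, t$rho))
  if (!is.null(x$derived)) {
    cat(sprintf("  fON = %.3f, burst size = %.3g, effective rate = %.3g\n",
                x$derived$fraction_on, x$derived$burst_size,
                x$derived$effective_rate))
  }
  cat(sprintf("  NLL = %.4f after %d evaluations%s\n", x$nll, x$iterations,
              if (x$degenerate) " [degenerate: all-zero data]" else ""))
  invisible(x)
}
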